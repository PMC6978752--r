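#' Design a mutated reporter insert that abolishes all binding sites
#'
#' Given a wild-type context containing at least one predicted binding
#' site, introduces a minimal greedy set of transversions (A<->C, G<->T)
#' so that no contiguous seed-substring match of length >= `min_match`
#' survives anywhere in the mutant.  Initial edits are placed left-to-right
#' every `min_match`-th base within each matched block, so no window of
#' `min_match` original bases survives inside a former site; the mutant is
#' then re-scanned and any residual or newly created match (e.g. at an
#' edit-flank junction) is broken by a further transversion at its centre
#' until the scanner reports zero sites.  The procedure is deterministic.
#'
#' @param wild_type_context DNA string (the candidate insert: site plus
#'   flanking context), or a [transcript_record()].
#' @param seed A [seed_query()] used for site detection and verification.
#' @param label Name for the insert.
#' @return An object of class `reporter_insert` with fields `label`,
#'   `wild_type_sequence`, `mutant_sequence`, `edited_positions` (0-based)
#'   and `seed`.  Invariants (equal length, zero sites in the mutant,
#'   >= 1 site in the wild type) are verified on construction.
#' @examples
#' ins <- design_mutant("GGTACTACCTCAGG", seed_query())
#' ins$edited_positions
#' @export
design_mutant <- function(wild_type_context, seed, label = "insert") {
  stopifnot(inherits(seed, "seed_query"))
  if (inherits(wild_type_context, "transcript_record"))
    wild_type_context <- wild_type_context$sequence
  wt <- normalize_dna(wild_type_context, what = "wild_type_context")
  if (nchar(wt) < seed$min_match)
    stop("context shorter than min_match (", seed$min_match, " nt)")
  wt_sites <- maximal_matches(wt, seed$extended_seed, seed$min_match)
  wt_sites <- merge_match_loci(wt_sites)
  if (nrow(wt_sites) == 0L)
    stop("wild-type context contains no binding site under this seed")
  wt_chars <- strsplit(wt, "", fixed = TRUE)[[1L]]
  mut <- wt_chars
  edited <- integer(0)
  transversion <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  edit_at <- function(pos0) {  # 0-based
    i <- pos0 + 1L
    if (pos0 %in% edited) {
      # already edited once: move to a base differing from both the current
      # and the wild-type base, so the edit never silently reverts
      cand <- setdiff(c("A", "C", "G", "T"), c(wt_chars[i], mut[i]))
      mut[i] <<- cand[1L]
    } else {
      mut[i] <<- transversion[[mut[i]]]
      edited <<- sort(c(edited, pos0))
    }
  }
  for (i in seq_len(nrow(wt_sites))) {
    pos <- seq(wt_sites$start[i], wt_sites$end[i] - 1L, by = seed$min_match)
    for (p in pos) edit_at(p)
  }
  for (iter in 1:25) {
    left <- maximal_matches(paste(mut, collapse = ""),
                            seed$extended_seed, seed$min_match)
    if (nrow(left) == 0L) break
    for (i in seq_len(nrow(left)))
      edit_at(left$start[i] + (left$end[i] - left$start[i]) %/% 2L)
  }
  reporter_insert(label, wt, paste(mut, collapse = ""), edited, seed)
}

#' Construct (and validate) a reporter insert
#'
#' Usually produced by [design_mutant()]; the constructor enforces the
#' invariants: equal-length sequences differing exactly at
#' `edited_positions`, at least one site in the wild type, no site in the
#' mutant.
#'
#' @param label Insert name.
#' @param wild_type_sequence,mutant_sequence Equal-length DNA strings.
#' @param edited_positions 0-based positions where the two differ.
#' @param seed The [seed_query()] used for verification.
#' @return An object of class `reporter_insert`.
#' @export
reporter_insert <- function(label, wild_type_sequence, mutant_sequence,
                            edited_positions, seed) {
  stopifnot(inherits(seed, "seed_query"),
            nchar(wild_type_sequence) == nchar(mutant_sequence))
  wt <- strsplit(wild_type_sequence, "", fixed = TRUE)[[1L]]
  mt <- strsplit(mutant_sequence, "", fixed = TRUE)[[1L]]
  diff0 <- which(wt != mt) - 1L
  if (!identical(sort(as.integer(edited_positions)), diff0))
    stop("edited_positions do not match the sequence differences")
  if (nrow(maximal_matches(wild_type_sequence, seed$extended_seed,
                           seed$min_match)) == 0L)
    stop("wild-type insert has no binding site")
  if (nrow(maximal_matches(mutant_sequence, seed$extended_seed,
                           seed$min_match)) > 0L)
    stop("mutant insert still contains a binding site")
  structure(list(label = label,
                 wild_type_sequence = wild_type_sequence,
                 mutant_sequence = mutant_sequence,
                 edited_positions = sort(as.integer(edited_positions)),
                 seed = seed),
            class = "reporter_insert")
}

#' @export
print.reporter_insert <- function(x, ...) {
  cat(sprintf("<reporter_insert> %s (%d nt, %d edit%s)\n",
              x$label, nchar(x$wild_type_sequence),
              length(x$edited_positions),
              if (length(x$edited_positions) == 1L) "" else "s"))
  cat("  WT : ", x$wild_type_sequence, "\n", sep = "")
  cat("  MUT: ", x$mutant_sequence, "\n", sep = "")
  invisible(x)
}

#' Extract a reporter context around a predicted site
#'
#' Cuts the site plus symmetric native flanks (default 10 nt each side,
#' clipped at the transcript ends) out of a transcript, ready for
#' [design_mutant()].
#'
#' @param transcript A [transcript_record()].
#' @param site One row of a [find_sites()] table.
#' @param flank Flank width in nt on each side (default 10).
#' @return List with `sequence`, `offset` (0-based start of the context on
#'   the transcript) and `label`.
#' @export
reporter_context <- function(transcript, site, flank = 10L) {
  stopifnot(inherits(transcript, "transcript_record"), nrow(site) == 1L)
  n <- nchar(transcript$sequence)
  lo <- max(0L, site$start - as.integer(flank))
  hi <- min(n, site$end + as.integer(flank))
  list(sequence = substr(transcript$sequence, lo + 1L, hi),
       offset = lo,
       label = sprintf("%s_%d_%d", transcript$transcript_id,
                       site$start, site$end))
}

#' Write wild-type/mutant inserts as FASTA plus an edit table
#'
#' @param inserts List of [reporter_insert()]s.
#' @param fasta_path,edits_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_inserts <- function(inserts, fasta_path, edits_path) {
  seqs <- unlist(lapply(inserts, function(x)
    setNames(c(x$wild_type_sequence, x$mutant_sequence),
             paste0(x$label, c("_WT", "_MUT")))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  tab <- do.call(rbind, lapply(inserts, function(x)
    data.frame(label = x$label, edited_position = x$edited_positions,
               wild_type_base = substring(x$wild_type_sequence,
                                          x$edited_positions + 1L,
                                          x$edited_positions + 1L),
               mutant_base = substring(x$mutant_sequence,
                                       x$edited_positions + 1L,
                                       x$edited_positions + 1L),
               stringsAsFactors = FALSE)))
  write.table(tab, edits_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, edits = edits_path))
}
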