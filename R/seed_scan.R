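#' Construct a seed query
#'
#' A seed query is the extended antisense seed of a miRNA written 5'->3' in
#' target-sense (DNA) orientation, plus the minimum perfect-match length.
#' The default is the let-7 configuration: extended seed `TACTACCTCA`
#' (reverse complement of the 5'-terminal decamer of mature let-7), with a
#' 6 bp minimum match.
#'
#' @param extended_seed DNA string of length `k`.
#' @param min_match Minimum perfect-match length (default 6);
#'   `1 <= min_match <= nchar(extended_seed)`.
#' @param mirna_name Optional name of the source miRNA.
#' @return An object of class `seed_query` with fields `mirna_name`,
#'   `extended_seed`, `k`, `min_match`.
#' @seealso [derive_extended_seed()] to build one from a mature miRNA.
#' @examples
#' seed_query()                       # let-7 default, TACTACCTCA / 6
#' seed_query("TACTACCTCA", min_match = 7)
#' @export
seed_query <- function(extended_seed = "TACTACCTCA", min_match = 6L,
                       mirna_name = "let-7") {
  stopifnot(is.character(extended_seed), length(extended_seed) == 1L)
  extended_seed <- normalize_dna(extended_seed, what = "extended_seed")
  if (grepl("N", extended_seed, fixed = TRUE))
    stop("extended_seed must not contain N")
  k <- nchar(extended_seed)
  min_match <- as.integer(min_match)
  if (is.na(min_match) || min_match < 1L || min_match > k)
    stop("min_match must satisfy 1 <= min_match <= ", k)
  structure(list(mirna_name = as.character(mirna_name),
                 extended_seed = extended_seed, k = k,
                 min_match = min_match),
            class = "seed_query")
}

#' @export
print.seed_query <- function(x, ...) {
  cat(sprintf("<seed_query> %s: extended seed 5'-%s-3' (k = %d, min match %d bp)\n",
              x$mirna_name, x$extended_seed, x$k, x$min_match))
  invisible(x)
}

#' Derive the extended antisense seed from a mature miRNA
#'
#' Takes the 5'-terminal `k` nucleotides of the mature miRNA and returns
#' their DNA reverse complement as a [seed_query()].  For mature let-7
#' (5'-UGAGGUAGUA...) with `k = 10` this yields `TACTACCTCA`.
#'
#' @param mirna A [microrna()].
#' @param k Extended-seed length (default 10); must not exceed the miRNA
#'   length and must be >= `min_match`.
#' @param min_match Minimum perfect-match length (default 6).
#' @return A [seed_query()].
#' @examples
#' derive_extended_seed(microrna("let-7g", "UGAGGUAGUAGUUUGUACAGUU"))
#' @export
derive_extended_seed <- function(mirna, k = 10L, min_match = 6L) {
  stopifnot(inherits(mirna, "microrna"))
  k <- as.integer(k)
  if (k > nchar(mirna$mature_sequence))
    stop("k = ", k, " exceeds miRNA length ", nchar(mirna$mature_sequence))
  if (k < min_match)
    stop("k = ", k, " is smaller than min_match = ", min_match)
  five_prime <- substr(mirna$mature_sequence, 1L, k)
  dna <- chartr("U", "T", five_prime)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  seed_query(rc, min_match = min_match, mirna_name = mirna$name)
}

#' Find binding sites: contiguous seed-substring matches in a transcript
#'
#' Enumerates every maximal contiguous exact match of length >=
#' `seed$min_match` between the transcript (sense strand) and any substring
#' of the extended seed.  A match is maximal when it cannot be extended by
#' one base on either side while still matching the seed; `N` in the
#' transcript never matches.  With `merge_overlaps = TRUE` (default),
#' maximal matches whose transcript intervals overlap are collapsed into a
#' single site spanning their union — one site per locus, as a site diagram
#' draws one tick per locus — recording the longest constituent `match_len`
#' and its `seed_offset` (ties broken toward the smaller offset).
#'
#' @param transcript A [transcript_record()].
#' @param seed A [seed_query()].
#' @param merge_overlaps Collapse overlapping maximal matches into one site
#'   per locus?  If `FALSE`, each maximal match is reported separately.
#' @return A data.frame with one row per site, columns `transcript_id`,
#'   `start`, `end` (0-based, half-open), `match_len`, `seed_offset`,
#'   `region` (label at the site start), `straddles_boundary` (site spans a
#'   region boundary) and `conserved` (logical, `NA` until filled by
#'   [classify_sites()]), sorted by `start`.
#' @examples
#' tx <- transcript_record("t", "GGGTACTACCTCAGG", 0, 15)
#' find_sites(tx, seed_query())
#' @export
find_sites <- function(transcript, seed, merge_overlaps = TRUE) {
  stopifnot(inherits(transcript, "transcript_record"),
            inherits(seed, "seed_query"))
  m <- maximal_matches(transcript$sequence, seed$extended_seed,
                       seed$min_match)
  if (merge_overlaps) m <- merge_match_loci(m)
  empty_site_df <- function() data.frame(
    transcript_id = character(), start = integer(), end = integer(),
    match_len = integer(), seed_offset = integer(), region = character(),
    straddles_boundary = logical(), conserved = logical(),
    stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty_site_df())
  data.frame(
    transcript_id = transcript$transcript_id,
    start = m$start, end = m$end,
    match_len = m$match_len, seed_offset = m$seed_offset,
    region = region_of(transcript, m$start),
    straddles_boundary =
      region_of(transcript, m$start) != region_of(transcript, m$end - 1L),
    conserved = NA,
    stringsAsFactors = FALSE)
}

# All maximal diagonal runs of equality between sequence and seed substrings
# of length >= min_match.  Returns start/end (0-based half-open, transcript
# coordinates), match_len, seed_offset, sorted by (start, seed_offset).
#
# L[i, j] is the length of the diagonal run of matching bases ending at
# transcript position i paired with seed position j; a run is maximal when
# the next diagonal cell does not match (or either sequence ends).
maximal_matches <- function(sequence, seed, min_match) {
  tx <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sd <- strsplit(seed, "", fixed = TRUE)[[1L]]
  n <- length(tx); k <- length(sd)
  if (n < min_match)
    return(data.frame(start = integer(), end = integer(),
                      match_len = integer(), seed_offset = integer()))
  M <- vapply(sd, function(ch) tx == ch, logical(n))  # n x k
  L <- matrix(0L, n, k)
  L[, 1L] <- M[, 1L]
  if (k > 1L) for (j in 2L:k) {
    L[1L, j] <- M[1L, j]
    L[2L:n, j] <- ifelse(M[2L:n, j], L[1L:(n - 1L), j - 1L] + 1L, 0L)
  }
  ext <- matrix(FALSE, n, k)  # run extendable past (i, j)?
  if (k > 1L) ext[1L:(n - 1L), 1L:(k - 1L)] <- M[2L:n, 2L:k]
  hit <- which(L >= min_match & !ext)
  i <- (hit - 1L) %% n + 1L
  j <- (hit - 1L) %/% n + 1L
  len <- L[hit]
  out <- data.frame(start = i - len, end = i, match_len = len,
                    seed_offset = j - len, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$seed_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Collapse maximal matches with overlapping transcript intervals into one
# locus spanning their union; representative = longest match_len, ties to
# the smaller seed_offset.  Input must be sorted by start.
merge_match_loci <- function(m) {
  if (nrow(m) <= 1L) { rownames(m) <- NULL; return(m) }
  grp <- integer(nrow(m)); grp[1L] <- 1L; hi <- m$end[1L]
  for (i in 2L:nrow(m)) {
    if (m$start[i] < hi) grp[i] <- grp[i - 1L]
    else grp[i] <- grp[i - 1L] + 1L
    hi <- max(hi, m$end[i])
  }
  merged <- lapply(split(seq_len(nrow(m)), grp), function(ix) {
    blk <- m[ix, , drop = FALSE]
    rep <- blk[order(-blk$match_len, blk$seed_offset), , drop = FALSE][1L, ]
    data.frame(start = min(blk$start), end = max(blk$end),
               match_len = rep$match_len, seed_offset = rep$seed_offset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Scan a set of transcripts and bind the results
#'
#' @param transcripts List of [transcript_record()]s.
#' @inheritParams find_sites
#' @return One data.frame of sites across all transcripts (see
#'   [find_sites()] for columns).
#' @export
scan_transcripts <- function(transcripts, seed, merge_overlaps = TRUE) {
  res <- lapply(transcripts, find_sites, seed = seed,
                merge_overlaps = merge_overlaps)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write / read a site table (BED-like TSV)
#'
#' Columns: `transcript_id`, `start`, `end`, `name`
#' (`<mirna>:<seed_offset>`), `match_len`, `region`, `conserved`.
#' Header comment lines beginning `#` are ignored on read.
#'
#' @param sites Site data.frame from [find_sites()]/[scan_transcripts()].
#' @param path Output path.
#' @param seed The [seed_query()] used (for the `name` column).
#' @param comments Optional character vector written as leading `#` lines.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(sites, path, seed = seed_query(),
                             comments = character()) {
  tab <- data.frame(
    transcript_id = sites$transcript_id, start = sites$start,
    end = sites$end,
    name = sprintf("%s:%d", seed$mirna_name, sites$seed_offset),
    match_len = sites$match_len, region = sites$region,
    conserved = sites$conserved, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
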