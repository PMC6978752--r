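#' Optimal global pairwise alignment of two transcript sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed via
#' [Biostrings::pairwiseAlignment()] (`type = "global"`, so terminal gaps
#' are penalized).  A gap of length `L` scores `gap_open + L * gap_extend`.
#' Defaults are standard DNA parameters (match +2, mismatch -1, gap open
#' -4, gap extend -1); alignment software differs in its unstated defaults,
#' so all four are exposed.
#'
#' @param seq_a,seq_b DNA sequences (character scalars or
#'   [transcript_record()]s), nonempty.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters;
#'   `gap_open` and `gap_extend` are penalties (non-positive).
#' @return An object of class `pairwise_alignment` with fields `aligned_a`,
#'   `aligned_b` (gapped strings, `-` for gaps), `score`, `a_to_column`,
#'   `b_to_column` (1-based alignment column of each ungapped position) and
#'   `scoring_params`.
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(seq_a, seq_b, match = 2, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  if (inherits(seq_a, "transcript_record")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "transcript_record")) seq_b <- seq_b$sequence
  stopifnot(is.character(seq_a), is.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap_open and gap_extend are penalties and must be <= 0")
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  out <- structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b,
         score = Biostrings::score(aln),
         a_to_column = which(ca != "-"), b_to_column = which(cb != "-"),
         scoring_params = c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)),
    class = "pairwise_alignment")
  stopifnot(gsub("-", "", aligned_a, fixed = TRUE) == seq_a,
            gsub("-", "", aligned_b, fixed = TRUE) == seq_b)
  out
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  n <- nchar(x$aligned_a)
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f\n", n, x$score))
  show <- min(n, width)
  cat("A: ", substr(x$aligned_a, 1, show),
      if (n > width) "..." else "", "\n", sep = "")
  cat("B: ", substr(x$aligned_b, 1, show),
      if (n > width) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Project an interval through a global alignment
#'
#' Maps a 0-based half-open interval on sequence A to the smallest interval
#' on sequence B whose alignment columns cover the A-interval's columns.
#' When every A position in the interval is aligned to a gap, the result is
#' an empty interval anchored at the insertion point in B.
#'
#' @param alignment A [global_align()] result.
#' @param interval Integer `c(start, end)`, 0-based half-open, within
#'   sequence A.
#' @return List with `start`, `end` (0-based half-open in B; `start == end`
#'   for an empty projection) and `empty` (logical).
#' @export
project_interval <- function(alignment, interval) {
  stopifnot(inherits(alignment, "pairwise_alignment"),
            length(interval) == 2L)
  start <- as.integer(interval[1L]); end <- as.integer(interval[2L])
  na <- length(alignment$a_to_column)
  if (is.na(start) || is.na(end) || start < 0L || end > na || start >= end)
    stop("interval [", start, ", ", end, ") out of bounds for sequence A (length ",
         na, ")")
  cols <- alignment$a_to_column[(start + 1L):end]
  lo <- min(cols); hi <- max(cols)
  idx <- which(alignment$b_to_column >= lo & alignment$b_to_column <= hi)
  if (length(idx) == 0L) {
    anchor <- sum(alignment$b_to_column < lo)
    return(list(start = anchor, end = anchor, empty = TRUE))
  }
  list(start = min(idx) - 1L, end = max(idx), empty = FALSE)
}

# Alignment columns occupied by an ungapped [start, end) interval.
interval_columns <- function(to_column, start, end) {
  to_column[(start + 1L):end]
}

#' Classify sites as conserved between ortholog transcripts
#'
#' Realizes the conservation criterion: a site on transcript A is conserved
#' when, under the optimal global pairwise alignment of the two ortholog
#' transcripts, its position is retained — operationally, when its alignment
#' columns share at least `min_overlap` columns (columns where both
#' sequences have bases) with some site on transcript B.  The default
#' threshold equals the scanner's minimum match length, keeping one
#' parameter family.
#'
#' @param transcript_a,transcript_b The ortholog [transcript_record()]s.
#' @param sites_a,sites_b Site tables from [find_sites()] run on the
#'   respective transcripts.
#' @param alignment Optional precomputed [global_align()] of the two
#'   transcript sequences (checked against them); computed if missing.
#' @param min_overlap Minimum shared alignment columns (default 6).
#' @param ... Scoring parameters passed to [global_align()] when
#'   `alignment` is not supplied.
#' @return A data.frame with one row per A site: the site columns plus
#'   `proj_start`, `proj_end` (projected interval in B coordinates),
#'   `overlap_columns` (best shared-column count over B sites, 0 if none)
#'   and `conserved`.
#' @export
classify_sites <- function(transcript_a, transcript_b, sites_a, sites_b,
                           alignment = NULL, min_overlap = 6L, ...) {
  stopifnot(inherits(transcript_a, "transcript_record"),
            inherits(transcript_b, "transcript_record"))
  if (is.null(alignment)) {
    alignment <- global_align(transcript_a, transcript_b, ...)
  } else {
    stopifnot(inherits(alignment, "pairwise_alignment"))
    if (gsub("-", "", alignment$aligned_a, fixed = TRUE) !=
        transcript_a$sequence ||
        gsub("-", "", alignment$aligned_b, fixed = TRUE) !=
        transcript_b$sequence)
      stop("alignment was not built from this transcript pair")
  }
  n_a <- nrow(sites_a)
  proj_start <- proj_end <- integer(n_a)
  overlap <- integer(n_a)
  b_cols <- lapply(seq_len(nrow(sites_b)), function(j)
    interval_columns(alignment$b_to_column, sites_b$start[j], sites_b$end[j]))
  for (i in seq_len(n_a)) {
    a_cols <- interval_columns(alignment$a_to_column,
                               sites_a$start[i], sites_a$end[i])
    pr <- project_interval(alignment, c(sites_a$start[i], sites_a$end[i]))
    proj_start[i] <- pr$start; proj_end[i] <- pr$end
    overlap[i] <- if (length(b_cols))
      max(vapply(b_cols, function(bc) sum(a_cols %in% bc), 0L)) else 0L
  }
  out <- sites_a
  out$proj_start <- proj_start
  out$proj_end <- proj_end
  out$overlap_columns <- overlap
  out$conserved <- overlap >= as.integer(min_overlap)
  out
}

#' Call conservation for an ortholog pair, both directions
#'
#' Scans both transcripts (unless site tables are given), aligns them once,
#' and fills the `conserved` column in each direction.
#'
#' @inheritParams classify_sites
#' @param seed A [seed_query()] used when `sites_a`/`sites_b` are missing.
#' @return List with `calls_a`, `calls_b` (see [classify_sites()]) and
#'   `alignment`.
#' @export
conserve_pair <- function(transcript_a, transcript_b, seed = seed_query(),
                          sites_a = NULL, sites_b = NULL,
                          min_overlap = 6L, ...) {
  if (is.null(sites_a)) sites_a <- find_sites(transcript_a, seed)
  if (is.null(sites_b)) sites_b <- find_sites(transcript_b, seed)
  aln <- global_align(transcript_a, transcript_b, ...)
  calls_a <- classify_sites(transcript_a, transcript_b, sites_a, sites_b,
                            alignment = aln, min_overlap = min_overlap)
  aln_ba <- structure(
    list(aligned_a = aln$aligned_b, aligned_b = aln$aligned_a,
         score = aln$score, a_to_column = aln$b_to_column,
         b_to_column = aln$a_to_column,
         scoring_params = aln$scoring_params),
    class = "pairwise_alignment")
  calls_b <- classify_sites(transcript_b, transcript_a, sites_b, sites_a,
                            alignment = aln_ba, min_overlap = min_overlap)
  list(calls_a = calls_a, calls_b = calls_b, alignment = aln)
}
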