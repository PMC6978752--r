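# Independent oracles used across the suite.
#
# oracle_sites():      brute-force site enumeration via Biostrings::matchPattern
#                      over every seed substring, maximality filter, and an
#                      IRanges-based merge — a different route from the
#                      package's diagonal run-length scanner.
# gotoh_score():       independent affine-gap global alignment DP (row-wise,
#                      cummax trick for the horizontal gap state).
# enumerate_align_best(): literal enumeration of all global alignments of two
#                      tiny strings with affine gap-run scoring; validates the
#                      DP oracle itself.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_sites <- function(sequence, seed_str = "TACTACCTCA",
                         min_match = 6L, merge = TRUE) {
  subj <- Biostrings::DNAString(sequence)
  k <- nchar(seed_str); n <- nchar(sequence)
  rows <- list()
  for (len in min_match:k) {
    for (off in 0:(k - len)) {
      pat <- substr(seed_str, off + 1L, off + len)
      st0 <- Biostrings::start(
        Biostrings::matchPattern(pat, subj, fixed = TRUE)) - 1L
      for (s in st0) {
        end0 <- s + len
        left_ext <- s > 0L && off > 0L &&
          substr(sequence, s, s) == substr(seed_str, off, off)
        right_ext <- end0 < n && off + len < k &&
          substr(sequence, end0 + 1L, end0 + 1L) ==
            substr(seed_str, off + len + 1L, off + len + 1L)
        if (!left_ext && !right_ext)
          rows[[length(rows) + 1L]] <- c(s, end0, len, off)
      }
    }
  }
  out <- if (length(rows))
    as.data.frame(do.call(rbind, rows)) else
    data.frame(V1 = integer(), V2 = integer(), V3 = integer(),
               V4 = integer())
  names(out) <- c("start", "end", "match_len", "seed_offset")
  out <- out[order(out$start, out$seed_offset), , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  if (!merge || nrow(out) <= 1L) return(out)
  ir <- IRanges::IRanges(out$start + 1L, out$end)
  # min.gapwidth = 0: merge overlapping intervals only, not abutting ones
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  grp <- IRanges::findOverlaps(ir, red, select = "first")
  merged <- do.call(rbind, lapply(seq_along(red), function(g) {
    blk <- out[grp == g, , drop = FALSE]
    rep <- blk[order(-blk$match_len, blk$seed_offset), ][1L, ]
    data.frame(start = IRanges::start(red)[g] - 1L,
               end = IRanges::end(red)[g],
               match_len = rep$match_len, seed_offset = rep$seed_offset)
  }))
  rownames(merged) <- NULL
  merged
}

gotoh_score <- function(a, b, match = 2, mismatch = -1,
                        gap_open = -4, gap_extend = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  go <- -gap_open; ge <- -gap_extend
  NEG <- -1e18
  M <- c(0, rep(NEG, m))
  F <- rep(NEG, m + 1L)
  E <- c(NEG, -(go + (1:m) * ge))
  for (i in seq_len(n)) {
    s <- ifelse(B == A[i], match, mismatch)
    best_prev <- pmax(M, E, F)
    Fi <- pmax(F, M - go) - ge
    Mi <- c(NEG, best_prev[1:m] + s)
    cm <- cummax(Mi + (0:m) * ge)
    Ei <- c(NEG, cm[1:m] - go - (1:m) * ge)
    M <- Mi; E <- Ei; F <- Fi
  }
  max(M[m + 1L], E[m + 1L], F[m + 1L])
}

# All global alignments of two tiny strings, affine gap-run scoring.
# Allows adjacent opposite gaps, so only valid as a cross-check where
# mismatch > 2 * (gap_open + gap_extend).
enumerate_align_best <- function(a, b, match = 2, mismatch = -1,
                                 gap_open = -4, gap_extend = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, "M",
          sc + if (A[i] == B[j]) match else mismatch)
    if (i <= length(A))
      rec(i + 1L, j, "F",
          sc + gap_extend + if (prev != "F") gap_open else 0)
    if (j <= length(B))
      rec(i, j + 1L, "E",
          sc + gap_extend + if (prev != "E") gap_open else 0)
  }
  rec(1L, 1L, "M", 0)
  best
}

# Random transcript around a fixed region layout, as a transcript_record.
random_transcript <- function(n, gc = 0.5, id = "rtx") {
  cds_start <- max(1L, round(0.2 * n))
  cds_end <- max(cds_start + 1L, round(0.7 * n))
  transcript_record(id, random_dna(n, gc), cds_start, cds_end)
}

site_core <- function(df) {
  out <- df[, c("start", "end", "match_len", "seed_offset")]
  rownames(out) <- NULL
  out
}
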