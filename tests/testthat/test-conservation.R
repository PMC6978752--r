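# Build a pairwise_alignment by hand from two gapped strings (for tests of
# projection logic with a known column layout).
manual_alignment <- function(aligned_a, aligned_b, score = 0) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, a_to_column = which(ca != "-"),
                 b_to_column = which(cb != "-"),
                 scoring_params = c(match = 2, mismatch = -1,
                                    gap_open = -4, gap_extend = -1)),
            class = "pairwise_alignment")
}

test_that("global alignment scores known small instances", {
  id <- global_align("ACGT", "ACGT", match = 2)
  expect_equal(id$score, 8)
  expect_false(grepl("-", id$aligned_a, fixed = TRUE))

  gap1 <- global_align("ACGT", "ACT")
  expect_equal(gap1$score, gotoh_score("ACGT", "ACT"))
  expect_equal(gap1$score, 1)  # 3 matches - (open 4 + extend 1)
  expect_equal(lengths(regmatches(gap1$aligned_b,
                                  gregexpr("-", gap1$aligned_b))), 1L)

  # all-mismatch beats gapping under these penalties
  mm <- global_align("AAAA", "TTTT", match = 2, mismatch = -1)
  expect_equal(mm$score, -4)
  expect_false(grepl("-", mm$aligned_a, fixed = TRUE))

  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment invariants hold: degapping recovers inputs, columns map bases", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_dna(sample(5:80, 1)); b <- random_dna(sample(5:80, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", al$aligned_b, fixed = TRUE), b)
    expect_equal(length(al$a_to_column), nchar(a))
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("alignment score equals the independent affine DP oracle", {
  # the DP oracle itself is validated against literal enumeration first
  set.seed(32)
  for (i in 1:60) {
    a <- random_dna(sample(1:5, 1)); b <- random_dna(sample(1:5, 1))
    expect_equal(gotoh_score(a, b), enumerate_align_best(a, b))
  }
  for (i in 1:120) {
    a <- random_dna(sample(1:12, 1)); b <- random_dna(sample(1:12, 1))
    expect_equal(global_align(a, b)$score, gotoh_score(a, b))
  }
  # alternative scoring parameters
  for (i in 1:40) {
    a <- random_dna(sample(2:12, 1)); b <- random_dna(sample(2:12, 1))
    expect_equal(
      global_align(a, b, match = 1, mismatch = -2,
                   gap_open = -5, gap_extend = -2)$score,
      gotoh_score(a, b, match = 1, mismatch = -2,
                  gap_open = -5, gap_extend = -2))
  }
  for (i in 1:25) {
    a <- random_dna(sample(50:200, 1)); b <- random_dna(sample(50:200, 1))
    expect_equal(global_align(a, b)$score, gotoh_score(a, b))
  }
})

test_that("interval projection follows alignment columns", {
  # identity alignment: interval maps to itself
  id <- global_align(strrep("ACGT", 5), strrep("ACGT", 5))
  pr <- project_interval(id, c(3, 13))
  expect_equal(c(pr$start, pr$end), c(3L, 13L))

  # hand-traced gapped alignment: A AACCC / B A-CCC
  al <- manual_alignment("AACCC", "A-CCC")
  pr <- project_interval(al, c(2, 5))
  expect_equal(c(pr$start, pr$end), c(1L, 4L))
  expect_false(pr$empty)

  # interval aligned wholly to gaps -> empty, anchored at insertion point
  al2 <- manual_alignment("AATTAA", "AA--AA")
  pr2 <- project_interval(al2, c(2, 4))
  expect_true(pr2$empty)
  expect_equal(pr2$start, 2L)
  expect_equal(pr2$end, 2L)

  expect_error(project_interval(al, c(4, 6)), "out of bounds")
})

test_that("projection is monotone over nested intervals", {
  set.seed(33)
  for (i in 1:15) {
    a <- random_dna(120); b <- random_dna(sample(90:150, 1))
    al <- global_align(a, b)
    s <- sort(sample(0:119, 4))
    outer <- project_interval(al, c(s[1], s[4] + 1))
    inner <- project_interval(al, c(s[2], s[3] + 1))
    expect_true(inner$start >= outer$start)
    expect_true(inner$end <= outer$end)
  }
})

test_that("conservation calls follow shared-column overlap against the threshold", {
  sq <- seed_query()
  # identical orthologs sharing one planted site -> conserved
  g <- generate_transcript(250, plants = data.frame(
    region = "UTR3", offset = 15, match_len = 10, seed_offset = 0),
    rng_seed = 41)
  o0 <- generate_ortholog(g$transcript, g$truth, substitution_rate = 0,
                          indel_rate = 0, rng_seed = 42)
  expect_equal(o0$transcript$sequence, g$transcript$sequence)
  cp <- conserve_pair(g$transcript, o0$transcript, seed = sq)
  expect_true(all(cp$calls_a$conserved))
  expect_true(all(cp$calls_b$conserved))
  expect_equal(cp$calls_a$overlap_columns, 10L)

  # site ablated in the ortholog -> non-conserved
  oa <- generate_ortholog(g$transcript, g$truth, substitution_rate = 0,
                          indel_rate = 0, preserve_planted_sites = FALSE,
                          rng_seed = 43)
  expect_equal(nrow(oa$truth), 0L)
  cpa <- conserve_pair(g$transcript, oa$transcript, seed = sq)
  expect_false(any(cpa$calls_a$conserved))

  # manual column bookkeeping: 10-bp sites overlapping in only 4 columns
  # stay below the 6-column threshold, 6 shared columns reach it
  txa <- transcript_record("a", paste0(strrep("G", 4), "TACTACCTCA",
                                       strrep("G", 10)), 0, 24)
  txb <- transcript_record("b", paste0(strrep("G", 10), "TACTACCTCA",
                                       strrep("G", 4)), 0, 24)
  sa <- find_sites(txa, sq); sb <- find_sites(txb, sq)
  al <- manual_alignment(txa$sequence, txb$sequence)  # ungapped overlay
  # A site occupies columns 5..14, B site columns 11..20 -> 4 shared
  calls <- classify_sites(txa, txb, sa, sb, alignment = al)
  expect_equal(calls$overlap_columns, 4L)
  expect_false(calls$conserved)
  calls4 <- classify_sites(txa, txb, sa, sb, alignment = al,
                           min_overlap = 4)
  expect_true(calls4$conserved)

  # alignment not built from the pair -> error
  expect_error(classify_sites(txa, g$transcript, sa, g$truth,
                              alignment = al), "not built")
})

test_that("conserved fraction is non-increasing with substitution divergence", {
  sq <- seed_query()
  set.seed(44)
  rates <- c(0, 0.1, 0.3)
  frac <- vapply(rates, function(r) {
    calls <- integer(0)
    for (i in 1:8) {
      g <- generate_transcript(300, plants = sample_plants(2, 300, sq),
                               seed = sq, rng_seed = 50 + i)
      o <- generate_ortholog(g$transcript, g$truth, substitution_rate = r,
                             indel_rate = 0.002, rng_seed = 500 + i)
      cp <- conserve_pair(g$transcript, o$transcript, seed = sq)
      shared <- cp$calls_a$start %in% g$truth$start[o$survived]
      calls <- c(calls, cp$calls_a$conserved[shared])
    }
    mean(calls)
  }, 0)
  expect_equal(frac[1], 1)                 # zero divergence: all conserved
  expect_true(all(diff(frac) <= 0.15))     # non-increasing up to sampling error
  expect_true(frac[3] <= frac[1])
})
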