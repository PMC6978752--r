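test_that("planted sites are recovered exactly and backgrounds are seed-free", {
  sq <- seed_query()
  g <- generate_transcript(500, plants = data.frame(
    region = "UTR3", offset = 40, match_len = 10, seed_offset = 0),
    seed = sq, rng_seed = 81)
  found <- find_sites(g$transcript, sq)
  expect_equal(nrow(found), 1L)
  expect_equal(site_core(found), site_core(g$truth))
  expect_equal(found$region, "UTR3")

  empty <- generate_transcript(500, rng_seed = 82)
  expect_equal(nrow(find_sites(empty$transcript, sq)), 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("generation is bit-reproducible under a fixed seed", {
  plants <- data.frame(region = c("CDS", "UTR3"), offset = c(5, 20),
                       match_len = c(7, 10), seed_offset = c(1, 0))
  a <- generate_transcript(400, plants = plants, rng_seed = 83)
  b <- generate_transcript(400, plants = plants, rng_seed = 83)
  expect_identical(a$transcript$sequence, b$transcript$sequence)
  expect_identical(a$truth, b$truth)

  o1 <- generate_ortholog(a$transcript, a$truth, rng_seed = 84)
  o2 <- generate_ortholog(a$transcript, a$truth, rng_seed = 84)
  expect_identical(o1$transcript$sequence, o2$transcript$sequence)

  t1 <- generate_assay_tables(rng_seed = 85)
  t2 <- generate_assay_tables(rng_seed = 85)
  expect_identical(as.data.frame(t1$luciferase), as.data.frame(t2$luciferase))
  expect_identical(as.data.frame(t1$clinical_score),
                   as.data.frame(t2$clinical_score))
})

test_that("infeasible plant layouts are rejected with diagnostics", {
  sq <- seed_query()
  expect_error(generate_transcript(100, plants = data.frame(
    region = "UTR5", offset = 10, match_len = 10, seed_offset = 0),
    rng_seed = 1), "does not fit")
  expect_error(generate_transcript(300, plants = data.frame(
    region = c("UTR3", "UTR3"), offset = c(10, 14),
    match_len = c(10, 10), seed_offset = c(0, 0)),
    rng_seed = 1), "separated")
  expect_error(generate_transcript(300, plants = data.frame(
    region = "UTR3", offset = 10, match_len = 5, seed_offset = 0),
    rng_seed = 1), "match_len")
  expect_error(generate_transcript(300, plants = data.frame(
    region = "UTR3", offset = 10, match_len = 8, seed_offset = 5),
    rng_seed = 1), "seed_offset")
})

test_that("random plant layouts are valid across regions and recovered at 100%", {
  sq <- seed_query()
  set.seed(86)
  regions_seen <- character(0)
  for (i in 1:40) {
    n <- sample(300:600, 1)
    plants <- sample_plants(sample(1:3, 1), n, sq)
    g <- generate_transcript(n, plants = plants, seed = sq)
    found <- find_sites(g$transcript, sq)
    expect_equal(site_core(found), site_core(g$truth))
    expect_equal(nrow(found), nrow(plants))
    regions_seen <- c(regions_seen, g$truth$region)
  }
  expect_setequal(unique(regions_seen), c("UTR5", "CDS", "UTR3"))
})

test_that("ortholog generation preserves or ablates planted sites as requested", {
  sq <- seed_query()
  g <- generate_transcript(400, plants = data.frame(
    region = c("CDS", "UTR3"), offset = c(20, 30),
    match_len = c(8, 10), seed_offset = c(1, 0)), rng_seed = 87)

  # zero divergence: identical sequence, all sites survive in place
  o0 <- generate_ortholog(g$transcript, g$truth, substitution_rate = 0,
                          indel_rate = 0, rng_seed = 88)
  expect_identical(o0$transcript$sequence, g$transcript$sequence)
  expect_true(all(o0$survived))
  expect_equal(site_core(o0$truth), site_core(g$truth))

  # with indels, surviving blocks are found verbatim at their new coordinates
  oi <- generate_ortholog(g$transcript, g$truth, substitution_rate = 0.05,
                          indel_rate = 0.02, rng_seed = 89)
  found <- find_sites(oi$transcript, sq)
  for (j in seq_len(nrow(oi$truth))) {
    hit <- found[found$start <= oi$truth$start[j] &
                 found$end >= oi$truth$end[j], , drop = FALSE]
    expect_gte(nrow(hit), 1L)
  }

  # forced ablation: none of the planted sites remain detectable
  oa <- generate_ortholog(g$transcript, g$truth,
                          preserve_planted_sites = FALSE, rng_seed = 90)
  expect_equal(nrow(oa$truth), 0L)
  expect_false(any(oa$survived))
  fa <- find_sites(oa$transcript, sq)
  if (nrow(fa)) {
    # no surviving site overlaps a former planted locus
    for (j in seq_len(nrow(g$truth)))
      expect_false(any(fa$start < g$truth$end[j] + 5 &
                       fa$end > g$truth$start[j] - 5))
  }
})

test_that("assay generator recovers declared effects and degenerates exactly", {
  # parameter recovery: 50% repression at n = 3, lognormal noise
  tabs <- generate_assay_tables(assay_effect_model(
    rlu_constructs = c(control = 1, wt_site = 0.5), rlu_sdlog = 0.2,
    n_replicates = 3L), rng_seed = 91)
  q <- quantify_assay(tabs$luciferase)
  wt <- q$value[q$group_label == "wt_site"]
  ctl <- q$value[q$group_label == "control"]
  sem3 <- sqrt(exp(2 * 0.2^2) - 1) / sqrt(3)  # lognormal ratio CV / sqrt(n)
  expect_lt(abs(mean(wt) / mean(ctl) - 0.5), 3 * sem3)

  # zero-noise model: quantification returns the declared truth exactly
  zn <- assay_effect_model(
    rlu_constructs = c(a = 0.5, b = 1.25), rlu_sdlog = 0,
    transwell_folds = data.frame(
      group_label = "WT", condition = c("control", "chemokine"),
      fold = c(1, 2.5)),
    transwell_control_mean = 80, transwell_poisson = FALSE,
    qpcr_folds = data.frame(group_label = "WT", gene = "Ccr2", fold = 4),
    ct_sd = 0,
    clinical_trajectories = data.frame(group_label = "WT", day = c(10, 12),
                                       true_mean = c(1, 3)),
    clinical_sd = 0)
  ztabs <- generate_assay_tables(zn, rng_seed = 92)
  expect_equal(unique(quantify_assay(ztabs$luciferase)$value), c(0.5, 1.25))
  qz <- quantify_assay(ztabs$transwell)
  expect_equal(sort(unique(qz$value)), c(100, 250))
  expect_equal(unique(quantify_assay(ztabs$qpcr)$value), 4)
  cz <- quantify_assay(ztabs$clinical_score)
  expect_equal(cz$mean_score, c(1, 3))
  expect_equal(cz$sem, c(0, 0))

  expect_error(assay_effect_model(rlu_constructs = c(a = -1)), "rlu")
})
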