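test_that("RLU, percent chemotaxis and relative expression match their closed forms", {
  expect_equal(rlu(1000, 500), 2.0)
  expect_equal(rlu(0, 500), 0.0)
  expect_error(rlu(100, 0), "undefined")
  expect_error(rlu(-5, 100), "non-negative")

  expect_equal(percent_chemotaxis(200, 100), 200.0)
  expect_equal(percent_chemotaxis(100, 100), 100.0)  # control defined as 100%
  expect_equal(percent_chemotaxis(0, 100), 0.0)
  expect_error(percent_chemotaxis(50, 0), "undefined")

  expect_equal(relative_expression(20, 20), 1.0)
  expect_equal(relative_expression(19, 20), 2.0)
  expect_equal(relative_expression(23, 20), 0.125)
  expect_error(relative_expression(NA, 20), "finite")
})

test_that("normalizations are scale-invariant and log-linear", {
  set.seed(71)
  for (i in 1:20) {
    f <- runif(1, 10, 1e6); r <- runif(1, 10, 1e6); c <- runif(1, 0.1, 50)
    expect_equal(rlu(c * f, c * r), rlu(f, r))
    expect_equal(percent_chemotaxis(c * f, c * r), percent_chemotaxis(f, r))
    x <- runif(1, 10, 35); y <- runif(1, 10, 35)
    expect_equal(relative_expression(x, x), 1.0)
    expect_equal(log2(relative_expression(x, y)), y - x)
  }
})

test_that("clinical-score curves average per day with SEM and flags", {
  d <- data.frame(mouse_id = c("m1", "m2", "m3"), day = 10,
                  score = c(1, 2, 3))
  cur <- mean_clinical_score(d)
  expect_equal(cur$mean_score, 2.0)
  expect_equal(cur$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(cur$sem, 1 / sqrt(3))

  single <- mean_clinical_score(data.frame(mouse_id = "m1", day = 12,
                                           score = 4))
  expect_equal(single$mean_score, 4.0)
  expect_equal(single$sem, 0)
  expect_true(single$single_animal)

  expect_error(mean_clinical_score(data.frame(mouse_id = "m", day = 1,
                                              score = 6)), "0-5")
  expect_error(mean_clinical_score(data.frame(mouse_id = "m", day = 1,
                                              score = 2.5)), "0-5")

  # a mouse missing on one day shrinks that day's n and flags it
  d2 <- data.frame(mouse_id = c("m1", "m2", "m1"), day = c(5, 5, 6),
                   score = c(1, 2, 3))
  cur2 <- mean_clinical_score(d2)
  expect_equal(cur2$n, c(2L, 1L))
  expect_equal(cur2$incomplete, c(FALSE, TRUE))
})

test_that("two-group comparison is a two-tailed Student's t with star thresholds", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$stars, "")

  sep <- group_compare(c(1, 1.01, 0.99), c(2, 2.01, 1.99))
  expect_lt(sep$p_value, 0.05)
  expect_true(nchar(sep$stars) >= 1)

  expect_error(group_compare(0, 1), "at least 2")

  # symmetry and closed-form cross-check
  set.seed(72)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 0.5)
    res <- group_compare(a, b)
    expect_equal(res$p_value, group_compare(b, a)$p_value)
    na <- length(a); nb <- length(b)
    sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
    tval <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
    expect_equal(res$t, tval)
    expect_equal(res$p_value, 2 * pt(-abs(tval), na + nb - 2))
  }

  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("", "*", "**", "***", "****"))
})

test_that("assay tables validate their kind-specific invariants", {
  expect_error(assay_table("luciferase",
                           data.frame(sample_id = "s", group_label = "g",
                                      replicate_index = 1, firefly = -1,
                                      renilla = 10)), "non-negative")
  tw <- data.frame(sample_id = "s", group_label = "g", replicate_index = 1,
                   condition = "chemokine", migrated_count = 50)
  expect_error(assay_table("transwell", tw), "control")
  cl <- data.frame(mouse_id = "m", group_label = "g", day = 1, score = 2.5)
  expect_error(assay_table("clinical_score", cl), "0-5")
  expect_error(assay_table("qpcr",
                           data.frame(sample_id = "s", group_label = "g",
                                      replicate_index = 1, gene = "x",
                                      ct_target = Inf, ct_reference = 20)),
               "finite")
})

test_that("transwell quantification maps control rows to exactly 100%", {
  tw <- assay_table("transwell", data.frame(
    sample_id = paste0("s", 1:6),
    group_label = rep(c("WT", "KO"), each = 3),
    replicate_index = rep(1:3, 2),
    condition = "control",
    migrated_count = c(80, 90, 100, 40, 50, 60)))
  q <- quantify_assay(tw)
  expect_equal(q$value, rep(100, 6))

  tabs <- generate_assay_tables(rng_seed = 73)
  q2 <- quantify_assay(tabs$transwell)
  expect_equal(q2$value[q2$condition == "control"],
               rep(100, sum(q2$condition == "control")))
})

test_that("group summaries compute n, mean and SEM per stratum", {
  tabs <- generate_assay_tables(rng_seed = 74)
  s <- summarize_assay(tabs$qpcr)
  expect_equal(nrow(s), nrow(unique(as.data.frame(
    tabs$qpcr)[c("group_label", "gene")])))
  expect_true(all(s$n == 3))
  one <- as.data.frame(tabs$qpcr)
  one <- one[one$group_label == s$group_label[1] & one$gene == s$gene[1], ]
  expect_equal(s$mean[1],
               mean(relative_expression(one$ct_target, one$ct_reference)))
})
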