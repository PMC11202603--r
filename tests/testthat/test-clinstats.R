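# Steatosis grading, ICC, ROC, correlation/regression, synthetic cohort.

test_that("PDFF grading applies the 5 / 16.3 / 21.6 percent cutoffs inclusively", {
  expect_identical(grade_from_pdff(4.9), 0L)
  expect_identical(grade_from_pdff(5), 1L)
  expect_identical(grade_from_pdff(11.16), 1L)
  expect_identical(grade_from_pdff(16.3), 2L)
  expect_identical(grade_from_pdff(21.6), 3L)
  expect_identical(grade_from_pdff(31.59), 3L)
  expect_error(grade_from_pdff(-1), class = "qusac_input_error")
})

test_that("measurement grading is monotone and threshold-inclusive", {
  cuts <- qus_ac_cutoffs()
  expect_identical(grade_from_measure(0.30, cuts), 0L)
  expect_identical(grade_from_measure(0.36, cuts), 1L)
  expect_identical(grade_from_measure(0.65, cuts), 3L)
  # monotone in the measurement for random cutoff sets
  set.seed(31)
  for (i in 1:20) {
    th <- sort(runif(3))
    cc <- grade_cutoffs("x", th)
    v <- sort(runif(50))
    g <- grade_from_measure(v, cc)
    expect_true(all(diff(g) >= 0))
    expect_true(all(g >= 0 & g <= 3))
  }
  expect_error(grade_cutoffs("bad", c(3, 2, 1)), class = "qusac_config_error")
})

test_that("ICC(2,1)/ICC(2,k) match the aov mean-squares oracle to 1e-10", {
  m0 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  res0 <- icc_two_way_random(m0)
  or0 <- aov_icc_oracle(m0)
  expect_equal(res0$icc_single, or0$single, tolerance = 1e-10)
  expect_equal(res0$icc_mean, or0$mean, tolerance = 1e-10)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:20, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n)  # subject effect
    res <- icc_two_way_random(m)
    or <- aov_icc_oracle(m)
    expect_equal(res$icc_single, or$single, tolerance = 1e-10)
    expect_equal(res$icc_mean, or$mean, tolerance = 1e-10)
    expect_lte(res$icc_single, 1)
    expect_lte(res$icc_mean, 1)
  }
})

test_that("ICC limits: identical raters give 1, independent raters give ~0", {
  m <- cbind(1:6, 1:6)
  res <- icc_two_way_random(m)
  expect_equal(res$icc_single, 1, tolerance = 1e-12)
  expect_equal(res$icc_mean, 1, tolerance = 1e-12)
  set.seed(11)
  big <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(icc_two_way_random(big)$icc_single), 0.1)
  expect_error(icc_two_way_random(matrix(1, 5, 2)), class = "qusac_input_error")
  expect_error(icc_two_way_random(matrix(1:4, 1, 4)), class = "qusac_input_error")
})

test_that("AUROC equals the exhaustive pairwise-concordance oracle (n <= 50)", {
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1), boot_n = 50)$auroc, 0.75)
  set.seed(13)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    if (runif(1) < 0.5) scores <- round(scores, 1)  # force ties
    res <- roc_analysis(scores, labels, boot_n = 50)
    expect_equal(res$auroc, pairwise_auroc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC operating point reproduces contingency arithmetic", {
  # perfectly separated scores
  res <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), boot_n = 50)
  expect_equal(res$auroc, 1.0)
  expect_equal(res$sens, 1.0)
  expect_equal(res$spec, 1.0)
  # TP=8 FN=2 TN=9 FP=1 at cutoff 0.5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 9), rep(0.8, 1))
  labels <- c(rep(1, 10), rep(0, 10))
  res <- roc_analysis(scores, labels, boot_n = 50, cutoff = 0.5)
  expect_equal(res$sens, 0.8)
  expect_equal(res$spec, 0.9)
  expect_equal(res$lr_pos, 8.0)
  expect_error(roc_analysis(1:5, rep(1, 5)), class = "qusac_input_error")
})

test_that("correlation/regression handles exact, reversed and tied ranks", {
  x <- 1:10
  res <- correlation_regression(x, 2 * x + 1)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$r_squared_pct, 100)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(correlation_regression(x, rev(x))$spearman_rho, -1)
  # rank formula: 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (1,1,1,1,0)
  expect_equal(
    correlation_regression(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$spearman_rho,
    0.8
  )
  expect_error(correlation_regression(x, rep(1, 10)), class = "qusac_input_error")
})

test_that("synthetic cohort reproduces marginals and copula rank correlation", {
  co <- synth_cohort(10000, rho_ac_pdff = 0.9, seed = 5)
  mg <- cohort_marginals()
  se <- mg$pdff[2] / sqrt(10000)
  expect_lt(abs(mean(co$pdff) - mg$pdff[1]), 3 * se)
  expect_true(all(co$pdff >= 0 & co$pdff <= 60))
  # independence limit
  co0 <- synth_cohort(10000, rho_ac_pdff = 0, seed = 6)
  expect_lt(abs(cor(co0$pdff, co0$qus_ac)), 0.05)
  # copula-implied Spearman: 6/pi * asin(rho/2)
  rs <- cor(co$pdff, co$qus_ac, method = "spearman")
  expect_lt(abs(rs - 6 / pi * asin(0.9 / 2)), 0.03)
  expect_error(synth_cohort(10, rho_ac_pdff = 1.2), class = "qusac_config_error")
})

test_that("high AC-PDFF correlation yields higher grade-1 AUROC than none", {
  co_hi <- synth_cohort(400, rho_ac_pdff = 0.9, seed = 9)
  co_no <- synth_cohort(400, rho_ac_pdff = 0, seed = 9)
  lab_hi <- as.integer(grade_from_pdff(co_hi$pdff) >= 1)
  lab_no <- as.integer(grade_from_pdff(co_no$pdff) >= 1)
  a_hi <- roc_analysis(co_hi$qus_ac, lab_hi, boot_n = 50)$auroc
  a_no <- roc_analysis(co_no$qus_ac, lab_no, boot_n = 50)$auroc
  expect_gt(a_hi, a_no)
  expect_gt(a_hi, 0.8)
})

test_that("rating tables round-trip through CSV with listwise deletion", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(subject_id = sprintf("s%02d", 1:5),
                   r1 = c(1, 2, 3, NA, 5), r2 = c(1.1, 2.2, 2.9, 4, 5.1))
  utils::write.csv(df, tmp, row.names = FALSE)
  m <- read_rating_table(tmp)
  expect_equal(dim(m), c(4L, 2L))
  expect_false(any(is.na(m)))
  unlink(tmp)
})
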