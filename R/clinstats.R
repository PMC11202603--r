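#' Steatosis grade cutoffs
#'
#' Ordered thresholds mapping a continuous measurement to hepatic steatosis
#' grades 0-3 (grade = number of thresholds met, threshold-inclusive).
#' Built-in sets: MRI proton-density fat fraction (5, 16.3, 21.6 %) and the
#' QUS attenuation-coefficient operating points (0.36, 0.46, 0.53 dB/cm/MHz).
#'
#' @param modality Name of the measurement.
#' @param thresholds Nondecreasing numeric triple: cutoffs for grades 1, 2
#'   and 3 (each meaning "at least this grade").
#' @return An object of class `grade_cutoffs`.
#' @export
grade_cutoffs <- function(modality, thresholds) {
  if (length(thresholds) != 3 || is.unsorted(thresholds)) {
    stop_config("thresholds must be a nondecreasing triple")
  }
  structure(list(modality = modality, thresholds = thresholds),
            class = "grade_cutoffs")
}

#' @rdname grade_cutoffs
#' @export
pdff_cutoffs <- function() grade_cutoffs("MRI-PDFF", c(5, 16.3, 21.6))

#' @rdname grade_cutoffs
#' @export
qus_ac_cutoffs <- function() grade_cutoffs("QUS-AC", c(0.36, 0.46, 0.53))

#' Grade hepatic steatosis from a continuous measurement
#'
#' `grade_from_pdff()` applies the MRI-PDFF cutoffs (5 / 16.3 / 21.6 %);
#' `grade_from_measure()` applies an arbitrary [grade_cutoffs()] set. Grading
#' is threshold-inclusive: a value equal to a cutoff attains the grade.
#'
#' @param pdff,value Measurement value(s); vectors allowed.
#' @param cutoffs A [grade_cutoffs()].
#' @return Integer grade(s) in 0-3.
#' @export
grade_from_pdff <- function(pdff) {
  if (any(pdff < 0)) stop_input("PDFF must be nonnegative")
  grade_from_measure(pdff, pdff_cutoffs())
}

#' @rdname grade_from_pdff
#' @export
grade_from_measure <- function(value, cutoffs) {
  stopifnot(inherits(cutoffs, "grade_cutoffs"))
  vapply(value, function(v) sum(v >= cutoffs$thresholds), 0L)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) (single rating) and ICC(2,k) (mean rating) from the two-way
#' ANOVA mean squares of a subjects x raters table, with F-distribution 95%
#' confidence intervals.
#'
#' @param table Numeric subjects x raters matrix or data frame (no missing
#'   cells; apply listwise deletion upstream).
#' @return A tibble with `icc_single`, `icc_mean` and their 95% CI bounds,
#'   plus the mean squares.
#' @export
icc_two_way_random <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m))) stop_input("ratings must be finite numeric")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_input("need at least 2 subjects and 2 raters")
  if (var(as.vector(m)) == 0) stop_input("degenerate input: zero total variance")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)

  # F-based CI for the single-rating ICC (two-way random, absolute agreement)
  alpha <- 0.05
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- qf(1 - alpha / 2, n - 1, v)
  f2 <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  step_up <- function(r) r * k / (1 + (k - 1) * r)
  tibble::tibble(
    icc_single = icc1, icc_single_lo = lo1, icc_single_hi = hi1,
    icc_mean = icck, icc_mean_lo = step_up(lo1), icc_mean_hi = step_up(hi1),
    msr = msr, msc = msc, mse = mse, n_subjects = n, n_raters = k
  )
}

#' ROC analysis with operating-point metrics
#'
#' AUROC (trapezoidal with tie correction, via the Mann-Whitney relation),
#' a bootstrap 95% CI, the Youden-optimal cutoff, and the contingency metrics
#' at that cutoff (sensitivity, specificity, predictive values, likelihood
#' ratios). Higher scores are assumed to indicate the positive class.
#'
#' @param scores Numeric predictor.
#' @param labels Binary labels (0/1 or logical).
#' @param boot_n Bootstrap replicates for the AUROC CI (stratified).
#' @param cutoff Operating point; `NULL` (default) selects it by Youden's J.
#' @param seed Bootstrap seed.
#' @return A one-row tibble.
#' @export
roc_analysis <- function(scores, labels, boot_n = 2000L, cutoff = NULL,
                         seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_input("both classes must be present")
  if (length(scores) != length(labels)) stop_input("length mismatch")
  roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  auroc <- as.numeric(pROC::auc(roc))
  ci <- suppressWarnings(with_seed(seed, pROC::ci.auc(
    roc, method = "bootstrap", boot.n = boot_n, boot.stratified = TRUE
  )))
  if (is.null(cutoff)) {
    best <- pROC::coords(roc, "best", best.method = "youden",
                         ret = "threshold", transpose = FALSE)
    cutoff <- best$threshold[1]
  }
  pos <- labels == 1
  tp <- sum(scores >= cutoff & pos); fn <- sum(scores < cutoff & pos)
  tn <- sum(scores < cutoff & !pos); fp <- sum(scores >= cutoff & !pos)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  tibble::tibble(
    auroc = auroc, auroc_lo = ci[1], auroc_hi = ci[3],
    cutoff = cutoff, sens = sens, spec = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
    lr_neg = if (spec > 0) (1 - sens) / spec else Inf
  )
}

#' Correlation and simple linear regression
#'
#' Spearman rank correlation (tie-aware), Pearson correlation, and an
#' ordinary-least-squares fit of `y` on `x` with the slope 95% CI and the
#' coefficient of determination in percent.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A one-row tibble.
#' @export
correlation_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_input("need equal-length x and y with n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) stop_input("degenerate input: constant vector")
  fit <- lm(y ~ x)
  ci <- confint(fit)["x", ]
  tibble::tibble(
    spearman_rho = cor(x, y, method = "spearman"),
    pearson_r = cor(x, y),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared_pct = 100 * summary(fit)$r.squared,
    ci95_slope_lo = ci[1], ci95_slope_hi = ci[2]
  )
}

#' Generate a synthetic clinical cohort
#'
#' Gaussian-copula cohort generator emulating the marginal distributions of a
#' fatty-liver study population (MRI-PDFF, QUS-AC, ATI, UAP, age, sex, BMI)
#' with a configurable latent correlation between PDFF and each attenuation
#' measure. Attenuation measures load on the PDFF latent factor, so their
#' mutual correlations are products of their PDFF loadings (guaranteeing a
#' valid correlation structure). Values are clamped to physical ranges.
#'
#' @param n Cohort size.
#' @param rho_ac_pdff Latent correlation between QUS-AC and PDFF, in (-1, 1).
#' @param marginals Named list of `c(mean, sd)` pairs for `pdff`, `qus_ac`,
#'   `ati`, `uap`, `age`, `bmi`, plus `p_male`. Defaults emulate the study
#'   population.
#' @param rho_ati_pdff,rho_uap_pdff Latent correlations for the comparator
#'   devices.
#' @param seed Seed.
#' @return A tibble with one row per subject.
#' @export
synth_cohort <- function(n, rho_ac_pdff = 0.9,
                         marginals = cohort_marginals(),
                         rho_ati_pdff = 0.73, rho_uap_pdff = 0.51,
                         seed = 1L) {
  for (r in c(rho_ac_pdff, rho_ati_pdff, rho_uap_pdff)) {
    if (abs(r) >= 1) stop_config("latent correlations must lie in (-1, 1)")
  }
  mg <- marginals
  with_seed(seed, {
    f <- rnorm(n)  # latent fat-content factor (drives PDFF)
    z_pdff <- f
    mix <- function(r) r * f + sqrt(1 - r^2) * rnorm(n)
    z_ac <- mix(rho_ac_pdff)
    z_ati <- mix(rho_ati_pdff)
    z_uap <- mix(rho_uap_pdff)
    # clamping a normal to [lo, hi] shifts its mean; pre-correct the location
    # so the post-clamp mean matches the requested marginal mean
    clamp_mean <- function(mu, s, lo, hi) {
      a <- (lo - mu) / s; b <- (hi - mu) / s
      mu + s * (stats::dnorm(a) - stats::dnorm(b)) +
        (lo - mu) * stats::pnorm(a) + (hi - mu) * (1 - stats::pnorm(b))
    }
    to_marg <- function(z, m, lo = -Inf, hi = Inf) {
      mu <- m[1]
      if (is.finite(lo) || is.finite(hi)) {
        mu <- stats::uniroot(
          function(g) clamp_mean(g, m[2], lo, hi) - m[1],
          interval = m[1] + c(-4, 4) * m[2]
        )$root
      }
      pmin(pmax(mu + m[2] * z, lo), hi)
    }
    tibble::tibble(
      subject_id = sprintf("s%05d", seq_len(n)),
      pdff = to_marg(z_pdff, mg$pdff, 0, 60),
      qus_ac = to_marg(z_ac, mg$qus_ac, 0, 1.2),
      ati = to_marg(z_ati, mg$ati, 0, 1.5),
      uap = to_marg(z_uap, mg$uap, 100, 400),
      age = round(to_marg(rnorm(n), mg$age, 18, 95)),
      sex = ifelse(rbinom(n, 1, mg$p_male) == 1, "M", "F"),
      bmi = to_marg(rnorm(n), mg$bmi, 15, 60)
    )
  })
}

#' @rdname synth_cohort
#' @export
cohort_marginals <- function() {
  list(
    pdff = c(11.16, 7.24), qus_ac = c(0.44, 0.09), ati = c(0.71, 0.09),
    uap = c(262.54, 46.66), age = c(52.3, 14.5), bmi = c(28.7, 5.1),
    p_male = 0.6
  )
}

#' Read a subjects x raters table from delimited text
#'
#' CSV with a header row; a `subject_id` column (if present) becomes row
#' names, all remaining columns are raters. Rows with missing cells are
#' dropped (listwise deletion).
#'
#' @param path CSV path.
#' @return Numeric matrix subjects x raters.
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("subject_id" %in% names(df)) {
    rn <- df$subject_id
    df$subject_id <- NULL
  } else {
    rn <- seq_len(nrow(df))
  }
  m <- as.matrix(df)
  keep <- apply(is.finite(m), 1, all)
  m <- m[keep, , drop = FALSE]
  rownames(m) <- rn[keep]
  m
}
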