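# Shared fixtures. Heavy objects are built once per test run and cached in
# this environment so several test files (and the acceptance suite) can reuse
# them.
.fixtures <- new.env()

fixture_probe <- function() probe_config()

# small phantom spec used across tests
fixture_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(200L, 100L), cell_size = 0.4, seed = seed)
}

# one small frameset + bmode reused by acoustics tests
fixture_frameset <- function() {
  if (is.null(.fixtures$frames)) {
    map <- warp_axial_grid(sample_phantom(fixture_spec(7L)), 60)
    .fixtures$frames <- acquire_frameset(map, fixture_probe())
    .fixtures$frames_map <- map
  }
  .fixtures$frames
}

fixture_frameset_map <- function() {
  fixture_frameset()
  .fixtures$frames_map
}

# brute-force AUROC oracle: exhaustive pairwise concordance with tie credit
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# independent ICC oracle from an aov-based mean-squares decomposition
aov_icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  list(
    single = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    mean = (msr - mse) / (msr + (msc - mse) / n)
  )
}
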