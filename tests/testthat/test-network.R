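# Network architecture, the BGN transform, gradients, determinism.

make_batch <- function(cf, B = 3L, seed = 1L) {
  set.seed(seed)
  list(
    env = array(runif(B * prod(cf$input_shape)), dim = c(B, cf$input_shape)),
    bm = array(runif(B * prod(cf$bmode_shape)), dim = c(B, 1L, cf$bmode_shape)),
    y = runif(B)
  )
}

small_config <- function(seed = 3L) {
  network_config(
    encoder_widths = c(4, 6), bgn_conv_channels = 2, bgn_fc_width = 8,
    trunk_widths = c(4, 6), head_width = 8,
    input_shape = c(5L, 4L, 32L), bmode_shape = c(16L, 16L), seed = seed
  )
}

test_that("BGN identity, moment and hand-computed cases hold to 1e-5", {
  # hand evaluation with the population-sd convention
  X <- bgn_apply(c(1, 2, 3), gamma = 2, beta = 1)
  expect_equal(as.numeric(X), c(-1.449490, 1, 3.449490), tolerance = 1e-5)
  expect_equal(attr(X, "mu"), 2, tolerance = 1e-12)
  expect_equal(attr(X, "sigma"), sqrt(2 / 3), tolerance = 1e-12)
  # identity: gamma = sigma, beta = mu
  set.seed(21)
  for (i in 1:20) {
    B <- sample(1:3, 1); C <- sample(3:10, 1); T_ <- sample(2:8, 1)
    x <- array(rnorm(B * C * T_, sd = runif(1, 0.1, 5)), dim = c(B, C, T_))
    X0 <- bgn_apply(x)
    Xi <- bgn_apply(x, gamma = attr(X0, "sigma"), beta = attr(X0, "mu"))
    expect_lt(max(abs(Xi - x)), 1e-5)
    # moments: slice mean -> beta, slice population sd -> |gamma|
    g <- matrix(rnorm(B * T_), B, T_); b <- matrix(rnorm(B * T_), B, T_)
    Xa <- bgn_apply(x, g, b)
    mu_out <- apply(Xa, c(1, 3), mean)
    sd_out <- sqrt(apply(Xa, c(1, 3), function(v) mean((v - mean(v))^2)))
    expect_lt(max(abs(mu_out - b)), 1e-5)
    expect_lt(max(abs(sd_out - abs(g))), 1e-5)
  }
})

test_that("BGN stabilizes constant slices at the epsilon floor", {
  x <- matrix(5, nrow = 4, ncol = 2)  # zero variance slices
  X <- bgn_apply(x, gamma = 1, beta = 0, eps = 1e-5)
  expect_true(all(is.finite(X)))
  expect_equal(attr(X, "sigma"), c(1e-5, 1e-5))
  expect_error(bgn_apply(numeric(0)), class = "qusac_input_error")
})

test_that("encoders are independent and concatenate channel-wise", {
  cf <- small_config()
  net <- build_ac_network(cf)
  d <- make_batch(cf)
  fused <- encode(net, d$env)
  expect_identical(dim(fused)[2], 5L * 6L)
  # identical frames through different encoders give different features
  xa <- aperm(array(d$env[, 1, , ], dim = dim(d$env)[-2]), c(2, 3, 1))
  e1 <- qusac:::layer_forward(net$encoders[[1]], xa, FALSE)
  e2 <- qusac:::layer_forward(net$encoders[[2]], xa, FALSE)
  expect_false(isTRUE(all.equal(e1, e2)))
  expect_error(encode(net, d$env[, 1:4, , , drop = FALSE]),
               class = "qusac_input_error")
})

test_that("prediction is deterministic, batched and order-equivariant", {
  cf <- small_config()
  net <- build_ac_network(cf)
  d <- make_batch(cf, B = 4L)
  p1 <- predict(net, d$env, d$bm)
  p2 <- predict(net, d$env, d$bm)
  expect_identical(p1$ac, p2$ac)
  expect_length(p1$ac, 4L)
  expect_true(all(is.finite(p1$ac)))
  expect_true(all(p1$ac >= cf$ac_range[1] & p1$ac <= cf$ac_range[2]))
  perm <- c(3, 1, 4, 2)
  p3 <- predict(net, d$env[perm, , , , drop = FALSE], d$bm[perm, , , , drop = FALSE])
  expect_equal(p3$ac, p1$ac[perm], tolerance = 1e-12)
  # identical config + seed rebuilds identical weights
  net2 <- build_ac_network(cf)
  expect_identical(predict(net2, d$env, d$bm)$ac, p1$ac)
  expect_error(predict(net, d$env[, , 1:2, , drop = FALSE], d$bm),
               class = "qusac_input_error")
  expect_error(predict(net, d$env, NULL), class = "qusac_input_error")
})

test_that("analytic gradients match finite differences through the whole net", {
  cf <- small_config()
  for (mode in c("bgn", "ablation")) {
    net <- build_ac_network(cf, mode)
    d <- make_batch(cf, B = 2L, seed = 5L)
    loss <- function() {
      fw <- qusac:::net_forward(net, d$env, d$bm, train = FALSE)
      mean(abs(fw$pred - d$y))
    }
    qusac:::zero_grads(net$layers)
    fw <- qusac:::net_forward(net, d$env, d$bm, train = FALSE)
    qusac:::net_backward(net, fw, sign(fw$pred - d$y) / length(d$y))
    set.seed(6)
    for (li in sample(seq_along(net$layers), 6)) {
      l <- net$layers[[li]]
      nm <- names(l$par)[1]
      k <- sample(length(l$par[[nm]]), 1)
      eps <- 1e-6
      p0 <- l$par[[nm]][k]
      l$par[[nm]][k] <- p0 + eps; up <- loss()
      l$par[[nm]][k] <- p0 - eps; dn <- loss()
      l$par[[nm]][k] <- p0
      fd <- (up - dn) / (2 * eps)
      an <- l$grad[[nm]][k]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("loss gradients reach both the envelope input and the B-mode branch", {
  cf <- small_config()
  net <- build_ac_network(cf, "bgn")
  d <- make_batch(cf, B = 2L, seed = 8L)
  qusac:::zero_grads(net$layers)
  fw <- qusac:::net_forward(net, d$env, d$bm, train = TRUE)
  gr <- qusac:::net_backward(net, fw, rep(1, 2))
  expect_gt(sum(abs(gr$denv)), 0)
  expect_gt(sum(abs(gr$dbmode)), 0)
  # B-mode branch parameters receive gradient
  bgn_layers <- qusac:::collect_layers(net$bgn_conv)
  expect_gt(sum(abs(bgn_layers[[1]]$grad$W)), 0)
})

test_that("ablation variant drops the B-mode branch but keeps the trunk", {
  cf <- small_config()
  net <- build_ac_network(cf, "bgn")
  ab <- build_ac_network(cf, "ablation")
  expect_lt(n_params(ab), n_params(net))
  # everything except the B-mode branch is architecture-identical
  branch <- n_params(net) -
    qusac:::count_params(c(
      qusac:::collect_layers(net$bgn_conv),
      qusac:::collect_layers(net$gamma_head),
      qusac:::collect_layers(net$beta_head)
    ))
  expect_identical(branch, n_params(ab))
  d <- make_batch(cf, B = 2L)
  p <- predict(ab, d$env)  # no bmode needed
  expect_true(all(is.finite(p$ac)))
})

test_that("per-channel BGN mode produces gamma/beta per slice and channel", {
  cf <- small_config()
  cf$bgn_per_channel <- TRUE
  net <- build_ac_network(cf, "bgn")
  d <- make_batch(cf, B = 2L)
  fw <- qusac:::net_forward(net, d$env, d$bm, train = FALSE)
  expect_true(all(is.finite(fw$pred)))
  qusac:::zero_grads(net$layers)
  fw <- qusac:::net_forward(net, d$env, d$bm, train = TRUE)
  gr <- qusac:::net_backward(net, fw, rep(1, 2))
  expect_gt(sum(abs(gr$dbmode)), 0)
})
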