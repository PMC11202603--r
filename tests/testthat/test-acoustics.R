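# Forward model, envelope detection, B-mode compounding, SLD estimator.

test_that("probe defaults are 64 channels and the five steering angles", {
  pr <- probe_config()
  expect_identical(pr$n_channels, 64L)
  expect_equal(pr$angles, c(-7.2, -3.6, 0, 3.6, 7.2))
  expect_error(probe_config(angles = c(0, 45)), class = "qusac_config_error")
})

test_that("frame sets have five angles x 64 channels with valid envelopes", {
  fr <- fixture_frameset()
  expect_length(fr$rf, 5L)
  for (a in 1:5) {
    expect_identical(ncol(fr$rf[[a]]), 64L)
    env <- fr$env[[a]]
    expect_true(all(env >= 0))
    # envelope bounds |rf| at its extrema (within interpolation tolerance)
    i <- which.max(abs(fr$rf[[a]]))
    expect_gte(env[i] * 1.01 + 1e-9, abs(fr$rf[[a]][i]))
  }
})

test_that("steering beyond +/-30 degrees is rejected", {
  m <- homogeneous_phantom(0.3, grid_shape = c(50L, 25L), seed = 1L)
  expect_error(simulate_planewave(m, probe_config(), 35),
               class = "qusac_config_error")
})

test_that("no echo precedes the two-way time of flight to the first reflector", {
  pt <- tibble::tibble(z_mm = 30, x_mm = 19.2, amplitude = 1)
  m <- homogeneous_phantom(0.3, scatterers_per_unit = 0, point_scatterers = pt)
  rf <- simulate_planewave(m, probe_config(), 0, snr_db = Inf)
  t0 <- attr(rf, "t0_us"); fs <- attr(rf, "fs_mhz")
  t_min <- 2 * 30 / 1.54  # us, round trip at the medium speed
  first <- (which(abs(rf) > 1e-9 * max(abs(rf)), arr.ind = TRUE)[, 1] - 1) / fs + t0
  # allow the pulse half-length before the geometric arrival
  expect_gte(min(first), t_min - 3)
})

test_that("simulated RF is reproducible from the seed", {
  m <- homogeneous_phantom(0.4, grid_shape = c(80L, 40L), seed = 5L)
  r1 <- simulate_planewave(m, probe_config(), 3.6, seed = 9L)
  r2 <- simulate_planewave(m, probe_config(), 3.6, seed = 9L)
  expect_identical(r1, r2)
  r3 <- simulate_planewave(m, probe_config(), 3.6, seed = 10L)
  expect_false(identical(r1, r3))
})

test_that("round-trip attenuation follows the closed-form frequency law", {
  # single target at 50 mm depth; alpha = 0.5 dB/cm/MHz at 3 MHz over a
  # 10 cm round trip must cost 15 dB relative to alpha = 0
  pr <- probe_config()
  pt <- tibble::tibble(z_mm = 50, x_mm = 19.2, amplitude = 1)
  m0 <- homogeneous_phantom(0, scatterers_per_unit = 0, point_scatterers = pt)
  m5 <- homogeneous_phantom(0.5, scatterers_per_unit = 0, point_scatterers = pt)
  r0 <- simulate_planewave(m0, pr, 0, snr_db = Inf)
  r5 <- simulate_planewave(m5, pr, 0, snr_db = Inf)
  d <- spectral_deficit_db(r0, r5, t_center = 2 * 50 / 1.54, f0 = 3)
  expect_equal(d, 15, tolerance = 0.5 / 15)
})

test_that("mean liver log-envelope decreases monotonically and linearly in alpha", {
  pr <- probe_config()
  alphas <- seq(0.1, 1.0, by = 0.1)
  deficit <- vapply(seq_along(alphas), function(i) {
    m <- homogeneous_phantom(alphas[i], grid_shape = c(150L, 50L),
                             cell_size = 0.4, seed = 77L)
    rf <- simulate_planewave(m, pr, 0, snr_db = Inf)
    env <- envelope_detect(rf)
    fs <- attr(rf, "fs_mhz"); t0 <- attr(rf, "t0_us")
    gate <- round((2 * 45 / 1.54 - t0) * fs) + seq(-30, 30)
    mean(20 * log10(colMeans(env[gate, ])))
  }, 1)
  expect_true(all(diff(deficit) < 0))
  expect_gt(summary(lm(deficit ~ alphas))$r.squared, 0.99)
})

test_that("envelope detection demodulates tones and AM signals", {
  t <- seq(0, 100, by = 1 / 12)
  env <- envelope_detect(cos(2 * pi * 3 * t))
  inner <- seq(120, length(t) - 120)
  expect_true(all(abs(env[inner] - 1) < 0.02))
  expect_true(all(envelope_detect(numeric(240)) == 0))
  m <- 1 + 0.5 * sin(2 * pi * 0.05 * t)
  env_am <- envelope_detect(m * cos(2 * pi * 3 * t))
  expect_lt(max(abs(env_am[inner] - m[inner]) / m[inner]), 0.01)
  expect_error(envelope_detect(c(1, NA, 3)), class = "qusac_input_error")
})

test_that("compounded B-mode localizes a point target within 1 mm", {
  pr <- probe_config()
  pt <- tibble::tibble(z_mm = 50, x_mm = 19.2, amplitude = 1)
  m <- homogeneous_phantom(0, scatterers_per_unit = 0, point_scatterers = pt)
  fr <- acquire_frameset(m, pr, snr_db = Inf)
  bm <- compound_bmode(fr)
  ij <- which(bm$pixels == max(bm$pixels), arr.ind = TRUE)[1, ]
  z_hat <- bm$z0_mm + (ij[1] - 1) * bm$pixel_mm
  x_hat <- bm$x0_mm + (ij[2] - 1) * bm$pixel_mm
  expect_lt(abs(z_hat - 50), 1)
  expect_lt(abs(x_hat - 19.2), 1)
  # pixel range respects the dynamic range and max-normalization
  expect_lte(max(bm$pixels), 0)
  expect_gte(min(bm$pixels), -bm$dynamic_range)
  expect_equal(max(bm$pixels), 0)
})

test_that("all-zero RF compounds to a uniform floor", {
  fr <- fixture_frameset()
  zfr <- fr
  zfr$rf <- lapply(fr$rf, function(m) m * 0)
  bm <- compound_bmode(zfr)
  expect_true(all(bm$pixels == -bm$dynamic_range))
})

test_that("duplicating an angle frame does not move the B-mode argmax", {
  pr <- probe_config()
  pt <- tibble::tibble(z_mm = 40, x_mm = 20, amplitude = 1)
  m <- homogeneous_phantom(0, scatterers_per_unit = 0, point_scatterers = pt)
  fr <- acquire_frameset(m, pr, snr_db = Inf)
  bm1 <- compound_bmode(fr)
  fr2 <- fr
  fr2$rf <- c(fr$rf, fr$rf[3])
  fr2$probe$angles <- c(pr$angles, 0)
  bm2 <- compound_bmode(fr2)
  expect_identical(
    which(bm1$pixels == max(bm1$pixels), arr.ind = TRUE)[1, ],
    which(bm2$pixels == max(bm2$pixels), arr.ind = TRUE)[1, ]
  )
})

test_that("spectral log difference recovers homogeneous attenuation within 0.1", {
  pr <- probe_config()
  for (a in c(0.2, 0.5, 0.8)) {
    m <- homogeneous_phantom(a, seed = 11L)
    fr <- acquire_frameset(m, pr, snr_db = 40, seed = 11L)
    expect_lt(abs(sld_estimate(fr) - a), 0.1)
  }
})
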