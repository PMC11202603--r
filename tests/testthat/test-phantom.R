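# Phantom sampling: geometry bounds, property containment, determinism, warp.

test_that("phantom sampling is reproducible and respects geometry bounds", {
  sp <- fixture_spec(3L)
  m1 <- sample_phantom(sp)
  m2 <- sample_phantom(sp)
  expect_identical(m1, m2)
  expect_true(m1$liver_ac_truth >= 0 && m1$liver_ac_truth <= 1.0)
  # liver truth equals the AC of liver-labelled cells
  liver_cells <- m1$ac[m1$label == qusac:::tissue_code("liver")]
  if (length(liver_cells) > 0) {
    expect_true(all(liver_cells == m1$liver_ac_truth))
  }
  # different seed changes the realization
  m3 <- sample_phantom(fixture_spec(4L))
  expect_false(identical(m1$sos, m3$sos))
})

test_that("sampled properties stay inside the tissue table for many phantoms", {
  # moderate-size Monte Carlo here; the acceptance suite runs the large one
  tab <- tissue_property_table()
  for (i in 1:40) {
    sp <- phantom_spec(grid_shape = c(80L, 40L), cell_size = 1, seed = 100L + i)
    m <- sample_phantom(sp)
    s <- phantom_property_summary(m, tab)
    expect_true(all(s$contained), info = paste("seed", 100 + i))
    # scatterer law: densities inside [800, 1200], count below 10 per unit area
    lam <- sp$wavelength_ref_sos / sp$wavelength_ref_freq / 1000
    n_units <- prod(sp$grid_shape) * sp$cell_size^2 / lam^2
    expect_lt(nrow(m$scatterers) / n_units, 10)
    expect_true(all(m$scatterers$density >= 800 & m$scatterers$density <= 1200))
  }
})

test_that("superficial layers are confined to the top 30 mm", {
  for (seed in 11:25) {
    m <- sample_phantom(fixture_spec(seed))
    layer_codes <- qusac:::tissue_code(c("skin", "fat", "muscle"))
    deep <- m$label[seq(ceiling(30 / m$cell_size) + 1, nrow(m$label)), ]
    expect_false(any(deep %in% layer_codes))
    # top row is skin
    expect_true(all(m$label[1, ] == qusac:::tissue_code("skin")))
  }
})

test_that("grid too shallow for the layer zone is a configuration error", {
  expect_error(
    phantom_spec(grid_shape = c(60L, 100L), cell_size = 0.4),
    class = "qusac_config_error"
  )
  expect_error(
    phantom_spec(liver_radius_range = c(80, 50)),
    class = "qusac_config_error"
  )
})

test_that("flat warp is the identity and the center column never moves", {
  m <- sample_phantom(fixture_spec(5L))
  expect_identical(warp_axial_grid(m, "flat"), m)
  expect_identical(warp_axial_grid(m, Inf), m)
  w <- warp_axial_grid(m, 60)
  mid <- ncol(m$sos) %/% 2
  expect_identical(w$sos[, mid], m$sos[, mid])
  expect_identical(w$label[, mid], m$label[, mid])
})

test_that("warped surface follows a circle of the probe radius", {
  m <- sample_phantom(fixture_spec(6L))
  R <- 60
  w <- warp_axial_grid(m, R)
  # first non-couplant row per column = the warped transducer-face surface
  wcode <- qusac:::tissue_code("water")
  nz <- nrow(w$label)
  surf <- apply(w$label, 2, function(col) which(col != wcode)[1]) - 1
  z <- surf * w$cell_size
  x <- (seq_len(ncol(w$label)) - 0.5) * w$cell_size
  x0 <- ncol(w$label) * w$cell_size / 2
  # least-squares circle with known center lateral position: fit z0 in
  # z = z0 + R - sqrt(R^2 - (x - x0)^2); residuals below one cell
  pred <- R - sqrt(R^2 - (x - x0)^2)
  z0 <- mean(z - pred)
  expect_lt(max(abs(z - z0 - pred)), w$cell_size)
})

test_that("warp conserves interior labels and shifts scatterers consistently", {
  m <- sample_phantom(fixture_spec(8L))
  w <- warp_axial_grid(m, 60)
  # superficial layer classes conserved exactly (nothing reaches the bottom)
  for (code in qusac:::tissue_code(c("skin", "fat", "muscle"))) {
    expect_identical(sum(w$label == code), sum(m$label == code))
  }
  # deepest classes may lose a small boundary fraction
  n_all <- length(m$label)
  for (code in qusac:::tissue_code(c("liver", "vessel", "other"))) {
    expect_lt(abs(sum(w$label == code) - sum(m$label == code)) / n_all, 0.05)
  }
  # scatterers only move deeper (or drop off the bottom edge)
  expect_lte(nrow(w$scatterers), nrow(m$scatterers))
  expect_true(all(w$scatterers$z_mm <= nrow(w$label) * w$cell_size))
  depth_mm <- nrow(m$label) * m$cell_size
  kept <- m$scatterers$z_mm %in% (w$scatterers$z_mm - 0) |
    m$scatterers$z_mm <= depth_mm
  expect_true(all(kept))
})

test_that("homogeneous phantom carries its attenuation as ground truth", {
  m <- homogeneous_phantom(0.7, grid_shape = c(50L, 25L), cell_size = 0.4,
                           seed = 2L)
  expect_equal(m$liver_ac_truth, 0.7)
  expect_true(all(m$ac == 0.7))
  expect_true(all(m$sos == 1540))
  m2 <- homogeneous_phantom(0.7, grid_shape = c(50L, 25L), cell_size = 0.4,
                            seed = 2L)
  expect_identical(m1 <- m$scatterers, m2$scatterers)
})
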