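#' Plane-wave probe configuration
#'
#' Defaults model a 64-channel convex abdominal probe driven with five steered
#' plane waves. Center frequency, sampling rate and pulse length are typical
#' abdominal values and are configurable.
#'
#' @param n_channels Number of transmit/receive channels.
#' @param angles Plane-wave steering angles in degrees.
#' @param center_frequency Transmit center frequency, MHz.
#' @param sampling_rate Receive sampling rate, MHz.
#' @param pulse_cycles Pulse length in periods (Gaussian-windowed tone; the
#'   full-width-half-maximum of the envelope spans this many periods).
#' @param curvature_radius Probe curvature radius, mm.
#' @param pitch Element pitch, mm.
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(n_channels = 64L,
                         angles = c(-7.2, -3.6, 0, 3.6, 7.2),
                         center_frequency = 3.0,
                         sampling_rate = 12.0,
                         pulse_cycles = 3,
                         curvature_radius = 60,
                         pitch = 0.6) {
  if (any(abs(angles) > 30)) {
    stop_config("steering angles beyond +/-30 degrees are not supported")
  }
  structure(
    list(
      n_channels = as.integer(n_channels), angles = angles,
      center_frequency = center_frequency, sampling_rate = sampling_rate,
      pulse_cycles = pulse_cycles, curvature_radius = curvature_radius,
      pitch = pitch
    ),
    class = "probe_config"
  )
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf(
    "<probe_config> %d ch, angles [%s] deg, f0 %.1f MHz, fs %.1f MHz\n",
    x$n_channels, paste(x$angles, collapse = ", "),
    x$center_frequency, x$sampling_rate
  ))
  invisible(x)
}

probe_element_x <- function(probe, width_mm) {
  width_mm / 2 + (seq_len(probe$n_channels) - (probe$n_channels + 1) / 2) * probe$pitch
}

# Bank of pre-attenuated pulse waveforms.
#
# For each two-way attenuation path integral A (dB/MHz) the received pulse is
# the transmit pulse filtered by 10^(-A f / 20): compute the one-sided
# Gaussian pulse spectrum, apply the filter, and inverse-transform. Returns an
# L x length(A_vals) matrix of real waveforms centered at index L/2.
attn_waveform_bank <- function(A_vals, probe, L = 64L) {
  fs <- probe$sampling_rate
  f0 <- probe$center_frequency
  sigma_t <- probe$pulse_cycles / (2.355 * f0)       # us
  sigma_f <- 1 / (2 * pi * sigma_t)                  # MHz
  N <- 1024L
  f <- (0:(N - 1)) * fs / N
  pos <- f <= fs / 2
  base <- ifelse(pos, exp(-(f - f0)^2 / (2 * sigma_f^2)), 0)
  out <- matrix(0, L, length(A_vals))
  half <- L %/% 2
  idx <- c((N - half + 1):N, 1:(L - half))  # circular gather around t = 0
  for (i in seq_along(A_vals)) {
    spec <- base * 10^(-pmax(A_vals[i], 0) * f / 20)
    pulse <- Re(fft(spec, inverse = TRUE)) / N
    out[, i] <- pulse[idx]
  }
  # normalize against the unattenuated pulse peak so attenuation is absolute
  ref <- Re(fft(base, inverse = TRUE))[1] / N
  out / abs(ref)
}

#' Simulate one plane-wave transmission
#'
#' Fast frequency-domain scatterer-summation forward model: every scatterer
#' (and every impedance step between tissue layers) returns a delayed replica
#' of the transmit pulse, spectrally shaped by the frequency-dependent
#' attenuation `10^(-alpha f d / 20)` accumulated along the two-way straight
#' axial path through the tissues above it. Times of flight use the local
#' speed-of-sound profile of the scatterer's column. Additive white receiver
#' noise at `snr_db` is seeded and reproducible.
#'
#' @param map A [tissue_map()].
#' @param probe A [probe_config()].
#' @param angle Steering angle in degrees.
#' @param snr_db Receiver signal-to-noise ratio in dB (`Inf` disables noise).
#' @param seed Noise seed; defaults to a stream derived from the map seed and
#'   the angle.
#' @param include_boundaries Add specular echoes from impedance steps.
#' @return A time x channel matrix of RF pressure samples with attributes
#'   `t0_us` and `fs_mhz`.
#' @export
simulate_planewave <- function(map, probe, angle, snr_db = 40,
                               seed = NULL, include_boundaries = TRUE) {
  stopifnot(inherits(map, "tissue_map"), inherits(probe, "probe_config"))
  if (abs(angle) > 30) {
    stop_config("steering angle %.1f deg beyond +/-30 deg", angle)
  }
  nz <- nrow(map$sos); nx <- ncol(map$sos); cs <- map$cell_size
  width_mm <- nx * cs
  c_mm_us <- map$sos / 1000
  # per-column cumulative one-way travel time (us) and two-way attenuation
  # (dB/MHz) to the bottom of each cell
  slow <- apply(cs / c_mm_us, 2, cumsum)
  attn <- apply(2 * map$ac * (cs / 10), 2, cumsum)

  th <- angle * pi / 180
  c_ref <- 1.54  # mm/us lateral reference for the steering term
  elem_x <- probe_element_x(probe, width_mm)

  sc <- map$scatterers
  z_s <- sc$z_mm; x_s <- sc$x_mm; a_s <- sc$amplitude
  if (include_boundaries) {
    bs <- boundary_scatterers(map, th)
    z_s <- c(z_s, bs$z_mm); x_s <- c(x_s, bs$x_mm); a_s <- c(a_s, bs$amplitude)
  }
  if (length(z_s) == 0) {
    n_t <- as.integer(ceiling((2 * max(slow) + 12) * probe$sampling_rate))
    rf <- matrix(0, n_t, probe$n_channels)
    attr(rf, "t0_us") <- -6; attr(rf, "fs_mhz") <- probe$sampling_rate
    return(rf)
  }
  iz <- pmin(nz, pmax(1L, ceiling(z_s / cs)))
  ix <- pmin(nx, pmax(1L, ceiling(x_s / cs)))
  lin <- cbind(iz, ix)
  S_s <- slow[lin]                     # one-way axial time, us
  A_s <- attn[lin]                     # two-way path attenuation, dB/MHz
  c_rx <- ifelse(z_s > cs, z_s / S_s, c_ref * 1000 / 1540 * 1.54)
  tau_tx <- cos(th) * S_s + sin(th) * x_s / c_ref

  binw <- 0.1
  bin <- as.integer(round(A_s / binw))
  ub <- sort(unique(bin))
  bank <- attn_waveform_bank(ub * binw, probe)
  bin_idx <- match(bin, ub) - 1L

  t0 <- -6
  t_end <- 2 * max(slow) + 8
  n_t <- as.integer(ceiling((t_end - t0) * probe$sampling_rate))
  rf <- fwd_scatter_sum(
    z_s, x_s, a_s, bin_idx, tau_tx, c_rx, elem_x, bank,
    probe$sampling_rate, t0, n_t, 1.0, probe$pitch
  )
  if (is.finite(snr_db)) {
    if (is.null(seed)) {
      seed <- derive_seed(
        if (is.na(map$seed)) 0L else map$seed,
        paste0("noise", format(angle))
      )
    }
    sig <- sqrt(mean(rf^2))
    if (sig > 0) {
      rf <- rf + with_seed(seed, matrix(
        rnorm(length(rf), sd = sig * 10^(-snr_db / 20)), nrow(rf), ncol(rf)
      ))
    }
  }
  attr(rf, "t0_us") <- t0
  attr(rf, "fs_mhz") <- probe$sampling_rate
  rf
}

# Specular echo sources at impedance steps between axial cells. Reflection
# coefficient (Z2 - Z1)/(Z2 + Z1); horizontal interfaces reflect steered
# transmissions away from the aperture, modelled by a Gaussian angular weight.
boundary_scatterers <- function(map, th_rad, gain = 3, every = 2L) {
  Zi <- map$density * map$sos
  nz <- nrow(Zi); nx <- ncol(Zi); cs <- map$cell_size
  cols <- seq(1L, nx, by = every)
  zl <- list(); xl <- list(); al <- list()
  ang_w <- exp(-(th_rad * 180 / pi / 4)^2)
  for (j in cols) {
    z_col <- Zi[, j]
    rc <- diff(z_col) / (z_col[-1] + z_col[-nz])
    k <- which(abs(rc) > 1e-4)
    if (length(k) == 0) next
    zl[[length(zl) + 1L]] <- (k + 0.5) * cs
    xl[[length(xl) + 1L]] <- rep((j - 0.5) * cs, length(k))
    al[[length(al) + 1L]] <- rc[k] * gain * every * ang_w
  }
  list(
    z_mm = unlist(zl) %||% numeric(0),
    x_mm = unlist(xl) %||% numeric(0),
    amplitude = unlist(al) %||% numeric(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Envelope detection
#'
#' Magnitude of the analytic signal, computed per channel (column) through the
#' discrete Fourier transform.
#'
#' @param rf Real-valued time x channel matrix (or a vector).
#' @return Nonnegative envelope of the same shape.
#' @export
envelope_detect <- function(rf) {
  v <- is.null(dim(rf))
  if (v) rf <- matrix(rf, ncol = 1)
  if (!all(is.finite(rf))) stop_input("RF data must be finite")
  n <- nrow(rf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(rf) * h
  env <- Mod(stats::mvfft(X, inverse = TRUE)) / n
  if (v) env <- drop(env)
  env
}

#' Acquire a five-angle plane-wave frame set
#'
#' Runs [simulate_planewave()] for every steering angle of the probe and
#' envelope-detects each frame.
#'
#' @param map A [tissue_map()].
#' @param probe A [probe_config()].
#' @param snr_db Receiver SNR in dB.
#' @param seed Master seed for the per-angle noise streams.
#' @return An object of class `rf_frameset` with per-angle `rf` and `env`
#'   matrices (time x channel), time origin `t0_us`, sampling rate `fs_mhz`,
#'   the probe, and the phantom's ground-truth liver AC.
#' @export
acquire_frameset <- function(map, probe = probe_config(), snr_db = 40,
                             seed = NULL) {
  if (is.null(seed)) seed <- if (is.na(map$seed)) 0L else map$seed
  frames <- lapply(seq_along(probe$angles), function(i) {
    simulate_planewave(
      map, probe, probe$angles[i], snr_db = snr_db,
      seed = derive_seed(seed, paste0("noise-a", i))
    )
  })
  structure(
    list(
      rf = frames,
      env = lapply(frames, envelope_detect),
      probe = probe,
      t0_us = attr(frames[[1]], "t0_us"),
      fs_mhz = attr(frames[[1]], "fs_mhz"),
      phantom_seed = map$seed,
      liver_ac_truth = map$liver_ac_truth
    ),
    class = "rf_frameset"
  )
}

#' @export
print.rf_frameset <- function(x, ...) {
  cat(sprintf(
    "<rf_frameset> %d angles x %d channels x %d samples (fs %.1f MHz)\n",
    length(x$rf), ncol(x$rf[[1]]), nrow(x$rf[[1]]), x$fs_mhz
  ))
  invisible(x)
}

#' Compound a B-mode image from a plane-wave frame set
#'
#' Delay-and-sum beamforms every angle frame onto a common pixel grid,
#' coherently sums the angles, envelope-detects along depth, log-compresses
#' and max-normalizes to 0 dB, clamped at `-dynamic_range`.
#'
#' @param frames An `rf_frameset` (or a list of RF matrices with `t0_us` and
#'   `fs_mhz` attributes plus a `probe`).
#' @param pixel_mm Pixel edge, mm.
#' @param dynamic_range Display dynamic range, dB.
#' @param depth_mm Imaging depth; defaults to the time axis extent.
#' @param c0 Beamforming speed of sound, m/s.
#' @param fnum Receive f-number.
#' @param tgc_alpha Nominal attenuation (dB/cm/MHz) compensated by the
#'   time-gain curve before log compression; `0` disables TGC.
#' @param tgc_spread Geometric-spreading compensation exponent.
#' @return An object of class `bmode_image`: dB pixel matrix (depth x lateral)
#'   plus geometry.
#' @export
compound_bmode <- function(frames, pixel_mm = 0.4, dynamic_range = 60,
                           depth_mm = NULL, c0 = 1540, fnum = 1.5,
                           tgc_alpha = 0.5, tgc_spread = 0.5) {
  stopifnot(inherits(frames, "rf_frameset"))
  if (length(frames$rf) < 1) stop_input("empty frame set")
  probe <- frames$probe
  c_mm_us <- c0 / 1000
  n_t <- nrow(frames$rf[[1]])
  if (is.null(depth_mm)) {
    depth_mm <- (frames$t0_us + n_t / frames$fs_mhz) * c_mm_us / 2 * 0.95
  }
  width_mm <- probe$n_channels * probe$pitch
  elem_x <- probe_element_x(probe, width_mm)
  px_z <- seq(pixel_mm, depth_mm, by = pixel_mm)
  px_x <- seq(pixel_mm / 2, width_mm, by = pixel_mm)
  acc <- matrix(0, length(px_z), length(px_x))
  for (i in seq_along(frames$rf)) {
    acc <- acc + das_beamform(
      frames$rf[[i]], elem_x, probe$angles[i] * pi / 180, c_mm_us,
      frames$fs_mhz, frames$t0_us, px_z, px_x, width_mm / 2, fnum
    )
  }
  acc <- acc * tgc_gain(px_z, frames$probe$center_frequency, tgc_alpha, tgc_spread)
  env <- envelope_detect(acc)
  mx <- max(env)
  px <- if (mx == 0) {
    matrix(-dynamic_range, nrow(acc), ncol(acc))
  } else {
    pmax(20 * log10(pmax(env, .Machine$double.xmin) / mx), -dynamic_range)
  }
  structure(
    list(
      pixels = px, dynamic_range = dynamic_range, pixel_mm = pixel_mm,
      z0_mm = px_z[1], x0_mm = px_x[1]
    ),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf(
    "<bmode_image> %d x %d px @ %.2f mm, dynamic range %g dB\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_mm, x$dynamic_range
  ))
  invisible(x)
}

#' Time-gain-compensation amplitude curve
#'
#' Standard scanner-style depth compensation: undoes geometric spreading
#' (`(z+1)^spread`) and a nominal round-trip tissue attenuation of
#' `alpha0` dB/cm/MHz at the transmit center frequency, so that residual
#' depth decay reflects the deviation of the medium's attenuation from the
#' nominal value.
#'
#' @param z_mm Depths, mm.
#' @param f0 Center frequency, MHz.
#' @param alpha0 Nominal attenuation coefficient, dB/cm/MHz.
#' @param spread Spreading-compensation exponent.
#' @return Amplitude gain factors.
#' @export
tgc_gain <- function(z_mm, f0, alpha0 = 0.5, spread = 0.5) {
  (z_mm + 1)^spread * 10^(alpha0 * f0 * 2 * (z_mm / 10) / 20)
}

#' Plot a B-mode image
#'
#' @param bmode A [compound_bmode()] result.
#' @return A ggplot object (gray-scale raster, dB).
#' @export
plot_bmode <- function(bmode) {
  px <- bmode$pixels
  df <- tibble::tibble(
    z = rep(bmode$z0_mm + (seq_len(nrow(px)) - 1) * bmode$pixel_mm, ncol(px)),
    x = rep(bmode$x0_mm + (seq_len(ncol(px)) - 1) * bmode$pixel_mm, each = nrow(px)),
    db = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral [mm]", y = "depth [mm]", fill = "dB")
}
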