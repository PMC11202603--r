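#' Spectral amplitude deficit between two recordings at one frequency
#'
#' Gates both channel-data sets around a common arrival time, sums channels,
#' and compares the windowed spectral amplitudes at frequency `f0`. Used to
#' check the round-trip attenuation law `10^(-alpha f d / 20)`: for a target
#' at depth `d` the deficit at `f0` equals `alpha * f0 * 2d` dB.
#'
#' @param rf_ref,rf_att Time x channel RF matrices (same geometry), each with
#'   `t0_us` and `fs_mhz` attributes.
#' @param t_center Gate center, us (two-way time of flight to the target).
#' @param f0 Evaluation frequency, MHz.
#' @param half_us Half gate length, us.
#' @return Deficit in dB (positive when `rf_att` is weaker).
#' @export
spectral_deficit_db <- function(rf_ref, rf_att, t_center, f0, half_us = 2) {
  one <- function(rf) {
    t0 <- attr(rf, "t0_us"); fs <- attr(rf, "fs_mhz")
    stopifnot(!is.null(t0), !is.null(fs))
    n <- round(2 * half_us * fs)
    i0 <- round((t_center - half_us - t0) * fs)
    if (i0 < 1 || i0 + n - 1 > nrow(rf)) stop_input("gate outside the recording")
    seg <- rowSums(rf[i0:(i0 + n - 1), , drop = FALSE])
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    sp <- Mod(fft(c(seg * win, numeric(2048 - n))))
    f <- (0:2047) * fs / 2048
    sp[which.min(abs(f - f0))]
  }
  20 * log10(one(rf_ref) / one(rf_att))
}

#' Reference spectral-log-difference attenuation estimator
#'
#' Classical non-learning attenuation-coefficient estimator used as an
#' independent check of the forward model's attenuation encoding. Per-channel
#' gated power spectra are averaged over a proximal and a distal family of
#' depth gates (several overlapping sub-gates per family, every receive
#' channel, and — when a full frame set is supplied — every steering angle);
#' the difference of the two averaged dB spectra is linear in frequency with
#' slope `-2 alpha (z2 - z1)` (dB per MHz), from which alpha (dB/cm/MHz)
#' follows. Window and diffraction effects are frequency-flat for plane-wave
#' transmissions and cancel in the ratio; averaging over sub-gates, channels
#' and angles suppresses spectral speckle noise.
#'
#' @param rf An `rf_frameset` (all angle frames are averaged), or a single
#'   time x channel RF matrix carrying `t0_us` and `fs_mhz` attributes.
#' @param z1_mm,z2_mm Centers of the proximal and distal gate families, mm.
#' @param gate_mm Axial gate length, mm.
#' @param n_subgates Number of overlapping sub-gates per family.
#' @param subgate_step_mm Axial spacing of the sub-gates, mm.
#' @param band_mhz Frequency band for the linear fit, MHz.
#' @param c0 Assumed speed of sound, m/s.
#' @param channels Channel subset (default: all).
#' @return Estimated attenuation coefficient in dB/cm/MHz.
#' @export
sld_estimate <- function(rf, z1_mm = 24, z2_mm = 52, gate_mm = 12,
                         n_subgates = 7, subgate_step_mm = 4,
                         band_mhz = c(2.2, 3.8), c0 = 1540, channels = NULL) {
  frames <- if (inherits(rf, "rf_frameset")) {
    lapply(rf$rf, function(m) {
      attr(m, "t0_us") <- rf$t0_us
      attr(m, "fs_mhz") <- rf$fs_mhz
      m
    })
  } else {
    list(rf)
  }
  t0 <- attr(frames[[1]], "t0_us"); fs <- attr(frames[[1]], "fs_mhz")
  stopifnot(!is.null(t0), !is.null(fs))
  c_mm_us <- c0 / 1000
  n_t <- nrow(frames[[1]]); n_e <- ncol(frames[[1]])
  if (is.null(channels)) channels <- seq_len(n_e)
  nw <- 2L * floor(gate_mm * fs / c_mm_us)  # even two-way gate length, samples
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  nfft <- 1024L
  f <- (0:(nfft - 1)) * fs / nfft
  offsets <- (seq_len(n_subgates) - (n_subgates + 1) / 2) * subgate_step_mm

  gate_power <- function(z_mm) {
    p <- numeric(nfft)
    for (frame in frames) {
      for (dz in offsets) {
        ic <- round((2 * (z_mm + dz) / c_mm_us - t0) * fs)
        i0 <- ic - nw %/% 2
        if (i0 < 1 || i0 + nw - 1 > n_t) stop_input("gate outside the recording")
        seg <- frame[i0:(i0 + nw - 1), channels, drop = FALSE] * win
        pad <- matrix(0, nfft - nw, length(channels))
        p <- p + rowSums(Mod(stats::mvfft(rbind(seg, pad)))^2)
      }
    }
    p
  }

  s1 <- gate_power(z1_mm)
  s2 <- gate_power(z2_mm)
  sel <- f >= band_mhz[1] & f <= band_mhz[2]
  d_db <- 10 * log10(s2[sel] / s1[sel])
  fs_sel <- f[sel]
  slope <- unname(coef(lm(d_db ~ fs_sel))[2])        # dB/MHz
  dz_cm <- (z2_mm - z1_mm) / 10
  -slope / (2 * dz_cm)
}
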