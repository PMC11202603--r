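#include <Rcpp.h>
using namespace Rcpp;

// Sum per-scatterer echoes into a channel-data matrix.
//
// rf is (n_t x n_elem), column-major so the inner element loop writes
// contiguously. Each scatterer s contributes, at element e,
//   w = amp[s] * directivity * spreading
// times a pre-attenuated pulse waveform (column attn_bin[s] of `waveforms`,
// centered at index L/2), arriving at
//   tau = tau_tx[s] + |r_s - r_e| / c_rx[s].
// Linear interpolation distributes the waveform onto the sample grid.
// The receive aperture is limited to |dx| <= z / (2 * fnum) + pitch.
// [[Rcpp::export]]
NumericMatrix fwd_scatter_sum(NumericVector z_mm, NumericVector x_mm,
                              NumericVector amp, IntegerVector attn_bin,
                              NumericVector tau_tx_us, NumericVector c_rx,
                              NumericVector elem_x_mm, NumericMatrix waveforms,
                              double fs_mhz, double t0_us, int n_t,
                              double fnum, double pitch_mm) {
  const int n_s = z_mm.size();
  const int n_e = elem_x_mm.size();
  const int L = waveforms.nrow();
  const int nb = waveforms.ncol();
  const int half = L / 2;
  // one-sample-delayed copy of each waveform so the interpolated sample is
  // a branch-free linear combination inside the hot loop
  std::vector<double> wprev((size_t)L * nb, 0.0);
  for (int b = 0; b < nb; ++b)
    for (int l = 1; l < L; ++l)
      wprev[(size_t)b * L + l] = waveforms(l - 1, b);
  NumericMatrix rf(n_t, n_e);
  for (int s = 0; s < n_s; ++s) {
    const double z = z_mm[s], x = x_mm[s], a = amp[s];
    if (a == 0.0) continue;
    const double ttx = tau_tx_us[s];
    const double cr = c_rx[s];
    const double *wave = &waveforms(0, attn_bin[s]);
    const double *wprv = &wprev[(size_t)attn_bin[s] * L];
    const double half_ap = z / (2.0 * fnum) + pitch_mm;
    for (int e = 0; e < n_e; ++e) {
      const double dx = elem_x_mm[e] - x;
      if (dx > half_ap || dx < -half_ap) continue;
      const double r = std::sqrt(dx * dx + z * z);
      const double tau = ttx + r / cr;
      const double w = a * (z / r) / std::sqrt(r + 1.0);
      const double fidx = (tau - t0_us) * fs_mhz;
      const int i0 = (int)std::floor(fidx) - half;
      const double frac = fidx - std::floor(fidx);
      const double w1 = w * (1.0 - frac), w2 = w * frac;
      const int l0 = i0 < 1 ? 1 - i0 : 0;
      const int l1 = i0 + L > n_t ? n_t - i0 : L;
      double *col = &rf(0, e) + i0;
      for (int l = l0; l < l1; ++l) {
        col[l] += w1 * wave[l] + w2 * wprv[l];
      }
    }
  }
  return rf;
}

// Delay-and-sum beamforming of one plane-wave frame onto a pixel grid.
//
// rf is (n_t x n_elem). Transmit delay of pixel (z, x) for steering angle
// `th`: (z cos th + (x - x_ref) sin th) / c. Receive delay: Euclidean
// distance to the element / c. Aperture growth is limited by `fnum`.
// Returns (n_z x n_x).
// [[Rcpp::export]]
NumericMatrix das_beamform(NumericMatrix rf, NumericVector elem_x_mm,
                           double angle_rad, double c_mm_us, double fs_mhz,
                           double t0_us, NumericVector px_z, NumericVector px_x,
                           double x_ref, double fnum) {
  const int n_t = rf.nrow();
  const int n_e = rf.ncol();
  const int n_z = px_z.size();
  const int n_x = px_x.size();
  const double st = std::sin(angle_rad), ct = std::cos(angle_rad);
  NumericMatrix img(n_z, n_x);
  for (int j = 0; j < n_x; ++j) {
    const double x = px_x[j];
    for (int i = 0; i < n_z; ++i) {
      const double z = px_z[i];
      const double ttx = (z * ct + (x - x_ref) * st) / c_mm_us;
      const double half_ap = z / (2.0 * fnum) + 1.0;
      double acc = 0.0;
      for (int e = 0; e < n_e; ++e) {
        const double dx = elem_x_mm[e] - x;
        if (dx > half_ap || dx < -half_ap) continue;
        const double trx = std::sqrt(dx * dx + z * z) / c_mm_us;
        const double fidx = (ttx + trx - t0_us) * fs_mhz;
        const int i0 = (int)std::floor(fidx);
        if (i0 < 0 || i0 + 1 >= n_t) continue;
        const double frac = fidx - i0;
        const double *col = &rf(0, e);
        acc += (1.0 - frac) * col[i0] + frac * col[i0 + 1];
      }
      img(i, j) = acc;
    }
  }
  return img;
}
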