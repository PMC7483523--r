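#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics confocal photon-trace simulator.
//
// Molecules random-walk in a periodic cubic box; per time bin each molecule
// emits Poisson photons with mean brightness * W(x,y,z), where W is the
// Gaussian detection profile exp(-2(x^2+y^2)/wxy^2 - 2 z^2/wz^2).  Photons
// are split donor/acceptor by a binomial draw with acceptor probability
// e_true; Poisson background is added per channel.  Uses R's RNG, so
// set.seed() in R makes runs bit-reproducible.
//
// Transit log: a molecule is "in focus" while (x^2+y^2)/wxy^2 + z^2/wz^2 <= 1;
// entry/exit bins and per-transit photon sums are recorded.
// [[Rcpp::export]]
List cpp_simulate_confocal(NumericVector D, NumericVector brightness,
                           NumericVector e_true, double box_edge,
                           double wxy, double wz, double dt, double n_bins_d,
                           double bg_donor, double bg_acceptor) {
  const R_xlen_t n_bins = (R_xlen_t)n_bins_d;
  const int n_mol = D.size();
  IntegerVector donor(n_bins), acceptor(n_bins);

  std::vector<double> x(n_mol), y(n_mol), z(n_mol), sd(n_mol);
  const double half = box_edge / 2.0;
  for (int m = 0; m < n_mol; ++m) {
    x[m] = R::runif(-half, half);
    y[m] = R::runif(-half, half);
    z[m] = R::runif(-half, half);
    sd[m] = std::sqrt(2.0 * D[m] * dt);
  }

  // transit bookkeeping
  std::vector<int> tr_mol;
  std::vector<double> tr_start, tr_end, tr_photons;
  std::vector<bool> inside(n_mol, false);
  std::vector<R_xlen_t> enter_bin(n_mol, 0);
  std::vector<double> phot_acc(n_mol, 0.0);

  const double inv_wxy2 = 1.0 / (wxy * wxy);
  const double inv_wz2 = 1.0 / (wz * wz);
  const bool has_bg = (bg_donor > 0.0) || (bg_acceptor > 0.0);

  for (R_xlen_t i = 0; i < n_bins; ++i) {
    int d_cnt = 0, a_cnt = 0;
    for (int m = 0; m < n_mol; ++m) {
      double xm = x[m] + R::norm_rand() * sd[m];
      double ym = y[m] + R::norm_rand() * sd[m];
      double zm = z[m] + R::norm_rand() * sd[m];
      // periodic wrap
      if (xm >= half) xm -= box_edge; else if (xm < -half) xm += box_edge;
      if (ym >= half) ym -= box_edge; else if (ym < -half) ym += box_edge;
      if (zm >= half) zm -= box_edge; else if (zm < -half) zm += box_edge;
      x[m] = xm; y[m] = ym; z[m] = zm;

      const double rho2 = (xm * xm + ym * ym) * inv_wxy2;
      const double zeta2 = zm * zm * inv_wz2;
      const double expo = -2.0 * (rho2 + zeta2);

      int n_phot = 0;
      if (expo > -18.0) { // lambda < 1.5e-8 * brightness otherwise
        const double lambda = brightness[m] * std::exp(expo);
        if (lambda > 0.0) n_phot = (int)R::rpois(lambda);
        if (n_phot > 0) {
          int a = (e_true[m] > 0.0)
                    ? (int)R::rbinom((double)n_phot, e_true[m]) : 0;
          a_cnt += a;
          d_cnt += n_phot - a;
        }
      }

      const bool in_now = (rho2 + zeta2) <= 1.0;
      if (in_now) {
        if (!inside[m]) { inside[m] = true; enter_bin[m] = i; phot_acc[m] = 0.0; }
        phot_acc[m] += n_phot;
      } else if (inside[m]) {
        inside[m] = false;
        tr_mol.push_back(m + 1);
        tr_start.push_back((double)enter_bin[m]);
        tr_end.push_back((double)i); // exclusive
        tr_photons.push_back(phot_acc[m]);
      }
    }
    if (has_bg) {
      if (bg_donor > 0.0) d_cnt += (int)R::rpois(bg_donor);
      if (bg_acceptor > 0.0) a_cnt += (int)R::rpois(bg_acceptor);
    }
    donor[i] = d_cnt;
    acceptor[i] = a_cnt;
  }
  // close transits still open at the end
  for (int m = 0; m < n_mol; ++m) {
    if (inside[m]) {
      tr_mol.push_back(m + 1);
      tr_start.push_back((double)enter_bin[m]);
      tr_end.push_back((double)n_bins);
      tr_photons.push_back(phot_acc[m]);
    }
  }

  return List::create(_["donor"] = donor, _["acceptor"] = acceptor,
                      _["transit_molecule"] = wrap(tr_mol),
                      _["transit_start_bin"] = wrap(tr_start),
                      _["transit_end_bin"] = wrap(tr_end),
                      _["transit_photons"] = wrap(tr_photons));
}

// Multi-tau autocorrelation: m linearly spaced lags per stage, x2 rebinning
// between stages.  Normalization: G(k) = mean(I_i I_{i+k}) / mean(I)^2 with
// the means taken over the current (rebinned) series.
// [[Rcpp::export]]
List cpp_multitau(NumericVector x, double bin_width, double max_lag, int m) {
  std::vector<double> cur(x.begin(), x.end());
  double binw = bin_width;
  std::vector<double> lags, g;

  int stage = 0;
  for (;;) {
    const R_xlen_t n = (R_xlen_t)cur.size();
    if (n < 2 * m) break;
    double mean = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) mean += cur[i];
    mean /= (double)n;
    if (mean <= 0.0) break;
    const double mean2 = mean * mean;

    const int k_lo = (stage == 0) ? 1 : (m / 2 + 1);
    bool done = false;
    for (int k = k_lo; k <= m; ++k) {
      const double lag = k * binw;
      if (lag > max_lag) { done = true; break; }
      double s = 0.0;
      const R_xlen_t nk = n - k;
      for (R_xlen_t i = 0; i < nk; ++i) s += cur[i] * cur[i + k];
      lags.push_back(lag);
      g.push_back(s / ((double)nk * mean2));
    }
    if (done) break;
    // rebin by 2
    const R_xlen_t n2 = n / 2;
    for (R_xlen_t i = 0; i < n2; ++i) cur[i] = cur[2 * i] + cur[2 * i + 1];
    cur.resize(n2);
    binw *= 2.0;
    ++stage;
  }
  return List::create(_["lag"] = wrap(lags), _["g"] = wrap(g));
}

// Sum consecutive groups of `factor` bins; trailing remainder dropped.
// [[Rcpp::export]]
IntegerVector cpp_rebin_sum(IntegerVector x, int factor) {
  const R_xlen_t n_out = x.size() / factor;
  IntegerVector out(n_out);
  for (R_xlen_t i = 0; i < n_out; ++i) {
    int s = 0;
    const R_xlen_t off = i * (R_xlen_t)factor;
    for (int j = 0; j < factor; ++j) s += x[off + j];
    out[i] = s;
  }
  return out;
}

// Replace bins outside the kept windows by Poisson draws at `rate`.
// Windows are 1-based [start, end] inclusive, sorted, non-overlapping.
// [[Rcpp::export]]
IntegerVector cpp_mask_poisson(IntegerVector x, NumericVector win_start,
                               NumericVector win_end, double rate) {
  const R_xlen_t n = x.size();
  IntegerVector out(n);
  R_xlen_t w = 0;
  const R_xlen_t n_win = win_start.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double bin1 = (double)(i + 1);
    while (w < n_win && win_end[w] < bin1) ++w;
    if (w < n_win && win_start[w] <= bin1 && bin1 <= win_end[w]) {
      out[i] = x[i];
    } else {
      out[i] = (rate > 0.0) ? (int)R::rpois(rate) : 0;
    }
  }
  return out;
}
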