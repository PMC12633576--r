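// Time-frequency engine: Morlet continuous wavelet transform and the
// smoothing operators behind wavelet coherence, plus a small boosted-stump
// learner used by the classification stage.
//
// The coherence path uses per-scale decimation: each Morlet daughter is
// narrowband, so low-frequency scales are synthesised on a power-of-two
// decimated time grid (an exact subsampling of the full-rate transform,
// since the daughter spectrum fits below the decimated Nyquist), smoothed
// there, and interpolated back to the full grid for the scale boxcar and
// the coherence ratio.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fourier factor: wavelength / scale for the Morlet wavelet.
static double fourier_factor(double omega0) {
  return 4.0 * M_PI / (omega0 + std::sqrt(2.0 + omega0 * omega0));
}

// [[Rcpp::export(name = ".cpp_fourier_factor")]]
double cpp_fourier_factor(double omega0) { return fourier_factor(omega0); }

static uword next_pow2(uword n) {
  uword p = 1;
  while (p < n) p <<= 1;
  return p;
}

// Morlet CWT via FFT at full time resolution. Rows are scales, columns
// time samples. The signal is mean-removed and zero-padded to the next
// power of two; edge wrap-around is confined to the cone of influence.
// [[Rcpp::export(name = ".cpp_cwt_morlet")]]
arma::cx_mat cpp_cwt_morlet(const arma::vec& x, double fs,
                            const arma::vec& freqs, double omega0) {
  const uword n = x.n_elem;
  const uword npad = next_pow2(n);

  vec xp(npad, fill::zeros);
  xp.head(n) = x - mean(x);
  cx_vec X = fft(xp);

  const double dt = 1.0 / fs;
  const double ff = fourier_factor(omega0);
  const double norm0 = std::pow(M_PI, -0.25);
  cx_mat W(freqs.n_elem, n);
  for (uword i = 0; i < freqs.n_elem; ++i) {
    const double s = 1.0 / (ff * freqs(i));
    cx_vec daughter(npad, fill::zeros);
    const double amp = norm0 * std::sqrt(2.0 * M_PI * s / dt);
    for (uword k = 0; k <= npad / 2; ++k) {
      const double arg = s * (2.0 * M_PI * k / (npad * dt)) - omega0;
      daughter(k) = std::complex<double>(amp * std::exp(-0.5 * arg * arg),
                                         0.0);
    }
    cx_vec row = ifft(cx_vec(X % daughter));
    W.row(i) = row.head(n).st();
  }
  return W;
}

// One centred box pass with edge-count normalisation.
static void box_pass(vec& v, uword r, vec& S) {
  const uword n = v.n_elem;
  S.set_size(n + 1);
  S(0) = 0.0;
  for (uword i = 0; i < n; ++i) S(i + 1) = S(i) + v(i);
  for (uword i = 0; i < n; ++i) {
    uword lo = (i > r) ? i - r : 0;
    uword hi = std::min<uword>(i + r, n - 1);
    v(i) = (S(hi + 1) - S(lo)) / double(hi - lo + 1);
  }
}

// Gaussian smoothing (sd = sigma samples) as three variance-matched box
// passes.
static void gauss_smooth(vec& v, double sigma, vec& scratch) {
  if (sigma <= 0.5) return;
  double rexact = (std::sqrt(4.0 * sigma * sigma + 1.0) - 1.0) / 2.0;
  uword r = (uword)std::max(1.0, std::round(rexact));
  for (int pass = 0; pass < 3; ++pass) box_pass(v, r, scratch);
}

// Per-scale decimation factor: power of two such that the daughter
// spectrum (support up to ~2.4 f) stays below the decimated Nyquist.
static uword decim_factor(double f, double fs, uword npad) {
  double dmax = 0.2 * fs / f;
  uword d = 1;
  while (2 * d <= dmax && npad / (2 * d) >= 64) d <<= 1;
  return d;
}

// Decimated daughter coefficients for one scale: W[tau * d] =
// (m / npad) * ifft_m(X_k ψ̂_k), k < m/2.
static cx_vec cwt_scale_decimated(const cx_vec& X, double fs, double f,
                                  double omega0, uword npad, uword d,
                                  uword n_keep) {
  const uword m = npad / d;
  const double ff = fourier_factor(omega0);
  const double s = 1.0 / (ff * f);
  const double dt = 1.0 / fs;
  const double amp = std::pow(M_PI, -0.25) * std::sqrt(2.0 * M_PI * s / dt);
  cx_vec c(m, fill::zeros);
  for (uword k = 0; k <= m / 2 && k < m; ++k) {
    const double arg = s * (2.0 * M_PI * k / (npad * dt)) - omega0;
    if (arg > 9.0) break;
    c(k) = X(k) * std::complex<double>(amp * std::exp(-0.5 * arg * arg), 0.0);
  }
  cx_vec w = ifft(c) * double(m) / double(npad);
  return w.head(n_keep);
}

// Linear interpolation of a decimated series (values at t = tau * d) onto
// the strided grid t = 0, stride, 2*stride, ...; constant extension past
// the last decimated sample.
static void upsample_into(const vec& v, uword d, uword stride, vec& out) {
  const uword nv = v.n_elem;
  for (uword c = 0; c < out.n_elem; ++c) {
    uword t = c * stride;
    uword tau = t / d;
    if (tau + 1 >= nv) {
      out(c) = v(nv - 1);
    } else {
      double w = double(t - tau * d) / double(d);
      out(c) = (1.0 - w) * v(tau) + w * v(tau + 1);
    }
  }
}

// Boxcar across scales (rows), half-width h, edge-count normalised.
static mat scale_boxcar(const mat& M, uword h) {
  if (h == 0) return M;
  const uword ns = M.n_rows;
  mat out(size(M));
  mat S(ns + 1, M.n_cols, fill::zeros);
  for (uword i = 0; i < ns; ++i) S.row(i + 1) = S.row(i) + M.row(i);
  for (uword i = 0; i < ns; ++i) {
    uword lo = (i > h) ? i - h : 0;
    uword hi = std::min<uword>(i + h, ns - 1);
    out.row(i) = (S.row(hi + 1) - S.row(lo)) / double(hi - lo + 1);
  }
  return out;
}

// Prepared transform of one signal: per-scale decimated coefficients plus
// the time-smoothed scale-normalised power, ready to be paired.
// [[Rcpp::export(name = ".cpp_wtc_prepare")]]
Rcpp::List cpp_wtc_prepare(const arma::vec& x, double fs,
                           const arma::vec& freqs, double omega0) {
  const uword n = x.n_elem;
  const uword npad = next_pow2(n);
  vec xp(npad, fill::zeros);
  xp.head(n) = x - mean(x);
  cx_vec X = fft(xp);

  const double ff = fourier_factor(omega0);
  const uword nf = freqs.n_elem;
  Rcpp::List w_list(nf);
  Rcpp::List a_list(nf);
  Rcpp::IntegerVector dvec(nf);
  vec scratch;
  for (uword i = 0; i < nf; ++i) {
    const double f = freqs(i);
    const double s = 1.0 / (ff * f);
    const uword d = decim_factor(f, fs, npad);
    const uword n_keep = (n + d - 1) / d;
    cx_vec w = cwt_scale_decimated(X, fs, f, omega0, npad, d, n_keep);
    vec a = square(abs(w)) / s;
    gauss_smooth(a, s * fs / double(d), scratch);
    w_list[i] = w;
    a_list[i] = a;
    dvec[i] = (int)d;
  }
  return Rcpp::List::create(Rcpp::Named("w") = w_list,
                            Rcpp::Named("a") = a_list,
                            Rcpp::Named("d") = dvec,
                            Rcpp::Named("n") = (int)n,
                            Rcpp::Named("fs") = fs,
                            Rcpp::Named("freqs") = freqs,
                            Rcpp::Named("omega0") = omega0);
}

// Smoothed magnitude coherence from two prepared transforms:
// |S(Wx conj Wy)|^2 / (S|Wx|^2 S|Wy|^2), with S = per-scale Gaussian time
// smoothing plus a boxcar over 2h+1 scales. Output columns are the time
// samples 0, stride, 2*stride, ... of the analysis window.
// [[Rcpp::export(name = ".cpp_wtc_pair")]]
arma::mat cpp_wtc_pair(const Rcpp::List& px, const Rcpp::List& py, int h,
                       int stride) {
  const Rcpp::List wxl = px["w"], axl = px["a"];
  const Rcpp::List wyl = py["w"], ayl = py["a"];
  const Rcpp::IntegerVector dvec = px["d"];
  const uword n = (uword)Rcpp::as<int>(px["n"]);
  const double fs = Rcpp::as<double>(px["fs"]);
  const double omega0 = Rcpp::as<double>(px["omega0"]);
  const vec freqs = Rcpp::as<vec>(px["freqs"]);
  const double ff = fourier_factor(omega0);
  const uword nf = freqs.n_elem;
  const uword st = (uword)std::max(1, stride);
  const uword nc = (n + st - 1) / st;

  // rows on the strided grid, stored as columns (arma is column-major)
  mat A(nc, nf), B(nc, nf), CR(nc, nf), CI(nc, nf);
  vec scratch, buf(nc);
  for (uword i = 0; i < nf; ++i) {
    const double s = 1.0 / (ff * freqs(i));
    const uword d = (uword)dvec[i];
    const cx_vec wx = Rcpp::as<cx_vec>(wxl[i]);
    const cx_vec wy = Rcpp::as<cx_vec>(wyl[i]);
    cx_vec cr = (wx % conj(wy)) / s;
    vec re = real(cr), im = imag(cr);
    const double sigma = s * fs / double(d);
    gauss_smooth(re, sigma, scratch);
    gauss_smooth(im, sigma, scratch);
    upsample_into(re, d, st, buf); CR.col(i) = buf;
    upsample_into(im, d, st, buf); CI.col(i) = buf;
    upsample_into(Rcpp::as<vec>(axl[i]), d, st, buf); A.col(i) = buf;
    upsample_into(Rcpp::as<vec>(ayl[i]), d, st, buf); B.col(i) = buf;
  }
  // scale boxcar as a running window over columns, fused with the ratio
  const uword hh = (uword)std::max(0, h);
  mat coh(nf, nc);
  vec sa(nc, fill::zeros), sb(nc, fill::zeros), sr(nc, fill::zeros),
      si(nc, fill::zeros);
  uword win_hi = 0;  // exclusive
  uword win_lo = 0;
  for (uword i = 0; i < nf; ++i) {
    uword lo = (i > hh) ? i - hh : 0;
    uword hi = std::min(i + hh + 1, nf);  // exclusive
    while (win_hi < hi) {
      sa += A.col(win_hi); sb += B.col(win_hi);
      sr += CR.col(win_hi); si += CI.col(win_hi);
      ++win_hi;
    }
    while (win_lo < lo) {
      sa -= A.col(win_lo); sb -= B.col(win_lo);
      sr -= CR.col(win_lo); si -= CI.col(win_lo);
      ++win_lo;
    }
    const double cnt = double(hi - lo);
    for (uword c = 0; c < nc; ++c) {
      double den = (sa(c) / cnt) * (sb(c) / cnt);
      double num = (sr(c) / cnt) * (sr(c) / cnt) +
                   (si(c) / cnt) * (si(c) / cnt);
      double v = num / std::max(den, 1e-300);
      coh(i, c) = std::min(std::max(v, 0.0), 1.0);
    }
  }
  return coh;
}

// ---- Sample entropy --------------------------------------------------------

// Pair counts for sample entropy: B over length-m templates, A over
// length-(m+1), both with starting indices 0..n-m-1, Chebyshev distance
// strictly below r, self-matches excluded, each pair counted once.
// [[Rcpp::export(name = ".cpp_sampen_counts")]]
Rcpp::NumericVector cpp_sampen_counts(const arma::vec& x, int m, double r) {
  const int n = (int)x.n_elem;
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      bool okB = true;
      for (int k = 0; k < m; ++k) {
        double d = std::abs(x(i + k) - x(j + k));
        if (d > dmax) dmax = d;
        if (dmax >= r) { okB = false; break; }
      }
      if (!okB) continue;
      B += 1.0;
      double d = std::abs(x(i + m) - x(j + m));
      if (std::max(dmax, d) < r) A += 1.0;
    }
  }
  return Rcpp::NumericVector::create(Rcpp::Named("A") = A,
                                     Rcpp::Named("B") = B);
}

// ---- AdaBoost (discrete SAMME) with depth-1 stumps -------------------------

// Returns per-round stump parameters. y must be -1/+1; weights start uniform.
// [[Rcpp::export(name = ".cpp_ada_fit")]]
Rcpp::List cpp_ada_fit(const arma::mat& X, const arma::vec& y, int nrounds) {
  const uword n = X.n_rows, p = X.n_cols;
  umat ord(n, p);
  for (uword j = 0; j < p; ++j) ord.col(j) = sort_index(X.col(j));

  vec w(n, fill::value(1.0 / n));
  ivec feat(nrounds, fill::value(-1));
  vec thr(nrounds, fill::zeros), pol(nrounds, fill::ones),
      alpha(nrounds, fill::zeros);
  int used = 0;

  for (int m = 0; m < nrounds; ++m) {
    double best_err = datum::inf, best_thr = 0.0, best_pol = 1.0;
    uword best_j = 0;
    double err_base = 0.0;
    for (uword i = 0; i < n; ++i) if (y(i) < 0) err_base += w(i);
    for (uword j = 0; j < p; ++j) {
      // stump "x > t -> +1"; start with t below all values
      double run = err_base;
      auto consider = [&](double e, double t) {
        double e2 = e, polc = 1.0;
        if (1.0 - e < e2) { e2 = 1.0 - e; polc = -1.0; }
        if (e2 < best_err - 1e-15) {
          best_err = e2; best_thr = t; best_pol = polc; best_j = j;
        }
      };
      consider(run, X(ord(0, j), j) - 1.0);
      for (uword k = 0; k < n - 1; ++k) {
        uword i = ord(k, j);
        run += (y(i) < 0) ? -w(i) : w(i);
        double v1 = X(ord(k, j), j), v2 = X(ord(k + 1, j), j);
        if (v2 > v1) consider(run, 0.5 * (v1 + v2));
      }
    }
    if (!std::isfinite(best_err)) break;
    double e = std::min(std::max(best_err, 1e-10), 1.0 - 1e-10);
    if (e >= 0.5 - 1e-12 && m > 0) break;
    double a = 0.5 * std::log((1.0 - e) / e);
    feat(m) = (int)best_j; thr(m) = best_thr; pol(m) = best_pol; alpha(m) = a;
    ++used;
    double wsum = 0.0;
    for (uword i = 0; i < n; ++i) {
      double hpred = (X(i, best_j) > best_thr) ? best_pol : -best_pol;
      w(i) *= std::exp(-a * y(i) * hpred);
      wsum += w(i);
    }
    w /= wsum;
  }
  return Rcpp::List::create(
      Rcpp::Named("feature") = feat.head(used),
      Rcpp::Named("threshold") = thr.head(used),
      Rcpp::Named("polarity") = pol.head(used),
      Rcpp::Named("alpha") = alpha.head(used));
}

// Staged margins: column m holds the margin using the first rounds(m) stumps.
// [[Rcpp::export(name = ".cpp_ada_margin")]]
arma::mat cpp_ada_margin(const arma::mat& X, const arma::ivec& feature,
                         const arma::vec& threshold, const arma::vec& polarity,
                         const arma::vec& alpha, const arma::ivec& rounds) {
  const uword n = X.n_rows;
  mat out(n, rounds.n_elem, fill::zeros);
  vec margin(n, fill::zeros);
  uword next = 0;
  for (uword m = 0; m < feature.n_elem; ++m) {
    for (uword i = 0; i < n; ++i) {
      double h = (X(i, (uword)feature(m)) > threshold(m)) ? polarity(m)
                                                          : -polarity(m);
      margin(i) += alpha(m) * h;
    }
    while (next < rounds.n_elem && (uword)rounds(next) == m + 1) {
      out.col(next) = margin;
      ++next;
    }
  }
  while (next < rounds.n_elem) { out.col(next) = margin; ++next; }
  return out;
}
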