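#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian log-density matrix, T x K
static NumericMatrix log_emission(const NumericVector& x,
                                  const NumericVector& mu,
                                  const NumericVector& sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);
  for (int k = 0; k < K; ++k) {
    const double s = sigma[k];
    const double c = -0.5 * std::log(2.0 * M_PI) - std::log(s);
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - mu[k]) / s;
      B(t, k) = c - 0.5 * z * z;
    }
  }
  return B;
}

// Scaled forward-backward for a Gaussian-emission HMM on one trace.
// Returns log-likelihood, posterior state probabilities gamma (T x K) and
// the expected transition counts xi (K x K) summed over time.
// [[Rcpp::export(name = ".fbGauss")]]
List fb_gauss(NumericVector x, NumericVector mu, NumericVector sigma,
              NumericVector pi0, NumericMatrix A) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B = log_emission(x, mu, sigma);
  // emission probabilities rescaled per frame to avoid under/overflow
  NumericMatrix E(T, K);
  for (int t = 0; t < T; ++t) {
    double mx = B(t, 0);
    for (int k = 1; k < K; ++k) if (B(t, k) > mx) mx = B(t, k);
    for (int k = 0; k < K; ++k) E(t, k) = std::exp(B(t, k) - mx);
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector scale(T);
  double ll = 0.0;
  for (int k = 0; k < K; ++k) alpha(0, k) = pi0[k] * E(0, k);
  double s0 = 0.0; for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  scale[0] = s0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= E(t, k);
      alpha(t, k) = a;
      st += a;
    }
    scale[t] = st;
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
  }
  // log-lik: sum log scale + sum of per-frame max shifts
  for (int t = 0; t < T; ++t) {
    double mx = B(t, 0);
    for (int k = 1; k < K; ++k) if (B(t, k) > mx) mx = B(t, k);
    ll += std::log(scale[t]) + mx;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * E(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / scale[t + 1];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(t, j);
      for (int k = 0; k < K; ++k)
        xi(j, k) += aj * A(j, k) * E(t + 1, k) * beta(t + 1, k) / scale[t + 1];
    }
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// One EM E-step over a set of traces stored concatenated in x with 0-based
// start offsets; returns the aggregated sufficient statistics.
// [[Rcpp::export(name = ".fbGaussMulti")]]
List fb_gauss_multi(NumericVector x, IntegerVector starts,
                    NumericVector mu, NumericVector sigma,
                    NumericVector pi0, NumericMatrix A) {
  const int n = starts.size(), K = mu.size(), total = x.size();
  double ll = 0.0;
  NumericVector sw(K), swx(K), swx2(K), pi0n(K);
  NumericMatrix xi(K, K);
  for (int i = 0; i < n; ++i) {
    const int a = starts[i];
    const int b = (i + 1 < n) ? starts[i + 1] : total;
    NumericVector xi_tr(x.begin() + a, x.begin() + b);
    List fb = fb_gauss(xi_tr, mu, sigma, pi0, A);
    ll += as<double>(fb["loglik"]);
    NumericMatrix g = fb["gamma"];
    NumericMatrix xx = fb["xi"];
    const int T = g.nrow();
    for (int k = 0; k < K; ++k) {
      double s = 0.0, sx = 0.0, sx2 = 0.0;
      for (int t = 0; t < T; ++t) {
        const double gk = g(t, k);
        s += gk;
        sx += gk * xi_tr[t];
        sx2 += gk * xi_tr[t] * xi_tr[t];
      }
      sw[k] += s; swx[k] += sx; swx2[k] += sx2;
      pi0n[k] += g(0, k);
      for (int j = 0; j < K; ++j) xi(j, k) += xx(j, k);
    }
  }
  return List::create(_["loglik"] = ll, _["sw"] = sw, _["swx"] = swx,
                      _["swx2"] = swx2, _["xi"] = xi, _["pi0n"] = pi0n);
}

// Viterbi decoding; returns 1-based most probable state path.
// [[Rcpp::export(name = ".viterbiGauss")]]
IntegerVector viterbi_gauss(NumericVector x, NumericVector mu,
                            NumericVector sigma, NumericVector pi0,
                            NumericMatrix A) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B = log_emission(x, mu, sigma);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : -1e300;
  std::vector<double> d(K), dn(K);
  IntegerMatrix bp(T, K);
  for (int k = 0; k < K; ++k)
    d[k] = (pi0[k] > 0 ? std::log(pi0[k]) : -1e300) + B(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = d[0] + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        const double v = d[j] + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      dn[k] = best + B(t, k);
      bp(t, k) = arg;
    }
    d = dn;
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (d[k] > d[arg]) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
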