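#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions over a set of series.
//
// dens: n x K observation densities (rows of all series concatenated)
// pi0:  S x K initial state probabilities (one row per series)
// A:    n x K x K array, A[i, j, k] = P(next = k | current = j) evaluated at
//       the covariates of row i (the "from" occasion)
// starts/lens: 1-based first row index and length of each series
//
// Returns scaled alpha/beta, gamma, per-row log normalizers, per-series
// log-likelihoods, and (optionally) per-series (T-1) x K x K xi arrays.
// [[Rcpp::export]]
List fb_core(NumericMatrix dens, NumericMatrix pi0, NumericVector A,
             IntegerVector starts, IntegerVector lens, bool compute_xi) {
  const int n = dens.nrow(), K = dens.ncol(), S = starts.size();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector logc(n), series_ll(S);
  List xi(S);
  std::vector<double> a(K);
  for (int s = 0; s < S; ++s) {
    const int i0 = starts[s] - 1, T = lens[s];
    double c = 0.0;
    for (int k = 0; k < K; ++k) { a[k] = pi0(s, k) * dens(i0, k); c += a[k]; }
    if (!(c > 0))
      stop("all-state-zero observation density (numerical underflow) in series %d at position 1",
           s + 1);
    for (int k = 0; k < K; ++k) alpha(i0, k) = a[k] / c;
    logc[i0] = std::log(c);
    for (int t = 1; t < T; ++t) {
      const int i = i0 + t, ip = i - 1;
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += alpha(ip, j) * A[ip + (size_t)n * j + (size_t)n * K * k];
        a[k] = acc * dens(i, k);
        c += a[k];
      }
      if (!(c > 0))
        stop("all-state-zero observation density (numerical underflow) in series %d at position %d",
             s + 1, t + 1);
      for (int k = 0; k < K; ++k) alpha(i, k) = a[k] / c;
      logc[i] = std::log(c);
    }
    const int iT = i0 + T - 1;
    for (int k = 0; k < K; ++k) beta(iT, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const int i = i0 + t, in = i + 1;
      const double cn = std::exp(logc[in]);
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k)
          acc += A[i + (size_t)n * j + (size_t)n * K * k] * dens(in, k) * beta(in, k);
        beta(i, j) = acc / cn;
      }
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      const int i = i0 + t;
      double g = 0.0;
      for (int k = 0; k < K; ++k) g += alpha(i, k) * beta(i, k);
      for (int k = 0; k < K; ++k) gamma(i, k) = alpha(i, k) * beta(i, k) / g;
      ll += logc[i];
    }
    series_ll[s] = ll;
    if (compute_xi) {
      const int Tm = T > 1 ? T - 1 : 0;
      NumericVector x(Dimension(Tm, K, K));
      for (int t = 0; t < Tm; ++t) {
        const int i = i0 + t, in = i + 1;
        const double cn = std::exp(logc[in]);
        for (int j = 0; j < K; ++j)
          for (int k = 0; k < K; ++k)
            x[t + (size_t)Tm * j + (size_t)Tm * K * k] =
              alpha(i, j) * A[i + (size_t)n * j + (size_t)n * K * k] *
              dens(in, k) * beta(in, k) / cn;
      }
      xi[s] = x;
    }
  }
  return List::create(_["forward"] = alpha, _["backward"] = beta,
                      _["gamma"] = gamma, _["scaling_log"] = logc,
                      _["series_loglik"] = series_ll, _["xi"] = xi);
}

// Forward recursion only: per-series log-likelihoods.
// [[Rcpp::export]]
NumericVector forward_ll_core(NumericMatrix dens, NumericMatrix pi0,
                              NumericVector A, IntegerVector starts,
                              IntegerVector lens) {
  const int n = dens.nrow(), K = dens.ncol(), S = starts.size();
  NumericVector series_ll(S);
  std::vector<double> a(K), anew(K);
  for (int s = 0; s < S; ++s) {
    const int i0 = starts[s] - 1, T = lens[s];
    double c = 0.0, ll = 0.0;
    for (int k = 0; k < K; ++k) { a[k] = pi0(s, k) * dens(i0, k); c += a[k]; }
    if (!(c > 0))
      stop("all-state-zero observation density in series %d at position 1", s + 1);
    for (int k = 0; k < K; ++k) a[k] /= c;
    ll = std::log(c);
    for (int t = 1; t < T; ++t) {
      const int i = i0 + t, ip = i - 1;
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += a[j] * A[ip + (size_t)n * j + (size_t)n * K * k];
        anew[k] = acc * dens(i, k);
        c += anew[k];
      }
      if (!(c > 0))
        stop("all-state-zero observation density in series %d at position %d",
             s + 1, t + 1);
      for (int k = 0; k < K; ++k) a[k] = anew[k] / c;
      ll += std::log(c);
    }
    series_ll[s] = ll;
  }
  return series_ll;
}

// Viterbi decoding in log space; ties break toward the lowest state index.
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix ldens, NumericMatrix lpi0,
                           NumericVector lA, IntegerVector starts,
                           IntegerVector lens) {
  const int n = ldens.nrow(), K = ldens.ncol(), S = starts.size();
  IntegerVector path(n);
  for (int s = 0; s < S; ++s) {
    const int i0 = starts[s] - 1, T = lens[s];
    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);
    for (int k = 0; k < K; ++k) delta(0, k) = lpi0(s, k) + ldens(i0, k);
    for (int t = 1; t < T; ++t) {
      const int ip = i0 + t - 1;
      for (int k = 0; k < K; ++k) {
        double best = R_NegInf;
        int arg = 0;
        for (int j = 0; j < K; ++j) {
          const double cand = delta(t - 1, j) +
            lA[ip + (size_t)n * j + (size_t)n * K * k];
          if (cand > best) { best = cand; arg = j; }  // strict: keeps lowest j
        }
        delta(t, k) = best + ldens(i0 + t, k);
        psi(t, k) = arg;
      }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int k = 0; k < K; ++k)
      if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
    path[i0 + T - 1] = arg + 1;
    for (int t = T - 2; t >= 0; --t) {
      arg = psi(t + 1, arg);
      path[i0 + t] = arg + 1;
    }
  }
  return path;
}
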