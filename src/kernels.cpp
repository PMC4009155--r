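#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Packed spike layout: all window-relative spike times concatenated in one
// vector; starts/counts are n_samples x n_units (0-based start index, count)
// so sample i, unit u occupies times[starts(i,u) .. starts(i,u)+counts(i,u)-1].
// Packed LFP layout: X is n_samples x (len * n_channels), channel-major blocks.

// Cross term of the rectangular-smoothing intensity integral on [0, Ts]:
// int lambda_a lambda_b dt = (1/Tsm^2) * sum_{m,n} max(0,
//   min(a_m + Tsm, b_n + Tsm, Ts) - max(a_m, b_n)).
static double cross_intensity(const double* a, int na, const double* b, int nb,
                              double Ts, double Tsm) {
  if (na == 0 || nb == 0) return 0.0;
  long double acc = 0.0L;
  for (int j = 0; j < nb; ++j) {
    double bj = b[j], bje = bj + Tsm;
    for (int i = 0; i < na; ++i) {
      double lo = a[i] > bj ? a[i] : bj;
      double hi = a[i] + Tsm;
      if (bje < hi) hi = bje;
      if (Ts < hi) hi = Ts;
      if (hi > lo) acc += (long double)(hi - lo);
    }
  }
  return (double)acc / (Tsm * Tsm);
}

static NumericMatrix spike_self_integrals(const NumericVector& times,
                                          const IntegerMatrix& starts,
                                          const IntegerMatrix& counts,
                                          double Ts, double Tsm) {
  int n = starts.nrow(), U = starts.ncol();
  NumericMatrix self(n, U);
  const double* t = times.begin();
  for (int u = 0; u < U; ++u)
    for (int i = 0; i < n; ++i)
      self(i, u) = cross_intensity(t + starts(i, u), counts(i, u),
                                   t + starts(i, u), counts(i, u), Ts, Tsm);
  return self;
}

// Multiunit spike Schoenberg kernel between packed sample i (of A) and j (of B):
// sum over units of exp(-||lambda_i - lambda_j||^2 / sigma^2), optionally / U.
static double spike_pair(const double* tA, const IntegerMatrix& sA,
                         const IntegerMatrix& cA, const NumericMatrix& selfA,
                         int i, const double* tB, const IntegerMatrix& sB,
                         const IntegerMatrix& cB, const NumericMatrix& selfB,
                         int j, double Ts, double Tsm, double sigma2,
                         bool normalize) {
  int U = sA.ncol();
  long double acc = 0.0L;
  for (int u = 0; u < U; ++u) {
    double cr = cross_intensity(tA + sA(i, u), cA(i, u),
                                tB + sB(j, u), cB(j, u), Ts, Tsm);
    double d2 = selfA(i, u) + selfB(j, u) - 2.0 * cr;
    // identical (typically both-empty) windows: exp(0) without the libm call
    if (d2 <= 0.0) acc += 1.0;
    else acc += std::exp(-d2 / sigma2);
  }
  double v = (double)acc;
  return normalize ? v / U : v;
}

// [[Rcpp::export]]
NumericMatrix cpp_spike_gram(NumericVector times, IntegerMatrix starts,
                             IntegerMatrix counts, double Ts, double Tsm,
                             double sigma, bool normalize) {
  int n = starts.nrow();
  NumericMatrix K(n, n);
  NumericMatrix self = spike_self_integrals(times, starts, counts, Ts, Tsm);
  double s2 = sigma * sigma;
  const double* t = times.begin();
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      double v = spike_pair(t, starts, counts, self, i,
                            t, starts, counts, self, j,
                            Ts, Tsm, s2, normalize);
      K(i, j) = v;
      K(j, i) = v;
    }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_spike_cross(NumericVector timesA, IntegerMatrix startsA,
                              IntegerMatrix countsA, NumericVector timesB,
                              IntegerMatrix startsB, IntegerMatrix countsB,
                              double Ts, double Tsm, double sigma,
                              bool normalize) {
  int nA = startsA.nrow(), nB = startsB.nrow();
  NumericMatrix K(nA, nB);
  NumericMatrix selfA = spike_self_integrals(timesA, startsA, countsA, Ts, Tsm);
  NumericMatrix selfB = spike_self_integrals(timesB, startsB, countsB, Ts, Tsm);
  double s2 = sigma * sigma;
  for (int j = 0; j < nB; ++j)
    for (int i = 0; i < nA; ++i)
      K(i, j) = spike_pair(timesA.begin(), startsA, countsA, selfA, i,
                           timesB.begin(), startsB, countsB, selfB, j,
                           Ts, Tsm, s2, normalize);
  return K;
}

// Mean pre-exponential squared distance over single-unit comparisons,
// skipping identical (zero-distance) ones: with sparse windows most unit
// pairs are both empty and carry no scale information, and the kernel size
// applies to single-unit intensity distances. Feeds the kernel-size
// heuristic.
// [[Rcpp::export]]
double cpp_spike_mean_sqdist(NumericVector times, IntegerMatrix starts,
                             IntegerMatrix counts, double Ts, double Tsm) {
  int n = starts.nrow(), U = starts.ncol();
  NumericMatrix self = spike_self_integrals(times, starts, counts, Ts, Tsm);
  const double* t = times.begin();
  long double acc = 0.0L;
  long double n_nonzero = 0.0L;
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) {
      for (int u = 0; u < U; ++u) {
        if (counts(i, u) == 0 && counts(j, u) == 0) continue;
        double cr = cross_intensity(t + starts(i, u), counts(i, u),
                                    t + starts(j, u), counts(j, u), Ts, Tsm);
        double d2 = self(i, u) + self(j, u) - 2.0 * cr;
        if (d2 > 1e-15) { acc += d2; n_nonzero += 1.0L; }
      }
    }
  if (n_nonzero == 0.0L) return 0.0;
  return (double)(acc / n_nonzero);
}

// Multichannel LFP Schoenberg kernel; squared distance is the left Riemann
// sum tau * sum_k (a_k - b_k)^2 per channel.
static double lfp_pair(const NumericMatrix& A, int i, const NumericMatrix& B,
                       int j, int len, int C, double tau, double sigma2,
                       bool normalize) {
  long double acc = 0.0L;
  for (int c = 0; c < C; ++c) {
    long double ssd = 0.0L;
    int off = c * len;
    for (int k = 0; k < len; ++k) {
      double d = A(i, off + k) - B(j, off + k);
      ssd += (long double)(d * d);
    }
    acc += std::exp(-((double)ssd * tau) / sigma2);
  }
  double v = (double)acc;
  return normalize ? v / C : v;
}

// [[Rcpp::export]]
NumericMatrix cpp_lfp_gram(NumericMatrix X, int len, int n_channels,
                           double tau, double sigma, bool normalize) {
  int n = X.nrow();
  NumericMatrix K(n, n);
  double s2 = sigma * sigma;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      double v = lfp_pair(X, i, X, j, len, n_channels, tau, s2, normalize);
      K(i, j) = v;
      K(j, i) = v;
    }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_lfp_cross(NumericMatrix XA, NumericMatrix XB, int len,
                            int n_channels, double tau, double sigma,
                            bool normalize) {
  int nA = XA.nrow(), nB = XB.nrow();
  NumericMatrix K(nA, nB);
  double s2 = sigma * sigma;
  for (int j = 0; j < nB; ++j)
    for (int i = 0; i < nA; ++i)
      K(i, j) = lfp_pair(XA, i, XB, j, len, n_channels, tau, s2, normalize);
  return K;
}

// Mean pre-exponential squared distance over single-channel comparisons
// (identical pairs skipped, as for spikes; LFP pairs are virtually never
// identical, so this matches the plain all-pairs mean there).
// [[Rcpp::export]]
double cpp_lfp_mean_sqdist(NumericMatrix X, int len, int n_channels,
                           double tau) {
  int n = X.nrow();
  long double acc = 0.0L;
  long double n_nonzero = 0.0L;
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) {
      for (int c = 0; c < n_channels; ++c) {
        long double ssd = 0.0L;
        int off = c * len;
        for (int k = 0; k < len; ++k) {
          double d = X(i, off + k) - X(j, off + k);
          ssd += (long double)(d * d);
        }
        double d2 = (double)ssd * tau;
        if (d2 > 1e-15) { acc += d2; n_nonzero += 1.0L; }
      }
    }
  if (n_nonzero == 0.0L) return 0.0;
  return (double)(acc / n_nonzero);
}

// The Q-KLMS recursion replayed against a precomputed kernel matrix:
// identical decisions to the online reference path. Returns the dictionary
// (1-based input indices), coefficients, per-step errors and dictionary
// sizes.
// [[Rcpp::export]]
List cpp_qklms_gram_fit(NumericMatrix K, NumericMatrix targets, double eta,
                        double eps, int epochs) {
  int n = K.nrow();
  int M = targets.ncol();
  NumericVector selfs(n);
  for (int i = 0; i < n; ++i) selfs[i] = K(i, i);
  NumericMatrix coef(M, n);
  IntegerVector dict(n);
  int Ncur = 0;
  NumericMatrix E(n * epochs, M);
  IntegerVector dict_size(n * epochs);
  std::vector<double> e(M);
  int r = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int j = 0; j < n; ++j, ++r) {
      if (Ncur == 0) {
        for (int m = 0; m < M; ++m) e[m] = targets(j, m);
        dict[0] = j;
        Ncur = 1;
        for (int m = 0; m < M; ++m) coef(m, 0) = eta * e[m];
      } else {
        const double* kcol = &K(0, j);
        double best = R_PosInf;
        int ibest = 0;
        for (int c = 0; c < Ncur; ++c) {
          double d2 = selfs[j] + selfs[dict[c]] - 2.0 * kcol[dict[c]];
          if (d2 < best) { best = d2; ibest = c; }
        }
        for (int m = 0; m < M; ++m) {
          long double acc = 0.0L;
          for (int c = 0; c < Ncur; ++c) acc += coef(m, c) * kcol[dict[c]];
          e[m] = targets(j, m) - (double)acc;
        }
        if (std::sqrt(best > 0.0 ? best : 0.0) <= eps) {
          for (int m = 0; m < M; ++m) coef(m, ibest) += eta * e[m];
        } else {
          dict[Ncur] = j;
          for (int m = 0; m < M; ++m) coef(m, Ncur) = eta * e[m];
          ++Ncur;
        }
      }
      for (int m = 0; m < M; ++m) E(r, m) = e[m];
      dict_size[r] = Ncur;
    }
  }
  IntegerVector dict_out(Ncur);
  NumericMatrix coef_out(M, Ncur);
  for (int c = 0; c < Ncur; ++c) {
    dict_out[c] = dict[c] + 1;
    for (int m = 0; m < M; ++m) coef_out(m, c) = coef(m, c);
  }
  return List::create(_["dict"] = dict_out, _["coef"] = coef_out,
                      _["E"] = E, _["dict_size"] = dict_size);
}
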