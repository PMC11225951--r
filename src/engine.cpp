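#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Streaming engine for the ocd / ocd' recursions.
//
// The normative state is the matrix of residual tail lengths t[j, b] and
// tail partial-sum vectors A[, j, b] over (coordinate, signed scale) pairs,
// updated with the reset recursion: after adding a new observation,
// (t, A) <- (0, 0) whenever b * A[j, j, b] - b^2 * t[j, b] / 2 <= 0.
//
// Internally the engine exploits the identity
//   A[j', j, b] = CS[n, j'] - CS[n - t[j, b], j']
// where CS holds cumulative sums of the stream, so only the diagonal sums
// have to be tracked through the recursion and the off-diagonal aggregation
// can be grouped by distinct tail length. This is an exact reformulation
// (up to floating-point association) of the online update, used because it
// makes gamma = 30000 calibration runs cheap; the R-level reference
// implementation in detector-state.R keeps the literal O(p^2 |B|) state and
// the two are cross-checked in the test suite.
//
// scales: signed scales of B0 followed by B, in the package's fixed order
// in_B:   TRUE for entries of B (off-diagonal aggregation for ocd),
//         FALSE for B0 (used by ocd')

// [[Rcpp::export]]
List ocd_engine(NumericMatrix X, NumericVector scales, LogicalVector in_B,
                double a_tilde, double T_diag, double T_off,
                int l, bool calibrate, bool prime) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int K = scales.size();

  // cumulative sums, row-major: CS[i * p + j] = sum of X[1..i, j], CS[0,] = 0
  std::vector<double> CS((size_t)(n + 1) * p, 0.0);
  for (int i = 1; i <= n; ++i) {
    const double* prev = &CS[(size_t)(i - 1) * p];
    double* cur = &CS[(size_t)i * p];
    for (int j = 0; j < p; ++j) cur[j] = prev[j] + X(i - 1, j);
  }

  std::vector<int> t((size_t)p * K, 0);
  std::vector<int> offK;
  for (int k = 0; k < K; ++k) {
    if (prime ? !in_B[k] : (bool)in_B[k]) offK.push_back(k);
  }

  // per-step workspace for grouping the off-diagonal sums by tail length
  std::vector<double> V((size_t)n + 1, 0.0);
  std::vector<int> stamp((size_t)n + 1, -1);

  double max_diag = 0.0, max_off = 0.0;
  bool declared = false;
  int N = n;
  int trigger = 0;  // 0 none, 1 diag, 2 offdiag
  double stat_diag = 0.0, stat_off = 0.0;

  for (int i = 1; i <= n; ++i) {
    const double* csi = &CS[(size_t)i * p];

    // tail-length recursion + diagonal statistic
    double sdiag = 0.0;
    for (int k = 0; k < K; ++k) {
      const double b = scales[k];
      const double bh = b * b * 0.5;
      int* tk = &t[(size_t)k * p];
      for (int j = 0; j < p; ++j) {
        int tj = tk[j] + 1;
        double D = csi[j] - CS[(size_t)(i - tj) * p + j];
        double g = b * D - bh * tj;
        if (g <= 0.0) { tj = 0; g = 0.0; }
        tk[j] = tj;
        if (g > sdiag) sdiag = g;
      }
    }

    // off-diagonal statistic: hard-thresholded sum of squared normalized
    // tail averages over the other coordinates, maximized over (j, b)
    double soff = 0.0;
    for (size_t m = 0; m < offK.size(); ++m) {
      const int k = offK[m];
      const int* tk = &t[(size_t)k * p];
      for (int j = 0; j < p; ++j) {
        const int tj = tk[j];
        if (stamp[tj] != i) {
          double s = 0.0;
          if (tj > 0) {
            const double inv = 1.0 / std::sqrt((double)tj);
            const double* csh = &CS[(size_t)(i - tj) * p];
            for (int jj = 0; jj < p; ++jj) {
              double e = (csi[jj] - csh[jj]) * inv;
              if (std::fabs(e) >= a_tilde) s += e * e;
            }
          }
          V[tj] = s;
          stamp[tj] = i;
        }
        double q = V[tj];
        if (tj > 0) {
          double e = (csi[j] - CS[(size_t)(i - tj) * p + j]) /
                     std::sqrt((double)tj);
          if (std::fabs(e) >= a_tilde) q -= e * e;
        }
        if (q > soff) soff = q;
      }
    }

    if (calibrate) {
      if (sdiag > max_diag) max_diag = sdiag;
      if (soff > max_off) max_off = soff;
    } else if (sdiag >= T_diag || soff >= T_off) {
      declared = true;
      N = i;
      trigger = (sdiag >= T_diag) ? 1 : 2;
      stat_diag = sdiag;
      stat_off = soff;
      break;
    }
    if (i == n) { stat_diag = sdiag; stat_off = soff; }
  }

  if (calibrate) {
    return List::create(_["max_diag"] = max_diag, _["max_off"] = max_off);
  }

  // snapshot at N: tail lengths, full tail partial sums, extra observations
  IntegerMatrix tmat(p, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < p; ++j) tmat(j, k) = t[(size_t)k * p + j];

  NumericVector A((R_xlen_t)p * p * K);
  const double* csN = &CS[(size_t)N * p];
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < p; ++j) {
      const int tj = t[(size_t)k * p + j];
      const double* csh = &CS[(size_t)(N - tj) * p];
      double* Aj = &A[(R_xlen_t)p * (j + (R_xlen_t)p * k)];
      for (int jj = 0; jj < p; ++jj) Aj[jj] = csN[jj] - csh[jj];
    }
  }

  NumericVector extra(p);
  int l_avail = std::min(l, n - N);
  if (l_avail > 0) {
    const double* cse = &CS[(size_t)(N + l_avail) * p];
    for (int j = 0; j < p; ++j) extra[j] = cse[j] - csN[j];
  }

  return List::create(
      _["declared"] = declared, _["N"] = N, _["trigger"] = trigger,
      _["stat_diag"] = stat_diag, _["stat_off"] = stat_off, _["t"] = tmat,
      _["A"] = A, _["extra_sum"] = extra, _["l_avail"] = l_avail);
}
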