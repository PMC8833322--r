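#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
//
// sire, dam: 1-based positions of each animal's parents in a pedigree already
// sorted so that parents precede offspring; 0 = unknown parent. The trick of
// carrying f = -1 for the unknown-parent slot makes the within-family
// (Mendelian sampling) variance d come out right for all three parent-
// knowledge cases: d = 1 (none known), 0.75 - 0.25*F_p (one known),
// 0.5 - 0.25*(F_s + F_d) (both known).
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> f(n + 1, 0.0);   // f[0] is the unknown-parent slot
  f[0] = -1.0;
  std::vector<double> D(n + 1, 0.0);   // Mendelian sampling variances
  std::vector<double> L(n + 1, 0.0);   // path coefficients, reset as we pop
  std::vector<char> inq(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    const int s = sire[i - 1], d = dam[i - 1];
    if (s < 0 || s > n || d < 0 || d > n || s >= i || d >= i)
      stop("pedigree is not sorted: parent index out of range at position %d", i);
    D[i] = 0.5 - 0.25 * (f[s] + f[d]);
    if (s == 0 || d == 0) {            // at least one unknown parent: F = 0
      f[i] = 0.0;
      F[i - 1] = 0.0;
      continue;
    }
    double fi = -1.0;                  // accumulates a_ii - 1 over ancestors
    L[i] = 1.0;
    std::priority_queue<int> q;        // ancestors processed youngest-first
    q.push(i);
    inq[i] = 1;
    while (!q.empty()) {
      const int j = q.top();
      q.pop();
      inq[j] = 0;
      const double Lj = L[j];
      L[j] = 0.0;
      fi += Lj * Lj * D[j];
      const int sj = sire[j - 1], dj = dam[j - 1];
      if (sj) {
        L[sj] += 0.5 * Lj;
        if (!inq[sj]) { q.push(sj); inq[sj] = 1; }
      }
      if (dj) {
        L[dj] += 0.5 * Lj;
        if (!inq[dj]) { q.push(dj); inq[dj] = 1; }
      }
    }
    f[i] = fi;
    F[i - 1] = fi;
  }
  return F;
}
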