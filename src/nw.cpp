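#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global Needleman-Wunsch with linear gap penalty. Returns the optimal
// score plus match count and alignment length from a canonical traceback
// (ties resolved diagonal > up > left, so the reported identity is a pure
// function of the inputs).
// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  // full matrix kept for traceback; desk-scale sequences only
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(n + 1));
  for (int j = 0; j <= n; ++j) F[0][j] = j * gap;
  for (int i = 1; i <= m; ++i) {
    F[i][0] = i * gap;
    for (int j = 1; j <= n; ++j) {
      double diag = F[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = F[i - 1][j] + gap;
      double left = F[i][j - 1] + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F[i][j] = best;
    }
  }
  int i = m, j = n, matches = 0, len = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(F[i][j] - (F[i - 1][j - 1] +
                 (a[i - 1] == b[j - 1] ? match : mismatch))) < eps) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && std::abs(F[i][j] - (F[i - 1][j] + gap)) < eps) {
      --i;
    } else {
      --j;
    }
    ++len;
  }
  return List::create(_["score"] = F[m][n],
                      _["matches"] = matches,
                      _["length"] = len);
}
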