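#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch -1,
// linear gap -2. Traceback prefers diagonal, then gap-in-b, then
// gap-in-a (deterministic). Identity is matches / aligned columns with
// terminal gap columns excluded; internal gap columns count in the
// denominator but never match.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const int GAP = -2;
  const int W = m + 1;
  // flat DP matrix for traceback (n,m <= a few kb: fine)
  std::vector<int> S((size_t)(n + 1) * W);
  for (int j = 0; j <= m; j++) S[j] = GAP * j;
  for (int i = 1; i <= n; i++) {
    const int *up_row = &S[(size_t)(i - 1) * W];
    int *row = &S[(size_t)i * W];
    const char ai = a[i - 1];
    row[0] = GAP * i;
    for (int j = 1; j <= m; j++) {
      int diag = up_row[j - 1] + (ai == b[j - 1] ? 1 : -1);
      int up = up_row[j] + GAP;
      int left = row[j - 1] + GAP;
      int best = diag >= up ? diag : up;
      if (left > best) best = left;
      row[j] = best;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = S[(size_t)i * W + j];
    if (i > 0 && j > 0 &&
        cur == S[(size_t)(i - 1) * W + j - 1] +
                 (a[i - 1] == b[j - 1] ? 1 : -1)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); i--; j--;
    } else if (i > 0 && cur == S[(size_t)(i - 1) * W + j] + GAP) {
      ra.push_back(a[i - 1]); rb.push_back('-'); i--;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); j--;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  const int L = ra.size();
  int i0 = -1, i1 = -1;
  for (int k = 0; k < L; k++) {
    if (ra[k] != '-' && rb[k] != '-') { if (i0 < 0) i0 = k; i1 = k; }
  }
  double ident = 0;
  if (i0 >= 0) {
    int matches = 0;
    for (int k = i0; k <= i1; k++) {
      if (ra[k] == rb[k] && ra[k] != '-') matches++;
    }
    ident = (double)matches / (double)(i1 - i0 + 1);
  }
  return List::create(_["a"] = ra, _["b"] = rb, _["identity"] = ident,
                      _["score"] = S[(size_t)n * W + m]);
}
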