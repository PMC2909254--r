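#include <Rcpp.h>
using namespace Rcpp;

// Independent (trial) swap chain on a binary presence/absence matrix.
// Each trial picks two distinct rows and two distinct columns uniformly;
// if the 2x2 submatrix is a checkerboard it is flipped, which preserves
// row sums (sample richness) and column sums (species frequency) exactly.
// Uses R's RNG so the chain is reproducible from set.seed().
// [[Rcpp::export]]
List swap_chain_cpp(IntegerMatrix m, double n_trials) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix x = clone(m);
  double accepted = 0;
  if (nr < 2 || nc < 2) {
    return List::create(_["matrix"] = x, _["accepted"] = accepted);
  }
  for (double t = 0; t < n_trials; t++) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    if (a == d && b == c && a != b) {
      x(r1, c1) = b; x(r1, c2) = a;
      x(r2, c1) = d; x(r2, c2) = c;
      accepted += 1;
    }
  }
  return List::create(_["matrix"] = x, _["accepted"] = accepted);
}
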