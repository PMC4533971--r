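#include <Rcpp.h>
using namespace Rcpp;

// Curveball trades on a binary incidence matrix. Each step picks two rows
// and randomly redistributes the columns held by exactly one of them,
// conserving both margins. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix curveball_trades(const IntegerMatrix& m, const int steps) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix a = clone(m);
  if (nr < 2) return a;
  std::vector<int> pool;
  pool.reserve(nc);
  for (int s = 0; s < steps; ++s) {
    int i = (int)(unif_rand() * nr);
    int j = (int)(unif_rand() * nr);
    if (i >= nr) i = nr - 1;
    if (j >= nr) j = nr - 1;
    if (i == j) continue;
    pool.clear();
    int ka = 0; // columns unique to row i
    for (int c = 0; c < nc; ++c) {
      const int ai = a(i, c), aj = a(j, c);
      if (ai == 1 && aj == 0) { pool.push_back(c); ++ka; }
      else if (ai == 0 && aj == 1) pool.push_back(c);
    }
    const int n = (int)pool.size();
    if (ka == 0 || ka == n) continue;
    // choose ka of the pooled columns for row i by partial Fisher-Yates
    for (int k = 0; k < ka; ++k) {
      int r = k + (int)(unif_rand() * (n - k));
      if (r >= n) r = n - 1;
      std::swap(pool[k], pool[r]);
    }
    for (int k = 0; k < n; ++k) {
      const int c = pool[k];
      a(i, c) = (k < ka) ? 1 : 0;
      a(j, c) = (k < ka) ? 0 : 1;
    }
  }
  return a;
}
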