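#include <Rcpp.h>
using namespace Rcpp;

// Geodesic distance within a mask by iterated two-direction chamfer
// sweeps (8-neighborhood, weights 1 and sqrt(2)). Seeds carry distance 0;
// propagation never leaves the mask, so concave regions are measured
// along in-mask paths. Sweeps repeat until stable, which handles masks
// whose geodesics wind (C-shapes, spirals).
// [[Rcpp::export]]
NumericMatrix chamfer_geodesic(LogicalMatrix mask, LogicalMatrix seeds) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double W1 = 1.0, W2 = std::sqrt(2.0);
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? (seeds(i, j) ? 0.0 : R_PosInf) : NA_REAL;

  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10000) {
    changed = false;
    // forward sweep
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!mask(i, j)) continue;
        double v = d(i, j);
        if (i > 0 && mask(i - 1, j)) v = std::min(v, d(i - 1, j) + W1);
        if (j > 0 && mask(i, j - 1)) v = std::min(v, d(i, j - 1) + W1);
        if (i > 0 && j > 0 && mask(i - 1, j - 1)) v = std::min(v, d(i - 1, j - 1) + W2);
        if (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) v = std::min(v, d(i + 1, j - 1) + W2);
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
    // backward sweep
    for (int j = nc - 1; j >= 0; --j) {
      for (int i = nr - 1; i >= 0; --i) {
        if (!mask(i, j)) continue;
        double v = d(i, j);
        if (i < nr - 1 && mask(i + 1, j)) v = std::min(v, d(i + 1, j) + W1);
        if (j < nc - 1 && mask(i, j + 1)) v = std::min(v, d(i, j + 1) + W1);
        if (i < nr - 1 && j < nc - 1 && mask(i + 1, j + 1)) v = std::min(v, d(i + 1, j + 1) + W2);
        if (i > 0 && j < nc - 1 && mask(i - 1, j + 1)) v = std::min(v, d(i - 1, j + 1) + W2);
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
  }
  return d;
}
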