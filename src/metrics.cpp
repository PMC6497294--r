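#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Pair-offset tallies for the NC density probability function. For every
// ordered pair of occupied sites (R, R2) the offset r = R2 - R is counted in
// `num`; `denom` counts, per offset, the occupied reference sites R for which
// R + r stays inside the lattice (offsets leaving the lattice are excluded
// from numerator and denominator alike). rho = num / denom.
// [[Rcpp::export]]
List cpp_density_tallies(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> xs, ys;
  xs.reserve(1024); ys.reserve(1024);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (mask(y, x) != 0) { xs.push_back(x); ys.push_back(y); }
  size_t n = xs.size();
  int DW = 2 * W - 1, DH = 2 * H - 1;
  NumericMatrix num(DH, DW), denom(DH, DW);
  for (size_t a = 0; a < n; ++a) {
    int xa = xs[a], ya = ys[a];
    for (size_t b = 0; b < n; ++b) {
      int dx = xs[b] - xa + (W - 1);
      int dy = ys[b] - ya + (H - 1);
      num(dy, dx) += 1.0;
    }
    if ((a & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // prefix sums of the mask for rectangle counts
  std::vector<double> pre((W + 1) * (H + 1), 0.0);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      pre[(x + 1) * (H + 1) + (y + 1)] =
        pre[x * (H + 1) + (y + 1)] + pre[(x + 1) * (H + 1) + y]
        - pre[x * (H + 1) + y] + (mask(y, x) != 0 ? 1.0 : 0.0);
  for (int dx = -(W - 1); dx <= W - 1; ++dx) {
    int x0 = std::max(0, -dx), x1 = std::min(W - 1, W - 1 - dx);
    for (int dy = -(H - 1); dy <= H - 1; ++dy) {
      int y0 = std::max(0, -dy), y1 = std::min(H - 1, H - 1 - dy);
      double cnt = pre[(x1 + 1) * (H + 1) + (y1 + 1)]
                 - pre[x0 * (H + 1) + (y1 + 1)]
                 - pre[(x1 + 1) * (H + 1) + y0]
                 + pre[x0 * (H + 1) + y0];
      denom(dy + H - 1, dx + W - 1) = cnt;
    }
  }
  return List::create(_["num"] = num, _["denom"] = denom,
                      _["n_sites"] = (double)n);
}
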