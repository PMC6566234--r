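#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft (partial-volume) joint histogram: each sample splits linearly
// between the two adjacent bins in each image, making downstream MI
// continuous in the intensity values. Ranges are fixed by the caller.
// [[Rcpp::export(name = ".soft_hist_cpp")]]
NumericMatrix soft_hist_cpp(NumericVector x, NumericVector y, int bins,
                            double ax, double bx, double ay, double by) {
  NumericMatrix h(bins, bins);
  const double sx = (bx > ax) ? (bins - 1) / (bx - ax) : 0.0;
  const double sy = (by > ay) ? (bins - 1) / (by - ay) : 0.0;
  const int n = x.size();
  for (int q = 0; q < n; ++q) {
    double u = (x[q] - ax) * sx;
    double v = (y[q] - ay) * sy;
    if (u < 0) u = 0; if (u > bins - 1) u = bins - 1;
    if (v < 0) v = 0; if (v > bins - 1) v = bins - 1;
    int iu = (int)std::floor(u); if (iu > bins - 2) iu = bins - 2;
    int iv = (int)std::floor(v); if (iv > bins - 2) iv = bins - 2;
    const double fu = u - iu, fv = v - iv;
    h(iu, iv) += (1 - fu) * (1 - fv);
    h(iu + 1, iv) += fu * (1 - fv);
    h(iu, iv + 1) += (1 - fu) * fv;
    h(iu + 1, iv + 1) += fu * fv;
  }
  return h;
}
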