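#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize a polyline given in final-pixel coordinates (pixel centres at
// integer positions, row 0 at the top) onto a side x side canvas.
// The line is drawn one supersample-pixel wide on a (side*ss) x (side*ss)
// grid, then box-averaged down to side x side, giving coverage in [0, 1].
// [[Rcpp::export]]
NumericMatrix rasterize_polyline_cpp(NumericVector x, NumericVector y,
                                     int side, int ss) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  if (x.size() < 2) stop("polyline needs at least 2 points");
  const int S = side * ss;
  std::vector<unsigned char> canvas((size_t)S * S, 0);

  // stamp an ss x ss square so the line is one final pixel thick; partial
  // overlap of the square with a block is what produces the gray ramp
  auto mark = [&](double px, double py) {
    long x0 = (long)std::lround(px * ss);
    long y0 = (long)std::lround(py * ss);
    for (long dy = 0; dy < ss; ++dy) {
      long cy = y0 + dy;
      if (cy < 0 || cy > S - 1) continue;
      for (long dx = 0; dx < ss; ++dx) {
        long cx = x0 + dx;
        if (cx < 0 || cx > S - 1) continue;
        canvas[(size_t)cy * S + cx] = 1;
      }
    }
  };

  const int n = x.size();
  for (int i = 0; i + 1 < n; ++i) {
    double x0 = x[i], y0 = y[i], x1 = x[i + 1], y1 = y[i + 1];
    double len = std::max(std::fabs(x1 - x0), std::fabs(y1 - y0)) * ss;
    int steps = (int)std::ceil(len) + 1;
    for (int s = 0; s < steps; ++s) {
      double t = (steps == 1) ? 0.0 : (double)s / (steps - 1);
      mark(x0 + t * (x1 - x0), y0 + t * (y1 - y0));
    }
  }

  NumericMatrix out(side, side);
  const double denom = (double)ss * ss;
  for (int r = 0; r < side; ++r) {
    for (int c = 0; c < side; ++c) {
      int acc = 0;
      for (int rr = r * ss; rr < (r + 1) * ss; ++rr)
        for (int cc = c * ss; cc < (c + 1) * ss; ++cc)
          acc += canvas[(size_t)rr * S + cc];
      out(r, c) = acc / denom;
    }
  }
  return out;
}
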