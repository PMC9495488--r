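#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// All 4-d tensors use the layout (H, W, B, C) in R's column-major order:
// height fastest, then width, then batch item, then channel.
//
// The 12 per-lead towers run as one grouped convolution: the lead tensors
// are concatenated along the channel axis (C = groups * c_in) and the
// weight matrix holds one column block of c_out filters per group
// (C_w = groups * c_out), so a single call advances every lead one layer.
// With `shared = true` the weight matrix holds a single block applied to
// every group (tied towers) and gradients accumulate over groups.
// Convolutions are valid (no padding), stride 1, kernel 3; weight rows are
// ordered (ky, kx, ci), the column-major flattening of a (3, 3, c_in)
// block.

static inline void get_dims4(const NumericVector &a, int d[4]) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array (H, W, B, C)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static inline int bias_len(int groups, int cout, bool shared) {
  return cout * (shared ? 1 : groups);
}

// [[Rcpp::export]]
NumericVector conv3g_fwd_cpp(NumericVector a, NumericMatrix w,
                             NumericVector bias, int groups, bool shared) {
  int d[4]; get_dims4(a, d);
  const int H = d[0], W = d[1], B = d[2], C = d[3];
  const int k = 3;
  if (H < k || W < k) stop("input smaller than kernel");
  if (C % groups != 0) stop("channels not divisible by groups");
  const int cin = C / groups;
  if (w.nrow() != k * k * cin) stop("weight rows do not match group channels");
  const int wcols = w.ncol();
  const int cout = shared ? wcols : wcols / groups;
  if (!shared && wcols % groups != 0) stop("weight columns not divisible by groups");
  if ((int)bias.size() != cout * (shared ? 1 : groups)) stop("bias length mismatch");
  const int oh = H - k + 1, ow = W - k + 1;
  NumericVector out((R_xlen_t)oh * ow * B * groups * cout);
  out.attr("dim") = IntegerVector::create(oh, ow, B, groups * cout);
  const double *A = a.begin();
  double *O = out.begin();
  for (int g = 0; g < groups; ++g) {
    const double *wg = &w(0, shared ? 0 : g * cout);
    const double *bg = &bias[shared ? 0 : g * cout];
    for (int co = 0; co < cout; ++co) {
      const double *wc = wg + (R_xlen_t)w.nrow() * co;
      const int oc = g * cout + co;
      for (int b = 0; b < B; ++b) {
        double *Ob = O + (R_xlen_t)oh * ow * (b + (R_xlen_t)B * oc);
        for (int x = 0; x < ow; ++x) {
          double *ocol = Ob + (R_xlen_t)oh * x;
          for (int y = 0; y < oh; ++y) ocol[y] = bg[co];
        }
        for (int ci = 0; ci < cin; ++ci) {
          const int ic = g * cin + ci;
          const double *Ab = A + (R_xlen_t)H * W * (b + (R_xlen_t)B * ic);
          for (int kx = 0; kx < k; ++kx) {
            for (int ky = 0; ky < k; ++ky) {
              const double wv = wc[ky + k * kx + k * k * ci];
              for (int x = 0; x < ow; ++x) {
                const double *acol = Ab + (R_xlen_t)H * (x + kx) + ky;
                double *ocol = Ob + (R_xlen_t)oh * x;
                for (int y = 0; y < oh; ++y) ocol[y] += wv * acol[y];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3g_bwd_cpp(NumericVector a, NumericMatrix w, NumericVector dout,
                    int groups, bool shared, bool need_dx) {
  int d[4]; get_dims4(a, d);
  const int H = d[0], W = d[1], B = d[2], C = d[3];
  const int k = 3;
  const int cin = C / groups;
  const int wcols = w.ncol();
  const int cout = shared ? wcols : wcols / groups;
  const int oh = H - k + 1, ow = W - k + 1;
  if ((R_xlen_t)dout.size() != (R_xlen_t)oh * ow * B * groups * cout)
    stop("gradient size mismatch");
  NumericVector da(need_dx ? (R_xlen_t)H * W * B * C : 0);
  if (need_dx) da.attr("dim") = IntegerVector::create(H, W, B, C);
  NumericMatrix dw(w.nrow(), wcols);
  NumericVector db(bias_len(groups, cout, shared));
  const double *A = a.begin();
  const double *dO = dout.begin();
  double *dA = da.begin();
  for (int g = 0; g < groups; ++g) {
    const double *wg = &w(0, shared ? 0 : g * cout);
    double *dwg = &dw(0, shared ? 0 : g * cout);
    double *dbg = &db[shared ? 0 : g * cout];
    for (int co = 0; co < cout; ++co) {
      const double *wc = wg + (R_xlen_t)w.nrow() * co;
      double *dwc = dwg + (R_xlen_t)w.nrow() * co;
      const int oc = g * cout + co;
      double dbacc = 0.0;
      for (int b = 0; b < B; ++b) {
        const double *dOb = dO + (R_xlen_t)oh * ow * (b + (R_xlen_t)B * oc);
        for (int x = 0; x < ow; ++x) {
          const double *dcol = dOb + (R_xlen_t)oh * x;
          for (int y = 0; y < oh; ++y) dbacc += dcol[y];
        }
        for (int ci = 0; ci < cin; ++ci) {
          const int ic = g * cin + ci;
          const double *Ab = A + (R_xlen_t)H * W * (b + (R_xlen_t)B * ic);
          double *dAb = need_dx ? dA + (R_xlen_t)H * W * (b + (R_xlen_t)B * ic)
                                : nullptr;
          for (int kx = 0; kx < k; ++kx) {
            for (int ky = 0; ky < k; ++ky) {
              const double wv = wc[ky + k * kx + k * k * ci];
              double wacc = 0.0;
              if (need_dx) {
                for (int x = 0; x < ow; ++x) {
                  const double *acol = Ab + (R_xlen_t)H * (x + kx) + ky;
                  double *dacol = dAb + (R_xlen_t)H * (x + kx) + ky;
                  const double *dcol = dOb + (R_xlen_t)oh * x;
                  for (int y = 0; y < oh; ++y) {
                    wacc += acol[y] * dcol[y];
                    dacol[y] += wv * dcol[y];
                  }
                }
              } else {
                for (int x = 0; x < ow; ++x) {
                  const double *acol = Ab + (R_xlen_t)H * (x + kx) + ky;
                  const double *dcol = dOb + (R_xlen_t)oh * x;
                  for (int y = 0; y < oh; ++y) wacc += acol[y] * dcol[y];
                }
              }
              dwc[ky + k * kx + k * k * ci] += wacc;
            }
          }
        }
      }
      dbg[co] += dbacc;
    }
  }
  return List::create(_["dx"] = da, _["dW"] = dw, _["db"] = db);
}

// channel count = last dimension; works for (N x C) matrices and 4-d
// (H, W, B, C) arrays alike, avoiding reshape copies in R
static inline R_xlen_t channel_rows(const NumericVector &z, int &c) {
  SEXP dimattr = z.attr("dim");
  if (Rf_isNull(dimattr)) stop("activation must have a dim attribute");
  IntegerVector dim(dimattr);
  c = dim[dim.size() - 1];
  return z.size() / c;
}

// Fused columnwise batch normalization + optional ReLU over the channel
// (last) dimension of an activation tensor. The backward pass recomputes
// the normalized values from the cached pre-normalization activations
// (mean, istd), so no extra activation-sized cache is allocated.
// [[Rcpp::export]]
List bn_relu_fwd_cpp(NumericVector z, NumericVector gamma, NumericVector beta,
                     NumericVector running_mean, NumericVector running_var,
                     bool training, bool relu, double momentum, double eps) {
  int c;
  const R_xlen_t n = channel_rows(z, c);
  NumericVector out(z.size());
  out.attr("dim") = z.attr("dim");
  const double *Z = z.begin();
  double *OUT = out.begin();
  if (training) {
    NumericVector mean(c), istd(c), new_rm(c), new_rv(c);
    for (int j = 0; j < c; ++j) {
      const double *zc = Z + n * j;
      double m = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) m += zc[i];
      m /= n;
      double v = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) { double t = zc[i] - m; v += t * t; }
      v /= n;
      const double is = 1.0 / std::sqrt(v + eps);
      mean[j] = m;
      istd[j] = is;
      new_rm[j] = (1 - momentum) * running_mean[j] + momentum * m;
      new_rv[j] = (1 - momentum) * running_var[j] + momentum * v;
      double *oc = OUT + n * j;
      const double g = gamma[j], bta = beta[j];
      for (R_xlen_t i = 0; i < n; ++i) {
        double y = g * (zc[i] - m) * is + bta;
        if (relu && y < 0) y = 0;
        oc[i] = y;
      }
    }
    return List::create(_["out"] = out, _["mean"] = mean, _["istd"] = istd,
                        _["running_mean"] = new_rm, _["running_var"] = new_rv);
  } else {
    for (int j = 0; j < c; ++j) {
      const double *zc = Z + n * j;
      double *oc = OUT + n * j;
      const double is = 1.0 / std::sqrt(running_var[j] + eps);
      const double m = running_mean[j], g = gamma[j], bta = beta[j];
      for (R_xlen_t i = 0; i < n; ++i) {
        double y = g * (zc[i] - m) * is + bta;
        if (relu && y < 0) y = 0;
        oc[i] = y;
      }
    }
    return List::create(_["out"] = out);
  }
}

// Backward of the fused layer. `z` is the pre-normalization activation,
// `out` the forward output (for the ReLU mask, out > 0). The returned
// gradient carries `dy`'s dim attribute.
// [[Rcpp::export]]
List bn_relu_bwd_cpp(NumericVector dy, NumericVector z, NumericVector out,
                     NumericVector mean, NumericVector istd,
                     NumericVector gamma, bool relu) {
  int c;
  const R_xlen_t n = channel_rows(dy, c);
  if (z.size() != dy.size() || out.size() != dy.size())
    stop("cache/gradient size mismatch");
  NumericVector dz(dy.size());
  dz.attr("dim") = dy.attr("dim");
  NumericVector dgamma(c), dbeta(c);
  const double *DY = dy.begin();
  const double *Z = z.begin();
  const double *O = out.begin();
  double *DZ = dz.begin();
  for (int j = 0; j < c; ++j) {
    const double *dyc = DY + n * j;
    const double *oc = O + n * j;
    const double *zc = Z + n * j;
    const double m = mean[j], is = istd[j];
    double sum_d = 0.0, sum_dx = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double dv = dyc[i];
      if (relu && oc[i] <= 0) dv = 0;
      const double xh = (zc[i] - m) * is;
      sum_d += dv;
      sum_dx += dv * xh;
    }
    dgamma[j] = sum_dx;
    dbeta[j] = sum_d;
    const double g = gamma[j];
    const double mean_d = sum_d / n, mean_dx = sum_dx / n;
    double *dzc = DZ + n * j;
    for (R_xlen_t i = 0; i < n; ++i) {
      double dv = dyc[i];
      if (relu && oc[i] <= 0) dv = 0;
      const double xh = (zc[i] - m) * is;
      dzc[i] = g * is * (dv - mean_d - xh * mean_dx);
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling with kernel k and stride s; returns the pooled tensor and
// 1-based linear argmax indices into the input (for the backward pass).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector a, int k, int s) {
  int d[4]; get_dims4(a, d);
  const int H = d[0], W = d[1], B = d[2], C = d[3];
  if (k > H || k > W) stop("pool kernel larger than input");
  const int oh = (H - k) / s + 1, ow = (W - k) / s + 1;
  NumericVector out((R_xlen_t)oh * ow * B * C);
  out.attr("dim") = IntegerVector::create(oh, ow, B, C);
  NumericVector arg((R_xlen_t)oh * ow * B * C);  // double: indices can exceed 2^31
  const double *A = a.begin();
  double *O = out.begin();
  double *G = arg.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double *Ab = A + (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      const R_xlen_t base = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int x = 0; x < ow; ++x) {
        for (int y = 0; y < oh; ++y) {
          double best = -DBL_MAX;
          R_xlen_t besti = 0;
          for (int kx = 0; kx < k; ++kx) {
            const double *colp = Ab + (R_xlen_t)H * (x * s + kx) + y * s;
            for (int ky = 0; ky < k; ++ky) {
              if (colp[ky] > best) {
                best = colp[ky];
                besti = base + (R_xlen_t)H * (x * s + kx) + y * s + ky;
              }
            }
          }
          R_xlen_t o = y + (R_xlen_t)oh * (x + (R_xlen_t)ow * (b + (R_xlen_t)B * c));
          O[o] = best;
          G[o] = (double)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, NumericVector argmax,
                              int H, int W, int B, int C) {
  NumericVector da((R_xlen_t)H * W * B * C);
  da.attr("dim") = IntegerVector::create(H, W, B, C);
  double *D = da.begin();
  const double *G = argmax.begin();
  const double *dO = dout.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) D[(R_xlen_t)G[i] - 1] += dO[i];
  return da;
}
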