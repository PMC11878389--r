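// Dense kernels for the small CNN: patch extraction (im2col) and its
// adjoint, plus 2x2 max-pooling with argmax bookkeeping. Arrays use a
// channels-first layout (C, H, W, B), column-major as R stores them.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cf(NumericVector x, int C, int H, int W, int B, int k) {
  const int oh = H - k + 1, ow = W - k + 1;
  const int rows = C * k * k;
  NumericMatrix out(rows, oh * ow * B);
  const double* px = x.begin();
  double* po = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (size_t)b * C * H * W;
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        const size_t col = (size_t)b * oh * ow + (size_t)wo * oh + ho;
        double* oc = po + col * rows;
        int r = 0;
        for (int kj = 0; kj < k; ++kj) {
          const double* xcol = xb + (size_t)C * ((size_t)H * (wo + kj) + ho);
          for (int ki = 0; ki < k; ++ki) {
            const double* xpix = xcol + (size_t)C * ki;
            for (int ci = 0; ci < C; ++ci) oc[r++] = xpix[ci];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cf(NumericMatrix cols, int C, int H, int W, int B,
                        int k) {
  const int oh = H - k + 1, ow = W - k + 1;
  const int rows = C * k * k;
  NumericVector x((size_t)C * H * W * B);
  double* px = x.begin();
  const double* pc = cols.begin();
  for (int b = 0; b < B; ++b) {
    double* xb = px + (size_t)b * C * H * W;
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        const size_t col = (size_t)b * oh * ow + (size_t)wo * oh + ho;
        const double* oc = pc + col * rows;
        int r = 0;
        for (int kj = 0; kj < k; ++kj) {
          double* xcol = xb + (size_t)C * ((size_t)H * (wo + kj) + ho);
          for (int ki = 0; ki < k; ++ki) {
            double* xpix = xcol + (size_t)C * ki;
            for (int ci = 0; ci < C; ++ci) xpix[ci] += oc[r++];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List maxpool_cf(NumericVector x, int C, int H, int W, int B) {
  const int oh = H / 2, ow = W / 2;
  NumericVector out((size_t)C * oh * ow * B);
  IntegerVector amax((size_t)C * oh * ow * B);
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = amax.begin();
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    const size_t xb = (size_t)b * C * H * W;
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        for (int ci = 0; ci < C; ++ci) {
          double best = -1e300;
          size_t besti = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const size_t ix = xb + ci +
                (size_t)C * ((size_t)H * (2 * wo + dj) + (2 * ho + di));
              if (px[ix] > best) { best = px[ix]; besti = ix; }
            }
          }
          po[o] = best;
          pa[o] = (int)(besti + 1);  // 1-based for R
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cf(NumericVector dout, IntegerVector amax,
                             int n_in) {
  NumericVector dx(n_in);
  double* pd = dx.begin();
  const double* po = dout.begin();
  const int* pa = amax.begin();
  const size_t n = dout.size();
  for (size_t i = 0; i < n; ++i) pd[pa[i] - 1] += po[i];
  return dx;
}
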