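#include <Rcpp.h>
using namespace Rcpp;

// Minimal CNN primitives for the denoiser networks. Feature tensors are R
// arrays with dim = c(channels, height, width) (column-major, channel
// fastest); weights have dim = c(cout, cin, k, k). All convolutions use
// "same" zero padding, stride 1, and an odd kernel with optional dilation.

static inline int tidx(int c, int h, int w, int C, int H) { return c + C * (h + H * w); }

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector wts,
                                 NumericVector bias, int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wts.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int CO = wd[0], CI = wd[1], K = wd[2];
  if (CI != C) stop("channel mismatch in conv2d");
  int ctr = (K - 1) / 2;
  NumericVector y(CO * H * W);
  y.attr("dim") = IntegerVector::create(CO, H, W);
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      for (int co = 0; co < CO; ++co) {
        double acc = bias[co];
        for (int kw = 0; kw < K; ++kw) {
          int wi = w0 + dilation * (kw - ctr);
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int hi = h0 + dilation * (kh - ctr);
            if (hi < 0 || hi >= H) continue;
            const double *xp = &x[tidx(0, hi, wi, C, H)];
            const double *wp = &wts[co + CO * (0 + CI * (kh + K * kw))];
            for (int ci = 0; ci < CI; ++ci) acc += xp[ci] * wp[(size_t)CO * ci];
          }
        }
        y[tidx(co, h0, w0, CO, H)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector wts, NumericVector gy,
                         int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wts.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int CO = wd[0], CI = wd[1], K = wd[2];
  int ctr = (K - 1) / 2;
  NumericVector gx(C * H * W);
  gx.attr("dim") = xd;
  NumericVector gw(CO * CI * K * K);
  gw.attr("dim") = wd;
  NumericVector gb(CO);
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      const double *gyp = &gy[tidx(0, h0, w0, CO, H)];
      for (int co = 0; co < CO; ++co) gb[co] += gyp[co];
      for (int kw = 0; kw < K; ++kw) {
        int wi = w0 + dilation * (kw - ctr);
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < K; ++kh) {
          int hi = h0 + dilation * (kh - ctr);
          if (hi < 0 || hi >= H) continue;
          const double *xp = &x[tidx(0, hi, wi, C, H)];
          double *gxp = &gx[tidx(0, hi, wi, C, H)];
          for (int co = 0; co < CO; ++co) {
            double g = gyp[co];
            if (g == 0.0) continue;
            const double *wp = &wts[co + CO * (0 + CI * (kh + K * kw))];
            double *gwp = &gw[co + CO * (0 + CI * (kh + K * kw))];
            for (int ci = 0; ci < CI; ++ci) {
              gxp[ci] += g * wp[(size_t)CO * ci];
              gwp[(size_t)CO * ci] += g * xp[ci];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 average pooling (H, W must be even).
// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int OH = H / 2, OW = W / 2;
  NumericVector y(C * OH * OW);
  y.attr("dim") = IntegerVector::create(C, OH, OW);
  for (int w0 = 0; w0 < OW; ++w0)
    for (int h0 = 0; h0 < OH; ++h0)
      for (int c = 0; c < C; ++c)
        y[tidx(c, h0, w0, C, OH)] = 0.25 *
          (x[tidx(c, 2 * h0, 2 * w0, C, H)] + x[tidx(c, 2 * h0 + 1, 2 * w0, C, H)] +
           x[tidx(c, 2 * h0, 2 * w0 + 1, C, H)] + x[tidx(c, 2 * h0 + 1, 2 * w0 + 1, C, H)]);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], OH = gd[1], OW = gd[2];
  NumericVector gx(C * H * W);
  gx.attr("dim") = IntegerVector::create(C, H, W);
  for (int w0 = 0; w0 < OW; ++w0)
    for (int h0 = 0; h0 < OH; ++h0)
      for (int c = 0; c < C; ++c) {
        double g = 0.25 * gy[tidx(c, h0, w0, C, OH)];
        gx[tidx(c, 2 * h0, 2 * w0, C, H)] += g;
        gx[tidx(c, 2 * h0 + 1, 2 * w0, C, H)] += g;
        gx[tidx(c, 2 * h0, 2 * w0 + 1, C, H)] += g;
        gx[tidx(c, 2 * h0 + 1, 2 * w0 + 1, C, H)] += g;
      }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  NumericVector y(C * 2 * H * 2 * W);
  y.attr("dim") = IntegerVector::create(C, 2 * H, 2 * W);
  for (int w0 = 0; w0 < 2 * W; ++w0)
    for (int h0 = 0; h0 < 2 * H; ++h0)
      for (int c = 0; c < C; ++c)
        y[tidx(c, h0, w0, C, 2 * H)] = x[tidx(c, h0 / 2, w0 / 2, C, H)];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], H2 = gd[1], W2 = gd[2];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx(C * H * W);
  gx.attr("dim") = IntegerVector::create(C, H, W);
  for (int w0 = 0; w0 < W2; ++w0)
    for (int h0 = 0; h0 < H2; ++h0)
      for (int c = 0; c < C; ++c)
        gx[tidx(c, h0 / 2, w0 / 2, C, H)] += gy[tidx(c, h0, w0, C, H2)];
  return gx;
}
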