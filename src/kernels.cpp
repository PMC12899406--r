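#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as dense matrices with one column per channel and
// rows ordered (h fastest, then w, then image-in-batch), i.e. row index
// r = h + H*w + H*W*b. Convolutions are realised as im2col + BLAS GEMM on the
// R side; these kernels only gather/scatter patches and run the pooling loops.

// Gather kh x kw patches (stride 1, zero padding ph/pw) into a
// (H*W*B) x (kh*kw*C) matrix whose column index is dh + kh*dw + kh*kw*c,
// matching matrix(weight_array, kh*kw*C, C_out) with dim (kh, kw, C, C_out).
// [[Rcpp::export]]
NumericMatrix im2col_hw(const NumericMatrix& x, int H, int W, int B,
                        int kh, int kw, int ph, int pw) {
  const int C = x.ncol();
  const int HW = H * W;
  NumericMatrix out(HW * B, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * dw + kh * kw * c;
        double* oc = &out(0, col);
        for (int b = 0; b < B; ++b) {
          const int xoff = HW * b;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw - pw;
            if (ws < 0 || ws >= W) continue;
            const int obase = xoff + H * w;
            const int ibase = xoff + H * ws + (dh - ph);
            const int h0 = std::max(0, ph - dh);
            const int h1 = std::min(H, H + ph - dh);
            for (int h = h0; h < h1; ++h) oc[obase + h] = xc[ibase + h];
          }
        }
      }
    }
  }
  return out;
}

// Transpose of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericMatrix col2im_hw(const NumericMatrix& cols, int H, int W, int B,
                        int kh, int kw, int ph, int pw, int C) {
  const int HW = H * W;
  NumericMatrix out(HW * B, C);
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * dw + kh * kw * c;
        const double* src = &cols(0, col);
        for (int b = 0; b < B; ++b) {
          const int xoff = HW * b;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw - pw;
            if (ws < 0 || ws >= W) continue;
            const int sbase = xoff + H * w;
            const int obase = xoff + H * ws + (dh - ph);
            const int h0 = std::max(0, ph - dh);
            const int h1 = std::min(H, H + ph - dh);
            for (int h = h0; h < h1; ++h) oc[obase + h] += src[sbase + h];
          }
        }
      }
    }
  }
  return out;
}

// Non-overlapping max pooling with window (fh, fw); H, W must be divisible.
// Returns pooled values plus 1-based argmax row indices for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd(const NumericMatrix& x, int H, int W, int B, int fh, int fw) {
  const int C = x.ncol();
  const int Ho = H / fh, Wo = W / fw;
  const int HWo = Ho * Wo;
  NumericMatrix y(HWo * B, C);
  IntegerMatrix idx(HWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int b = 0; b < B; ++b) {
      const int xoff = H * W * b, yoff = HWo * b;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int besti = -1;
          for (int dw = 0; dw < fw; ++dw) {
            const int wcol = wo * fw + dw;
            for (int dh = 0; dh < fh; ++dh) {
              const int r = xoff + H * wcol + ho * fh + dh;
              if (xc[r] > best) { best = xc[r]; besti = r; }
            }
          }
          const int ro = yoff + Ho * wo + ho;
          y(ro, c) = best;
          idx(ro, c) = besti + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                          int n_in_rows) {
  const int C = dy.ncol();
  NumericMatrix dx(n_in_rows, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < dy.nrow(); ++r)
      dx(idx(r, c) - 1, c) += dy(r, c);
  return dx;
}

// Direct-form II transposed IIR filter with initial state zi (length
// max(len(a), len(b)) - 1); coefficients must be normalised so a[0] = 1.
// [[Rcpp::export]]
NumericVector iir_df2t(const NumericVector& b, const NumericVector& a,
                       const NumericVector& x, const NumericVector& zi) {
  const int n = x.size();
  const int k = zi.size();
  std::vector<double> bb(k + 1, 0.0), aa(k + 1, 0.0), z(zi.begin(), zi.end());
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < k - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[k - 1] = bb[k] * xi - aa[k] * yi;
    y[i] = yi;
  }
  return y;
}

// y[r,c] = x[r,c] * s[c] + t[c]  (fused column-wise affine, avoids sweep()).
// [[Rcpp::export]]
NumericMatrix colscale_add(const NumericMatrix& x, const NumericVector& s,
                           const NumericVector& t) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double sc = s[c], tc = t[c];
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int r = 0; r < n; ++r) yc[r] = xc[r] * sc + tc;
  }
  return y;
}

// Column means of an elementwise product, without materialising it.
// [[Rcpp::export]]
NumericVector colmeans_prod(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), C = a.ncol();
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &a(0, c); const double* bc = &b(0, c);
    double s = 0;
    for (int r = 0; r < n; ++r) s += ac[r] * bc[r];
    out[c] = s / n;
  }
  return out;
}

// Fused batch-norm input gradient:
// dx[r,c] = (dxhat[r,c] - m1[c] - xhat[r,c] * m2[c]) * inv[c].
// [[Rcpp::export]]
NumericMatrix bn_bwd_dx(const NumericMatrix& dxhat, const NumericMatrix& xhat,
                        const NumericVector& m1, const NumericVector& m2,
                        const NumericVector& inv) {
  const int n = dxhat.nrow(), C = dxhat.ncol();
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double a1 = m1[c], a2 = m2[c], iv = inv[c];
    const double* dc = &dxhat(0, c); const double* hc = &xhat(0, c);
    double* oc = &dx(0, c);
    for (int r = 0; r < n; ++r) oc[r] = (dc[r] - a1 - hc[r] * a2) * iv;
  }
  return dx;
}
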