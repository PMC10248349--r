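// 2D convolution (stride 1, zero padding) for H x W x C x N arrays via
// im2col + GEMM, with the exact adjoint for backpropagation. Column layout
// of the patch matrix matches an R weight array of dim (kh, kw, Cin, Cout)
// flattened column-major to a (kh*kw*Cin) x Cout matrix.

#include <RcppArmadillo.h>
using namespace Rcpp;

static void getDims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (H x W x C x N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static arma::mat im2col4(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int pad) {
  const arma::uword HW = (arma::uword)H * W;
  arma::mat cols((arma::uword)N * HW, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword col = (arma::uword)ki + (arma::uword)kh * (kj + (arma::uword)kw * c);
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + ((arma::uword)n * C + c) * HW;
          double* d = dst + (arma::uword)n * HW;
          for (int cp = 0; cp < W; ++cp) {
            double* dcol = d + (arma::uword)cp * H;
            const int sj = cp + kj - pad;
            if (sj < 0 || sj >= W) { std::fill(dcol, dcol + H, 0.0); continue; }
            const double* xcol = xs + (arma::uword)sj * H;
            const int si0 = ki - pad;              // src row offset for dst row 0
            const int rlo = std::max(0, -si0);
            const int rhi = std::min(H, H - si0);
            std::fill(dcol, dcol + rlo, 0.0);
            if (rhi > rlo) std::copy(xcol + rlo + si0, xcol + rhi + si0, dcol + rlo);
            std::fill(dcol + std::max(rlo, rhi), dcol + H, 0.0);
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col4: scatter-add patch-matrix gradients back onto dx
static void col2im4(const arma::mat& dcols, double* dx, int H, int W, int C, int N,
                    int kh, int kw, int pad) {
  const arma::uword HW = (arma::uword)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword col = (arma::uword)ki + (arma::uword)kh * (kj + (arma::uword)kw * c);
        const double* src = dcols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* xs = dx + ((arma::uword)n * C + c) * HW;
          const double* s = src + (arma::uword)n * HW;
          for (int cp = 0; cp < W; ++cp) {
            const int sj = cp + kj - pad;
            if (sj < 0 || sj >= W) continue;
            double* xcol = xs + (arma::uword)sj * H;
            const double* scol = s + (arma::uword)cp * H;
            const int si0 = ki - pad;
            const int rlo = std::max(0, -si0);
            const int rhi = std::min(H, H - si0);
            for (int r = rlo; r < rhi; ++r) xcol[r + si0] += scol[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector convForward(NumericVector x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int pad) {
  int H, W, C, N;
  getDims4(x, H, W, C, N);
  if ((int)w.n_rows != kh * kw * C) stop("weight rows do not match kh*kw*Cin");
  const int Cout = (int)w.n_cols;
  const arma::uword HW = (arma::uword)H * W;
  arma::mat cols = im2col4(REAL(x), H, W, C, N, kh, kw, pad);
  arma::mat out = cols * w;              // (N*H*W) x Cout
  out.each_row() += b.t();
  NumericVector y((R_xlen_t)HW * Cout * N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::copy(out.colptr(co) + (arma::uword)n * HW,
                out.colptr(co) + (arma::uword)(n + 1) * HW,
                yp + ((arma::uword)n * Cout + co) * HW);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".convBackward")]]
List convBackward(NumericVector x, const arma::mat& w, NumericVector dy,
                  int kh, int kw, int pad) {
  int H, W, C, N, H2, W2, Cout, N2;
  getDims4(x, H, W, C, N);
  getDims4(dy, H2, W2, Cout, N2);
  if (H2 != H || W2 != W || N2 != N) stop("dy shape does not match x");
  if ((int)w.n_cols != Cout) stop("dy channels do not match weight columns");
  const arma::uword HW = (arma::uword)H * W;
  // repack dy into (N*H*W) x Cout
  arma::mat dym((arma::uword)N * HW, Cout);
  const double* dp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::copy(dp + ((arma::uword)n * Cout + co) * HW,
                dp + ((arma::uword)n * Cout + co + 1) * HW,
                dym.colptr(co) + (arma::uword)n * HW);
  arma::mat cols = im2col4(REAL(x), H, W, C, N, kh, kw, pad);
  arma::mat dw = cols.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = dym * w.t();
  NumericVector dx((R_xlen_t)HW * C * N);
  std::fill(REAL(dx), REAL(dx) + dx.size(), 0.0);
  col2im4(dcols, REAL(dx), H, W, C, N, kh, kw, pad);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
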