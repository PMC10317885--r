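// 3x3x3 convolution kernels for the segmentation network.
//
// Feature maps arrive as (C x N) matrices over an (X, Y, Z) voxel grid with
// x fastest. The convolution is evaluated as im2col + one GEMM. The column
// matrix built during the forward pass is kept alive behind an external
// pointer and reused by the backward pass (for the weight gradient), which
// halves the gather traffic; the input gradient is scattered with col2im.
// Zero padding of one voxel on every side; stride 1 (same-size output) or 2
// (halved grid).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column row index is c + Cin * o with tap index o = i + 3*j + 9*k,
// (i, j, k) in {0,1,2}^3 — the same order as the R-side weight array.
static void im2col(const arma::mat& x, int X, int Y, int Z, int stride,
                   int OX, int OY, int OZ, arma::mat& col) {
  const int cin = x.n_rows;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int n = ox + OX * (oy + OY * oz);
        const int cx = stride * ox, cy = stride * oy, cz = stride * oz;
        double* cp = col.colptr(n);
        for (int k = 0; k < 3; ++k) {
          const int tz = cz + k - 1;
          for (int j = 0; j < 3; ++j) {
            const int ty = cy + j - 1;
            for (int i = 0; i < 3; ++i) {
              const int tx = cx + i - 1;
              double* dst = cp + cin * (i + 3 * j + 9 * k);
              if (tx < 0 || tx >= X || ty < 0 || ty >= Y ||
                  tz < 0 || tz >= Z) {
                for (int c = 0; c < cin; ++c) dst[c] = 0.0;
              } else {
                const double* src = x.colptr(tx + X * (ty + Y * tz));
                for (int c = 0; c < cin; ++c) dst[c] = src[c];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3_fwd_cpp(const arma::mat& x, const arma::mat& w2d,
                   const arma::vec& b, const arma::ivec& dims,
                   int stride, bool keep_col) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = X / stride, OY = Y / stride, OZ = Z / stride;
  arma::mat* col = new arma::mat(x.n_rows * 27, OX * OY * OZ);
  im2col(x, X, Y, Z, stride, OX, OY, OZ, *col);
  arma::mat out = w2d * (*col);
  out.each_col() += b;
  if (!keep_col) {
    delete col;
    return List::create(_["out"] = out, _["col"] = R_NilValue);
  }
  XPtr<arma::mat> p(col, true);
  return List::create(_["out"] = out, _["col"] = p);
}

// [[Rcpp::export]]
List conv3_bwd_cpp(SEXP col_ptr, const arma::mat& w2d, const arma::mat& dout,
                   const arma::ivec& dims, int stride) {
  XPtr<arma::mat> col(col_ptr);
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = X / stride, OY = Y / stride, OZ = Z / stride;
  const int cin = col->n_rows / 27;
  arma::mat dW = dout * col->t();
  arma::vec db = arma::sum(dout, 1);
  arma::mat dcol = w2d.t() * dout;
  arma::mat dx(cin, X * Y * Z, arma::fill::zeros);
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int n = ox + OX * (oy + OY * oz);
        const int cx = stride * ox, cy = stride * oy, cz = stride * oz;
        const double* src = dcol.colptr(n);
        for (int k = 0; k < 3; ++k) {
          const int tz = cz + k - 1;
          if (tz < 0 || tz >= Z) continue;
          for (int j = 0; j < 3; ++j) {
            const int ty = cy + j - 1;
            if (ty < 0 || ty >= Y) continue;
            for (int i = 0; i < 3; ++i) {
              const int tx = cx + i - 1;
              if (tx < 0 || tx >= X) continue;
              double* dst = dx.colptr(tx + X * (ty + Y * tz));
              const double* s = src + cin * (i + 3 * j + 9 * k);
              for (int c = 0; c < cin; ++c) dst[c] += s[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
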