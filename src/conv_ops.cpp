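// Convolutional autoencoder kernels for per-spot image grids.
//
// One image = one column of X, a 48x48 grid flattened column-major
// (pixel index p = r + h*c). Feature maps at resolution h x w with ch
// channels are arma::mat(h*w, ch). Architecture (shared across channels
// and spots):
//   encoder: conv 5x5 "same" (1->8) + ReLU + avgpool2
//            conv 5x5 "same" (8->4) + ReLU + avgpool2   -> 12x12x4 = 576
//   decoder: tconv 2x2 stride 2 (4->8) + ReLU
//            tconv 2x2 stride 2 (8->1), linear
// Loss: sum over images of squared Frobenius reconstruction error.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for "same" convolution: out(h*w, k*k*ch); contiguous row runs
// are block-copied per output column.
static void im2col_same(const mat& M, int h, int w, int k, mat& out) {
  const int ch = M.n_cols, pad = (k - 1) / 2;
  out.zeros(h * w, k * k * ch);
  for (int ci = 0; ci < ch; ++ci) {
    const double* src = M.colptr(ci);
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        double* dst = out.colptr(dr + k * dc + k * k * ci);
        const int r0 = std::max(0, pad - dr), r1 = std::min(h, h + pad - dr);
        if (r1 <= r0) continue;
        for (int c = std::max(0, pad - dc); c < std::min(w, w + pad - dc); ++c) {
          const int cc = c + dc - pad;
          std::memcpy(dst + h * c + r0, src + h * cc + r0 + dr - pad,
                      (r1 - r0) * sizeof(double));
        }
      }
  }
}

static void col2im_same(const mat& cols, int h, int w, int k, int ch, mat& out) {
  const int pad = (k - 1) / 2;
  out.zeros(h * w, ch);
  for (int ci = 0; ci < ch; ++ci) {
    double* dst = out.colptr(ci);
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        const double* src = cols.colptr(dr + k * dc + k * k * ci);
        const int r0 = std::max(0, pad - dr), r1 = std::min(h, h + pad - dr);
        if (r1 <= r0) continue;
        for (int c = std::max(0, pad - dc); c < std::min(w, w + pad - dc); ++c) {
          const int cc = c + dc - pad;
          double* d = dst + h * cc + dr - pad;
          const double* s = src + h * c;
          for (int r = r0; r < r1; ++r) d[r] += s[r];
        }
      }
  }
}

static void avgpool2(const mat& M, int h, int w, mat& out) {
  const int ch = M.n_cols, h2 = h / 2, w2 = w / 2;
  out.set_size(h2 * w2, ch);
  for (int ci = 0; ci < ch; ++ci) {
    const double* src = M.colptr(ci);
    double* dst = out.colptr(ci);
    for (int c = 0; c < w2; ++c) {
      const double* a = src + h * (2 * c);
      const double* b = src + h * (2 * c + 1);
      double* d = dst + h2 * c;
      for (int r = 0; r < h2; ++r)
        d[r] = 0.25 * (a[2 * r] + a[2 * r + 1] + b[2 * r] + b[2 * r + 1]);
    }
  }
}

static void avgpool2_back(const mat& dP, int h, int w, mat& out) {
  const int ch = dP.n_cols, h2 = h / 2, w2 = w / 2;
  out.set_size(h * w, ch);
  for (int ci = 0; ci < ch; ++ci) {
    const double* src = dP.colptr(ci);
    double* dst = out.colptr(ci);
    for (int c = 0; c < w2; ++c) {
      double* a = dst + h * (2 * c);
      double* b = dst + h * (2 * c + 1);
      const double* s = src + h2 * c;
      for (int r = 0; r < h2; ++r) {
        const double g = 0.25 * s[r];
        a[2 * r] = g; a[2 * r + 1] = g; b[2 * r] = g; b[2 * r + 1] = g;
      }
    }
  }
}

// Transposed conv, kernel 2x2 stride 2. W is (cin x 4*cout), column index
// dd + 4*co with dd = dr + 2*dc. P = X*W is staged in `tmp`.
static void tconv2_fwd(const mat& X, const mat& W, const vec& b,
                       int h, int w, int cout, mat& tmp, mat& out) {
  tmp = X * W;
  const int H = 2 * h;
  out.set_size(4 * h * w, cout);
  for (int co = 0; co < cout; ++co) {
    double* dst = out.colptr(co);
    const double bb = b(co);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        const double* src = tmp.colptr(dr + 2 * dc + 4 * co);
        for (int c = 0; c < w; ++c) {
          double* d = dst + H * (2 * c + dc) + dr;
          const double* s = src + h * c;
          for (int r = 0; r < h; ++r) d[2 * r] = s[r] + bb;
        }
      }
  }
}

// Gather the 2x2-strided blocks of dY into (h*w) x (4*cout).
static void tconv2_gather(const mat& dY, int h, int w, int cout, mat& B) {
  const int H = 2 * h;
  B.set_size(h * w, 4 * cout);
  for (int co = 0; co < cout; ++co) {
    const double* src = dY.colptr(co);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        double* dst = B.colptr(dr + 2 * dc + 4 * co);
        for (int c = 0; c < w; ++c) {
          const double* s = src + H * (2 * c + dc) + dr;
          double* d = dst + h * c;
          for (int r = 0; r < h; ++r) d[r] = s[2 * r];
        }
      }
  }
}

static inline void relu_inplace(mat& M) {
  double* p = M.memptr();
  for (uword i = 0; i < M.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

// dM[i] <- 0 where act[i] == 0 (act is the post-ReLU activation).
static inline void relu_mask(mat& dM, const mat& act) {
  double* d = dM.memptr();
  const double* a = act.memptr();
  for (uword i = 0; i < dM.n_elem; ++i) if (a[i] <= 0) d[i] = 0;
}

// Forward (+ optional backward) pass over a batch of flattened grids.
// Returns total loss, parameter gradients, and encoder features.
// [[Rcpp::export(name = ".cnn_ae_pass")]]
Rcpp::List cnn_ae_pass(const arma::mat& X,
                       const arma::mat& W1, const arma::vec& b1,
                       const arma::mat& W2, const arma::vec& b2,
                       const arma::mat& W3, const arma::vec& b3,
                       const arma::mat& W4, const arma::vec& b4,
                       const bool want_grads, const bool want_features) {
  const int n = X.n_cols, h0 = 48;
  const int c1 = W1.n_cols, c2 = W2.n_cols, c3 = W3.n_cols / 4;
  double loss = 0.0;
  mat dW1(size(W1), fill::zeros), dW2(size(W2), fill::zeros);
  mat dW3(size(W3), fill::zeros), dW4(size(W4), fill::zeros);
  vec db1(b1.n_elem, fill::zeros), db2(b2.n_elem, fill::zeros);
  vec db3(b3.n_elem, fill::zeros), db4(b4.n_elem, fill::zeros);
  mat feats;
  if (want_features) feats.set_size(144 * c2, n);

  mat im1, A1, P1, im2, A2, P2, T1, xrec, diff;
  mat tmp3, tmp4, B4, dT1, B3, dP2, dA2, dP1cols, dP1, dA1;

  for (int img = 0; img < n; ++img) {
    const mat x(const_cast<double*>(X.colptr(img)), h0 * h0, 1, false, true);
    im2col_same(x, h0, h0, 5, im1);
    A1 = im1 * W1;
    A1.each_row() += b1.t();
    relu_inplace(A1);
    avgpool2(A1, h0, h0, P1);                            // 24x24 x c1
    im2col_same(P1, 24, 24, 5, im2);
    A2 = im2 * W2;
    A2.each_row() += b2.t();
    relu_inplace(A2);
    avgpool2(A2, 24, 24, P2);                            // 12x12 x c2
    if (want_features) feats.col(img) = vectorise(P2);
    tconv2_fwd(P2, W3, b3, 12, 12, c3, tmp3, T1);        // 24x24 x c3
    relu_inplace(T1);
    tconv2_fwd(T1, W4, b4, 24, 24, 1, tmp4, xrec);       // 48x48, linear
    diff = xrec - x;
    loss += accu(square(diff));

    if (!want_grads) continue;
    diff *= 2.0;                                         // dxrec
    tconv2_gather(diff, 24, 24, 1, B4);                  // 576 x 4
    dW4 += T1.t() * B4;
    db4 += sum(diff, 0).t();
    dT1 = B4 * W4.t();
    relu_mask(dT1, T1);
    tconv2_gather(dT1, 12, 12, c3, B3);                  // 144 x 4*c3
    dW3 += P2.t() * B3;
    db3 += sum(dT1, 0).t();
    dP2 = B3 * W3.t();                                   // 144 x c2
    avgpool2_back(dP2, 24, 24, dA2);
    relu_mask(dA2, A2);
    dW2 += im2.t() * dA2;
    db2 += sum(dA2, 0).t();
    dP1cols = dA2 * W2.t();
    col2im_same(dP1cols, 24, 24, 5, c1, dP1);
    avgpool2_back(dP1, h0, h0, dA1);
    relu_mask(dA1, A1);
    dW1 += im1.t() * dA1;
    db1 += sum(dA1, 0).t();
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss);
  if (want_grads)
    out["grads"] = Rcpp::List::create(
      Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
      Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
      Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3,
      Rcpp::Named("W4") = dW4, Rcpp::Named("b4") = db4);
  if (want_features) out["features"] = feats;
  return out;
}
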