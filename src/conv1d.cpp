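// 1-D temporal convolution kernels for the CNN/ADANN models.
//
// Activations are stored as (maps x T*B) matrices: B independent
// sequences (window-channel pairs) of length T laid out as contiguous
// column slabs. Convolutions use "same" zero padding (odd kernel K).
// Weights are (Mout x Min*K) with column index k*Min + m, matching the
// k-blocked im2col layout below (contiguous submatrix copies).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int CHUNK = 64;   // slices per im2col/gemm chunk

// Fill col (Min*K x T*nb) from slices [b0, b0+nb) of X.
static void im2colChunk(const mat& X, mat& col, int b0, int nb, int T,
                        int K, int pad) {
  const int Min = X.n_rows;
  for (int b = 0; b < nb; ++b) {
    const int xc = (b0 + b) * T, cc = b * T;
    for (int k = 0; k < K; ++k) {
      const int off = k - pad;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      const int r0 = k * Min, r1 = k * Min + Min - 1;
      if (t0 > 0)
        col.submat(r0, cc, r1, cc + t0 - 1).zeros();
      if (t1 < T)
        col.submat(r0, cc + t1, r1, cc + T - 1).zeros();
      if (t1 > t0)
        col.submat(r0, cc + t0, r1, cc + t1 - 1) =
          X.submat(0, xc + t0 + off, Min - 1, xc + t1 - 1 + off);
    }
  }
}

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& X, const arma::mat& W, int T, int K) {
  const int Min = X.n_rows;
  const int B = X.n_cols / T;
  const int pad = K / 2;
  mat Y(W.n_rows, X.n_cols);
  mat col(Min * K, T * std::min(CHUNK, B));
  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    const int nb = std::min(CHUNK, B - b0);
    if ((int)col.n_cols != T * nb) col.set_size(Min * K, T * nb);
    im2colChunk(X, col, b0, nb, T, K, pad);
    Y.cols(b0 * T, (b0 + nb) * T - 1) = W * col;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& X, const arma::mat& W,
                      const arma::mat& dY, int T, int K,
                      bool needInputGrad = true) {
  const int Min = X.n_rows;
  const int B = X.n_cols / T;
  const int pad = K / 2;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dX(Min, needInputGrad ? X.n_cols : 0, fill::zeros);
  mat col(Min * K, T * std::min(CHUNK, B));
  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    const int nb = std::min(CHUNK, B - b0);
    if ((int)col.n_cols != T * nb) col.set_size(Min * K, T * nb);
    im2colChunk(X, col, b0, nb, T, K, pad);
    const int c0 = b0 * T, c1 = (b0 + nb) * T - 1;
    dW += dY.cols(c0, c1) * col.t();
    if (!needInputGrad) continue;
    mat dcol = W.t() * dY.cols(c0, c1);
    for (int b = 0; b < nb; ++b) {
      const int xc = (b0 + b) * T, cc = b * T;
      for (int k = 0; k < K; ++k) {
        const int off = k - pad;
        const int t0 = std::max(0, -off);
        const int t1 = std::min(T, T - off);
        if (t1 > t0)
          dX.submat(0, xc + t0 + off, Min - 1, xc + t1 - 1 + off) +=
            dcol.submat(k * Min, cc + t0, k * Min + Min - 1, cc + t1 - 1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW);
}

// Global average pooling over the temporal axis of each sequence.
// [[Rcpp::export]]
arma::mat gap_fwd(const arma::mat& X, int T) {
  const int B = X.n_cols / T;
  mat Y(X.n_rows, B);
  for (int b = 0; b < B; ++b)
    Y.col(b) = mean(X.cols(b * T, b * T + T - 1), 1);
  return Y;
}

// [[Rcpp::export]]
arma::mat gap_bwd(const arma::mat& dY, int T) {
  const int B = dY.n_cols;
  mat dX(dY.n_rows, B * T);
  for (int b = 0; b < B; ++b)
    dX.cols(b * T, b * T + T - 1) = repmat(dY.col(b) / T, 1, T);
  return dX;
}

// Leaky rectifier, fused single-pass forward/backward.
// [[Rcpp::export]]
arma::mat leaky_fwd(const arma::mat& Z, double slope) {
  mat Y(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  double* y = Y.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) y[i] = z[i] > 0 ? z[i] : slope * z[i];
  return Y;
}

// [[Rcpp::export]]
arma::mat leaky_bwd(const arma::mat& dH, const arma::mat& Z, double slope) {
  mat dZ(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  const double* dh = dH.memptr();
  double* dz = dZ.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) dz[i] = z[i] > 0 ? dh[i] : slope * dh[i];
  return dZ;
}

// Per-row (feature-map) mean and biased variance in one pass.
// [[Rcpp::export]]
Rcpp::List row_stats(const arma::mat& X) {
  const uword M = X.n_rows, N = X.n_cols;
  vec s(M, fill::zeros), s2(M, fill::zeros);
  const double* x = X.memptr();
  for (uword j = 0; j < N; ++j) {
    const double* cx = x + j * M;
    for (uword i = 0; i < M; ++i) {
      s[i] += cx[i];
      s2[i] += cx[i] * cx[i];
    }
  }
  vec mu = s / N;
  vec v = s2 / N - mu % mu;
  v.transform([](double a) { return a > 0 ? a : 0.0; });
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = v);
}

// (x - mu) / sd, single pass.
// [[Rcpp::export]]
arma::mat bn_norm(const arma::mat& X, const arma::vec& mu,
                  const arma::vec& sd) {
  const uword M = X.n_rows, N = X.n_cols;
  mat Y(M, N);
  const double* x = X.memptr();
  double* y = Y.memptr();
  for (uword j = 0; j < N; ++j) {
    const double* cx = x + j * M;
    double* cy = y + j * M;
    for (uword i = 0; i < M; ++i) cy[i] = (cx[i] - mu[i]) / sd[i];
  }
  return Y;
}

// BN backward without affine: (dy - mean(dy) - xhat * mean(dy*xhat)) / sd
// [[Rcpp::export]]
arma::mat bn_bwd(const arma::mat& dY, const arma::mat& Xhat,
                 const arma::vec& sd) {
  const uword M = dY.n_rows, N = dY.n_cols;
  vec m1(M, fill::zeros), m2(M, fill::zeros);
  const double* dy = dY.memptr();
  const double* xh = Xhat.memptr();
  for (uword j = 0; j < N; ++j) {
    const double* cd = dy + j * M;
    const double* cx = xh + j * M;
    for (uword i = 0; i < M; ++i) {
      m1[i] += cd[i];
      m2[i] += cd[i] * cx[i];
    }
  }
  m1 /= N; m2 /= N;
  mat out(M, N);
  double* o = out.memptr();
  for (uword j = 0; j < N; ++j) {
    const double* cd = dy + j * M;
    const double* cx = xh + j * M;
    double* co = o + j * M;
    for (uword i = 0; i < M; ++i)
      co[i] = (cd[i] - m1[i] - cx[i] * m2[i]) / sd[i];
  }
  return out;
}

// Leaky rectifier + inverted dropout in one pass. The mask is drawn
// from R's RNG stream (deterministic under set.seed) and returned as a
// raw matrix for the backward pass.
// [[Rcpp::export]]
Rcpp::List act_dropout_fwd(const arma::mat& Xhat, double slope, double p) {
  const uword M = Xhat.n_rows, N = Xhat.n_cols;
  mat H(M, N);
  Rcpp::RawMatrix mask(M, N);
  const double scale = 1.0 / (1.0 - p);
  const double* x = Xhat.memptr();
  double* h = H.memptr();
  Rbyte* mk = mask.begin();
  Rcpp::RNGScope scope;
  const uword n = Xhat.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double keep = unif_rand() >= p ? 1.0 : 0.0;
    mk[i] = (Rbyte)keep;
    const double a = x[i] > 0 ? x[i] : slope * x[i];
    h[i] = keep ? a * scale : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("mask") = mask);
}

// Backward through dropout + leaky rectifier in one pass.
// [[Rcpp::export]]
arma::mat act_dropout_bwd(const arma::mat& dH, const arma::mat& Xhat,
                          const Rcpp::RawMatrix& mask, double slope,
                          double p) {
  const uword n = Xhat.n_elem;
  mat dX(Xhat.n_rows, Xhat.n_cols);
  const double scale = 1.0 / (1.0 - p);
  const double* dh = dH.memptr();
  const double* x = Xhat.memptr();
  const Rbyte* mk = mask.begin();
  double* o = dX.memptr();
  for (uword i = 0; i < n; ++i) {
    if (!mk[i]) { o[i] = 0.0; continue; }
    const double g = dh[i] * scale;
    o[i] = x[i] > 0 ? g : slope * g;
  }
  return dX;
}

// Direct-form-II-transposed IIR filter with initial state (the state
// convention of standard filtfilt implementations).
// [[Rcpp::export]]
arma::vec iir_filter(const arma::vec& b, const arma::vec& a,
                     const arma::vec& x, const arma::vec& zi) {
  const uword n = x.n_elem, m = b.n_elem;   // length(a) == length(b)
  vec z = zi;                                // m - 1 states
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (m > 1 ? z[0] : 0.0);
    for (uword k = 1; k < m - 1; ++k)
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    if (m > 1) z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}
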