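// Low-level numeric kernels: im2col-based 2D convolution (forward/backward),
// 2x2 max-pooling, and patchwise Non-Local Means. Feature maps are arma::cube
// with dimensions (H, W, C); weight matrices are laid out so that reshaping an
// R array of dim c(k, k, Cin, Cout) column-major gives row index
// ki + k*kj + k*k*ci for output channel co.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& X, const int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int p = (k - 1) / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& sl = X.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= H) continue;
            cols(r, i + H * j) = sl(si, sj);
          }
        }
      }
    }
  }
  return cols;
}

// accumulate columns back onto an image (adjoint of im2col)
static cube col2im(const mat& cols, const int k, const int H, const int W,
                   const int C) {
  const int p = (k - 1) / 2;
  cube X(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = X.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= H) continue;
            sl(si, sj) += cols(r, i + H * j);
          }
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& X, const arma::mat& Wm,
                      const arma::vec& b, const int k) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_cols;
  mat cols = im2col(X, k);
  mat Y = Wm.t() * cols;      // Cout x (H*W)
  Y.each_col() += b;
  cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(Y.row(co).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& X, const arma::mat& Wm,
                      const arma::cube& dY, const int k) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  mat dYm(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    dYm.row(co) = vectorise(dY.slice(co)).t();
  mat cols = im2col(X, k);
  mat dW = cols * dYm.t();                  // (k*k*Cin) x Cout
  vec db = sum(dYm, 1);
  cube dX = col2im(Wm * dYm, k, H, W, Cin); // adjoint
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;  // floor division: trailing row/col dropped
  cube Y(Ho, Wo, C);
  Rcpp::IntegerVector idx(Ho * Wo * C);  // linear index into the input slice
  int q = 0;
  for (int c = 0; c < C; ++c) {
    const mat& sl = X.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j, ai = bi, aj = bj;
        double best = sl(bi, bj);
        if (sl(bi + 1, bj) > best) { best = sl(bi + 1, bj); ai = bi + 1; }
        if (sl(bi, bj + 1) > best) { best = sl(bi, bj + 1); aj = bj + 1; ai = bi; }
        if (sl(bi + 1, bj + 1) > best) { best = sl(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
        Y(i, j, c) = best;
        idx[q] = ai + H * aj;
        ++q;
      }
    }
  }
  // q runs in (i, j, c) column-major order matching vectorised Y
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dY, const Rcpp::IntegerVector& idx,
                        const int H, const int W) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  cube dX(H, W, C, fill::zeros);
  int q = 0;
  for (int c = 0; c < C; ++c) {
    mat& sl = dX.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        sl(idx[q] % H, idx[q] / H) += dY(i, j, c);
        ++q;
      }
    }
  }
  return dX;
}

// Non-Local Means with patch radius f and search radius t. Patch distance is
// the mean squared difference over the (2f+1)^2 patch (replicate padding at
// borders); weights exp(-d2/h^2), centre pixel weight 1.
// [[Rcpp::export]]
arma::mat nlm_filter(const arma::mat& X, const double h, const int f,
                     const int t) {
  const int H = X.n_rows, W = X.n_cols;
  mat out(H, W);
  const double h2 = h * h;
  const int np = (2 * f + 1) * (2 * f + 1);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = X(i, j), wsum = 1.0;  // centre: d2 = 0, weight 1
      for (int dj = -t; dj <= t; ++dj) {
        for (int di = -t; di <= t; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ci = i + di, cj = j + dj;
          if (ci < 0 || ci >= H || cj < 0 || cj >= W) continue;
          double d2 = 0.0;
          for (int pj = -f; pj <= f; ++pj) {
            for (int pi = -f; pi <= f; ++pi) {
              int ai = std::min(std::max(i + pi, 0), H - 1);
              int aj = std::min(std::max(j + pj, 0), W - 1);
              int bi = std::min(std::max(ci + pi, 0), H - 1);
              int bj = std::min(std::max(cj + pj, 0), W - 1);
              const double d = X(ai, aj) - X(bi, bj);
              d2 += d * d;
            }
          }
          d2 /= np;
          const double w = std::exp(-d2 / h2);
          acc += w * X(ci, cj);
          wsum += w;
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
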