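// Hot kernels for the network: 1-D same-padding convolution via im2col +
// BLAS GEMM (with optional fused ReLU on input or output), non-overlapping
// max pooling, and bilinear upsampling. Feature maps are (channels,
// positions, batch) arrays in R's column-major layout; all functions take
// no-copy views of R memory. The im2col matrix is rebuilt in the backward
// pass instead of being shipped to R and back.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void dims3(const NumericVector& x, int& C, int& L, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  C = d[0]; L = d[1]; N = d[2];
}

// Build the (C*k) x (L*N) im2col matrix; kernel offsets are row blocks.
static arma::mat im2col(const double* x, int C, int L, int N, int k,
                        bool relu_in) {
  const int p = (k - 1) / 2;
  arma::mat M(C * k, (size_t)L * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x + (size_t)n * C * L;
    for (int t = 0; t < L; ++t) {
      double* col = M.colptr((size_t)n * L + t);
      for (int j = 0; j < k; ++j) {
        const int src = t + j - p;
        double* dst = col + (size_t)j * C;
        if (src >= 0 && src < L) {
          const double* sp = xs + (size_t)src * C;
          if (relu_in) {
            for (int c = 0; c < C; ++c) dst[c] = sp[c] > 0 ? sp[c] : 0.0;
          } else {
            std::memcpy(dst, sp, C * sizeof(double));
          }
        } else {
          std::memset(dst, 0, C * sizeof(double));
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix W,
                               NumericVector b, int k, bool relu_in,
                               bool relu_out) {
  int C, L, N;
  dims3(x, C, L, N);
  const int Co = W.nrow();
  if (W.ncol() != C * k) stop("weight shape mismatch");
  arma::mat M = im2col(x.begin(), C, L, N, k, relu_in);
  const arma::mat Wv(W.begin(), Co, C * k, false, true);
  NumericVector y(Rcpp::no_init((size_t)Co * L * N));
  arma::mat Yv(y.begin(), Co, (size_t)L * N, false, true);
  Yv = Wv * M;
  const double* bp = b.begin();
  double* yp = y.begin();
  const size_t ncol = (size_t)L * N;
  for (size_t i = 0; i < ncol; ++i) {
    double* col = yp + i * Co;
    if (relu_out) {
      for (int c = 0; c < Co; ++c) {
        const double v = col[c] + bp[c];
        col[c] = v > 0 ? v : 0.0;
      }
    } else {
      for (int c = 0; c < Co; ++c) col[c] += bp[c];
    }
  }
  y.attr("dim") = IntegerVector::create(Co, L, N);
  return y;
}

// Backward of cpp_conv_forward. `y` (the forward output) supplies the ReLU
// mask when relu_out; `x` (the forward input) rebuilds the im2col matrix
// and supplies the mask when relu_in. dx is skipped for input layers.
// [[Rcpp::export]]
List cpp_conv_backward(NumericVector dy, NumericVector x, NumericVector y,
                       NumericMatrix W, int k, bool relu_in, bool relu_out,
                       bool need_dx) {
  int C, L, N;
  dims3(x, C, L, N);
  const int Co = W.nrow();
  const int p = (k - 1) / 2;
  const size_t ncol = (size_t)L * N;
  arma::mat M = im2col(x.begin(), C, L, N, k, relu_in);
  const arma::mat Wv(W.begin(), Co, C * k, false, true);
  arma::mat dY;
  if (relu_out) {
    dY.set_size(Co, ncol);
    const double* dp = dy.begin();
    const double* yp = y.begin();
    double* op = dY.memptr();
    const size_t n = (size_t)Co * ncol;
    for (size_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? dp[i] : 0.0;
  } else {
    dY = arma::mat(dy.begin(), Co, ncol, false, true);
  }
  arma::mat dW = dY * M.t();
  arma::vec db = arma::sum(dY, 1);
  List out = List::create(Named("dx") = R_NilValue,
                          Named("dW") = wrap(dW),
                          Named("db") = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    arma::mat dM = Wv.t() * dY;
    NumericVector dx((size_t)C * L * N); // zero-initialized
    double* dxp = dx.begin();
    const double* xp = x.begin();
    for (int n = 0; n < N; ++n) {
      double* dxs = dxp + (size_t)n * C * L;
      for (int t = 0; t < L; ++t) {
        const double* col = dM.colptr((size_t)n * L + t);
        for (int j = 0; j < k; ++j) {
          const int src = t + j - p;
          if (src >= 0 && src < L) {
            double* dst = dxs + (size_t)src * C;
            const double* sp = col + (size_t)j * C;
            for (int c = 0; c < C; ++c) dst[c] += sp[c];
          }
        }
      }
    }
    if (relu_in) {
      const size_t n = (size_t)C * L * N;
      for (size_t i = 0; i < n; ++i) {
        if (xp[i] <= 0) dxp[i] = 0.0;
      }
    }
    dx.attr("dim") = IntegerVector::create(C, L, N);
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int pool) {
  int C, L, N;
  dims3(x, C, L, N);
  const int Lo = L / pool;
  NumericVector y(Rcpp::no_init((size_t)C * Lo * N));
  IntegerVector amax(Rcpp::no_init((size_t)C * Lo * N));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * C * L;
    double* ys = yp + (size_t)n * C * Lo;
    int* as = ap + (size_t)n * C * Lo;
    for (int g = 0; g < Lo; ++g) {
      const double* base = xs + (size_t)g * pool * C;
      double* yo = ys + (size_t)g * C;
      int* ao = as + (size_t)g * C;
      for (int c = 0; c < C; ++c) {
        double best = base[c];
        int bj = 0;
        for (int j = 1; j < pool; ++j) {
          const double v = base[(size_t)j * C + c];
          if (v > best) { best = v; bj = j; }
        }
        yo[c] = best;
        ao[c] = bj;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Lo, N);
  return List::create(Named("y") = y, Named("amax") = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector amax,
                                   int pool) {
  int C, Lo, N;
  dims3(dy, C, Lo, N);
  const int L = Lo * pool;
  NumericVector dx((size_t)C * L * N);
  const double* dp = dy.begin();
  const int* ap = amax.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double* ds = dp + (size_t)n * C * Lo;
    const int* as = ap + (size_t)n * C * Lo;
    double* xs = xp + (size_t)n * C * L;
    for (int g = 0; g < Lo; ++g) {
      for (int c = 0; c < C; ++c) {
        const size_t i = (size_t)g * C + c;
        xs[((size_t)g * pool + as[i]) * C + c] = ds[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, N);
  return dx;
}

// Bilinear upsampling along positions; lo/hi are 0-based source indices.
// [[Rcpp::export]]
NumericVector cpp_bilinear_forward(NumericVector x, IntegerVector lo,
                                   IntegerVector hi, NumericVector wlo,
                                   NumericVector whi) {
  int C, Ti, N;
  dims3(x, C, Ti, N);
  const int To = lo.size();
  NumericVector y(Rcpp::no_init((size_t)C * To * N));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * C * Ti;
    double* ys = yp + (size_t)n * C * To;
    for (int i = 0; i < To; ++i) {
      const double* a = xs + (size_t)lo[i] * C;
      const double* b = xs + (size_t)hi[i] * C;
      double* o = ys + (size_t)i * C;
      const double wl = wlo[i], wh = whi[i];
      for (int c = 0; c < C; ++c) o[c] = wl * a[c] + wh * b[c];
    }
  }
  y.attr("dim") = IntegerVector::create(C, To, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_backward(NumericVector dy, int t_in,
                                    IntegerVector lo, IntegerVector hi,
                                    NumericVector wlo, NumericVector whi) {
  int C, To, N;
  dims3(dy, C, To, N);
  NumericVector dx((size_t)C * t_in * N);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double* ds = dp + (size_t)n * C * To;
    double* xs = xp + (size_t)n * C * t_in;
    for (int i = 0; i < To; ++i) {
      const double* d = ds + (size_t)i * C;
      double* a = xs + (size_t)lo[i] * C;
      double* b = xs + (size_t)hi[i] * C;
      const double wl = wlo[i], wh = whi[i];
      for (int c = 0; c < C; ++c) {
        a[c] += wl * d[c];
        b[c] += wh * d[c];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, t_in, N);
  return dx;
}
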