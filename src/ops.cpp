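// Low-level kernels for the 1D residual network: same-padding strided
// convolution (im2col + GEMM, batched over records), max-pooling, and fused
// batch-normalization + ReLU. Tensors cross the R boundary as double arrays
// with layout (time, channel, batch) and are processed in single precision
// (statistics and weight-gradient reductions accumulate in double).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static fcube r2f(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  fcube out(d[0], d[1], d[2]);
  const double* src = x.begin();
  float* dst = out.memptr();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static Rcpp::NumericVector f2r(const fcube& x) {
  Rcpp::NumericVector out(x.n_elem);
  const float* src = x.memptr();
  double* dst = out.begin();
  for (uword i = 0; i < x.n_elem; ++i) dst[i] = (double)src[i];
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols,
                                                x.n_slices);
  return out;
}

static fvec r2fv(const Rcpp::NumericVector& x) {
  fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

static fmat r2fm(const Rcpp::NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  for (R_xlen_t i = 0; i < x.size(); ++i) dst[i] = (float)src[i];
  return out;
}

// Patch-matrix column order: column c*k + kk holds tap kk of input channel c;
// weight matrices are (k*Cin) x Cout with matching row order. Rows of P:
// record-major blocks of Lout rows each.
static void im2col_slice(const fmat& xs, int k, int stride, int pad_left,
                         fmat& P, int row0, int Lout) {
  const int L = xs.n_rows, Cin = xs.n_cols;
  for (int c = 0; c < Cin; ++c) {
    const float* xc = xs.colptr(c);
    for (int kk = 0; kk < k; ++kk) {
      float* pc = P.colptr(c * k + kk) + row0;
      if (stride == 1) {
        const int t0 = kk - pad_left;
        const int lo = std::max(0, -t0);
        const int hi = std::min(Lout, L - t0);
        if (lo > 0) std::memset(pc, 0, sizeof(float) * lo);
        if (hi > lo)
          std::memcpy(pc + lo, xc + t0 + lo, sizeof(float) * (hi - lo));
        if (hi < Lout)
          std::memset(pc + std::max(hi, 0), 0,
                      sizeof(float) * (Lout - std::max(hi, 0)));
      } else {
        for (int o = 0; o < Lout; ++o) {
          const int t = o * stride + kk - pad_left;
          pc[o] = (t >= 0 && t < L) ? xc[t] : 0.0f;
        }
      }
    }
  }
}

static int same_pad(int L, int Lout, int k, int stride) {
  int pad = (Lout - 1) * stride + k - L;
  return pad > 0 ? pad : 0;
}

static const int CHUNK = 32;  // records per stacked GEMM

// [[Rcpp::export(name = ".conv1d_fwd")]]
Rcpp::NumericVector conv1d_fwd(const Rcpp::NumericVector& xr,
                               const Rcpp::NumericMatrix& Wr,
                               const Rcpp::NumericVector& br, int stride) {
  const fcube x = r2f(xr);
  const fmat W = r2fm(Wr);
  const frowvec bias = r2fv(br).t();
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = W.n_rows / Cin;
  const int Lout = (L + stride - 1) / stride;
  const int pad_left = same_pad(L, Lout, k, stride) / 2;
  fcube y(Lout, W.n_cols, B);
  const int chunk = std::min(CHUNK, B);
  fmat P(Lout * chunk, Cin * k);
  fmat Y(Lout * chunk, W.n_cols);
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int nb = std::min(chunk, B - b0);
    if (nb != (int)(P.n_rows / Lout)) { P.resize(Lout * nb, Cin * k);
                                        Y.resize(Lout * nb, W.n_cols); }
    for (int j = 0; j < nb; ++j)
      im2col_slice(x.slice(b0 + j), k, stride, pad_left, P, j * Lout, Lout);
    Y = P * W;
    Y.each_row() += bias;
    for (int j = 0; j < nb; ++j)
      for (uword cc = 0; cc < W.n_cols; ++cc)
        std::memcpy(y.slice(b0 + j).colptr(cc),
                    Y.colptr(cc) + j * Lout, sizeof(float) * Lout);
  }
  return f2r(y);
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const Rcpp::NumericVector& xr,
                      const Rcpp::NumericMatrix& Wr,
                      const Rcpp::NumericVector& dyr, int stride,
                      bool need_dx) {
  const fcube x = r2f(xr);
  const fmat W = r2fm(Wr);
  const fcube dy = r2f(dyr);
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = W.n_rows / Cin;
  const int Lout = dy.n_rows;
  const int pad_left = same_pad(L, Lout, k, stride) / 2;
  mat dW(W.n_rows, W.n_cols, fill::zeros);   // accumulate in double
  vec db(W.n_cols, fill::zeros);
  fcube dx;
  if (need_dx) dx.zeros(L, Cin, B);
  const int chunk = std::min(CHUNK, B);
  fmat P(Lout * chunk, Cin * k);
  fmat DY(Lout * chunk, W.n_cols);
  fmat dP;
  if (need_dx) dP.set_size(Lout * chunk, Cin * k);
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int nb = std::min(chunk, B - b0);
    if ((int)(P.n_rows / Lout) != nb) {
      P.resize(Lout * nb, Cin * k);
      DY.resize(Lout * nb, W.n_cols);
      if (need_dx) dP.resize(Lout * nb, Cin * k);
    }
    for (int j = 0; j < nb; ++j) {
      im2col_slice(x.slice(b0 + j), k, stride, pad_left, P, j * Lout, Lout);
      for (uword cc = 0; cc < W.n_cols; ++cc)
        std::memcpy(DY.colptr(cc) + j * Lout,
                    dy.slice(b0 + j).colptr(cc), sizeof(float) * Lout);
    }
    dW += conv_to<mat>::from(P.t() * DY);
    db += conv_to<vec>::from(sum(DY, 0).t());
    if (need_dx) {
      dP = DY * W.t();                            // (Lout*nb) x (Cin*k)
      for (int j = 0; j < nb; ++j) {
        fmat& dxs = dx.slice(b0 + j);
        for (int c = 0; c < Cin; ++c) {
          float* dxc = dxs.colptr(c);
          for (int kk = 0; kk < k; ++kk) {
            const float* dpc = dP.colptr(c * k + kk) + j * Lout;
            if (stride == 1) {
              const int t0 = kk - pad_left;
              const int lo = std::max(0, -t0);
              const int hi = std::min(Lout, L - t0);
              for (int o = lo; o < hi; ++o) dxc[o + t0] += dpc[o];
            } else {
              for (int o = 0; o < Lout; ++o) {
                const int t = o * stride + kk - pad_left;
                if (t >= 0 && t < L) dxc[t] += dpc[o];
              }
            }
          }
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) out["dx"] = f2r(dx);
  return out;
}

// [[Rcpp::export(name = ".maxpool1d_fwd")]]
Rcpp::List maxpool1d_fwd(const Rcpp::NumericVector& xr, int width,
                         int stride) {
  const fcube x = r2f(xr);
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int Lout = (L + stride - 1) / stride;
  fcube y(Lout, C, B);
  Rcpp::IntegerVector arg(Lout * C * B);
  int* ap = arg.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const float* xc = x.slice(b).colptr(c);
      float* yc = y.slice(b).colptr(c);
      int* ac = ap + ((R_xlen_t)b * C + c) * Lout;
      for (int o = 0; o < Lout; ++o) {
        const int lo = o * stride;
        const int hi = std::min(lo + width, L);
        int am = lo;
        float m = xc[lo];
        for (int t = lo + 1; t < hi; ++t)
          if (xc[t] > m) { m = xc[t]; am = t; }
        yc[o] = m;
        ac[o] = am;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = f2r(y),
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export(name = ".maxpool1d_bwd")]]
Rcpp::NumericVector maxpool1d_bwd(const Rcpp::NumericVector& dyr,
                                  const Rcpp::IntegerVector& arg, int L) {
  const fcube dy = r2f(dyr);
  const int Lout = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  fcube dx(L, C, B, fill::zeros);
  const int* ap = arg.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const float* dc = dy.slice(b).colptr(c);
      float* xc = dx.slice(b).colptr(c);
      const int* ac = ap + ((R_xlen_t)b * C + c) * Lout;
      for (int o = 0; o < Lout; ++o) xc[ac[o]] += dc[o];
    }
  return f2r(dx);
}

// Fused batch normalization (+ optional ReLU) over (time, batch) per
// channel. Training mode returns the per-channel batch mean/invstd; the
// backward pass recomputes normalized values from them and takes the ReLU
// mask from the forward output.
// [[Rcpp::export(name = ".bn_fwd")]]
Rcpp::List bn_fwd(const Rcpp::NumericVector& xr,
                  const Rcpp::NumericVector& gamma,
                  const Rcpp::NumericVector& beta,
                  const Rcpp::NumericVector& rmean,
                  const Rcpp::NumericVector& rvar, bool train,
                  double momentum, double eps, bool relu) {
  const fcube x = r2f(xr);
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const double N = (double)L * B;
  fcube y(L, C, B);
  Rcpp::NumericVector mu(C), invstd(C), nmean = Rcpp::clone(rmean),
                      nvar = Rcpp::clone(rvar);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (train) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const float* xc = x.slice(b).colptr(c);
        for (int t = 0; t < L; ++t) {
          s += xc[t];
          s2 += (double)xc[t] * xc[t];
        }
      }
      m = s / N;
      v = s2 / N - m * m;
      if (v < 0) v = 0;
      nmean[c] = momentum * rmean[c] + (1 - momentum) * m;
      nvar[c] = momentum * rvar[c] + (1 - momentum) * v;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    invstd[c] = is;
    const float a = (float)(gamma[c] * is);
    const float b0 = (float)(beta[c] - gamma[c] * is * m);
    for (int b = 0; b < B; ++b) {
      const float* xc = x.slice(b).colptr(c);
      float* yc = y.slice(b).colptr(c);
      if (relu)
        for (int t = 0; t < L; ++t) {
          const float z = a * xc[t] + b0;
          yc[t] = z > 0.0f ? z : 0.0f;
        }
      else
        for (int t = 0; t < L; ++t) yc[t] = a * xc[t] + b0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = f2r(y),
                            Rcpp::Named("mean") = mu,
                            Rcpp::Named("invstd") = invstd,
                            Rcpp::Named("rmean") = nmean,
                            Rcpp::Named("rvar") = nvar);
}

// dy arrives at the (optionally ReLU-masked) BN output; yr is the forward
// output used for the ReLU mask (strictly positive where the unit was
// active; zero slope at exactly 0).
// [[Rcpp::export(name = ".bn_bwd")]]
Rcpp::List bn_bwd(const Rcpp::NumericVector& dyr,
                  const Rcpp::NumericVector& yr,
                  const Rcpp::NumericVector& xr,
                  const Rcpp::NumericVector& mean,
                  const Rcpp::NumericVector& invstd,
                  const Rcpp::NumericVector& gamma, bool relu) {
  const fcube dy = r2f(dyr);
  const fcube x = r2f(xr);
  fcube yf;
  if (relu) yf = r2f(yr);
  const int L = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  const double N = (double)L * B;
  fcube dx(L, C, B);
  Rcpp::NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const float m = (float)mean[c], is = (float)invstd[c];
    double sd = 0, sdh = 0;
    for (int b = 0; b < B; ++b) {
      const float* dc = dy.slice(b).colptr(c);
      const float* xc = x.slice(b).colptr(c);
      const float* yc = relu ? yf.slice(b).colptr(c) : nullptr;
      for (int t = 0; t < L; ++t) {
        const float d = relu ? (yc[t] > 0.0f ? dc[t] : 0.0f) : dc[t];
        sd += d;
        sdh += (double)d * (xc[t] - m) * is;
      }
    }
    dbeta[c] = sd;
    dgamma[c] = sdh;
    const float gis = (float)(gamma[c] * invstd[c] / N);
    const float fsd = (float)sd, fsdh = (float)sdh, fN = (float)N;
    for (int b = 0; b < B; ++b) {
      const float* dc = dy.slice(b).colptr(c);
      const float* xc = x.slice(b).colptr(c);
      const float* yc = relu ? yf.slice(b).colptr(c) : nullptr;
      float* oc = dx.slice(b).colptr(c);
      for (int t = 0; t < L; ++t) {
        const float d = relu ? (yc[t] > 0.0f ? dc[t] : 0.0f) : dc[t];
        oc[t] = gis * (fN * d - fsd - (xc[t] - m) * is * fsdh);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = f2r(dx),
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
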