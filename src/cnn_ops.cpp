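// Hot paths of the 1D-CNN: same-padding convolution and max pooling, forward
// and backward. Activations are cubes with dimensions (time, batch, channel);
// weights are (kernel_len * in_channels) x out_channels matrices whose rows
// are ordered kernel-tap-fastest within each input channel.
//
// The convolution kernels here are long (up to one second of signal, i.e. as
// long as a quarter of the input), so the usual im2col + GEMM lowering
// inflates memory traffic by the kernel length and is memory-bound. The
// production path therefore evaluates the convolutions via FFT (circular
// convolution on a power-of-two grid of at least L + k - 1 points, which
// makes it exact for the linear case). The direct im2col implementations are
// kept as `*_ref` references; unit tests assert the two paths agree.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static int next_pow2(int n) {
  int p = 1;
  while (p < n) p <<= 1;
  return p;
}

// ---------------------------------------------------------------- FFT path

// Z[i,b,f] = b[f] + sum_{c,t} A[i + t - pl, b, c] * W[c*k + t, f],
// pl = (k-1)/2 (symmetric zero padding, length preserving).
// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& A, const arma::mat& W,
                         const arma::vec& b, const int k,
                         const bool rectify = false) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int F = W.n_cols;
  const int pl = (k - 1) / 2, off = k - 1 - pl;
  const int Lf = next_pow2(L + k - 1);

  cx_cube Ah(Lf, B, C);
  {
    mat pad(Lf, B, fill::zeros);
    for (int c = 0; c < C; ++c) {
      pad.rows(0, L - 1) = A.slice(c);
      Ah.slice(c) = fft(pad);
    }
  }
  // reversed kernels, so circular convolution realizes the correlation above
  mat Wr(Lf, C * F, fill::zeros);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < k; ++t)
        Wr(k - 1 - t, c + C * f) = W(c * k + t, f);
  cx_mat Wh = fft(Wr);

  cube out(L, B, F);
  cx_mat acc(Lf, B);
  for (int f = 0; f < F; ++f) {
    acc.zeros();
    for (int c = 0; c < C; ++c)
      acc += Ah.slice(c).each_col() % Wh.col(c + C * f);
    mat y = real(ifft(acc));
    out.slice(f) = y.rows(off, off + L - 1);
    out.slice(f) += b(f);
    if (rectify) out.slice(f).transform([](double v) { return v > 0 ? v : 0.0; });
  }
  return out;
}

// Gradients of the forward map: dW, db and dA from upstream dZ.
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::cube& A, const arma::mat& W,
                         const arma::cube& dZ, const int k) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int F = W.n_cols;
  const int pl = (k - 1) / 2;
  const int Lf = next_pow2(L + k - 1);

  cx_cube Ah(Lf, B, C), Gh(Lf, B, F);
  {
    mat pad(Lf, B, fill::zeros);
    for (int c = 0; c < C; ++c) {
      pad.rows(0, L - 1) = A.slice(c);
      Ah.slice(c) = fft(pad);
    }
    for (int f = 0; f < F; ++f) {
      pad.rows(0, L - 1) = dZ.slice(f);
      Gh.slice(f) = fft(pad);
    }
  }

  // dW[c*k+t, f] = sum_{i,b} A[i + t - pl, b, c] * dZ[i, b, f]
  //             = IFFT_u( sum_b conj(dZhat) .* Ahat )[(t - pl) mod Lf];
  // Lf >= L + k - 1 keeps the needed lags free of circular aliasing.
  mat dW(k * C, F);
  {
    cx_mat Acc(Lf, C * F);
    for (int f = 0; f < F; ++f) {
      const cx_mat Gc = conj(Gh.slice(f));
      for (int c = 0; c < C; ++c)
        Acc.col(c + C * f) = sum(Gc % Ah.slice(c), 1);
    }
    cx_mat xc = ifft(Acc);
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < k; ++t) {
          const int u = t - pl;
          dW(c * k + t, f) = xc(u >= 0 ? u : Lf + u, c + C * f).real();
        }
  }

  vec db(F);
  for (int f = 0; f < F; ++f) db(f) = accu(dZ.slice(f));

  // dA[j,b,c] = sum_{f,t} dZ[j + pl - t, b, f] * W[c*k+t, f]
  //           = (dZ (*) W)[j + pl] summed over f (plain circular convolution)
  mat Wp(Lf, C * F, fill::zeros);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < k; ++t)
        Wp(t, c + C * f) = W(c * k + t, f);
  cx_mat Wh2 = fft(Wp);

  cube dA(L, B, C);
  cx_mat acc(Lf, B);
  for (int c = 0; c < C; ++c) {
    acc.zeros();
    for (int f = 0; f < F; ++f)
      acc += Gh.slice(f).each_col() % Wh2.col(c + C * f);
    mat y = real(ifft(acc));
    dA.slice(c) = y.rows(pl, pl + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}

// ------------------------------------------------- direct (im2col) references

static mat im2col_same(const cube& A, const int k) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int pl = (k - 1) / 2;
  mat M(static_cast<size_t>(L) * B, static_cast<size_t>(k) * C);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (int t = 0; t < k; ++t) {
      const int off = t - pl; // source index = output index + off
      double* dst = M.colptr(static_cast<size_t>(c) * k + t);
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      for (int b = 0; b < B; ++b) {
        const double* src = S.colptr(b);
        double* d = dst + static_cast<size_t>(b) * L;
        for (int i = 0; i < lo; ++i) d[i] = 0.0;
        for (int i = lo; i < hi; ++i) d[i] = src[i + off];
        for (int i = hi; i < L; ++i) d[i] = 0.0;
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fw_ref(const arma::cube& A, const arma::mat& W,
                             const arma::vec& b, const int k) {
  const int L = A.n_rows, B = A.n_cols;
  const int F = W.n_cols;
  mat M = im2col_same(A, k);
  mat Z = M * W;
  Z.each_row() += b.t();
  cube out(L, B, F);
  std::memcpy(out.memptr(), Z.memptr(), sizeof(double) * Z.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw_ref(const arma::cube& A, const arma::mat& W,
                             const arma::cube& dZ, const int k) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int F = W.n_cols;
  mat M = im2col_same(A, k);
  const mat dZm(const_cast<double*>(dZ.memptr()),
                static_cast<size_t>(L) * B, F, false, true);
  mat dW = M.t() * dZm;
  vec db = sum(dZm, 0).t();
  mat dM = dZm * W.t(); // (L*B) x (k*C)
  cube dA(L, B, C, fill::zeros);
  const int pl = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat& S = dA.slice(c);
    for (int t = 0; t < k; ++t) {
      const int off = t - pl;
      const double* src = dM.colptr(static_cast<size_t>(c) * k + t);
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      for (int b2 = 0; b2 < B; ++b2) {
        double* d = S.colptr(b2);
        const double* s = src + static_cast<size_t>(b2) * L;
        for (int i = lo; i < hi; ++i) d[i + off] += s[i];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}

// --------------------------------------------------------------- max pooling

// Window 2, stride 2, no padding; a trailing odd sample is dropped.
// [[Rcpp::export]]
arma::cube cpp_maxpool_fw(const arma::cube& A) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int Lo = L / 2;
  cube out(Lo, B, C);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    mat& O = out.slice(c);
    for (int b = 0; b < B; ++b) {
      const double* s = S.colptr(b);
      double* o = O.colptr(b);
      for (int i = 0; i < Lo; ++i)
        o[i] = std::max(s[2 * i], s[2 * i + 1]);
    }
  }
  return out;
}

// Gradient routed to the (first) maximum of each pooling pair.
// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& A, const arma::cube& dZ) {
  const int L = A.n_rows, B = A.n_cols, C = A.n_slices;
  const int Lo = L / 2;
  cube dA(L, B, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    const mat& G = dZ.slice(c);
    mat& D = dA.slice(c);
    for (int b = 0; b < B; ++b) {
      const double* s = S.colptr(b);
      const double* g = G.colptr(b);
      double* d = D.colptr(b);
      for (int i = 0; i < Lo; ++i) {
        if (s[2 * i] >= s[2 * i + 1]) d[2 * i] += g[i];
        else d[2 * i + 1] += g[i];
      }
    }
  }
  return dA;
}

// ------------------------------------------------------------ IIR filtering

// Direct-form II transposed IIR filter with initial state zi (length
// max(len(a), len(b)) - 1); a[0] must be 1. Used by the zero-phase band-pass.
// [[Rcpp::export]]
arma::vec cpp_iir_filter(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem, nf = zi.n_elem;
  vec bb(nf + 1, fill::zeros), aa(nf + 1, fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  vec z = zi, y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 1] = bb[nf] * xi - aa[nf] * yi;
    y[i] = yi;
  }
  return y;
}

// --------------------------------------------------------- batch normalization

// Per-channel mean and biased variance over (time x batch).
// [[Rcpp::export]]
Rcpp::List cpp_bn_stats(const arma::cube& R) {
  const int C = R.n_slices;
  vec mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    mu(c) = accu(R.slice(c)) / R.slice(c).n_elem;
    v(c) = accu(square(R.slice(c) - mu(c))) / R.slice(c).n_elem;
  }
  return Rcpp::List::create(Rcpp::Named("mu") = mu, Rcpp::Named("v") = v);
}

// y = gamma * (x - mu) * invstd + beta, per channel.
// [[Rcpp::export]]
arma::cube cpp_bn_apply(const arma::cube& R, const arma::vec& mu,
                        const arma::vec& invstd, const arma::vec& gamma,
                        const arma::vec& beta) {
  cube Y(R.n_rows, R.n_cols, R.n_slices);
  for (unsigned c = 0; c < R.n_slices; ++c) {
    const double a = gamma(c) * invstd(c);
    const double b = beta(c) - a * mu(c);
    Y.slice(c) = a * R.slice(c) + b;
  }
  return Y;
}

// Joint backward of batch normalization (training statistics) and the
// preceding ReLU: dR is gated where the rectified input R is zero.
// [[Rcpp::export]]
Rcpp::List cpp_bn_relu_bw(const arma::cube& R, const arma::cube& dY,
                          const arma::vec& mu, const arma::vec& invstd,
                          const arma::vec& gamma) {
  const int C = R.n_slices;
  cube dR(R.n_rows, R.n_cols, R.n_slices);
  vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const mat& Rc = R.slice(c);
    const mat& dYc = dY.slice(c);
    const double m = Rc.n_elem;
    mat xhat = (Rc - mu(c)) * invstd(c);
    dgamma(c) = accu(dYc % xhat);
    dbeta(c) = accu(dYc);
    // dxhat = gamma*dY; dR = invstd*(dxhat - mean(dxhat) - xhat*mean(dxhat%xhat))
    const double mean_dx = gamma(c) * dbeta(c) / m;
    const double mean_dxx = gamma(c) * dgamma(c) / m;
    mat d = invstd(c) * (gamma(c) * dYc - mean_dx - xhat * mean_dxx);
    d.elem(find(Rc <= 0)).zeros();
    dR.slice(c) = d;
  }
  return Rcpp::List::create(Rcpp::Named("dR") = dR,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
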