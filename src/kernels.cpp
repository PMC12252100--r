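// Hot-path kernels: 1-D convolution and GRU recursions over (channels,
// length, batch) cubes. Only the inner numerics live here; layer logic,
// shapes and parameter bookkeeping stay on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// weight layout matches the R side: W is (C_out, C_in * k) with column
// index c + (j - 1) * C_in, i.e. channel fastest, tap second.

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, const int pad, const bool bias) {
  const int C = x.n_rows, L = x.n_cols, n = x.n_slices;
  const int Cout = W.n_rows;
  const int k = W.n_cols / C;
  const int Lp = L + 2 * pad;
  const int Lout = Lp - k + 1;
  cube out(Cout, Lout, n, fill::zeros);
  mat xp(C, Lp, fill::zeros);
  for (int i = 0; i < n; ++i) {
    xp.zeros();
    xp.cols(pad, pad + L - 1) = x.slice(i);
    mat& o = out.slice(i);
    for (int j = 0; j < k; ++j) {
      o += W.cols(j * C, (j + 1) * C - 1) * xp.cols(j, j + Lout - 1);
    }
    if (bias) o.each_col() += b;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& dout, const arma::cube& x,
                          const arma::mat& W, const int pad, const bool bias) {
  const int C = x.n_rows, L = x.n_cols, n = x.n_slices;
  const int k = W.n_cols / C;
  const int Lp = L + 2 * pad;
  const int Lout = dout.n_cols;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  cube dx(C, L, n, fill::zeros);
  mat xp(C, Lp, fill::zeros);
  mat dxp(C, Lp, fill::zeros);
  for (int i = 0; i < n; ++i) {
    xp.zeros();
    xp.cols(pad, pad + L - 1) = x.slice(i);
    const mat& dm = dout.slice(i);
    if (bias) db += sum(dm, 1);
    dxp.zeros();
    for (int j = 0; j < k; ++j) {
      dW.cols(j * C, (j + 1) * C - 1) += dm * xp.cols(j, j + Lout - 1).t();
      dxp.cols(j, j + Lout - 1) += W.cols(j * C, (j + 1) * C - 1).t() * dm;
    }
    dx.slice(i) = dxp.cols(pad, pad + L - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

static inline mat sigm(const mat& m) { return 1.0 / (1.0 + exp(-m)); }

// gather time step t (H, n) from a (H, L, n) cube
static inline mat step_of(const cube& c, const int t) {
  mat m(c.n_rows, c.n_slices);
  for (unsigned int i = 0; i < c.n_slices; ++i) m.col(i) = c.slice(i).col(t);
  return m;
}

static inline void set_step(cube& c, const int t, const mat& m) {
  for (unsigned int i = 0; i < c.n_slices; ++i) c.slice(i).col(t) = m.col(i);
}

// [[Rcpp::export]]
Rcpp::List gru_fwd_cpp(const arma::cube& x,
                       const arma::mat& Wz, const arma::mat& Uz, const arma::vec& bz,
                       const arma::mat& Wr, const arma::mat& Ur, const arma::vec& br,
                       const arma::mat& Wn, const arma::mat& Un, const arma::vec& bn) {
  const int D = x.n_rows, L = x.n_cols, n = x.n_slices;
  const int H = Wz.n_rows;
  const mat xmat(const_cast<double*>(x.memptr()), D, L * n, false, true);
  mat pz = Wz * xmat; pz.each_col() += bz;
  mat pr = Wr * xmat; pr.each_col() += br;
  mat pn = Wn * xmat; pn.each_col() += bn;
  const cube cpz(pz.memptr(), H, L, n);
  const cube cpr(pr.memptr(), H, L, n);
  const cube cpn(pn.memptr(), H, L, n);
  cube out(H, L, n), Z(H, L, n), R(H, L, n), A(H, L, n), Cst(H, L, n),
      Hprev(H, L, n);
  mat h(H, n, fill::zeros);
  for (int t = 0; t < L; ++t) {
    mat z = sigm(step_of(cpz, t) + Uz * h);
    mat r = sigm(step_of(cpr, t) + Ur * h);
    mat a = Un * h;
    mat cst = tanh(step_of(cpn, t) + r % a);
    set_step(Hprev, t, h);
    h = (1.0 - z) % cst + z % h;
    set_step(out, t, h);
    set_step(Z, t, z); set_step(R, t, r); set_step(A, t, a); set_step(Cst, t, cst);
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("A") = A,
                            Rcpp::Named("Cst") = Cst, Rcpp::Named("Hprev") = Hprev);
}

// [[Rcpp::export]]
Rcpp::List gru_bwd_cpp(const arma::cube& dout, const arma::cube& x,
                       const arma::cube& Z, const arma::cube& R,
                       const arma::cube& A, const arma::cube& Cst,
                       const arma::cube& Hprev,
                       const arma::mat& Uz, const arma::mat& Ur,
                       const arma::mat& Un,
                       const arma::mat& Wz, const arma::mat& Wr,
                       const arma::mat& Wn) {
  const int D = x.n_rows, L = x.n_cols, n = x.n_slices;
  const int H = Uz.n_rows;
  cube DZ(H, L, n), DR(H, L, n), DC(H, L, n);
  mat gUz(H, H, fill::zeros), gUr(H, H, fill::zeros), gUn(H, H, fill::zeros);
  mat dh(H, n, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    mat z = step_of(Z, t), r = step_of(R, t), a = step_of(A, t);
    mat cst = step_of(Cst, t), hprev = step_of(Hprev, t);
    dh += step_of(dout, t);
    mat dz = dh % (hprev - cst);
    mat dc = dh % (1.0 - z);
    mat dh_prev = dh % z;
    mat dc_pre = dc % (1.0 - cst % cst);
    mat dr = dc_pre % a;
    mat da = dc_pre % r;
    mat dz_pre = dz % z % (1.0 - z);
    mat dr_pre = dr % r % (1.0 - r);
    gUn += da * hprev.t();
    gUz += dz_pre * hprev.t();
    gUr += dr_pre * hprev.t();
    dh = dh_prev + Un.t() * da + Uz.t() * dz_pre + Ur.t() * dr_pre;
    set_step(DZ, t, dz_pre); set_step(DR, t, dr_pre); set_step(DC, t, dc_pre);
  }
  const mat xmat(const_cast<double*>(x.memptr()), D, L * n, false, true);
  const mat mDZ(DZ.memptr(), H, L * n, false, true);
  const mat mDR(DR.memptr(), H, L * n, false, true);
  const mat mDC(DC.memptr(), H, L * n, false, true);
  mat gWz = mDZ * xmat.t();
  mat gWr = mDR * xmat.t();
  mat gWn = mDC * xmat.t();
  vec gbz = sum(mDZ, 1), gbr = sum(mDR, 1), gbn = sum(mDC, 1);
  mat dxm = Wz.t() * mDZ + Wr.t() * mDR + Wn.t() * mDC;
  cube dx(dxm.memptr(), D, L, n);
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx,
      Rcpp::Named("gWz") = gWz, Rcpp::Named("gUz") = gUz, Rcpp::Named("gbz") = gbz,
      Rcpp::Named("gWr") = gWr, Rcpp::Named("gUr") = gUr, Rcpp::Named("gbr") = gbr,
      Rcpp::Named("gWn") = gWn, Rcpp::Named("gUn") = gUn, Rcpp::Named("gbn") = gbn);
}
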