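// Euler-discretized leaky RNN: forward simulation and backpropagation
// through time for the masked squared-error objective.
//
// Layout conventions (chosen for contiguous BLAS calls):
//   states/input cubes are [channels x trial x time]; R-facing arrays are
//   time-major and get permuted at the boundary.
// Update rule per trial b, step t (alive = 1 while the trial is running):
//   i_t = W_rec h_{t-1} + W_in u_t + b_in + xi_t,   xi ~ N(0, noise_sd^2)
//   h_t = h_{t-1} + gamma * alive * (sigma(i_t) - h_{t-1})
//   z_t = W_out h_t + b_out
// After a trial ends (alive = 0) its state is frozen; the loss mask is zero
// there so padded steps contribute nothing.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// activation codes: 0 = softplus, 1 = tanh, 2 = retanh
// branchless loops so the compiler can vectorize the transcendentals
static void act_eval(const int kind, const mat& x, mat& s, mat& d) {
  const uword n = x.n_elem;
  s.set_size(x.n_rows, x.n_cols);
  d.set_size(x.n_rows, x.n_cols);
  const double* xp = x.memptr();
  double* sp = s.memptr();
  double* dp = d.memptr();
  switch (kind) {
  case 0: // softplus: ln(1 + e^x); derivative = logistic
#pragma omp simd
    for (uword k = 0; k < n; ++k) {
      const double v = xp[k];
      const double vc = v < -30.0 ? -30.0 : (v > 30.0 ? 30.0 : v);
      const double e = std::exp(vc);
      sp[k] = std::log(1.0 + e) + (v > 30.0 ? v - 30.0 : 0.0);
      dp[k] = e / (1.0 + e);
    }
    break;
  case 1: // tanh
#pragma omp simd
    for (uword k = 0; k < n; ++k) {
      const double t = std::tanh(xp[k]);
      sp[k] = t;
      dp[k] = 1.0 - t * t;
    }
    break;
  case 2: // retanh: max(tanh(x), 0)
#pragma omp simd
    for (uword k = 0; k < n; ++k) {
      const double v = xp[k];
      const double t = std::tanh(v);
      sp[k] = v > 0.0 ? t : 0.0;
      dp[k] = v > 0.0 ? 1.0 - t * t : 0.0;
    }
    break;
  default:
    Rcpp::stop("unknown activation code");
  }
}

// Box-Muller over bulk uniform draws; the log/sin/cos loop vectorizes.
static void fill_noise(mat& xi, const double sd, std::mt19937_64& gen) {
  const uword n = xi.n_elem;
  const uword half = (n + 1) / 2;
  static std::vector<double> u;
  u.resize(2 * half);
  for (uword k = 0; k < 2 * half; ++k)
    u[k] = ((gen() >> 11) + 1.0) * (1.0 / 9007199254740993.0); // (0, 1]
  double* p = xi.memptr();
  const double* u1 = u.data();
  const double* u2 = u.data() + half;
#pragma omp simd
  for (uword k = 0; k < half; ++k) {
    const double r = sd * std::sqrt(-2.0 * std::log(u1[k]));
    const double a = 6.283185307179586476925286766559 * u2[k];
    p[k] = r * std::cos(a);
    if (half + k < n) p[half + k] = r * std::sin(a);
  }
}

// Forward pass only. Returns states H [N x B x T] and outputs Z [Nout x B x T].
// [[Rcpp::export]]
Rcpp::List rnn_forward_cpp(const arma::mat& h0, const arma::cube& U,
                           const arma::mat& Wrec, const arma::mat& Win,
                           const arma::vec& bin, const arma::mat& Wout,
                           const arma::vec& bout, int act, double gamma,
                           const arma::mat& alive, double noise_sd,
                           unsigned long seed) {
  const uword N = Wrec.n_rows, B = U.n_cols, T = U.n_slices;
  std::mt19937_64 gen(seed);
  cube H(N, B, T);
  const mat Uflat(const_cast<double*>(U.memptr()), U.n_rows, B * T, false);
  mat Uproj = Win * Uflat; // all input projections in one gemm
  Uproj.each_col() += bin;
  mat prev = h0, i(N, B), s, d, xi(N, B);
  for (uword t = 0; t < T; ++t) {
    i = Uproj.cols(t * B, t * B + B - 1);
    i += Wrec * prev;
    if (noise_sd > 0.0) { fill_noise(xi, noise_sd, gen); i += xi; }
    act_eval(act, i, s, d);
    mat upd = s - prev;
    upd.each_row() %= gamma * alive.col(t).t();
    prev += upd;
    if (abs(prev).max() > 1e6)
      Rcpp::stop("network state diverged at step %d", (int)(t + 1));
    H.slice(t) = prev;
  }
  mat Hflat(H.memptr(), N, B * T, false);
  mat Zflat = Wout * Hflat;
  Zflat.each_col() += bout;
  cube Z(Zflat.memptr(), Wout.n_rows, B, T);
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Z") = Z);
}

// Forward + backward: masked squared-error loss with L2 weight and activity
// regularization, and gradients for all learned parameters.
// [[Rcpp::export]]
Rcpp::List rnn_loss_grad_cpp(const arma::mat& h0, const arma::cube& U,
                             const arma::cube& target, const arma::cube& mask,
                             const arma::mat& Wrec, const arma::mat& Win,
                             const arma::vec& bin, const arma::mat& Wout,
                             const arma::vec& bout, int act, double gamma,
                             const arma::mat& alive, double noise_sd,
                             unsigned long seed, double lambda_w,
                             double lambda_a, bool want_grad) {
  const uword N = Wrec.n_rows, B = U.n_cols, T = U.n_slices;
  const uword Nout = Wout.n_rows;
  std::mt19937_64 gen(seed);

  const mat Uflat(const_cast<double*>(U.memptr()), U.n_rows, B * T, false);
  mat Uproj = Win * Uflat;
  Uproj.each_col() += bin;

  cube Hall(N, B, T + 1), D(N, B, T);
  Hall.slice(0) = h0;
  mat i(N, B), s, xi(N, B);
  for (uword t = 0; t < T; ++t) {
    const mat& prev = Hall.slice(t);
    i = Uproj.cols(t * B, t * B + B - 1);
    i += Wrec * prev;
    if (noise_sd > 0.0) { fill_noise(xi, noise_sd, gen); i += xi; }
    mat d(D.slice_memptr(t), N, B, false, true); // write sigma' in place
    act_eval(act, i, s, d);
    mat upd = s - prev;
    upd.each_row() %= gamma * alive.col(t).t();
    Hall.slice(t + 1) = prev + upd;
    if (abs(Hall.slice(t + 1)).max() > 1e6)
      Rcpp::stop("network state diverged at step %d", (int)(t + 1));
  }

  // outputs from post-update states h_1..h_T
  mat H1flat(Hall.memptr() + N * B, N, B * T, false);
  mat Zflat = Wout * H1flat;
  Zflat.each_col() += bout;

  const mat Tflat(const_cast<double*>(target.memptr()), Nout, B * T, false);
  const mat Mflat(const_cast<double*>(mask.memptr()), Nout, B * T, false);
  const double ntot = (double)(Nout * B * T);
  mat Err = Zflat - Tflat;
  const double loss_mse = accu(Mflat % square(Err)) / ntot;

  const double n_alive = accu(alive);
  double ss_act = 0.0;
  for (uword t = 0; t < T; ++t) {
    mat hsq = square(Hall.slice(t + 1));
    ss_act += accu(hsq.each_row() % alive.col(t).t());
  }
  const double denom_act = (double)N * std::max(n_alive, 1.0);
  const double loss_act = lambda_a * ss_act / denom_act;
  const double loss_w = lambda_w * (accu(square(Win)) + accu(square(Wrec)) +
                                    accu(square(Wout)));
  const double loss = loss_mse + loss_act + loss_w;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("loss_mse") = loss_mse,
      Rcpp::Named("loss_act") = loss_act, Rcpp::Named("loss_w") = loss_w);
  if (!want_grad) return out;

  // dL/dz, and its pullback through W_out for every step in one gemm
  mat dZ = (2.0 / ntot) * (Mflat % Err);
  mat WdZ = Wout.t() * dZ; // N x BT
  const double ca = 2.0 * lambda_a / denom_act;

  // backward through time
  cube A(N, B, T); // A_t = gamma * alive * sigma'(i_t) .* dL/dh_t (post-sigma)
  mat G = WdZ.cols((T - 1) * B, T * B - 1) +
          ca * (Hall.slice(T).each_row() % alive.col(T - 1).t());
  for (uword tt = T; tt-- > 0;) {
    mat At(A.slice_memptr(tt), N, B, false, true);
    At = D.slice(tt) % G;
    At.each_row() %= gamma * alive.col(tt).t();
    if (tt > 0) {
      // dL/dh_{t-1} = (1 - gamma*alive) dL/dh_t + Wrec^T A_t + direct terms
      G.each_row() %= (1.0 - gamma * alive.col(tt).t());
      G += Wrec.t() * At;
      G += WdZ.cols((tt - 1) * B, tt * B - 1);
      G += ca * (Hall.slice(tt).each_row() % alive.col(tt - 1).t());
    }
  }

  mat Aflat(A.memptr(), N, B * T, false);
  mat Hprev(Hall.memptr(), N, B * T, false); // h_0..h_{T-1}

  mat dWrec = Aflat * Hprev.t() + 2.0 * lambda_w * Wrec;
  mat dWin = Aflat * Uflat.t() + 2.0 * lambda_w * Win;
  vec dbin = sum(Aflat, 1);
  mat dWout = dZ * H1flat.t() + 2.0 * lambda_w * Wout;
  vec dbout = sum(dZ, 1);

  out["grad"] = Rcpp::List::create(
      Rcpp::Named("W_rec") = dWrec, Rcpp::Named("W_in") = dWin,
      Rcpp::Named("b_in") = dbin, Rcpp::Named("W_out") = dWout,
      Rcpp::Named("b_out") = dbout);
  return out;
}
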