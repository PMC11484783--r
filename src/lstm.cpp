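// LSTM forward and backward (BPTT) kernels for the adversarial denoiser.
// Array layout everywhere: cube(batch, features, time); slice t is the
// batch x features matrix at timestep t. Gate order along the 4H axis of the
// weight matrices: input, forget, cell candidate, output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& W,
                            const arma::mat& U, const arma::rowvec& b) {
  const uword T = X.n_slices, B = X.n_rows, H = U.n_rows;
  if (W.n_cols != 4 * H || U.n_cols != 4 * H || b.n_elem != 4 * H)
    Rcpp::stop("inconsistent LSTM parameter shapes");
  cube Hc(B, H, T), Cc(B, H, T), Ic(B, H, T), Fc(B, H, T), Gc(B, H, T),
      Oc(B, H, T);
  mat hprev(B, H, fill::zeros), cprev(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat Z = X.slice(t) * W + hprev * U;
    Z.each_row() += b;
    mat I = sigm(Z.cols(0, H - 1));
    mat F = sigm(Z.cols(H, 2 * H - 1));
    mat G = tanh(Z.cols(2 * H, 3 * H - 1));
    mat O = sigm(Z.cols(3 * H, 4 * H - 1));
    mat C = F % cprev + I % G;
    mat Ht = O % tanh(C);
    Ic.slice(t) = I; Fc.slice(t) = F; Gc.slice(t) = G; Oc.slice(t) = O;
    Cc.slice(t) = C; Hc.slice(t) = Ht;
    hprev = Ht; cprev = C;
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = Hc, Rcpp::Named("c") = Cc, Rcpp::Named("i") = Ic,
      Rcpp::Named("f") = Fc, Rcpp::Named("g") = Gc, Rcpp::Named("o") = Oc);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::cube& X,
                             const arma::cube& Hc, const arma::cube& Cc,
                             const arma::cube& Ic, const arma::cube& Fc,
                             const arma::cube& Gc, const arma::cube& Oc,
                             const arma::mat& W, const arma::mat& U) {
  const uword T = X.n_slices, B = X.n_rows, H = U.n_rows;
  cube dX(B, X.n_cols, T, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros), dU(U.n_rows, U.n_cols, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    mat hprev = (ti > 0) ? Hc.slice(ti - 1) : mat(B, H, fill::zeros);
    mat cprev = (ti > 0) ? Cc.slice(ti - 1) : mat(B, H, fill::zeros);
    mat tc = tanh(Cc.slice(ti));
    mat dh = dH.slice(ti) + dh_next;
    mat d_o = dh % tc;
    mat dc = dh % Oc.slice(ti) % (1.0 - tc % tc) + dc_next;
    mat di = dc % Gc.slice(ti);
    mat df = dc % cprev;
    mat dg = dc % Ic.slice(ti);
    mat dzi = di % Ic.slice(ti) % (1.0 - Ic.slice(ti));
    mat dzf = df % Fc.slice(ti) % (1.0 - Fc.slice(ti));
    mat dzg = dg % (1.0 - Gc.slice(ti) % Gc.slice(ti));
    mat dzo = d_o % Oc.slice(ti) % (1.0 - Oc.slice(ti));
    mat dZ = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    dW += X.slice(ti).t() * dZ;
    dU += hprev.t() * dZ;
    db += sum(dZ, 0);
    dX.slice(ti) = dZ * W.t();
    dh_next = dZ * U.t();
    dc_next = dc % Fc.slice(ti);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dw") = dW,
                            Rcpp::Named("du") = dU, Rcpp::Named("db") = db);
}
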