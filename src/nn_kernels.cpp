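// Compiled hot loops for the recurrent networks: fused GRU layer forward /
// backward-through-time and the Adam update. Only the time-stepped
// recurrence lives here; everything else runs on the R autodiff tape.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// X: (B*T) x 3H time-major input projections; h0: B x H; mask: B x T (or
// 0 x 0 for none). Returns stacked hidden states (B*T x H) plus the
// per-step gate activations needed for the backward pass.
// [[Rcpp::export(name = ".gru_forward_cpp")]]
List gru_forward_cpp(const arma::mat& X, const arma::mat& h0,
                     const arma::mat& Wrz, const arma::mat& Wn,
                     const arma::rowvec& bn, const arma::mat& mask) {
  const int B = h0.n_rows, H = h0.n_cols;
  const int T = X.n_rows / B;
  const bool useMask = mask.n_elem > 0;
  arma::mat out(B * T, H), rzs(B * T, 2 * H), hns(B * T, H), ns(B * T, H);
  arma::mat h = h0;
  for (int t = 0; t < T; ++t) {
    const arma::span rows(t * B, (t + 1) * B - 1);
    arma::mat xt = X.rows(rows);
    arma::mat rz = 1.0 / (1.0 + arma::exp(-(xt.cols(0, 2 * H - 1) + h * Wrz)));
    arma::mat hn = h * Wn;
    hn.each_row() += bn;
    arma::mat n = arma::tanh(xt.cols(2 * H, 3 * H - 1) +
                             rz.cols(0, H - 1) % hn);
    arma::mat z = rz.cols(H, 2 * H - 1);
    arma::mat hnew = (1.0 - z) % n + z % h;
    rzs.rows(rows) = rz;
    hns.rows(rows) = hn;
    ns.rows(rows) = n;
    if (useMask) {
      arma::mat m = arma::repmat(mask.col(t), 1, H);
      h = m % hnew + (1.0 - m) % h;
    } else {
      h = hnew;
    }
    out.rows(rows) = h;
  }
  return List::create(_["out"] = out, _["rzs"] = rzs, _["hns"] = hns,
                      _["ns"] = ns);
}

// [[Rcpp::export(name = ".gru_backward_cpp")]]
List gru_backward_cpp(const arma::mat& G, const arma::mat& out,
                      const arma::mat& h0, const arma::mat& rzs,
                      const arma::mat& hns, const arma::mat& ns,
                      const arma::mat& Wrz, const arma::mat& Wn,
                      const arma::mat& mask) {
  const int B = h0.n_rows, H = h0.n_cols;
  const int T = G.n_rows / B;
  const bool useMask = mask.n_elem > 0;
  arma::mat dX(B * T, 3 * H, arma::fill::zeros);
  arma::mat dWrz(arma::size(Wrz), arma::fill::zeros);
  arma::mat dWn(arma::size(Wn), arma::fill::zeros);
  arma::rowvec dbn(H, arma::fill::zeros);
  arma::mat dh(B, H, arma::fill::zeros);
  const arma::mat tWrz = Wrz.t(), tWn = Wn.t();
  for (int t = T - 1; t >= 0; --t) {
    const arma::span rows(t * B, (t + 1) * B - 1);
    arma::mat dht = G.rows(rows) + dh;
    arma::mat hp = (t == 0) ? h0
                            : arma::mat(out.rows((t - 1) * B, t * B - 1));
    arma::mat dhnew, dcarry;
    if (useMask) {
      arma::mat m = arma::repmat(mask.col(t), 1, H);
      dhnew = dht % m;
      dcarry = dht % (1.0 - m);
    } else {
      dhnew = dht;
      dcarry.zeros(B, H);
    }
    arma::mat rz = rzs.rows(rows);
    arma::mat r = rz.cols(0, H - 1), z = rz.cols(H, 2 * H - 1);
    arma::mat n = ns.rows(rows), hn = hns.rows(rows);
    arma::mat dz = dhnew % (hp - n);
    arma::mat dn = dhnew % (1.0 - z);
    arma::mat dhp = dhnew % z + dcarry;
    arma::mat dpn = dn % (1.0 - n % n);
    arma::mat dr = dpn % hn;
    arma::mat dhn = dpn % r;
    dWn += hp.t() * dhn;
    dbn += arma::sum(dhn, 0);
    dhp += dhn * tWn;
    arma::mat dprz = arma::join_rows(dr, dz) % rz % (1.0 - rz);
    dWrz += hp.t() * dprz;
    dhp += dprz * tWrz;
    dX.submat(t * B, 0, (t + 1) * B - 1, 2 * H - 1) = dprz;
    dX.submat(t * B, 2 * H, (t + 1) * B - 1, 3 * H - 1) = dpn;
    dh = dhp;
  }
  return List::create(_["dX"] = dX, _["dh0"] = dh, _["dWrz"] = dWrz,
                      _["dWn"] = dWn, _["dbn"] = dbn);
}

// in-place Adam update: value, m and v are modified without copying
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(NumericMatrix value, NumericMatrix grad,
                     NumericMatrix m, NumericMatrix v, double lr,
                     double beta1, double beta2, double eps, int t) {
  const R_xlen_t n = value.size();
  double* V = value.begin();
  const double* G = grad.begin();
  double* M = m.begin();
  double* W = v.begin();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    M[i] = beta1 * M[i] + (1.0 - beta1) * G[i];
    W[i] = beta2 * W[i] + (1.0 - beta2) * G[i] * G[i];
    V[i] -= lr * (M[i] / c1) / (std::sqrt(W[i] / c2) + eps);
  }
}
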