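// Batched forward/backward pass of the pairwise moment recursion.
//
// Pair blocks are 61x61 codon matrices, one per unordered position pair.
// Forward:  P^(r+1) = M . (K^T (P^(r) / D) K),  D = K M K^T  (per block),
// where M is the landscape pair marginal and K the shared codon kernel.
// The data loss is the aggregated log-loss against empirical pair
// frequencies (both orders, hence the factor 2); the backward pass
// accumulates d(loss)/dM by reverse-mode differentiation of the
// recursion. Empirical frequency blocks are mostly zeros (at most one
// nonzero per sequenced read), so the log-loss and its gradient only
// touch their nonzero entries.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LOG_FLOOR = 1e-300;

// out.slice(p) = A * X.slice(p) * B for every block; the left
// multiplication runs as one large GEMM over all blocks at once
static void sandwich(const mat& A, const mat& B, const cube& X, cube& out) {
  const uword q = X.n_rows, np = X.n_slices;
  const mat Xflat(const_cast<double*>(X.memptr()), q, q * np, false, true);
  mat Y = A * Xflat;                          // q x (q * np)
  for (uword p = 0; p < np; ++p)
    out.slice(p) = Y.cols(p * q, p * q + q - 1) * B;
}

// [[Rcpp::export]]
Rcpp::List pair_forward_backward(const arma::mat& K,
                                 const arma::mat& M2flat,
                                 const arma::uvec& p0_index,
                                 const Rcpp::List& F2,
                                 const arma::ivec& data_round,
                                 const int Rmax,
                                 const bool gradient) {
  const uword q = K.n_rows;            // 61
  const uword q2 = q * q;
  const uword np = M2flat.n_cols;
  const uword nel = q2 * np;
  const mat Kt = K.t();

  const cube M(const_cast<double*>(M2flat.memptr()), q, q, np, false, true);
  cube D(q, q, np);
  sandwich(K, Kt, M, D);

  // forward: keep P^(0..Rmax) and the pre-product U^(r) = K^T W K
  std::vector<cube> P(Rmax + 1), U(Rmax + 1);
  P[0].zeros(q, q, np);
  for (uword p = 0; p < np; ++p)
    P[0].slice(p)(p0_index[p] % q, p0_index[p] / q) = 1.0;
  cube W(q, q, np);
  for (int r = 1; r <= Rmax; ++r) {
    W = P[r - 1] / D;
    U[r].set_size(q, q, np);
    sandwich(Kt, K, W, U[r]);
    P[r] = M % U[r];
  }

  const int nd = F2.size();
  std::vector<mat> Fm(nd);
  double loss = 0.0;
  for (int k = 0; k < nd; ++k) {
    Fm[k] = Rcpp::as<mat>(F2[k]);       // 3721 x np, mostly zeros
    const double* f = Fm[k].memptr();
    const double* pr = P[data_round[k]].memptr();
    double acc = 0.0;
    for (uword e = 0; e < nel; ++e)
      if (f[e] > 0.0)
        acc += f[e] * std::log(std::max(pr[e], LOG_FLOOR));
    loss -= 2.0 * acc;
  }

  Rcpp::List out;
  out["loss"] = loss;
  if (!gradient) return out;

  const cube Dsq = D % D;
  cube G(q, q, np, fill::zeros), Mbar(q, q, np, fill::zeros), V(q, q, np),
    tmp(q, q, np);
  for (int r = Rmax; r >= 1; --r) {
    for (int k = 0; k < nd; ++k)
      if (data_round[k] == r) {
        const double* f = Fm[k].memptr();
        const double* pr = P[r].memptr();
        double* g = G.memptr();
        for (uword e = 0; e < nel; ++e)
          if (f[e] > 0.0)
            g[e] -= 2.0 * f[e] / std::max(pr[e], LOG_FLOOR);
      }
    tmp = G % M;
    sandwich(K, Kt, tmp, V);
    Mbar += G % U[r];
    tmp = (P[r - 1] % V) / Dsq;
    sandwich(Kt, K, tmp, W);
    Mbar -= W;
    G = V / D;
  }
  mat Mbar_flat(Mbar.memptr(), q2, np, true);
  out["M2bar"] = Mbar_flat;
  return out;
}
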