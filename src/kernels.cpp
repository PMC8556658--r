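// Batched linear-algebra kernels for the spatial-temporal graph engine.
// Each 3-d array is treated as a stack of matrices over its last
// dimension (the minibatch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Slice-wise matrix product C[,,b] = op(A[,,b]) %*% op(B[,,b]) with
// optional transposes. A, B: numeric 3-d arrays sharing the batch dim.
// [[Rcpp::export(name = "cpp_bmm")]]
arma::cube cpp_bmm(const arma::cube& A, const arma::cube& B,
                   const bool ta = false, const bool tb = false) {
  const arma::uword nb = A.n_slices;
  const arma::uword m = ta ? A.n_cols : A.n_rows;
  const arma::uword n = tb ? B.n_rows : B.n_cols;
  arma::cube C(m, n, nb);
  for (arma::uword b = 0; b < nb; ++b) {
    if (!ta && !tb)      C.slice(b) = A.slice(b) * B.slice(b);
    else if (ta && !tb)  C.slice(b) = A.slice(b).t() * B.slice(b);
    else if (!ta && tb)  C.slice(b) = A.slice(b) * B.slice(b).t();
    else                 C.slice(b) = A.slice(b).t() * B.slice(b).t();
  }
  return C;
}

// Largest eigenvalue and its eigenvector for each symmetric slice.
// [[Rcpp::export(name = "cpp_batch_eig_top")]]
List cpp_batch_eig_top(const arma::cube& L) {
  const arma::uword nb = L.n_slices;
  const arma::uword n = L.n_rows;
  arma::vec lmax(nb);
  arma::mat vecs(n, nb);
  arma::vec eval;
  arma::mat evec;
  for (arma::uword b = 0; b < nb; ++b) {
    arma::eig_sym(eval, evec, L.slice(b));
    lmax(b) = eval(n - 1);
    vecs.col(b) = evec.col(n - 1);
  }
  return List::create(Named("lmax") = lmax, Named("vec") = vecs);
}

// Chebyshev recursion per slice: returns the K bases stacked along rows
// ([K*N, N, B]) so the graph convolution can consume them in one block.
// [[Rcpp::export(name = "cpp_cheb_stack")]]
arma::cube cpp_cheb_stack(const arma::cube& Lt, const int K) {
  const arma::uword nb = Lt.n_slices;
  const arma::uword n = Lt.n_rows;
  arma::cube out(K * n, n, nb);
  for (arma::uword b = 0; b < nb; ++b) {
    arma::mat prev2 = arma::eye<arma::mat>(n, n);
    out.slice(b).rows(0, n - 1) = prev2;
    if (K >= 2) {
      arma::mat prev1 = Lt.slice(b);
      out.slice(b).rows(n, 2 * n - 1) = prev1;
      for (int k = 3; k <= K; ++k) {
        arma::mat cur = 2.0 * Lt.slice(b) * prev1 - prev2;
        out.slice(b).rows((k - 1) * n, k * n - 1) = cur;
        prev2 = prev1;
        prev1 = cur;
      }
    }
  }
  return out;
}

// Backward of the Chebyshev recursion: given per-order upstream
// gradients stacked as [K*N, N, B], accumulate the gradient w.r.t. Lt.
// [[Rcpp::export(name = "cpp_cheb_stack_bwd")]]
arma::cube cpp_cheb_stack_bwd(const arma::cube& Lt, const arma::cube& Ts,
                              const arma::cube& dTs, const int K) {
  const arma::uword nb = Lt.n_slices;
  const arma::uword n = Lt.n_rows;
  arma::cube dLt(n, n, nb, arma::fill::zeros);
  for (arma::uword b = 0; b < nb; ++b) {
    std::vector<arma::mat> g(K);
    for (int k = 0; k < K; ++k)
      g[k] = dTs.slice(b).rows(k * n, (k + 1) * n - 1);
    for (int k = K - 1; k >= 2; --k) {
      const arma::mat Tprev = Ts.slice(b).rows((k - 1) * n, k * n - 1);
      dLt.slice(b) += 2.0 * g[k] * Tprev.t();
      g[k - 1] += 2.0 * Lt.slice(b).t() * g[k];
      g[k - 2] -= g[k];
    }
    if (K >= 2) dLt.slice(b) += g[1];
  }
  return dLt;
}

// ---- stage kernels -------------------------------------------------------
// All 4-d tensors use the layout [N, F, T, B] in column-major memory and
// are passed as cubes reinterpreted as [N*F, T, B] or [N, F*T, B].

static inline arma::mat slice_nf(const arma::cube& X, const arma::uword N,
                                 const arma::uword F, const arma::uword t,
                                 const arma::uword b) {
  // view of X[, , t, b] as an N x F matrix (X passed as [N*F, T, B])
  return arma::mat(const_cast<double*>(X.slice_memptr(b)) + t * N * F,
                   N, F, false, true);
}

// Temporal attention forward. X: [N*F, T, B] view of [N, F, T, B].
// [[Rcpp::export(name = "cpp_ta_fwd")]]
List cpp_ta_fwd(const arma::cube& X, const int N_, const arma::vec& M1,
                const arma::mat& M2, const arma::vec& M3,
                const arma::mat& Vq, const arma::mat& bq) {
  const arma::uword N = N_;
  const arma::uword F = X.n_rows / N;
  const arma::uword T = X.n_cols;
  const arma::uword B = X.n_slices;
  arma::cube B1(T, F, B), B2(T, N, B), B3(N, T, B), Sq(T, T, B), Q(T, T, B);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat Xt = slice_nf(X, N, F, t, b);         // N x F
      B1.slice(b).row(t) = M1.t() * Xt;               // 1 x F
      B3.slice(b).col(t) = Xt * M3;                   // N
    }
    B2.slice(b) = B1.slice(b) * M2;                   // T x N
    arma::mat Et = B2.slice(b) * B3.slice(b) + bq;    // T x T
    Sq.slice(b) = 1.0 / (1.0 + arma::exp(-Et));
    arma::mat Qm = Vq * Sq.slice(b);
    // row softmax
    for (arma::uword u = 0; u < T; ++u) {
      arma::rowvec r = Qm.row(u);
      r -= r.max();
      arma::rowvec e = arma::exp(r);
      Qm.row(u) = e / arma::accu(e);
    }
    Q.slice(b) = Qm;
  }
  return List::create(Named("Qp") = Q, Named("B1") = B1, Named("B2") = B2,
                      Named("B3") = B3, Named("Sq") = Sq);
}

static inline arma::mat softmax_bwd_rows(const arma::mat& A,
                                         const arma::mat& dA) {
  arma::mat out = A % dA;
  arma::vec s = arma::sum(out, 1);
  out -= A.each_col() % s;
  return out;
}

// Temporal attention backward; returns parameter grads and dX.
// [[Rcpp::export(name = "cpp_ta_bwd")]]
List cpp_ta_bwd(const arma::cube& X, const int N_, const arma::vec& M1,
                const arma::mat& M2, const arma::vec& M3,
                const arma::mat& Vq, const arma::cube& B1,
                const arma::cube& B2, const arma::cube& B3,
                const arma::cube& Sq, const arma::cube& Qp,
                const arma::cube& dQp) {
  const arma::uword N = N_;
  const arma::uword F = X.n_rows / N;
  const arma::uword T = X.n_cols;
  const arma::uword B = X.n_slices;
  arma::vec dM1(N, arma::fill::zeros), dM3(F, arma::fill::zeros);
  arma::mat dM2(F, N, arma::fill::zeros), dVq(T, T, arma::fill::zeros),
            dbq(T, T, arma::fill::zeros);
  arma::cube dX(N * F, T, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    arma::mat dQ = softmax_bwd_rows(Qp.slice(b), dQp.slice(b));
    dVq += dQ * Sq.slice(b).t();
    arma::mat dS = Vq.t() * dQ;
    arma::mat dpre = dS % Sq.slice(b) % (1.0 - Sq.slice(b));
    dbq += dpre;
    arma::mat dB2 = dpre * B3.slice(b).t();           // T x N
    arma::mat dB3 = B2.slice(b).t() * dpre;           // N x T
    dM2 += B1.slice(b).t() * dB2;
    arma::mat dB1 = dB2 * M2.t();                     // T x F
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat Xt = slice_nf(X, N, F, t, b);         // N x F
      dM1 += Xt * dB1.row(t).t();
      dM3 += Xt.t() * dB3.col(t);
      arma::mat dXt = M1 * dB1.row(t) + dB3.col(t) * M3.t();  // N x F
      dX.slice(b).col(t) += arma::vectorise(dXt);
    }
  }
  return List::create(Named("M1") = dM1, Named("M2") = dM2,
                      Named("M3") = dM3, Named("Vq") = dVq,
                      Named("bq") = dbq, Named("dX") = dX);
}

// Spatial attention forward. X: [N*F, T, B].
// [[Rcpp::export(name = "cpp_sa_fwd")]]
List cpp_sa_fwd(const arma::cube& X, const int N_, const arma::vec& Z1,
                const arma::mat& Z2, const arma::vec& Z3,
                const arma::mat& Vp, const arma::mat& bp) {
  const arma::uword N = N_;
  const arma::uword F = X.n_rows / N;
  const arma::uword T = X.n_cols;
  const arma::uword B = X.n_slices;
  arma::cube A1(N, F, B), A2(N, T, B), A3(N, T, B), Sp(N, N, B), P(N, N, B);
  for (arma::uword b = 0; b < B; ++b) {
    A1.slice(b).zeros();
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat Xt = slice_nf(X, N, F, t, b);
      A1.slice(b) += Z1(t) * Xt;
      A3.slice(b).col(t) = Xt * Z3;
    }
    A2.slice(b) = A1.slice(b) * Z2;                   // N x T
    arma::mat E = A2.slice(b) * A3.slice(b).t() + bp; // N x N
    Sp.slice(b) = 1.0 / (1.0 + arma::exp(-E));
    arma::mat Pm = Vp * Sp.slice(b);
    for (arma::uword m = 0; m < N; ++m) {
      arma::rowvec r = Pm.row(m);
      r -= r.max();
      arma::rowvec e = arma::exp(r);
      Pm.row(m) = e / arma::accu(e);
    }
    P.slice(b) = Pm;
  }
  return List::create(Named("Pp") = P, Named("A1") = A1, Named("A2") = A2,
                      Named("A3") = A3, Named("Sp") = Sp);
}

// Spatial attention backward.
// [[Rcpp::export(name = "cpp_sa_bwd")]]
List cpp_sa_bwd(const arma::cube& X, const int N_, const arma::vec& Z1,
                const arma::mat& Z2, const arma::vec& Z3,
                const arma::mat& Vp, const arma::cube& A1,
                const arma::cube& A2, const arma::cube& A3,
                const arma::cube& Sp, const arma::cube& Pp,
                const arma::cube& dPp) {
  const arma::uword N = N_;
  const arma::uword F = X.n_rows / N;
  const arma::uword T = X.n_cols;
  const arma::uword B = X.n_slices;
  arma::vec dZ1(T, arma::fill::zeros), dZ3(F, arma::fill::zeros);
  arma::mat dZ2(F, T, arma::fill::zeros), dVp(N, N, arma::fill::zeros),
            dbp(N, N, arma::fill::zeros);
  arma::cube dX(N * F, T, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    arma::mat dP = softmax_bwd_rows(Pp.slice(b), dPp.slice(b));
    dVp += dP * Sp.slice(b).t();
    arma::mat dS = Vp.t() * dP;
    arma::mat dpre = dS % Sp.slice(b) % (1.0 - Sp.slice(b));
    dbp += dpre;
    arma::mat dA2 = dpre * A3.slice(b);               // N x T
    arma::mat dA3 = dpre.t() * A2.slice(b);           // N x T
    dZ2 += A1.slice(b).t() * dA2;
    arma::mat dA1 = dA2 * Z2.t();                     // N x F
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat Xt = slice_nf(X, N, F, t, b);
      dZ1(t) += arma::accu(Xt % dA1);
      dZ3 += Xt.t() * dA3.col(t);
      arma::mat dXt = Z1(t) * dA1 + dA3.col(t) * Z3.t();
      dX.slice(b).col(t) += arma::vectorise(dXt);
    }
  }
  return List::create(Named("Z1") = dZ1, Named("Z2") = dZ2,
                      Named("Z3") = dZ3, Named("Vp") = dVp,
                      Named("bp") = dbp, Named("dX") = dX);
}

// Graph convolution forward: Z[n, c, t, b] =
//   sum_k (Gs block k %*% X)[n, (f,t)] Theta_k[f, c] + bg[c].
// Gs: [K*N, N, B]; X: [N, F*T, B]; Theta: [K*F, C] (k-blocks stacked).
// Returns Z as [N*C, T, B] and the per-order products GXs [K*N, F*T, B].
// [[Rcpp::export(name = "cpp_gconv_fwd")]]
List cpp_gconv_fwd(const arma::cube& Gs, const arma::cube& X, const int K_,
                   const arma::mat& Theta, const arma::vec& bg,
                   const int T_) {
  const arma::uword K = K_, T = T_;
  const arma::uword N = X.n_rows;
  const arma::uword F = Theta.n_rows / K;
  const arma::uword C = Theta.n_cols;
  const arma::uword B = X.n_slices;
  arma::cube GXs(K * N, F * T, B);
  arma::cube Z(N * C, T, B);
  arma::rowvec bgr = bg.t();
  for (arma::uword b = 0; b < B; ++b) {
    GXs.slice(b) = Gs.slice(b) * X.slice(b);
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat acc(N, C, arma::fill::zeros);
      for (arma::uword k = 0; k < K; ++k) {
        arma::mat gx = GXs.slice(b).submat(k * N, t * F,
                                           (k + 1) * N - 1, (t + 1) * F - 1);
        acc += gx * Theta.rows(k * F, (k + 1) * F - 1);
      }
      acc.each_row() += bgr;
      Z.slice(b).col(t) = arma::vectorise(acc);
    }
  }
  return List::create(Named("Z") = Z, Named("GXs") = GXs);
}

// Graph convolution backward. dZ: [N*C, T, B] (already ReLU-masked).
// Returns dTheta ([K*F, C]), dbg, dGs ([K*N, N, B]) and dX ([N, F*T, B]).
// [[Rcpp::export(name = "cpp_gconv_bwd")]]
List cpp_gconv_bwd(const arma::cube& dZ, const arma::cube& Gs,
                   const arma::cube& GXs, const arma::cube& X,
                   const int K_, const arma::mat& Theta) {
  const arma::uword K = K_;
  const arma::uword N = X.n_rows;
  const arma::uword F = Theta.n_rows / K;
  const arma::uword C = Theta.n_cols;
  const arma::uword T = dZ.n_cols;
  const arma::uword B = X.n_slices;
  arma::mat dTheta(K * F, C, arma::fill::zeros);
  arma::vec dbg(C, arma::fill::zeros);
  arma::cube dGs(K * N, N, B);
  arma::cube dX(N, F * T, B, arma::fill::zeros);
  arma::cube dGXs(K * N, F * T, B);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat dZt(const_cast<double*>(dZ.slice_memptr(b)) + t * N * C,
                    N, C, false, true);
      dbg += arma::sum(dZt, 0).t();
      for (arma::uword k = 0; k < K; ++k) {
        arma::mat gx = GXs.slice(b).submat(k * N, t * F,
                                           (k + 1) * N - 1, (t + 1) * F - 1);
        dTheta.rows(k * F, (k + 1) * F - 1) += gx.t() * dZt;
        dGXs.slice(b).submat(k * N, t * F, (k + 1) * N - 1, (t + 1) * F - 1) =
          dZt * Theta.rows(k * F, (k + 1) * F - 1).t();
      }
    }
    dGs.slice(b) = dGXs.slice(b) * X.slice(b).t();
    dX.slice(b) = Gs.slice(b).t() * dGXs.slice(b);
  }
  return List::create(Named("Theta") = dTheta, Named("bg") = dbg,
                      Named("dGs") = dGs, Named("dX") = dX,
                      Named("dGXs") = dGXs);
}

// Temporal convolution forward (same padding).
// H: [N*C, T, B]; Phi: [kt*C, C2] (tau-blocks stacked). Returns Z2.
// [[Rcpp::export(name = "cpp_tconv_fwd")]]
arma::cube cpp_tconv_fwd(const arma::cube& H, const int N_, const int kt_,
                         const arma::mat& Phi, const arma::vec& bt) {
  const arma::uword N = N_, kt = kt_;
  const arma::uword C = H.n_rows / N;
  const arma::uword C2 = Phi.n_cols;
  const arma::uword T = H.n_cols;
  const arma::uword B = H.n_slices;
  const int pad = (kt - 1) / 2;
  arma::cube Z2(N * C2, T, B);
  arma::rowvec btr = bt.t();
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat acc(N, C2, arma::fill::zeros);
      for (arma::uword tau = 0; tau < kt; ++tau) {
        const int ts = (int)t + (int)tau - pad;
        if (ts < 0 || ts >= (int)T) continue;
        arma::mat Ht(const_cast<double*>(H.slice_memptr(b)) + ts * N * C,
                     N, C, false, true);
        acc += Ht * Phi.rows(tau * C, (tau + 1) * C - 1);
      }
      acc.each_row() += btr;
      Z2.slice(b).col(t) = arma::vectorise(acc);
    }
  }
  return Z2;
}

// Temporal convolution backward. dZ2 masked upstream.
// [[Rcpp::export(name = "cpp_tconv_bwd")]]
List cpp_tconv_bwd(const arma::cube& dZ2, const arma::cube& H, const int N_,
                   const int kt_, const arma::mat& Phi) {
  const arma::uword N = N_, kt = kt_;
  const arma::uword C = H.n_rows / N;
  const arma::uword C2 = dZ2.n_rows / N;
  const arma::uword T = H.n_cols;
  const arma::uword B = H.n_slices;
  const int pad = (kt - 1) / 2;
  arma::mat dPhi(kt * C, C2, arma::fill::zeros);
  arma::vec dbt(C2, arma::fill::zeros);
  arma::cube dH(N * C, T, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat dZt(const_cast<double*>(dZ2.slice_memptr(b)) + t * N * C2,
                    N, C2, false, true);
      dbt += arma::sum(dZt, 0).t();
      for (arma::uword tau = 0; tau < kt; ++tau) {
        const int ts = (int)t + (int)tau - pad;
        if (ts < 0 || ts >= (int)T) continue;
        arma::mat Ht(const_cast<double*>(H.slice_memptr(b)) + ts * N * C,
                     N, C, false, true);
        dPhi.rows(tau * C, (tau + 1) * C - 1) += Ht.t() * dZt;
        arma::mat dHt(dH.slice_memptr(b) + ts * N * C, N, C, false, true);
        dHt += dZt * Phi.rows(tau * C, (tau + 1) * C - 1).t();
      }
    }
  }
  return List::create(Named("Phi") = dPhi, Named("bt") = dbt,
                      Named("dH") = dH);
}
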