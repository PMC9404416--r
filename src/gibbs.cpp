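// Multi-trait linear/threshold animal-model Gibbs sampler.
//
// Model per record unit i (a heifer row or one cow lactation row) and trait
// j of the unit's trait block:
//   w_ij = x_ij' b_j + a_{animal(i), j} + pe_{level(i), j} + e_i,j
// with e_i ~ N(0, R0_b) within the unit's block, a ~ N(0, A (x) G0) via the
// sparse A-inverse, pe ~ N(0, I (x) P0).  w is the observed value for linear
// traits, a latent liability for binary (threshold) traits (category 1 below
// 0, category 2 above), and an augmented draw for missing values.  Residual
// covariances between trait blocks are structural zeros (the blocks are
// observed on disjoint record units).
//
// Location effects are sampled single-site (fixed-effect columns) or in
// small per-animal / per-pe-level t-vectors; covariance matrices from their
// inverse-Wishart full conditionals.  Threshold-trait identifiability is
// enforced by fixing the threshold-threshold residual sub-block to the
// identity and drawing the remaining residual elements from the exact
// conditional inverse-Wishart given that sub-block.  All randomness comes
// from R's RNG so runs are reproducible under set.seed().
//
// The per-cycle loops run over every animal and record, so the small
// t-dimensional linear algebra is hand-rolled on preallocated buffers
// (column-major, element (i,j) at [j*p+i]) rather than through allocating
// matrix temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cholesky A = L L' for small p; returns false if not positive definite.
static bool chol_lower(int p, const double* A, double* L) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= L[k * p + j] * L[k * p + j];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    const double lj = std::sqrt(d);
    L[j * p + j] = lj;
    for (int i = j + 1; i < p; ++i) {
      double s = A[j * p + i];
      for (int k = 0; k < j; ++k) s -= L[k * p + i] * L[k * p + j];
      L[j * p + i] = s / lj;
    }
    for (int i = 0; i < j; ++i) L[j * p + i] = 0.0;
  }
  return true;
}

// solve L L' x = b in place of x
static void chol_solve(int p, const double* L, const double* b, double* x) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[k * p + i] * x[k];
    x[i] = s / L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < p; ++k) s -= L[i * p + k] * x[k];
    x[i] = s / L[i * p + i];
  }
}

// solve L' x = z in place (z N(0,1) draws -> x ~ N(0, (LL')^-1))
static void chol_backsolve(int p, const double* L, double* z) {
  for (int i = p - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < p; ++k) s -= L[i * p + k] * z[k];
    z[i] = s / L[i * p + i];
  }
}

static arma::mat rinvwishart(double nu, const arma::mat& S, int cycle) {
  const int p = S.n_rows;
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, arma::symmatu(S)))
    stop("non-PSD inverse-Wishart scale matrix at cycle %d", cycle);
  arma::mat L;
  if (!arma::chol(L, arma::symmatu(Sinv), "lower"))
    stop("non-PSD inverse-Wishart scale matrix at cycle %d", cycle);
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  arma::mat X;
  if (!arma::inv_sympd(X, arma::symmatu(W)))
    stop("singular Wishart draw at cycle %d", cycle);
  return arma::symmatu(X);
}

// standard normal truncated to [alpha, Inf)
static double rltnorm(double alpha) {
  if (alpha < 4.5) {
    double plo = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double p = plo + R::unif_rand() * (1.0 - plo);
    if (p > 1.0 - 1e-16) p = 1.0 - 1e-16;
    if (p < 1e-316) p = 1e-316;
    double z = R::qnorm(p, 0.0, 1.0, 1, 0);
    return z < alpha ? alpha : z;
  }
  // far tail: Robert's shifted-exponential rejection
  for (;;) {
    double z = alpha + R::exp_rand() / alpha;
    double d = z - alpha;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

static double rtnorm0(double mu, double sd, bool above) {
  if (above) return mu + sd * rltnorm((0.0 - mu) / sd);
  return mu - sd * rltnorm(mu / sd);
}

// [[Rcpp::export]]
List gibbs_sampler_cpp(NumericMatrix Y, List Xs, IntegerVector animal,
                       const arma::sp_mat& Ainv, IntegerVector pe_level,
                       int npe, IntegerVector trait_block,
                       IntegerVector unit_block, LogicalVector threshold,
                       LogicalVector pe_trait, arma::mat G0, arma::mat P0,
                       arma::mat R0, double nuG, arma::mat SG, double nuP,
                       arma::mat SP, double nuR, arma::mat SR, int n_iter,
                       int burn_in, int thin) {
  RNGScope scope;
  const int N = Y.nrow(), t = Y.ncol(), n = Ainv.n_rows;
  const int B = Rcpp::max(trait_block) + 1;

  std::vector<arma::sp_mat> X(t);
  std::vector<arma::vec> b(t), xss(t);
  for (int j = 0; j < t; ++j) {
    X[j] = as<arma::sp_mat>(Xs[j]);
    b[j] = arma::vec(X[j].n_cols, arma::fill::zeros);
    xss[j] = arma::vec(X[j].n_cols, arma::fill::zeros);
    for (arma::sp_mat::const_iterator it = X[j].begin(); it != X[j].end(); ++it)
      xss[j]((int)it.col()) += (*it) * (*it);
  }
  // raw CSC views of A-inverse (kept alive by the reference argument)
  const arma::uword* Acp = Ainv.col_ptrs;
  const arma::uword* Ari = Ainv.row_indices;
  const double* Avx = Ainv.values;

  // index structures
  std::vector<arma::uvec> tb(B);  // traits of block
  {
    std::vector<std::vector<arma::uword> > tmp(B);
    for (int j = 0; j < t; ++j) tmp[trait_block[j]].push_back(j);
    for (int bk = 0; bk < B; ++bk) tb[bk] = arma::uvec(tmp[bk]);
  }
  std::vector<arma::uvec> ub(B);  // units of block
  {
    std::vector<std::vector<arma::uword> > tmp(B);
    for (int i = 0; i < N; ++i) tmp[unit_block[i]].push_back(i);
    for (int bk = 0; bk < B; ++bk) ub[bk] = arma::uvec(tmp[bk]);
  }
  // units per animal / pe level, CSR-style
  std::vector<int> ua_ptr(n + 1, 0), ua_idx(N), up_ptr(npe + 1, 0), up_idx;
  std::vector<double> nqb(n * B, 0.0);
  {
    for (int i = 0; i < N; ++i) ++ua_ptr[animal[i] + 1];
    for (int q = 0; q < n; ++q) ua_ptr[q + 1] += ua_ptr[q];
    std::vector<int> pos(ua_ptr.begin(), ua_ptr.end() - 1);
    for (int i = 0; i < N; ++i) {
      ua_idx[pos[animal[i]]++] = i;
      nqb[animal[i] * B + unit_block[i]] += 1.0;
    }
    if (npe > 0) {
      int m = 0;
      for (int i = 0; i < N; ++i) if (pe_level[i] >= 0) ++m;
      up_idx.resize(m);
      for (int i = 0; i < N; ++i)
        if (pe_level[i] >= 0) ++up_ptr[pe_level[i] + 1];
      for (int l = 0; l < npe; ++l) up_ptr[l + 1] += up_ptr[l];
      std::vector<int> ppos(up_ptr.begin(), up_ptr.end() - 1);
      for (int i = 0; i < N; ++i)
        if (pe_level[i] >= 0) up_idx[ppos[pe_level[i]]++] = i;
    }
  }
  arma::uvec tp;  // pe traits
  {
    std::vector<arma::uword> tmp;
    for (int j = 0; j < t; ++j) if (pe_trait[j]) tmp.push_back(j);
    tp = arma::uvec(tmp);
  }
  const int ntp = tp.n_elem;

  // state
  arma::mat W(N, t, arma::fill::zeros), E(N, t, arma::fill::zeros);
  arma::mat a(n, t, arma::fill::zeros);
  arma::mat pe(npe > 0 ? npe : 1, t, arma::fill::zeros);
  arma::umat obs(N, t, arma::fill::zeros);
  for (int j = 0; j < t; ++j) {
    double sum = 0.0; int nobs = 0;
    for (int i = 0; i < N; ++i) {
      if (trait_block[j] != unit_block[i]) continue;
      double y = Y(i, j);
      if (!NumericMatrix::is_na(y)) {
        obs(i, j) = 1;
        if (threshold[j]) W(i, j) = (y == 2.0) ? 0.5 : -0.5;
        else { W(i, j) = y; sum += y; ++nobs; }
      }
    }
    if (!threshold[j] && nobs > 0) {
      double mu = sum / nobs;
      b[j](0) = mu;  // first column is the intercept
      for (int i = 0; i < N; ++i)
        if (trait_block[j] == unit_block[i] && !obs(i, j)) W(i, j) = mu;
    }
  }
  // E = W - X b (a = pe = 0 initially)
  E = W;
  for (int j = 0; j < t; ++j) {
    arma::vec fit(N, arma::fill::zeros);
    for (arma::sp_mat::const_iterator it = X[j].begin(); it != X[j].end(); ++it)
      fit((int)it.row()) += (*it) * b[j]((int)it.col());
    E.col(j) -= fit;
  }

  arma::mat G0inv, R0inv(t, t, arma::fill::zeros), P0inv_tp;
  std::vector<arma::mat> R0inv_emb(B);
  auto refresh_inverses = [&](int cycle) {
    if (!arma::inv_sympd(G0inv, arma::symmatu(G0)))
      stop("non-PSD additive covariance at cycle %d", cycle);
    R0inv.zeros();
    for (int bk = 0; bk < B; ++bk) {
      arma::mat Rb = R0.submat(tb[bk], tb[bk]), Rbi;
      if (!arma::inv_sympd(Rbi, arma::symmatu(Rb)))
        stop("non-PSD residual covariance at cycle %d", cycle);
      R0inv.submat(tb[bk], tb[bk]) = Rbi;
      R0inv_emb[bk] = arma::mat(t, t, arma::fill::zeros);
      R0inv_emb[bk].submat(tb[bk], tb[bk]) = Rbi;
    }
    if (ntp > 0) {
      arma::mat Pb = P0.submat(tp, tp);
      if (!arma::inv_sympd(P0inv_tp, arma::symmatu(Pb)))
        stop("non-PSD permanent-environment covariance at cycle %d", cycle);
    }
  };
  refresh_inverses(0);

  const int nsave = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  arma::mat Gs(nsave, t * t), Ps(nsave, t * t), Rs(nsave, t * t);
  IntegerVector iters(nsave);
  int isave = 0;

  // scratch buffers for the small per-animal / per-level systems
  std::vector<double> Pb(t * t), Lb(t * t), Db(t * t), rhsb(t), mub(t),
      zb(t), sqb(t), cqb(t), deltab(t), Sb(t * t), vbuf(N);
  double* Em = E.memptr();
  double* am = a.memptr();

  for (int cycle = 1; cycle <= n_iter; ++cycle) {
    if (cycle % 1000 == 0) Rcpp::checkUserInterrupt();
    const double* R0i = R0inv.memptr();
    const double* G0i = G0inv.memptr();

    // ---- fixed effects, single-site over design columns ----
    for (int j = 0; j < t; ++j) {
      const double rjj = R0i[j * t + j];
      for (int i = 0; i < N; ++i) {  // v_i = [R0inv e_i]_j
        double s = 0.0;
        for (int k = 0; k < t; ++k) s += R0i[j * t + k] * Em[k * N + i];
        vbuf[i] = s;
      }
      for (arma::uword k = 0; k < X[j].n_cols; ++k) {
        double num = 0.0;
        for (arma::sp_mat::const_col_iterator it = X[j].begin_col(k);
             it != X[j].end_col(k); ++it)
          num += (*it) * vbuf[(int)it.row()];
        const double den = rjj * xss[j](k);
        const double bnew = b[j](k) + num / den + R::norm_rand() / std::sqrt(den);
        const double delta = bnew - b[j](k);
        b[j](k) = bnew;
        for (arma::sp_mat::const_col_iterator it = X[j].begin_col(k);
             it != X[j].end_col(k); ++it) {
          const int i = (int)it.row();
          E(i, j) -= delta * (*it);
          vbuf[i] -= delta * (*it) * rjj;
        }
      }
    }

    // ---- additive genetic effects, per-animal t-vectors ----
    for (int q = 0; q < n; ++q) {
      // D = sum_b n_qb R0inv_emb[b]; precision P = D + Ainv_qq G0inv
      std::fill(Db.begin(), Db.end(), 0.0);
      for (int bk = 0; bk < B; ++bk) {
        const double w = nqb[q * B + bk];
        if (w == 0.0) continue;
        const double* Rb = R0inv_emb[bk].memptr();
        for (int x = 0; x < t * t; ++x) Db[x] += w * Rb[x];
      }
      std::fill(sqb.begin(), sqb.end(), 0.0);
      for (int u = ua_ptr[q]; u < ua_ptr[q + 1]; ++u) {
        const int i = ua_idx[u];
        for (int j = 0; j < t; ++j) sqb[j] += Em[j * N + i];
      }
      std::fill(cqb.begin(), cqb.end(), 0.0);
      double aqq = 0.0;
      for (arma::uword ptr = Acp[q]; ptr < Acp[q + 1]; ++ptr) {
        const int qq = (int)Ari[ptr];
        const double v = Avx[ptr];
        if (qq == q) { aqq = v; continue; }
        for (int j = 0; j < t; ++j) cqb[j] += v * am[j * n + qq];
      }
      for (int j = 0; j < t; ++j) {
        double s = 0.0;
        for (int k = 0; k < t; ++k)
          s += R0i[k * t + j] * sqb[k] + Db[k * t + j] * am[k * n + q] -
               G0i[k * t + j] * cqb[k];
        rhsb[j] = s;
        for (int k = 0; k < t; ++k)
          Pb[k * t + j] = Db[k * t + j] + aqq * G0i[k * t + j];
      }
      if (!chol_lower(t, Pb.data(), Lb.data()))
        stop("non-PSD conditional precision (animal %d) at cycle %d", q + 1, cycle);
      chol_solve(t, Lb.data(), rhsb.data(), mub.data());
      for (int j = 0; j < t; ++j) zb[j] = R::norm_rand();
      chol_backsolve(t, Lb.data(), zb.data());
      for (int j = 0; j < t; ++j) {
        deltab[j] = mub[j] + zb[j] - am[j * n + q];
        am[j * n + q] += deltab[j];
      }
      for (int u = ua_ptr[q]; u < ua_ptr[q + 1]; ++u) {
        const int i = ua_idx[u];
        const arma::uvec& tj = tb[unit_block[i]];
        for (arma::uword jj = 0; jj < tj.n_elem; ++jj)
          Em[tj(jj) * N + i] -= deltab[tj(jj)];
      }
    }

    // ---- permanent-environment effects ----
    if (npe > 0 && ntp > 0) {
      const double* Ppi = P0inv_tp.memptr();
      double* pm = pe.memptr();
      const int npel = pe.n_rows;
      for (int l = 0; l < npe; ++l) {
        const int m = up_ptr[l + 1] - up_ptr[l];
        if (m == 0) continue;
        std::fill(sqb.begin(), sqb.end(), 0.0);
        for (int u = up_ptr[l]; u < up_ptr[l + 1]; ++u) {
          const int i = up_idx[u];
          for (int j = 0; j < t; ++j) sqb[j] += Em[j * N + i];
        }
        for (int jj = 0; jj < ntp; ++jj) {
          const int j = tp(jj);
          double s = 0.0;
          for (int k = 0; k < t; ++k) s += R0i[k * t + j] * sqb[k];
          for (int kk = 0; kk < ntp; ++kk) {
            const int k = tp(kk);
            s += m * R0i[k * t + j] * pm[k * npel + l];
            Pb[kk * ntp + jj] = m * R0i[k * t + j] + Ppi[kk * ntp + jj];
          }
          rhsb[jj] = s;
        }
        if (!chol_lower(ntp, Pb.data(), Lb.data()))
          stop("non-PSD conditional precision (pe level %d) at cycle %d", l + 1, cycle);
        chol_solve(ntp, Lb.data(), rhsb.data(), mub.data());
        for (int jj = 0; jj < ntp; ++jj) zb[jj] = R::norm_rand();
        chol_backsolve(ntp, Lb.data(), zb.data());
        for (int jj = 0; jj < ntp; ++jj) {
          const int j = tp(jj);
          deltab[jj] = mub[jj] + zb[jj] - pm[j * npel + l];
          pm[j * npel + l] += deltab[jj];
        }
        for (int u = up_ptr[l]; u < up_ptr[l + 1]; ++u) {
          const int i = up_idx[u];
          for (int jj = 0; jj < ntp; ++jj) Em[tp(jj) * N + i] -= deltab[jj];
        }
      }
    }

    // ---- liabilities and missing-value augmentation ----
    for (int i = 0; i < N; ++i) {
      const arma::uvec& tj = tb[unit_block[i]];
      for (arma::uword jj = 0; jj < tj.n_elem; ++jj) {
        const int j = tj(jj);
        const bool is_obs = obs(i, j) != 0;
        if (is_obs && !threshold[j]) continue;
        const double rjj = R0i[j * t + j];
        const double cvar = 1.0 / rjj;
        double dot = 0.0;
        for (arma::uword kk = 0; kk < tj.n_elem; ++kk) {
          const int k = tj(kk);
          if (k != j) dot += R0i[k * t + j] * E(i, k);
        }
        const double mu_ij = W(i, j) - E(i, j);
        const double cmean = mu_ij - cvar * dot;
        const double csd = std::sqrt(cvar);
        double wnew;
        if (!is_obs) wnew = cmean + csd * R::norm_rand();
        else wnew = rtnorm0(cmean, csd, Y(i, j) == 2.0);
        E(i, j) += wnew - W(i, j);
        W(i, j) = wnew;
      }
    }

    // ---- covariance components ----
    {
      std::fill(Sb.begin(), Sb.end(), 0.0);  // S = a' Ainv a
      for (int c = 0; c < n; ++c) {
        for (arma::uword ptr = Acp[c]; ptr < Acp[c + 1]; ++ptr) {
          const int r = (int)Ari[ptr];
          const double v = Avx[ptr];
          for (int k = 0; k < t; ++k) {
            const double vak = v * am[k * n + c];
            for (int j = 0; j < t; ++j)
              Sb[k * t + j] += vak * am[j * n + r];
          }
        }
      }
      arma::mat S(Sb.data(), t, t);
      G0 = rinvwishart(nuG + n, arma::symmatu(SG + S), cycle);
    }
    if (npe > 0 && ntp > 0) {
      arma::mat petp = pe.cols(tp);
      arma::mat S = petp.t() * petp;
      P0.zeros();
      P0.submat(tp, tp) = rinvwishart(nuP + npe, arma::symmatu(SP.submat(tp, tp) + S), cycle);
    }
    // Residual covariance per block.  Threshold traits keep residual
    // variance fixed at 1 (their scale is not identified from binary
    // data), so the threshold-threshold sub-block is pinned to the
    // identity and the remaining elements are drawn from the exact
    // conditional of the inverse-Wishart given that sub-block: with
    // partition (L = linear, T = threshold) and V the conditional scale,
    //   D = R_LL - R_LT R_TT^-1 R_TL ~ IW(V_LL - V_LT V_TT^-1 V_TL, nu),
    //   B = R_LT R_TT^-1 | D        ~ MN(V_LT V_TT^-1, D, V_TT^-1),
    // then R_LL = D + B B', R_LT = B under R_TT = I.
    for (int bk = 0; bk < B; ++bk) {
      if (ub[bk].n_elem == 0) continue;
      arma::mat Eb = E.submat(ub[bk], tb[bk]);
      const double nu = nuR + ub[bk].n_elem;
      arma::mat V = arma::symmatu(SR.submat(tb[bk], tb[bk]) + Eb.t() * Eb);
      std::vector<arma::uword> Lv, Tv;
      for (arma::uword x = 0; x < tb[bk].n_elem; ++x) {
        if (threshold[tb[bk](x)]) Tv.push_back(x); else Lv.push_back(x);
      }
      if (Tv.empty()) {
        R0.submat(tb[bk], tb[bk]) = rinvwishart(nu, V, cycle);
      } else {
        const arma::uvec Lu(Lv), Tu(Tv);
        arma::mat Rb(tb[bk].n_elem, tb[bk].n_elem, arma::fill::zeros);
        Rb.submat(Tu, Tu) = arma::eye(Tu.n_elem, Tu.n_elem);
        if (!Lv.empty()) {
          arma::mat VTTi;
          if (!arma::inv_sympd(VTTi, arma::symmatu(V.submat(Tu, Tu))))
            stop("non-PSD residual scale matrix at cycle %d", cycle);
          arma::mat Vc = V.submat(Lu, Lu) -
            V.submat(Lu, Tu) * VTTi * V.submat(Tu, Lu);
          arma::mat D = rinvwishart(nu, arma::symmatu(Vc), cycle);
          arma::mat M = V.submat(Lu, Tu) * VTTi;
          arma::mat Lr, Lc;
          if (!arma::chol(Lr, arma::symmatu(D), "lower") ||
              !arma::chol(Lc, arma::symmatu(VTTi), "lower"))
            stop("non-PSD residual draw at cycle %d", cycle);
          arma::mat Z(Lu.n_elem, Tu.n_elem);
          for (arma::uword r = 0; r < Z.n_rows; ++r)
            for (arma::uword c = 0; c < Z.n_cols; ++c)
              Z(r, c) = R::norm_rand();
          arma::mat Bm = M + Lr * Z * Lc.t();
          Rb.submat(Lu, Lu) = D + Bm * Bm.t();
          Rb.submat(Lu, Tu) = Bm;
          Rb.submat(Tu, Lu) = Bm.t();
        }
        R0.submat(tb[bk], tb[bk]) = Rb;
      }
    }
    refresh_inverses(cycle);

    if (cycle > burn_in && (cycle - burn_in) % thin == 0 && isave < nsave) {
      Gs.row(isave) = arma::vectorise(G0).t();
      Ps.row(isave) = arma::vectorise(P0).t();
      Rs.row(isave) = arma::vectorise(R0).t();
      iters[isave] = cycle;
      ++isave;
    }
  }

  return List::create(_["G0"] = Gs.rows(0, isave > 0 ? isave - 1 : 0),
                      _["P0"] = Ps.rows(0, isave > 0 ? isave - 1 : 0),
                      _["R0"] = Rs.rows(0, isave > 0 ? isave - 1 : 0),
                      _["iteration"] = iters, _["n_saved"] = isave);
}
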