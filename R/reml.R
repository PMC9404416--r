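# Average-information REML for all-linear multi-trait animal models.
#
# Works on the stacked (trait-major) mixed-model equations
#   C = U' (R0inv (x) I_N) U + blkdiag(0, G0inv (x) Ainv, P0inv (x) I_npe)
# with U = [X | Z | W].  The REML log-likelihood is evaluated through the
# sparse Cholesky factor of C (Henderson's identity); the score vector by
# central finite differences of that exact likelihood; and the average
# information matrix exactly through the standard quadratic forms
# AI_kl = 0.5 f_k' P f_l, where each working vector f_k = V_k P y reduces to
# cheap transforms of the BLUP solutions (e.g. for an element of G0,
# f = Z ahat G0inv S).  When an AI step leaves the parameter space or fails
# to improve the likelihood, the step is halved and, as a last resort, an
# EM update (trace terms from the dense inverse of C) is taken.

vech_index <- function(t) {
  idx <- which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

pack_theta <- function(G0, R0, P0 = NULL) {
  v <- function(M) M[vech_index(nrow(M))]
  c(v(G0), if (!is.null(P0)) v(P0), v(R0))
}

unpack_theta <- function(theta, t, pe) {
  m <- t * (t + 1L) / 2L
  unv <- function(x) {
    M <- matrix(0, t, t)
    M[vech_index(t)] <- x
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  }
  G0 <- unv(theta[seq_len(m)])
  P0 <- if (pe) unv(theta[m + seq_len(m)]) else NULL
  R0 <- unv(theta[(if (pe) 2L * m else m) + seq_len(m)])
  list(G0 = G0, P0 = P0, R0 = R0)
}

is_pd <- function(M) {
  ok <- try(chol(M), silent = TRUE)
  !inherits(ok, "try-error")
}

# environment holding the fixed model pieces for one REML run
reml_workspace <- function(mme) {
  if (any(mme$threshold))
    stop("ai_reml_fit() handles linear traits only; threshold traits need gibbs_fit()")
  if (length(unique(mme$trait_block)) > 1L)
    stop("ai_reml_fit() requires traits observed on a single record class")
  complete <- rowSums(is.na(mme$Y)) == 0L
  if (!all(complete))
    warning(sum(!complete), " record(s) with missing trait values dropped for REML")
  t <- ncol(mme$Y)
  Y <- mme$Y[complete, , drop = FALSE]
  N <- nrow(Y)
  n <- length(mme$ainv$ids)
  Xs <- lapply(mme$Xs, function(X) {
    X <- X[complete, , drop = FALSE]
    keep <- Matrix::colSums(X != 0) > 0
    X[, keep, drop = FALSE]
  })
  animal <- mme$animal[complete] + 1L
  Z <- Matrix::sparseMatrix(i = seq_len(N), j = animal, x = 1, dims = c(N, n))
  pe <- any(mme$pe_trait)
  if (pe && !all(mme$pe_trait))
    stop("ai_reml_fit() supports permanent environment on all traits or none")
  if (pe) {
    lev <- mme$pe_level[complete] + 1L
    npe <- mme$npe
    Wp <- Matrix::sparseMatrix(i = seq_len(N), j = lev, x = 1, dims = c(N, npe))
  } else {
    npe <- 0L
    Wp <- NULL
  }
  Xb <- Reduce(Matrix::bdiag, lapply(seq_len(t), function(j) Xs[[j]]))
  It <- Matrix::Diagonal(t)
  U <- cbind(Xb, Matrix::kronecker(It, Z),
             if (pe) Matrix::kronecker(It, Wp))
  U <- methods::as(U, "CsparseMatrix")
  p <- ncol(Xb)
  list(t = t, N = N, n = n, p = p, npe = npe, pe = pe, Y = Y, U = U,
       animal = animal, pe_level = if (pe) lev else NULL,
       Ainv = mme$ainv$matrix, yty = crossprod(Y))
}

reml_system <- function(ws, G0, R0, P0) {
  t <- ws$t
  R0inv <- solve(R0)
  G0inv <- solve(G0)
  yvec <- as.numeric(ws$Y)
  # Rinv y, trait-major: vec(Y %*% R0inv)
  Ry <- as.numeric(ws$Y %*% R0inv)
  rhs <- as.numeric(Matrix::crossprod(ws$U, Ry))
  RU <- Matrix::kronecker(R0inv, Matrix::Diagonal(ws$N))
  C <- Matrix::crossprod(ws$U, RU %*% ws$U)
  Gpart <- Matrix::kronecker(G0inv, ws$Ainv)
  zero_p <- Matrix::Matrix(0, ws$p, ws$p, sparse = TRUE)
  blocks <- list(zero_p, Gpart)
  if (ws$pe) blocks <- c(blocks, list(Matrix::kronecker(solve(P0), Matrix::Diagonal(ws$npe))))
  C <- C + Reduce(Matrix::bdiag, blocks)
  C <- Matrix::forceSymmetric(C)
  ch <- try(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE), silent = TRUE)
  if (inherits(ch, "try-error")) return(NULL)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  yRy <- sum(R0inv * ws$yty)
  m2l <- ws$N * determinant(R0)$modulus[1L] +
    ws$n * determinant(G0)$modulus[1L] +
    (if (ws$pe) ws$npe * determinant(P0)$modulus[1L] else 0) +
    logdetC + yRy - sum(sol * rhs)
  list(C = C, ch = ch, sol = sol, rhs = rhs, m2l = as.numeric(m2l),
       R0inv = R0inv, G0inv = G0inv,
       P0inv = if (ws$pe) solve(P0) else NULL)
}

reml_m2l <- function(ws, theta) {
  par <- unpack_theta(theta, ws$t, ws$pe)
  if (!is_pd(par$G0) || !is_pd(par$R0) || (ws$pe && !is_pd(par$P0))) return(NA_real_)
  sys <- reml_system(ws, par$G0, par$R0, par$P0)
  if (is.null(sys)) return(NA_real_)
  sys$m2l
}

# working vectors f_k = V_k P y as N x t matrices, one per parameter
reml_fvecs <- function(ws, sys) {
  t <- ws$t
  idx <- vech_index(t)
  sol <- sys$sol
  Ah <- matrix(sol[ws$p + seq_len(ws$n * t)], ws$n, t)
  Ph <- if (ws$pe) matrix(sol[ws$p + ws$n * t + seq_len(ws$npe * t)], ws$npe, t)
  fitted <- matrix(as.numeric(ws$U %*% sol), ws$N, t)
  E <- ws$Y - fitted
  PyM <- E %*% sys$R0inv
  fl <- list()
  basis <- function(r, s) {
    S <- matrix(0, t, t)
    S[r, s] <- S[s, r] <- 1
    S
  }
  for (k in seq_len(nrow(idx))) {
    S <- basis(idx[k, 1L], idx[k, 2L])
    fl[[length(fl) + 1L]] <- (Ah %*% sys$G0inv %*% S)[ws$animal, , drop = FALSE]
  }
  if (ws$pe) for (k in seq_len(nrow(idx))) {
    S <- basis(idx[k, 1L], idx[k, 2L])
    fl[[length(fl) + 1L]] <- (Ph %*% sys$P0inv %*% S)[ws$pe_level, , drop = FALSE]
  }
  for (k in seq_len(nrow(idx))) {
    S <- basis(idx[k, 1L], idx[k, 2L])
    fl[[length(fl) + 1L]] <- PyM %*% S
  }
  fl
}

reml_ai_matrix <- function(ws, sys) {
  fl <- reml_fvecs(ws, sys)
  np <- length(fl)
  rhs_k <- vector("list", np)
  sol_k <- vector("list", np)
  for (k in seq_len(np)) {
    Rf <- as.numeric(fl[[k]] %*% sys$R0inv)
    rhs_k[[k]] <- as.numeric(Matrix::crossprod(ws$U, Rf))
    sol_k[[k]] <- as.numeric(Matrix::solve(sys$ch, rhs_k[[k]]))
  }
  AI <- matrix(0, np, np)
  for (k in seq_len(np)) for (l in k:np) {
    fRf <- sum((fl[[k]] %*% sys$R0inv) * fl[[l]])
    AI[k, l] <- AI[l, k] <- 0.5 * (fRf - sum(rhs_k[[k]] * sol_k[[l]]))
  }
  AI
}

reml_gradient <- function(ws, theta, m2l0) {
  np <- length(theta)
  g <- numeric(np)
  for (k in seq_len(np)) {
    h <- max(1e-5, 1e-4 * abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    fu <- reml_m2l(ws, up)
    fd <- reml_m2l(ws, dn)
    if (is.na(fu) && is.na(fd)) { g[k] <- 0; next }
    if (is.na(fu)) g[k] <- -0.5 * (m2l0 - fd) / h
    else if (is.na(fd)) g[k] <- -0.5 * (fu - m2l0) / h
    else g[k] <- -0.5 * (fu - fd) / (2 * h)  # d logL / d theta
  }
  g
}

reml_em_step <- function(ws, sys, dense_limit = 9000L) {
  dim_c <- nrow(sys$C)
  if (dim_c > dense_limit) return(NULL)
  t <- ws$t
  Ci <- solve(as.matrix(Matrix::forceSymmetric(sys$C)))
  sol <- sys$sol
  Ah <- matrix(sol[ws$p + seq_len(ws$n * t)], ws$n, t)
  arows <- function(j) ws$p + (j - 1L) * ws$n + seq_len(ws$n)
  Aden <- as.matrix(ws$Ainv)
  TrG <- matrix(0, t, t)
  for (r in seq_len(t)) for (s in r:t)
    TrG[r, s] <- TrG[s, r] <- sum(Aden * Ci[arows(r), arows(s)])
  G0 <- (t(Ah) %*% Aden %*% Ah + TrG) / ws$n
  P0 <- NULL
  if (ws$pe) {
    Ph <- matrix(sol[ws$p + ws$n * t + seq_len(ws$npe * t)], ws$npe, t)
    prow <- function(j) ws$p + ws$n * t + (j - 1L) * ws$npe + seq_len(ws$npe)
    TrP <- matrix(0, t, t)
    for (r in seq_len(t)) for (s in r:t)
      TrP[r, s] <- TrP[s, r] <- sum(diag(Ci[prow(r), prow(s), drop = FALSE]))
    P0 <- (crossprod(Ph) + TrP) / ws$npe
  }
  fitted <- matrix(as.numeric(ws$U %*% sol), ws$N, t)
  E <- ws$Y - fitted
  urow <- function(j) (j - 1L) * ws$N + seq_len(ws$N)
  TrR <- matrix(0, t, t)
  for (r in seq_len(t)) for (s in r:t) {
    M <- Matrix::crossprod(ws$U[urow(r), , drop = FALSE], ws$U[urow(s), , drop = FALSE])
    M <- methods::as(M, "TsparseMatrix")
    TrR[r, s] <- TrR[s, r] <- sum(Ci[cbind(M@i + 1L, M@j + 1L)] * M@x)
  }
  R0 <- (crossprod(E) + TrR) / ws$N
  list(G0 = as.matrix(G0), P0 = if (ws$pe) as.matrix(P0), R0 = as.matrix(R0))
}

#' Fit linear traits by average-information REML
#'
#' Restricted maximum likelihood for all-linear multi-trait animal models,
#' used as an independent cross-check on the Gibbs sampler.  Updates use the
#' exact average-information matrix with step halving and an
#' expectation-maximisation fallback whenever a step would leave the
#' parameter space or decrease the likelihood; convergence is declared when
#' the relative change in the REML log-likelihood falls below `tol`.
#' Threshold traits are not supported (the categorical/continuous mix is
#' the Gibbs sampler's job); records missing any model trait are dropped.
#'
#' @param mme an [build_mme()] object with linear traits only.
#' @param start optional list with starting `G0`, `P0`, `R0`.
#' @param max_iter maximum REML iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param verbose print per-iteration log-likelihoods.
#' @return A `reml_fit`: list with `G0`, `P0`, `R0`, `loglik`,
#'   `iterations`, `converged`, `se` (asymptotic SEs of the covariance
#'   parameters from the inverse AI matrix, in [pack_theta()] order) and
#'   `identifiable`.
#' @export
ai_reml_fit <- function(mme, start = NULL, max_iter = 100L, tol = 1e-8,
                        verbose = FALSE) {
  ws <- reml_workspace(mme)
  t <- ws$t
  vy <- diag(ws$yty) / ws$N - (colMeans(ws$Y))^2
  G0 <- if (!is.null(start$G0)) start$G0 else diag(0.4 * vy, t)
  R0 <- if (!is.null(start$R0)) start$R0 else diag(0.5 * vy, t)
  P0 <- if (ws$pe) { if (!is.null(start$P0)) start$P0 else diag(0.1 * vy, t) } else NULL
  theta <- pack_theta(G0, R0, P0)
  sys <- reml_system(ws, G0, R0, P0)
  if (is.null(sys)) stop("starting values give a singular system")
  identifiable <- TRUE
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    AI <- reml_ai_matrix(ws, sys)
    if (!is.finite(rcond(AI)) || rcond(AI) < 1e-10) {
      warning("average-information matrix is singular: variance components ",
              "are not separately identifiable for this design (boundary or ",
              "confounded parameters)")
      identifiable <- FALSE
      break
    }
    g <- reml_gradient(ws, theta, sys$m2l)
    delta <- solve(AI, g)
    step_ok <- FALSE
    for (half in 0:10) {
      cand <- theta + delta / 2^half
      m2l_new <- reml_m2l(ws, cand)
      if (!is.na(m2l_new) && m2l_new <= sys$m2l + 1e-10) {
        step_ok <- TRUE
        theta_new <- cand
        break
      }
    }
    if (!step_ok) {
      em <- reml_em_step(ws, sys)
      if (is.null(em)) break
      theta_new <- pack_theta(em$G0, em$R0, em$P0)
      m2l_new <- reml_m2l(ws, theta_new)
      if (is.na(m2l_new)) break
    }
    par <- unpack_theta(theta_new, t, ws$pe)
    sys_new <- reml_system(ws, par$G0, par$R0, par$P0)
    if (verbose)
      message(sprintf("iter %d: logL = %.6f", iter, -0.5 * sys_new$m2l))
    rel <- abs(sys_new$m2l - sys$m2l) / max(1, abs(sys$m2l))
    theta <- theta_new
    sys <- sys_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  par <- unpack_theta(theta, t, ws$pe)
  dimnames(par$G0) <- dimnames(par$R0) <- list(mme$spec$traits, mme$spec$traits)
  se <- if (identifiable && !is.null(AI) && rcond(AI) > 1e-12)
    sqrt(pmax(diag(solve(AI)), 0)) else rep(NA_real_, length(theta))
  fit <- structure(list(G0 = par$G0,
                        P0 = if (ws$pe) par$P0 else matrix(0, t, t),
                        R0 = par$R0, loglik = -0.5 * sys$m2l,
                        iterations = iter, converged = converged,
                        identifiable = identifiable, se = se,
                        traits = mme$spec$traits),
                   class = "reml_fit")
  if (!converged && identifiable) {
    cond <- structure(class = c("reml_nonconvergence", "error", "condition"),
                      list(message = sprintf(
                        "AI-REML did not converge in %d iterations (last logL %.4f)",
                        iter, fit$loglik), call = sys.call(-1L), estimates = fit))
    stop(cond)
  }
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: logL = %.4f after %d iterations (%sconverged)\n",
              x$loglik, x$iterations, if (x$converged) "" else "NOT "))
  cat("G0:\n"); print(round(x$G0, 4))
  cat("R0:\n"); print(round(x$R0, 4))
  invisible(x)
}
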