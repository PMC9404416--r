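#' Posterior summaries of heritabilities and correlations
#'
#' Computes, at every retained sample, the heritability
#' `h2 = s2_a / (s2_a + s2_pe + s2_e)` (the permanent-environment term
#' enters only for cow traits), the genetic correlation
#' `rg_ij = G0_ij / sqrt(G0_ii G0_jj)` and the phenotypic correlation from
#' `T = G0 + P0 + R0`, then averages the per-sample ratios (ratio first,
#' then mean, with the posterior SD over the same per-sample values).
#'
#' @param chains a [chain_samples()] object.
#' @param burn_in cycles to discard (on the original cycle scale); samples
#'   with `iteration <= burn_in` are dropped.  Defaults to the burn-in the
#'   chain was run with, which [gibbs_fit()] has already removed.
#' @param thinning keep every `thinning`-th retained sample.
#' @return A `posterior_summary`: list with `traits`, `h2` (`mean`, `sd`
#'   vectors), `rg` and `rp` (`mean`, `sd` matrices) and `n_samples`.
#' @export
summarize_chain <- function(chains, burn_in = chains$config$burn_in,
                            thinning = 1L) {
  stopifnot(inherits(chains, "chain_samples"))
  keep <- which(chains$iteration > burn_in)
  if (length(keep) == 0L) stop("no samples remain after burn-in")
  if (thinning > 1L) keep <- keep[seq(1L, length(keep), by = thinning)]
  t <- length(chains$traits)
  ns <- length(keep)
  pe_in_denom <- chains$animal_class == "cow"
  h2s <- matrix(NA_real_, ns, t)
  rgs <- rps <- array(NA_real_, c(ns, t, t))
  for (k in seq_len(ns)) {
    G <- chains$G0[keep[k], , , drop = TRUE]
    P <- chains$P0[keep[k], , , drop = TRUE]
    R <- chains$R0[keep[k], , , drop = TRUE]
    G <- matrix(G, t, t); P <- matrix(P, t, t); R <- matrix(R, t, t)
    Tm <- G + P + R
    denom <- diag(G) + ifelse(pe_in_denom, diag(P), 0) + diag(R)
    h2s[k, ] <- diag(G) / denom
    sg <- sqrt(diag(G)); st <- sqrt(diag(Tm))
    rgs[k, , ] <- G / tcrossprod(sg)
    rps[k, , ] <- Tm / tcrossprod(st)
  }
  msd <- function(a) list(mean = apply(a, c(2L, 3L), mean),
                          sd = apply(a, c(2L, 3L), stats::sd))
  out <- list(traits = chains$traits,
              h2 = list(mean = colMeans(h2s), sd = apply(h2s, 2L, stats::sd)),
              rg = msd(rgs), rp = msd(rps), n_samples = ns)
  dimnames(out$rg$mean) <- dimnames(out$rg$sd) <-
    dimnames(out$rp$mean) <- dimnames(out$rp$sd) <-
    list(chains$traits, chains$traits)
  names(out$h2$mean) <- names(out$h2$sd) <- chains$traits
  structure(out, class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 3L, ...) {
  cat("posterior_summary over", x$n_samples, "samples\n")
  cat("heritabilities (posterior mean +/- SD):\n")
  for (j in seq_along(x$traits))
    cat(sprintf("  %-7s %.*f +/- %.*f\n", x$traits[j], digits, x$h2$mean[j],
                digits, x$h2$sd[j]))
  if (length(x$traits) > 1L) {
    cat("genetic correlations (upper triangle):\n")
    print(round(x$rg$mean, digits))
  }
  invisible(x)
}

# AR-based estimate of the spectral density at frequency zero, the
# long-run variance used by the Geweke diagnostic and the ESS.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  ord <- min(30L, max(1L, floor(10 * log10(n))))
  fit <- try(stats::ar(x, aic = TRUE, order.max = ord), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (length(fit$ar) == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Chain convergence diagnostics
#'
#' Geweke z-score (first 10% vs last 50% of the chain, long-run variances
#' from an AR spectral estimator), effective sample size and Monte-Carlo
#' standard error for every distinct covariance component, plus the data
#' needed for trace plots.  Components with |z| > 2 or ESS < 100 are
#' flagged.
#'
#' @param chains a [chain_samples()] object.
#' @param frac1,frac2 Geweke window fractions.
#' @return A `chain_diagnostics` object: data frame with one row per
#'   component (`component`, `trait_i`, `trait_j`, `mean`, `sd`,
#'   `geweke_z`, `ess`, `mcse`, `flagged`), with the per-iteration series in
#'   the `traces` attribute.
#' @export
diagnostics <- function(chains, frac1 = 0.1, frac2 = 0.5) {
  stopifnot(inherits(chains, "chain_samples"))
  ns <- dim(chains$G0)[1L]
  if (ns < 100L) stop("need at least 100 saved samples for diagnostics")
  t <- length(chains$traits)
  rows <- list()
  traces <- list()
  for (comp in c("G0", "P0", "R0")) {
    arr <- chains[[comp]]
    for (i in seq_len(t)) for (j in i:t) {
      x <- arr[, i, j]
      if (stats::var(x) == 0) next  # structural zeros / fixed scales
      n1 <- max(2L, floor(frac1 * ns))
      n2 <- max(2L, floor(frac2 * ns))
      x1 <- x[seq_len(n1)]
      x2 <- x[seq(ns - n2 + 1L, ns)]
      s1 <- spectrum0_ar(x1); s2 <- spectrum0_ar(x2)
      z <- (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
      s0 <- spectrum0_ar(x)
      ess <- if (s0 > 0) ns * stats::var(x) / s0 else ns
      key <- sprintf("%s[%s,%s]", comp, chains$traits[i], chains$traits[j])
      rows[[key]] <- data.frame(
        component = comp, trait_i = chains$traits[i], trait_j = chains$traits[j],
        mean = mean(x), sd = stats::sd(x), geweke_z = z, ess = ess,
        mcse = stats::sd(x) / sqrt(max(ess, 1)),
        flagged = abs(z) > 2 | ess < 100, stringsAsFactors = FALSE)
      traces[[key]] <- x
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, traces = traces, iteration = chains$iteration,
            class = c("chain_diagnostics", "data.frame"))
}

#' Write trace-plot data
#'
#' @param diag a [diagnostics()] result.
#' @param path output CSV path (`iteration` plus one column per component).
#' @export
write_traces <- function(diag, path) {
  traces <- attr(diag, "traces")
  df <- data.frame(iteration = attr(diag, "iteration"))
  for (k in names(traces)) df[[k]] <- traces[[k]]
  utils::write.csv(df, path, row.names = FALSE)  # component names hold commas
  invisible(path)
}
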