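#' Gibbs chain configuration
#'
#' Defaults mirror routine practice for threshold variance-component
#' estimation: a single chain of 300,000 cycles with the first 50,000
#' discarded as burn-in and every 10th sample kept.
#'
#' @param n_iter total Gibbs cycles.
#' @param burn_in initial cycles discarded.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @return A `chain_config` list.
#' @export
chain_config <- function(n_iter = 300000L, burn_in = 50000L, thin = 10L) {
  stopifnot(n_iter > burn_in, burn_in >= 0L, thin >= 1L,
            (n_iter - burn_in) >= thin)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)), class = "chain_config")
}

#' Container for saved covariance samples
#'
#' Normally produced by [gibbs_fit()]; the constructor is exported so that
#' small chains with known values can be assembled directly (e.g. to check
#' summary arithmetic).
#'
#' @param G0,P0,R0 arrays of dimension (samples, t, t).
#' @param iteration cycle index of each saved sample.
#' @param traits trait names.
#' @param animal_class `"heifer"`/`"cow"` per trait (governs whether the
#'   permanent-environment variance enters the heritability denominator).
#' @param threshold logical per trait.
#' @param config the [chain_config()] used (defaults to a minimal one).
#' @param seed RNG seed used.
#' @return A `chain_samples` object.
#' @export
chain_samples <- function(G0, P0, R0, iteration, traits, animal_class,
                          threshold = rep(FALSE, length(traits)),
                          config = NULL, seed = NA_integer_) {
  stopifnot(length(dim(G0)) == 3L, dim(G0)[2L] == length(traits))
  if (is.null(config))
    config <- chain_config(n_iter = max(iteration) + 1L, burn_in = 0L, thin = 1L)
  structure(list(G0 = G0, P0 = P0, R0 = R0, iteration = iteration,
                 traits = traits, animal_class = animal_class,
                 threshold = threshold, config = config, seed = seed),
            class = "chain_samples")
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf("chain_samples: %d saved samples of %d-trait covariance matrices (cycles %d..%d)\n",
              dim(x$G0)[1L], length(x$traits), min(x$iteration), max(x$iteration)))
  invisible(x)
}

#' Fit the multi-trait animal model by Gibbs sampling
#'
#' Runs the liability-augmented Gibbs sampler: Gaussian full-conditional
#' draws for fixed, additive-genetic and permanent-environment effects;
#' truncated-normal liability draws for threshold traits; augmentation of
#' missing trait values; and inverse-Wishart draws for the additive (`G0`),
#' permanent-environment (`P0`) and residual (`R0`) covariance matrices.
#' For identifiability, threshold traits keep residual variance 1: the
#' threshold-threshold sub-block of `R0` is fixed to the identity and the
#' free residual elements are drawn from the exact conditional
#' inverse-Wishart given that sub-block.  Priors are flat for location
#' effects and weakly
#' informative inverse-Wishart for the covariance matrices (degrees of
#' freedom t + 1, scale 0.1 times the observed phenotypic variances).
#' Given the same seed the saved samples are bitwise reproducible.
#'
#' @param mme an [build_mme()] object.
#' @param config a [chain_config()].
#' @param seed integer RNG seed.
#' @param start optional list with starting `G0`, `P0`, `R0` matrices.
#' @param priors optional list overriding `nu_G`, `S_G`, `nu_P`, `S_P`,
#'   `nu_R`, `S_R`.
#' @return A [chain_samples()] object.
#' @export
gibbs_fit <- function(mme, config = chain_config(), seed = 1L, start = NULL,
                      priors = NULL) {
  stopifnot(inherits(mme, "mme"), inherits(config, "chain_config"))
  t <- ncol(mme$Y)
  n <- length(mme$ainv$ids)
  vy <- apply(mme$Y, 2L, stats::var, na.rm = TRUE)
  vy[mme$threshold | !is.finite(vy) | vy <= 0] <- 1
  dflt <- function(x, d) if (is.null(x)) d else x
  G0 <- dflt(start$G0, diag(0.4 * vy, t))
  P0 <- if (any(mme$pe_trait)) dflt(start$P0, diag(ifelse(mme$pe_trait, 0.2 * vy, 0), t))
        else matrix(0, t, t)
  R0 <- dflt(start$R0, {
    R <- diag(ifelse(mme$threshold, 1, 0.4 * vy), t)
    R
  })
  nu_G <- dflt(priors$nu_G, t + 1)
  nu_P <- dflt(priors$nu_P, sum(mme$pe_trait) + 1)
  nu_R <- dflt(priors$nu_R, t + 1)
  S_G <- dflt(priors$S_G, diag(0.1 * vy, t))
  S_P <- dflt(priors$S_P, diag(0.1 * vy, t))
  S_R <- dflt(priors$S_R, diag(0.1 * vy, t))
  if (nu_G <= t - 1 || nu_R <= t - 1)
    stop("inverse-Wishart degrees of freedom below the minimum for ", t, " traits")
  nsave <- (config$n_iter - config$burn_in) %/% config$thin
  if (nsave < 1L) stop("chain configuration saves no samples")

  set.seed(seed)
  res <- gibbs_sampler_cpp(mme$Y, mme$Xs, mme$animal, mme$ainv$matrix,
                           mme$pe_level, mme$npe, mme$trait_block,
                           mme$unit_block, mme$threshold, mme$pe_trait,
                           G0, P0, R0, nu_G, S_G, nu_P, S_P, nu_R, S_R,
                           config$n_iter, config$burn_in, config$thin)
  ns <- res$n_saved
  to_array <- function(M) {
    a <- array(0, dim = c(ns, t, t),
               dimnames = list(NULL, mme$spec$traits, mme$spec$traits))
    for (k in seq_len(ns)) a[k, , ] <- matrix(M[k, ], t, t)
    a
  }
  chain_samples(to_array(res$G0), to_array(res$P0), to_array(res$R0),
                iteration = res$iteration[seq_len(ns)],
                traits = mme$spec$traits,
                animal_class = mme$spec$spec$animal_class,
                threshold = mme$threshold, config = config, seed = seed)
}

#' Save chain samples as a long table
#'
#' One row per (iteration, component, trait pair): columns `iteration`,
#' `component` (`G0`/`P0`/`R0`), `trait_i`, `trait_j`, `value`.
#'
#' @param chains a [chain_samples()] object.
#' @param path output CSV path.
#' @export
write_chain_samples <- function(chains, path) {
  t <- length(chains$traits)
  rows <- list()
  for (comp in c("G0", "P0", "R0")) {
    arr <- chains[[comp]]
    for (i in seq_len(t)) for (j in i:t) {
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = chains$iteration, component = comp,
        trait_i = chains$traits[i], trait_j = chains$traits[j],
        value = arr[, i, j], stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
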