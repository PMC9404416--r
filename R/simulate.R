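#' Herd simulation configuration
#'
#' Parameters for the event-level herd simulator.  Defaults emulate the
#' reproductive biology of a pasture-based Holstein herd: oestrus returns on
#' a ~21-day cycle (jittered a few days), conception per service is a
#' Bernoulli draw on the probit (liability) scale around a baseline
#' probability of 0.65 for heifers and 0.45 for cows (matching mean
#' services per conception of roughly 1.5 and 2.2), gestation is 280 days
#' truncated to 260-302, and cows are rebred after a voluntary waiting
#' period.  Age at first service is drawn around 16.8 months (sd 3.5).
#'
#' @param n_herds number of herds.
#' @param n_founders founder animals in the simulated pedigree.
#' @param n_generations discrete generations after the founders.
#' @param n_per_generation offspring per generation (default `n_founders`).
#' @param sire_pool sires in use per generation (creates half-sib families).
#' @param afs_mean_months,afs_sd_months age at first service policy.
#' @param cycle_days,cycle_jitter_days heat-cycle return interval and its
#'   uniform jitter.
#' @param p_conception_heifer,p_conception_cow baseline per-service
#'   conception probabilities.
#' @param fertility_sd SD of the animal-level conception liability; links
#'   conception probability to a probit-scale animal effect.
#' @param gestation_mean,gestation_sd,gestation_range gestation length in
#'   days (truncated normal).
#' @param vwp_days voluntary waiting period after calving before rebreeding.
#' @param heat_wait_max_days uniform wait from end of VWP to the first
#'   observed heat.
#' @param max_services services allowed per episode before the animal is
#'   left open (cull cap).
#' @param n_lactations lactations simulated per cow.
#' @param diagnosis_delay_days days from conception to the pregnancy
#'   diagnosis.
#' @param base_year founder birth year.
#' @return A `herd_sim_config` list.
#' @export
herd_sim_config <- function(n_herds = 2L, n_founders = 100L,
                            n_generations = 3L, n_per_generation = NULL,
                            sire_pool = 5L, afs_mean_months = 16.8,
                            afs_sd_months = 3.5, cycle_days = 21,
                            cycle_jitter_days = 3,
                            p_conception_heifer = 0.65,
                            p_conception_cow = 0.45, fertility_sd = 0.3,
                            gestation_mean = 280, gestation_sd = 7,
                            gestation_range = c(260, 302), vwp_days = 70,
                            heat_wait_max_days = 20, max_services = 8L,
                            n_lactations = 3L, diagnosis_delay_days = 42L,
                            base_year = 2000L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_per_generation)) cfg$n_per_generation <- n_founders
  stopifnot(p_conception_heifer > 0, p_conception_heifer < 1,
            p_conception_cow > 0, p_conception_cow < 1,
            cycle_days > 0, gestation_mean > 0, vwp_days > 0,
            n_founders >= 2L, n_generations >= 1L)
  structure(cfg, class = "herd_sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (generation 0, unknown parents), then each
#' generation's offspring get a sire drawn from a small pool of the previous
#' generation's males (half-sib family structure) and a dam drawn from its
#' females.  Birth dates advance two years per generation with day-of-year
#' jitter, so the pedigree is acyclic by construction.
#'
#' @param config a [herd_sim_config()].
#' @param seed integer RNG seed.
#' @return A sorted [pedigree()] with extra columns `sex`, `herd` and
#'   `generation`.
#' @export
simulate_pedigree <- function(config = herd_sim_config(), seed = 1L) {
  set.seed(seed)
  nf <- config$n_founders
  ng <- config$n_generations
  npg <- config$n_per_generation
  id <- function(g, i) sprintf("G%d_%04d", g, i)
  animal <- id(0L, seq_len(nf))
  sire <- dam <- rep(NA_character_, nf)
  sex <- sample(rep_len(c("M", "F"), nf))
  gen <- rep(0L, nf)
  for (g in seq_len(ng - 1L)) {
    prev <- which(gen == g - 1L)
    males <- animal[prev][sex[prev] == "M"]
    females <- animal[prev][sex[prev] == "F"]
    pool <- sample(males, min(config$sire_pool, length(males)))
    s <- sample(pool, npg, replace = TRUE)
    d <- sample(females, npg, replace = TRUE)
    animal <- c(animal, id(g, seq_len(npg)))
    sire <- c(sire, s)
    dam <- c(dam, d)
    sex <- c(sex, sample(rep_len(c("M", "F"), npg)))
    gen <- c(gen, rep(g, npg))
  }
  birth <- as.Date(sprintf("%d-01-01", config$base_year + 2L * gen)) +
    sample.int(300L, length(animal), replace = TRUE)
  ped <- pedigree(animal, sire, dam, birth)
  ped$sex <- sex
  ped$herd <- sprintf("H%d", sample.int(config$n_herds, length(animal), replace = TRUE))
  ped$generation <- gen
  attr(ped, "sorted") <- TRUE  # construction order is parents-first
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw from N(0, G0); each descendant is the parent average plus a
#' Mendelian-sampling deviation with covariance `d_i * G0`, where
#' `d_i = 1 - 0.25 k - 0.25 (F_s + F_d)` over the k known parents.  The
#' resulting vectors have covariance `A` (x) `G0` without ever forming the
#' dense A.
#'
#' @param ped a sorted [pedigree()].
#' @param G0 additive-genetic covariance matrix (one row/col per trait).
#' @param seed integer RNG seed.
#' @return Matrix of breeding values, one row per animal in pedigree order,
#'   one column per trait.
#' @export
simulate_breeding_values <- function(ped, G0, seed = 1L) {
  ped <- as_sorted_pedigree(ped)
  G0 <- as.matrix(G0)
  t <- nrow(G0)
  eg <- eigen(G0, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("G0 is not positive semi-definite")
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t)
  set.seed(seed)
  n <- nrow(ped)
  Fv <- unname(inbreeding(ped))
  p <- parent_indices(ped)
  si <- p$sire + 1L; di <- p$dam + 1L  # 0 = unknown
  bv <- matrix(0, n, t, dimnames = list(ped$animal, rownames(G0)))
  Z <- matrix(stats::rnorm(n * t), n, t) %*% t(L)
  for (i in seq_len(n)) {
    pa <- numeric(t)
    k <- 0L
    fs <- fd <- 0
    if (si[i] > 0L) { pa <- pa + bv[si[i], ]; k <- k + 1L; fs <- Fv[si[i]] }
    if (di[i] > 0L) { pa <- pa + bv[di[i], ]; k <- k + 1L; fd <- Fv[di[i]] }
    d <- 1 - 0.25 * k - 0.25 * (fs + fd)
    bv[i, ] <- 0.5 * pa + sqrt(d) * Z[i, ]
  }
  bv
}

#' Simulation ground truth container
#'
#' Bundles the generative parameters and per-animal effects used by
#' [simulate_phenotypes()] and [simulate_service_records()], so that tests
#' can compare model estimates and derived traits against known truth.
#'
#' @param G0,P0,R0 trait covariance matrices (P0/R0 may be `NULL` when a
#'   component is absent).
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param traits trait names (defaults to `colnames(bv)`).
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(G0, P0 = NULL, R0 = NULL, bv = NULL, traits = NULL) {
  G0 <- as.matrix(G0)
  t <- nrow(G0)
  if (is.null(traits)) traits <- colnames(bv) %||% paste0("T", seq_len(t))
  if (is.null(P0)) P0 <- matrix(0, t, t)
  if (is.null(R0)) R0 <- matrix(0, t, t)
  structure(list(G0 = G0, P0 = as.matrix(P0), R0 = as.matrix(R0), bv = bv,
                 traits = traits), class = "sim_truth")
}

#' Simulate phenotypes under the animal model
#'
#' Generates records directly under the estimation model: contemporary-group
#' effect + breeding value + permanent-environment effect (shared across an
#' animal's repeated records) + residual, with residual/pe covariances R0
#' and P0.  Threshold traits are generated by thresholding the latent
#' liability at 0 into codes 1 (below) / 2 (above).  The result is a
#' `phenotype_table` ready for [build_mme()].
#'
#' @param ped a sorted [pedigree()].
#' @param truth a [sim_truth()] with breeding values.
#' @param spec a [model_spec()] naming the traits and their response types.
#' @param phenotyped ids of animals receiving records (default: all).
#' @param n_records records per animal (repeated records activate pe).
#' @param n_cg number of contemporary groups.
#' @param cg_sd SD of contemporary-group effects.
#' @param seed integer RNG seed.
#' @return A `phenotype_table` with `cg_code` filled; the true liabilities
#'   are kept in the `liabilities` attribute.
#' @export
simulate_phenotypes <- function(ped, truth, spec, phenotyped = NULL,
                                n_records = 1L, n_cg = 50L, cg_sd = 0.5,
                                seed = 1L) {
  ped <- as_sorted_pedigree(ped)
  traits <- spec$traits
  t <- length(traits)
  stopifnot(identical(dim(truth$G0), c(t, t)))
  if (is.null(phenotyped)) phenotyped <- ped$animal
  set.seed(seed)
  n <- length(phenotyped)
  bv <- truth$bv[phenotyped, , drop = FALSE]
  cg_eff <- stats::rnorm(n_cg, 0, cg_sd)
  chol_or_zero <- function(M) {
    if (all(M == 0)) return(matrix(0, nrow(M), nrow(M)))
    eg <- eigen(M, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(M))
  }
  Lp <- chol_or_zero(truth$P0)
  Lr <- chol_or_zero(truth$R0)
  pe <- matrix(stats::rnorm(n * t), n, t) %*% t(Lp)
  cls <- spec$spec$animal_class
  rows <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    cg <- sample.int(n_cg, n, replace = TRUE)
    e <- matrix(stats::rnorm(n * t), n, t) %*% t(Lr)
    liab <- cg_eff[cg] + bv + if (n_records > 1L) pe else 0
    liab <- liab + e
    rows[[r]] <- data.frame(animal_id = phenotyped,
                            herd = "SIM", parity = if (all(cls == "heifer")) 1L else r + 1L,
                            record_date = as.Date(NA), age_months = NA_real_,
                            cg_code = sprintf("CG%02d", cg),
                            stringsAsFactors = FALSE)
    for (j in seq_len(t)) {
      v <- liab[, j]
      if (spec$response[j] == "threshold") v <- ifelse(v >= 0, 2, 1)
      rows[[r]][[traits[j]]] <- v
    }
  }
  out <- do.call(rbind, rows)
  # heifer and cow traits live on different record rows
  if (any(cls == "heifer") && any(cls == "cow")) {
    warning("mixed heifer/cow trait simulation places all traits on the same rows; ",
            "use simulate_service_records() for the class-split structure")
  }
  out <- out[order(out$animal_id, out$parity), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("phenotype_table", "data.frame"),
            edit_log = empty_edit_log())
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate on-farm AI service records with known truth
#'
#' Event-level simulator: each female is first served at the policy age,
#' then re-served on a jittered 21-day heat cycle until she conceives or
#' reaches the service cap; conception per service is Bernoulli with
#' probability `pnorm(qnorm(p_base) + u)` for an animal-level liability
#' `u ~ N(0, fertility_sd^2)`; calving follows at a truncated-normal
#' gestation, a pregnancy diagnosis is recorded in between, and later
#' lactations repeat the cycle after the voluntary waiting period.  The
#' returned truth ledger bookkeeps every derivable trait value, so
#' [derive_traits()] can be checked record-for-record.
#'
#' @param ped a pedigree from [simulate_pedigree()] (needs `sex` and `herd`).
#' @param config a [herd_sim_config()].
#' @param seed integer RNG seed.
#' @return List with `herd` (a `herd_records`) and `truth` (data frame
#'   `animal_id`, `parity`, `trait`, `value`).
#' @export
simulate_service_records <- function(ped, config = herd_sim_config(), seed = 1L) {
  ped <- as_sorted_pedigree(ped)
  if (is.null(ped$sex)) stop("pedigree lacks a 'sex' column; use simulate_pedigree()")
  set.seed(seed)
  females <- which(ped$sex == "F")
  events <- list()
  truth <- list()
  add_truth <- function(id, parity, trait, value) {
    truth[[length(truth) + 1L]] <<- data.frame(
      animal_id = id, parity = parity, trait = trait, value = value,
      stringsAsFactors = FALSE)
  }
  zb_h <- stats::qnorm(config$p_conception_heifer)
  zb_c <- stats::qnorm(config$p_conception_cow)
  for (k in females) {
    id <- ped$animal[k]
    birth <- ped$birth_date[k]
    u <- stats::rnorm(1L, 0, config$fertility_sd)
    p_h <- stats::pnorm(zb_h + u)
    p_c <- stats::pnorm(zb_c + u)
    serve_episode <- function(start, p) {
      dates <- as.Date(character(0))
      date <- start
      conceived <- FALSE
      for (s in seq_len(config$max_services)) {
        dates <- c(dates, date)
        if (stats::runif(1L) < p) { conceived <- TRUE; break }
        date <- date + config$cycle_days +
          sample.int(2L * config$cycle_jitter_days + 1L, 1L) -
          config$cycle_jitter_days - 1L
      }
      list(dates = dates, conceived = conceived)
    }
    afs_days <- max(300L, round(stats::rnorm(1L, config$afs_mean_months,
                                             config$afs_sd_months) * DAYS_PER_MONTH))
    ep <- serve_episode(birth + afs_days, p_h)
    sv <- ep$dates
    out <- c(rep("failure", length(sv) - 1L),
             if (ep$conceived) "success" else "failure")
    for (i in seq_along(sv))
      events[[length(events) + 1L]] <- list(id, "SERVICE", sv[i], out[i])
    add_truth(id, 1L, "AFS", days_to_months(as.integer(sv[1L] - birth)))
    calv <- as.Date(NA)
    if (ep$conceived) {
      conc <- sv[length(sv)]
      add_truth(id, 1L, "SPCh", length(sv))
      gest <- round(rtrunc_norm(1L, config$gestation_mean, config$gestation_sd,
                                config$gestation_range[1L] + 0.5,
                                config$gestation_range[2L] - 0.5))
      calv <- conc + gest
      events[[length(events) + 1L]] <-
        list(id, "DIAGNOSIS", conc + config$diagnosis_delay_days, "pregnant")
      add_truth(id, 1L, "AFC", days_to_months(as.integer(calv - birth)))
    }
    l <- 0L
    while (!is.na(calv) && l < config$n_lactations) {
      l <- l + 1L
      events[[length(events) + 1L]] <- list(id, "CALVING", calv, as.character(l))
      start <- calv + config$vwp_days +
        sample.int(config$heat_wait_max_days + 1L, 1L) - 1L
      ep <- serve_episode(start, p_c)
      sv <- ep$dates
      out <- c(rep("failure", length(sv) - 1L),
               if (ep$conceived) "success" else "failure")
      for (i in seq_along(sv))
        events[[length(events) + 1L]] <- list(id, "SERVICE", sv[i], out[i])
      cfs <- as.integer(sv[1L] - calv)
      add_truth(id, l + 1L, "CFS", cfs)
      add_truth(id, l + 1L, "FS80d", if (cfs <= 80) 2 else 1)
      if (ep$conceived) {
        conc <- sv[length(sv)]
        do <- as.integer(conc - calv)
        add_truth(id, l + 1L, "DO", do)
        add_truth(id, l + 1L, "SPC", length(sv))
        add_truth(id, l + 1L, "PD100d", if (do <= 100) 2 else 1)
        add_truth(id, l + 1L, "PD200d", if (do <= 200) 2 else 1)
        events[[length(events) + 1L]] <-
          list(id, "DIAGNOSIS", conc + config$diagnosis_delay_days, "pregnant")
        gest <- round(rtrunc_norm(1L, config$gestation_mean, config$gestation_sd,
                                  config$gestation_range[1L] + 0.5,
                                  config$gestation_range[2L] - 0.5))
        calv <- conc + gest
      } else calv <- as.Date(NA)
    }
  }
  ev <- data.frame(animal_id = vapply(events, function(e) e[[1L]], ""),
                   event_type = vapply(events, function(e) e[[2L]], ""),
                   event_date = as.Date(vapply(events, function(e) as.character(e[[3L]]), "")),
                   event_value = vapply(events, function(e) e[[4L]], ""),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$animal_id, ev$event_date), , drop = FALSE]
  rownames(ev) <- NULL
  keep <- ped$animal %in% unique(ev$animal_id)
  animals <- data.frame(animal_id = ped$animal[keep], herd = ped$herd[keep],
                        birth_date = ped$birth_date[keep], sire = ped$sire[keep],
                        dam = ped$dam[keep], stringsAsFactors = FALSE)
  herd <- structure(list(animals = animals, events = ev,
                         edit_log = data.frame(row = integer(0),
                                               animal_id = character(0),
                                               reason = character(0))),
                    class = "herd_records")
  list(herd = herd, truth = do.call(rbind, truth))
}
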