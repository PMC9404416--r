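#' Specify a multi-trait animal model
#'
#' Fixes the model structure used throughout: every trait gets its
#' herd-year-season contemporary group as a fixed effect; cow traits
#' additionally get parity (as a class) and age at calving (as a covariate);
#' SPCh gets age at first insemination as a covariate.  The additive genetic
#' effect is always fitted; a permanent-environment effect is fitted for cow
#' traits when the data carry repeated records.  Success traits are analysed
#' as threshold (liability) traits, all others as linear.
#'
#' @param traits trait names, an ordered subset of [trait_specs()].
#' @return A `model_spec` list with elements `traits`, `spec` (the trait
#'   table), `response` (`"linear"`/`"threshold"`), and logical vectors
#'   `use_parity`, `use_age`, `use_pe`.
#' @export
model_spec <- function(traits) {
  spec <- trait_specs(traits)
  structure(list(
    traits = spec$name,
    spec = spec,
    response = ifelse(spec$category == "success", "threshold", "linear"),
    use_parity = spec$animal_class == "cow",
    use_age = spec$animal_class == "cow" | spec$name == "SPCh",
    use_pe = spec$animal_class == "cow"),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", paste(x$traits, collapse = ", "), "\n")
  cat("  threshold:", paste(x$traits[x$response == "threshold"], collapse = ", "), "\n")
  invisible(x)
}

# full-rank design matrix for one trait on its block rows, embedded to N rows
trait_design <- function(d, use_parity, use_age, trait, N, rows) {
  f <- ~1
  if (length(unique(d$cg)) > 1L) f <- stats::update(f, ~. + cg)
  if (use_parity && length(unique(d$parity)) > 1L) f <- stats::update(f, ~. + parity)
  if (use_age && !all(is.na(d$age))) {  # all-NA: covariate not in these data
    if (anyNA(d$age)) stop("missing age covariate for trait ", trait)
    if (stats::sd(d$age) > 0) f <- stats::update(f, ~. + age)
  }
  X <- stats::model.matrix(f, d)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) X <- X[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
  Xfull <- Matrix::sparseMatrix(i = rep(rows, ncol(X)),
                                j = rep(seq_len(ncol(X)), each = length(rows)),
                                x = as.numeric(X), dims = c(N, ncol(X)))
  methods::as(Matrix::drop0(Xfull), "CsparseMatrix")
}

#' Build mixed-model equation components
#'
#' Assembles, per trait, the fixed-effect design (reference level absorbed),
#' the record-to-animal and record-to-permanent-environment maps, and the
#' response matrix with its missingness mask, for the Gibbs sampler and the
#' REML fitter.  Records are sorted canonically by (animal, parity) so
#' results do not depend on input row order.  Heifer traits attach to
#' heifer rows (parity 1) and cow traits to cow rows; records missing a
#' trait of their own class are kept and masked, records carrying no trait
#' of the model are dropped.
#'
#' @param spec a [model_spec()].
#' @param phenotypes a `phenotype_table` with `cg_code` filled.
#' @param ainv a `relationship_matrix` of kind `"Ainv"` from [a_inverse()]
#'   covering every phenotyped animal.
#' @return An `mme` object.
#' @export
build_mme <- function(spec, phenotypes, ainv) {
  stopifnot(inherits(spec, "model_spec"),
            inherits(ainv, "relationship_matrix"), ainv$kind == "Ainv")
  miss_tr <- setdiff(spec$traits, names(phenotypes))
  if (length(miss_tr))
    stop("trait(s) absent from phenotype table: ", paste(miss_tr, collapse = ", "))
  ph <- as.data.frame(phenotypes)
  ph <- ph[order(ph$animal_id, ph$parity), , drop = FALSE]

  classes <- unique(spec$spec$animal_class)  # blocks, in trait order
  unit_class <- ifelse(ph$parity == 1L, "heifer", "cow")
  ph <- ph[unit_class %in% classes, , drop = FALSE]
  unit_class <- ifelse(ph$parity == 1L, "heifer", "cow")
  # drop units with no observed model trait
  has_obs <- rep(FALSE, nrow(ph))
  for (j in seq_along(spec$traits)) {
    cls <- spec$spec$animal_class[j]
    has_obs <- has_obs | (unit_class == cls & !is.na(ph[[spec$traits[j]]]))
  }
  ph <- ph[has_obs, , drop = FALSE]
  unit_class <- unit_class[has_obs]
  N <- nrow(ph)
  if (N == 0L) stop("no records carry any trait of this model")
  if (anyNA(ph$cg_code)) stop("records with missing contemporary group; run build_contemporary_groups() first")
  missing_animals <- setdiff(unique(ph$animal_id), ainv$ids)
  if (length(missing_animals))
    stop("animal(s) missing from the relationship matrix: ",
         paste(utils::head(missing_animals, 10L), collapse = ", "),
         if (length(missing_animals) > 10L) " ..." else "")

  trait_block <- match(spec$spec$animal_class, classes) - 1L
  unit_block <- match(unit_class, classes) - 1L

  Y <- matrix(NA_real_, N, length(spec$traits),
              dimnames = list(NULL, spec$traits))
  for (j in seq_along(spec$traits)) {
    sel <- unit_block == trait_block[j]
    Y[sel, j] <- ph[[spec$traits[j]]][sel]
  }

  Xs <- vector("list", length(spec$traits))
  for (j in seq_along(spec$traits)) {
    rows <- which(unit_block == trait_block[j])
    d <- data.frame(cg = factor(ph$cg_code[rows]),
                    parity = factor(ph$parity[rows]),
                    age = ph$age_months[rows])
    Xs[[j]] <- trait_design(d, spec$use_parity[j], spec$use_age[j],
                            spec$traits[j], N, rows)
  }

  animal0 <- match(ph$animal_id, ainv$ids) - 1L
  cow_units <- unit_class == "cow"
  repeated <- any(duplicated(ph$animal_id[cow_units]))
  pe_trait <- spec$use_pe & repeated
  if (any(pe_trait)) {
    pe_ids <- unique(ph$animal_id[cow_units])
    pe_level0 <- ifelse(cow_units, match(ph$animal_id, pe_ids) - 1L, -1L)
    npe <- length(pe_ids)
  } else {
    pe_level0 <- rep(-1L, N)
    npe <- 0L
  }

  structure(list(Y = Y, Xs = Xs, animal = animal0, ainv = ainv,
                 pe_level = as.integer(pe_level0), npe = as.integer(npe),
                 trait_block = as.integer(trait_block),
                 unit_block = as.integer(unit_block),
                 threshold = spec$response == "threshold",
                 pe_trait = pe_trait, spec = spec,
                 units = ph[, c("animal_id", "parity")],
                 n_records = N),
            class = "mme")
}

#' @export
print.mme <- function(x, ...) {
  cat(sprintf("mme: %d records, %d traits (%d threshold), %d animals in A-inverse, %d pe levels\n",
              x$n_records, ncol(x$Y), sum(x$threshold), length(x$ainv$ids), x$npe))
  invisible(x)
}
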