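#' Construct a pedigree table
#'
#' Builds a validated pedigree from animal-sire-dam triples.  Parents that
#' are referenced but have no row of their own are added as founders with
#' unknown birth date (the implied-founder rule used throughout animal
#' breeding).  Unknown parents are represented by `NA`; on disk the
#' conventional sentinel is `"0"` (see [read_pedigree()]).
#'
#' @param animal character vector of animal identifiers, one per animal.
#' @param sire,dam character vectors of parent identifiers; `NA` or `"0"`
#'   for unknown.
#' @param birth_date optional [Date] vector (`NA` = unknown).
#' @return A `pedigree` object: a data frame with columns `animal`, `sire`,
#'   `dam`, `birth_date`, in the order given (founders appended), plus a
#'   `sorted` attribute.
#' @seealso [sort_pedigree()], [inbreeding()], [relationship_matrix()],
#'   [a_inverse()]
#' @examples
#' # a full-sib mating: the offspring of C x D is inbred with F = 0.25
#' ped <- pedigree(c("A", "B", "C", "D", "E"),
#'                 sire = c(NA, NA, "A", "A", "C"),
#'                 dam  = c(NA, NA, "B", "B", "D"))
#' inbreeding(ped)
#' relationship_matrix(ped)$matrix
#' @export
pedigree <- function(animal, sire, dam, birth_date = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[sire %in% c("0", "", "NA")] <- NA_character_
  dam[dam %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(animal)) {
    dup <- unique(animal[duplicated(animal)])
    stop("duplicate animal id(s) in pedigree: ", paste(dup, collapse = ", "))
  }
  if (is.null(birth_date)) birth_date <- as.Date(rep(NA, length(animal)))
  birth_date <- as.Date(birth_date)
  implied <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(implied)) {
    animal <- c(animal, implied)
    sire <- c(sire, rep(NA_character_, length(implied)))
    dam <- c(dam, rep(NA_character_, length(implied)))
    birth_date <- c(birth_date, as.Date(rep(NA, length(implied))))
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    birth_date = birth_date, stringsAsFactors = FALSE)
  structure(ped, class = c("pedigree", "data.frame"), sorted = FALSE)
}

#' Topologically sort and validate a pedigree
#'
#' Reorders a pedigree so that every parent precedes its offspring, which
#' the relationship-matrix recursions require.  Self-ancestry (cycles) is an
#' error naming the animals involved; a parent whose known birth date is not
#' before its offspring's is reported as a warning but retained.
#'
#' @param ped a [pedigree()] object.
#' @return The pedigree in topological order with `sorted = TRUE`.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  # Kahn's algorithm on the parent -> offspring DAG
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    members <- ped$animal[setdiff(seq_len(n), ord)]
    stop("pedigree contains a cycle involving: ", paste(members, collapse = ", "))
  }
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  bi <- stats::setNames(out$birth_date, out$animal)
  for (col in c("sire", "dam")) {
    p <- out[[col]]
    bad <- !is.na(p) & !is.na(bi[p]) & !is.na(out$birth_date) &
      bi[p] >= out$birth_date
    if (any(bad))
      warning("parent birth date not before offspring for: ",
              paste(out$animal[bad], collapse = ", "))
  }
  attr(out, "sorted") <- TRUE
  class(out) <- c("pedigree", "data.frame")
  out
}

as_sorted_pedigree <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) ped <- sort_pedigree(ped) else ped
  ped
}

# 0-based parent indices for the C++ recursions, -1 = unknown
parent_indices <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  list(sire = as.integer(si - 1L), dam = as.integer(di - 1L))
}

#' Prune a pedigree to phenotyped animals and their ancestors
#'
#' Keeps the phenotyped animals and their full ancestor closure.  Animals
#' with unknown birth dates are dropped unless they are required ancestors,
#' in which case they are retained as founders.  Phenotyped ids absent from
#' the pedigree are reported in a warning.
#'
#' @param ped a [pedigree()] object.
#' @param phenotyped character vector of ids with phenotypes.
#' @return The pruned, sorted pedigree.
#' @export
prune_pedigree <- function(ped, phenotyped) {
  ped <- as_sorted_pedigree(ped)
  phenotyped <- unique(as.character(phenotyped))
  missing_ids <- setdiff(phenotyped, ped$animal)
  if (length(missing_ids))
    warning("phenotyped id(s) absent from pedigree: ",
            paste(missing_ids, collapse = ", "))
  keep <- ped$animal %in% phenotyped
  # ancestors: sweep from youngest to oldest, marking parents of kept animals
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  # drop undated animals unless required: after the closure every retained
  # non-phenotyped animal is a required ancestor, so only undated phenotyped
  # leaves (never ancestors) could be dropped without breaking the closure.
  drop <- is.na(out$birth_date) & out$animal %in% phenotyped &
    !(out$animal %in% c(out$sire, out$dam))
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F by the Meuwissen-Luo ancestor
#' tracing recursion (partial tabular evaluation of A = TDT').  Founders and
#' animals with an unknown parent have F = 0.
#'
#' @param ped a [pedigree()] object.
#' @return Named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- as_sorted_pedigree(ped)
  p <- parent_indices(ped)
  stats::setNames(ml_inbreeding_cpp(p$sire, p$dam), ped$animal)
}

#' Dense numerator relationship matrix A
#'
#' Computes A by the tabular method: `a(i,i) = 1 + 0.5 a(s,d)` and
#' `a(i,j) = 0.5 (a(j,s) + a(j,d))`, unknown parents contributing 0.  Dense
#' storage is quadratic in the number of animals, so the size is capped; for
#' larger pedigrees use the sparse inverse from [a_inverse()] directly.
#'
#' @param ped a [pedigree()] object.
#' @param dense_limit maximum pedigree size for dense A.
#' @return A `relationship_matrix` object (`kind = "A"`).
#' @export
relationship_matrix <- function(ped, dense_limit = 5000L) {
  ped <- as_sorted_pedigree(ped)
  if (nrow(ped) > dense_limit)
    stop("pedigree has ", nrow(ped), " animals; dense A is capped at ",
         dense_limit, ". Use a_inverse() for the sparse inverse instead.")
  p <- parent_indices(ped)
  A <- tabular_a_cpp(p$sire, p$dam)
  dimnames(A) <- list(ped$animal, ped$animal)
  structure(list(ids = ped$animal, matrix = A,
                 F = stats::setNames(diag(A) - 1, ped$animal), kind = "A"),
            class = "relationship_matrix")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly by Henderson's rules accounting for
#' inbreeding.  For animal i with Mendelian-sampling variance
#' `d_i = 1 - 0.25 k - 0.25 (F_s + F_d)` (k = number of known parents, F
#' over known parents only), the contributions are `1/d_i` to (i,i),
#' `-0.5/d_i` to (i, parent) and `0.25/d_i` to each (parent, parent) pair.
#'
#' @param ped a [pedigree()] object.
#' @param inbred if `FALSE`, assume F = 0 throughout (the classical
#'   non-inbred rules); used for oracle comparisons.
#' @return A `relationship_matrix` object (`kind = "Ainv"`) whose `matrix`
#'   is a sparse symmetric [Matrix::sparseMatrix()].
#' @export
a_inverse <- function(ped, inbred = TRUE) {
  ped <- as_sorted_pedigree(ped)
  n <- nrow(ped)
  Fv <- if (inbred) unname(inbreeding(ped)) else numeric(n)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  ks <- !is.na(si); kd <- !is.na(di)
  Fs <- ifelse(ks, Fv[ifelse(ks, si, 1L)], 0)
  Fd <- ifelse(kd, Fv[ifelse(kd, di, 1L)], 0)
  d <- 1 - 0.25 * (ks + kd) - 0.25 * (Fs + Fd)
  alpha <- 1 / d
  i <- seq_len(n)
  ii <- c(i, i[ks], si[ks], i[kd], di[kd],
          si[ks], di[kd],
          si[ks & kd], di[ks & kd])
  jj <- c(i, si[ks], i[ks], di[kd], i[kd],
          si[ks], di[kd],
          di[ks & kd], si[ks & kd])
  xx <- c(alpha,
          rep(-0.5 * alpha[ks], 2L), rep(-0.5 * alpha[kd], 2L),
          0.25 * alpha[ks], 0.25 * alpha[kd],
          rep(0.25 * alpha[ks & kd], 2L))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  structure(list(ids = ped$animal, matrix = Ainv,
                 F = stats::setNames(Fv, ped$animal), kind = "Ainv"),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s) for %d animals; mean F = %.4f\n",
              if (x$kind == "A") "dense A" else "sparse A-inverse",
              length(x$ids), mean(x$F)))
  invisible(x)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals (%d founders), %s\n", nrow(x),
              sum(is.na(x$sire) & is.na(x$dam)),
              if (isTRUE(attr(x, "sorted"))) "sorted" else "unsorted"))
  NextMethod()
}
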