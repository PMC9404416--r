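#' The nine fertility trait definitions
#'
#' Heifer traits (first parity): AFS, age at first service (months); AFC,
#' age at first calving (months); SPCh, services per conception.  Cow traits
#' (second parity and above, one record per lactation): CFS, calving to
#' first service (days); DO, days open, calving to conception (days); SPC,
#' services per conception; and the binary success traits FS80d (first
#' service within 80 days post partum), PD100d and PD200d (confirmed
#' pregnant within 100 / 200 days post partum), coded 1 = no, 2 = yes.
#' Interval and count traits carry the edit bounds outside which values are
#' treated as recording anomalies and removed.
#'
#' @param traits optional subset of trait names, in the order wanted.
#' @return Data frame with columns `name`, `category`
#'   (`interval`/`count`/`success`), `animal_class` (`heifer`/`cow`),
#'   `lower`, `upper`, `cg_basis` (`birth`/`calving`).
#' @export
trait_specs <- function(traits = NULL) {
  specs <- data.frame(
    name = c("AFS", "AFC", "SPCh", "FS80d", "PD100d", "PD200d",
             "SPC", "CFS", "DO"),
    category = c("interval", "interval", "count", "success", "success",
                 "success", "count", "interval", "interval"),
    animal_class = c("heifer", "heifer", "heifer", "cow", "cow", "cow",
                     "cow", "cow", "cow"),
    lower = c(10, 20, 1, 1, 1, 1, 1, 21, 21),
    upper = c(30, 48, 8, 2, 2, 2, 8, 250, 435),
    cg_basis = c("birth", "birth", "birth", "calving", "calving", "calving",
                 "calving", "calving", "calving"),
    stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    bad <- setdiff(traits, specs$name)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    specs <- specs[match(traits, specs$name), , drop = FALSE]
    rownames(specs) <- NULL
  }
  specs
}

#' The standard trait ordering and analysis sets
#'
#' `analysis_sets()` returns the two standard multi-trait analyses: the cow
#' set (the six cow traits) and the joint set (all nine traits, giving the
#' heifer heritabilities and heifer-by-cow correlations).
#'
#' @return Named list of trait-name vectors.
#' @export
analysis_sets <- function() {
  list(cow = c("FS80d", "PD100d", "PD200d", "SPC", "CFS", "DO"),
       joint = trait_specs()$name)
}

#' Season of a date
#'
#' Southern-hemisphere dairy convention: summer runs October through March,
#' winter April through September.
#'
#' @param dates a [Date] vector.
#' @return Character vector, `"summer"` or `"winter"`.
#' @examples
#' assign_season(as.Date(c("2005-10-01", "2005-04-30", "2005-03-31")))
#' @export
assign_season <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(m >= 4L & m <= 9L, "winter", "summer")
}

DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

days_to_months <- function(days) round(days / DAYS_PER_MONTH, 1L)

# Conception attribution for one service episode: the conceiving service is
# the last service of the episode, confirmed either by a later "pregnant"
# diagnosis (before the next calving, if any) or by a next calving
# 260-302 days after it (the biological gestation window).
conception_date <- function(service_dates, next_calving, diagnoses,
                            gestation_window = c(260, 302)) {
  if (length(service_dates) == 0L) return(as.Date(NA))
  last <- service_dates[length(service_dates)]
  if (!is.na(next_calving)) {
    gap <- as.integer(next_calving - last)
    if (gap >= gestation_window[1L] && gap <= gestation_window[2L]) return(last)
    preg <- diagnoses$event_date[diagnoses$event_value == "pregnant" &
                                   diagnoses$event_date > last &
                                   diagnoses$event_date < next_calving]
    if (length(preg)) return(last)
    return(as.Date(NA))
  }
  preg <- diagnoses$event_date[diagnoses$event_value == "pregnant" &
                                 diagnoses$event_date > last]
  if (length(preg)) return(last) else return(as.Date(NA))
}

derive_one_animal <- function(animal_id, herd, birth, services, calvings,
                              diagnoses, gestation_window) {
  rows <- list()
  log <- list()
  sdates <- services$event_date
  cdates <- calvings$event_date
  if (length(sdates) == 0L && length(cdates) == 0L) {
    log[[1L]] <- data.frame(animal_id = animal_id, parity = 1L, trait = "all",
                            raw_value = NA_real_, rule_violated = "no services",
                            stringsAsFactors = FALSE)
    return(list(rows = NULL, log = do.call(rbind, log)))
  }

  first_calving <- if (length(cdates)) cdates[1L] else as.Date(NA)

  # heifer row: services before the first calving
  hserv <- if (is.na(first_calving)) sdates else sdates[sdates < first_calving]
  afs <- if (length(hserv)) days_to_months(as.integer(hserv[1L] - birth)) else NA_real_
  afc <- if (!is.na(first_calving)) days_to_months(as.integer(first_calving - birth)) else NA_real_
  conc <- conception_date(hserv, first_calving, diagnoses, gestation_window)
  spch <- if (!is.na(conc)) length(hserv) else NA_real_
  if (any(!is.na(c(afs, afc, spch)))) {
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = animal_id, herd = herd, parity = 1L,
      record_date = birth, age_months = afs,
      AFS = afs, AFC = afc, SPCh = spch, FS80d = NA_real_, PD100d = NA_real_,
      PD200d = NA_real_, SPC = NA_real_, CFS = NA_real_, DO = NA_real_,
      stringsAsFactors = FALSE)
  } else if (length(hserv) == 0L && is.na(first_calving)) {
    log[[length(log) + 1L]] <- data.frame(
      animal_id = animal_id, parity = 1L, trait = "all", raw_value = NA_real_,
      rule_violated = "no services", stringsAsFactors = FALSE)
  }

  # cow rows: one per lactation, the episode starting at calving l
  for (l in seq_along(cdates)) {
    calv <- cdates[l]
    nxt <- if (l < length(cdates)) cdates[l + 1L] else as.Date(NA)
    eserv <- sdates[sdates > calv & (is.na(nxt) | sdates < nxt)]
    if (length(eserv) == 0L) next
    cfs <- as.integer(eserv[1L] - calv)
    conc <- conception_date(eserv, nxt, diagnoses, gestation_window)
    do <- if (!is.na(conc)) as.integer(conc - calv) else NA_real_
    spc <- if (!is.na(conc)) length(eserv) else NA_real_
    fs80 <- if (!is.na(cfs)) ifelse(cfs <= 80, 2, 1) else NA_real_
    pd100 <- if (!is.na(do)) ifelse(do <= 100, 2, 1) else NA_real_
    pd200 <- if (!is.na(do)) ifelse(do <= 200, 2, 1) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = animal_id, herd = herd, parity = l + 1L,
      record_date = calv, age_months = days_to_months(as.integer(calv - birth)),
      AFS = NA_real_, AFC = NA_real_, SPCh = NA_real_, FS80d = fs80,
      PD100d = pd100, PD200d = pd200, SPC = spc, CFS = as.numeric(cfs),
      DO = as.numeric(do), stringsAsFactors = FALSE)
  }
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Derive the nine fertility traits from herd records
#'
#' Walks each animal's event history, splits it into service episodes (the
#' pre-first-calving heifer episode and one episode per lactation), derives
#' the Table-style traits, and returns one heifer row per animal plus one
#' cow row per lactation.  Conception is attributed to the last service of
#' an episode when confirmed by a subsequent pregnancy diagnosis or by a
#' next calving within the gestation window.  No editing is applied here;
#' see [apply_edits()] and [build_contemporary_groups()], or the
#' [derive_phenotypes()] wrapper.
#'
#' @param herd a `herd_records` object from [read_service_records()] or
#'   [simulate_service_records()].
#' @param gestation_window integer days, the plausible conception-to-calving
#'   interval used to validate conception.
#' @return A `phenotype_table`: data frame with columns `animal_id`, `herd`,
#'   `parity` (1 = heifer row), `record_date` (birth for heifer rows,
#'   calving for cow rows), `age_months` (age at first insemination for
#'   heifer rows, age at calving for cow rows), the nine trait columns, and
#'   an `edit_log` attribute for animals contributing no row.
#' @export
derive_traits <- function(herd, gestation_window = c(260, 302)) {
  stopifnot(inherits(herd, "herd_records"))
  an <- herd$animals
  ev <- herd$events
  ev_by <- split(ev, ev$animal_id)
  rows <- vector("list", nrow(an))
  logs <- vector("list", nrow(an))
  for (k in seq_len(nrow(an))) {
    id <- an$animal_id[k]
    e <- ev_by[[id]]
    if (is.null(e)) e <- ev[0L, ]
    res <- derive_one_animal(
      id, an$herd[k], an$birth_date[k],
      e[e$event_type == "SERVICE", , drop = FALSE],
      e[e$event_type == "CALVING", , drop = FALSE],
      e[e$event_type == "DIAGNOSIS", , drop = FALSE],
      gestation_window)
    rows[[k]] <- res$rows
    logs[[k]] <- res$log
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no derivable phenotype rows in these records")
  out <- out[order(out$animal_id, out$parity), , drop = FALSE]
  out$cg_code <- NA_character_
  rownames(out) <- NULL
  log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  structure(out, class = c("phenotype_table", "data.frame"),
            edit_log = if (is.null(log)) empty_edit_log() else log)
}

empty_edit_log <- function() {
  data.frame(animal_id = character(0), parity = integer(0), trait = character(0),
             raw_value = numeric(0), rule_violated = character(0),
             stringsAsFactors = FALSE)
}

#' Apply the trait editing rules
#'
#' Removes biologically unreasonable values: each trait value outside its
#' [trait_specs()] bounds is set to missing and logged (e.g. CFS outside
#' 21-250 days, DO outside 21-435 days).  Rows of animals with an unknown
#' sire or dam are removed entirely, as are rows left with no trait values.
#' Every removed value appears exactly once in the edit log.
#'
#' @param table a `phenotype_table`.
#' @param parents optional data frame with columns `animal_id`, `sire`,
#'   `dam` (e.g. the `animals` element of a `herd_records`); when supplied,
#'   unknown-parent animals are excluded.
#' @param specs trait specifications, a subset of [trait_specs()].
#' @return The edited `phenotype_table`; its `edit_log` attribute gains one
#'   row per removed value.
#' @export
apply_edits <- function(table, parents = NULL, specs = trait_specs()) {
  log <- attr(table, "edit_log")
  if (is.null(log)) log <- empty_edit_log()
  if (!is.null(parents)) {
    unknown <- parents$animal_id[is.na(parents$sire) | is.na(parents$dam)]
    drop <- table$animal_id %in% unknown
    if (any(drop)) {
      log <- rbind(log, data.frame(animal_id = table$animal_id[drop],
                                   parity = table$parity[drop], trait = "all",
                                   raw_value = NA_real_,
                                   rule_violated = "unknown parent",
                                   stringsAsFactors = FALSE))
      table <- table[!drop, , drop = FALSE]
    }
  }
  removed <- list()
  for (k in seq_len(nrow(specs))) {
    tr <- specs$name[k]
    if (!tr %in% names(table)) next
    v <- table[[tr]]
    bad <- !is.na(v) & (v < specs$lower[k] | v > specs$upper[k])
    if (specs$category[k] == "success") bad <- !is.na(v) & !(v %in% c(1, 2))
    if (any(bad)) {
      log <- rbind(log, data.frame(animal_id = table$animal_id[bad],
                                   parity = table$parity[bad], trait = tr,
                                   raw_value = v[bad],
                                   rule_violated = sprintf("outside [%g, %g]",
                                                           specs$lower[k], specs$upper[k]),
                                   stringsAsFactors = FALSE))
      table[[tr]][bad] <- NA_real_
    }
    removed[[tr]] <- bad
  }
  # success traits are functions of the interval they summarise: an interval
  # removed as a recording anomaly invalidates its derived binary trait too
  cascade <- list(CFS = "FS80d", DO = c("PD100d", "PD200d"))
  for (src in names(cascade)) {
    bad <- removed[[src]]
    if (is.null(bad) || !any(bad)) next
    for (tr in intersect(cascade[[src]], names(table))) {
      hit <- bad & !is.na(table[[tr]])
      if (!any(hit)) next
      log <- rbind(log, data.frame(animal_id = table$animal_id[hit],
                                   parity = table$parity[hit], trait = tr,
                                   raw_value = table[[tr]][hit],
                                   rule_violated = paste("derived from excluded", src),
                                   stringsAsFactors = FALSE))
      table[[tr]][hit] <- NA_real_
    }
  }
  present <- intersect(specs$name, names(table))
  empty <- rowSums(!is.na(table[, present, drop = FALSE])) == 0L
  if (any(empty)) {
    log <- rbind(log, data.frame(animal_id = table$animal_id[empty],
                                 parity = table$parity[empty], trait = "all",
                                 raw_value = NA_real_,
                                 rule_violated = "no surviving trait values",
                                 stringsAsFactors = FALSE))
    table <- table[!empty, , drop = FALSE]
  }
  rownames(table) <- NULL
  structure(table, class = c("phenotype_table", "data.frame"), edit_log = log)
}

#' Assign herd-year-season contemporary groups
#'
#' Contemporary group is the herd-year-season of birth for heifer rows and
#' of calving for cow rows, coded `"<herd>-<year>-<season>"` from each row's
#' `record_date`.  Groups smaller than `min_size` (counted within the
#' heifer/cow row class) carry too little information to separate management
#' from genetics; their rows are dropped and logged.
#'
#' @param table a `phenotype_table`.
#' @param min_size minimum rows per contemporary group.
#' @return The table with `cg_code` filled.
#' @export
build_contemporary_groups <- function(table, min_size = 3L) {
  log <- attr(table, "edit_log")
  if (is.null(log)) log <- empty_edit_log()
  d <- as.Date(table$record_date)
  cg <- paste(table$herd, format(d, "%Y"), assign_season(d), sep = "-")
  cls <- ifelse(table$parity == 1L, "heifer", "cow")
  size <- stats::ave(seq_along(cg), paste(cls, cg), FUN = length)
  small <- size < min_size
  table$cg_code <- cg
  if (any(small)) {
    log <- rbind(log, data.frame(animal_id = table$animal_id[small],
                                 parity = table$parity[small], trait = "all",
                                 raw_value = NA_real_,
                                 rule_violated = "contemporary group below minimum size",
                                 stringsAsFactors = FALSE))
    table <- table[!small, , drop = FALSE]
  }
  rownames(table) <- NULL
  structure(table, class = c("phenotype_table", "data.frame"), edit_log = log)
}

#' Full derivation pipeline
#'
#' [derive_traits()], then [apply_edits()] against the herd's parent
#' information, then [build_contemporary_groups()].
#'
#' @inheritParams derive_traits
#' @inheritParams build_contemporary_groups
#' @param specs trait specifications to edit against.
#' @return An edited `phenotype_table` with contemporary groups assigned.
#' @export
derive_phenotypes <- function(herd, specs = trait_specs(), min_size = 3L,
                              gestation_window = c(260, 302)) {
  tab <- derive_traits(herd, gestation_window)
  tab <- apply_edits(tab, parents = herd$animals, specs = specs)
  build_contemporary_groups(tab, min_size = min_size)
}

#' Write a phenotype table and its edit log
#'
#' @param table a `phenotype_table`.
#' @param path output CSV path; the edit log goes to
#'   `<path minus extension>_edits.csv`.
#' @param dialect a [table_dialect()].
#' @export
write_phenotypes <- function(table, path, dialect = table_dialect()) {
  out <- as.data.frame(table)
  out$record_date <- format(as.Date(out$record_date), dialect$date_format)
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, na = dialect$missing_token)
  log <- attr(table, "edit_log")
  if (!is.null(log)) {
    edit_path <- paste0(sub("\\.[^.]*$", "", path), "_edits.csv")
    utils::write.table(log, edit_path, sep = dialect$delimiter,
                       row.names = FALSE, quote = FALSE, na = dialect$missing_token)
  }
  invisible(path)
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d rows (%d heifer, %d cow), %d edit-log entries\n",
              nrow(x), sum(x$parity == 1L), sum(x$parity > 1L),
              nrow(attr(x, "edit_log") %||% empty_edit_log())))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
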