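#' Delimited-table dialect
#'
#' Describes how the plain-text herd and pedigree tables are written: field
#' delimiter, date format and the tokens used for missing values and
#' unknown parents (the animal-breeding convention is the literal `"0"`).
#'
#' @param delimiter single field-separator character.
#' @param date_format [strptime] format string; all dates in a file must
#'   round-trip through it.
#' @param missing_token string standing for a missing value.
#' @param unknown_parent string standing for an unknown sire or dam.
#' @return A `table_dialect` object.
#' @export
table_dialect <- function(delimiter = ",", date_format = "%Y-%m-%d",
                          missing_token = "NA", unknown_parent = "0") {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  structure(list(delimiter = delimiter, date_format = date_format,
                 missing_token = missing_token,
                 unknown_parent = unknown_parent),
            class = "table_dialect")
}

parse_dates <- function(x, dialect) as.Date(as.character(x), format = dialect$date_format)

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
}

service_columns <- c("animal_id", "herd", "birth_date", "sire", "dam",
                     "event_type", "event_date", "event_value")

#' Read on-farm AI service records
#'
#' Reads a delimited event table with one row per AI service, calving or
#' pregnancy diagnosis.  Rows that cannot be interpreted (unparseable dates,
#' unknown event types, invalid outcomes or lactation numbers, events dated
#' before birth, out-of-order events, metadata conflicting with the
#' animal's first row) are rejected, never silently dropped: each appears
#' once in the returned edit log with a machine-readable reason code.
#'
#' @param path path to the service-record file.  Columns: `animal_id`,
#'   `herd`, `birth_date`, `sire`, `dam`, `event_type`
#'   (`SERVICE`/`CALVING`/`DIAGNOSIS`), `event_date`, `event_value` (service
#'   outcome `success`/`failure`/`unknown`, lactation number, or diagnosis
#'   result `pregnant`/`open`).
#' @param dialect a [table_dialect()].
#' @return A `herd_records` object: list with `animals` (one row per
#'   animal: id, herd, birth date, sire, dam), `events` (parsed events) and
#'   `edit_log` (rejected input rows with reasons).
#' @examples
#' path <- system.file("extdata", "example_services.csv", package = "fertgibbs")
#' herd <- read_service_records(path)
#' herd
#' derive_traits(herd)
#' @export
read_service_records <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", na.strings = dialect$missing_token,
                           stringsAsFactors = FALSE)
  require_columns(raw, service_columns, path)
  raw$.row <- seq_len(nrow(raw))
  reject <- data.frame(row = integer(0), animal_id = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  note <- function(rows, ids, reason) {
    if (length(rows))
      reject <<- rbind(reject, data.frame(row = rows, animal_id = ids,
                                          reason = reason, stringsAsFactors = FALSE))
  }

  bdate <- parse_dates(raw$birth_date, dialect)
  edate <- parse_dates(raw$event_date, dialect)
  bad <- is.na(bdate) | is.na(edate)
  note(raw$.row[bad], raw$animal_id[bad], "unparseable date")
  keep <- !bad

  etype <- toupper(raw$event_type)
  bad <- keep & !(etype %in% c("SERVICE", "CALVING", "DIAGNOSIS"))
  note(raw$.row[bad], raw$animal_id[bad], "unknown event type")
  keep <- keep & !bad

  eval_lc <- tolower(raw$event_value)
  bad <- keep & etype == "SERVICE" &
    !(eval_lc %in% c("success", "failure", "unknown") | is.na(raw$event_value))
  note(raw$.row[bad], raw$animal_id[bad], "invalid service outcome")
  keep <- keep & !bad
  lact <- suppressWarnings(as.integer(raw$event_value))
  bad <- keep & etype == "CALVING" & (is.na(lact) | lact < 1L)
  note(raw$.row[bad], raw$animal_id[bad], "invalid lactation number")
  keep <- keep & !bad
  bad <- keep & etype == "DIAGNOSIS" & !(eval_lc %in% c("pregnant", "open"))
  note(raw$.row[bad], raw$animal_id[bad], "invalid diagnosis result")
  keep <- keep & !bad

  bad <- keep & edate <= bdate
  note(raw$.row[bad], raw$animal_id[bad], "event before birth")
  keep <- keep & !bad

  # header record: the animal's first surviving row wins; conflicts rejected
  df <- raw[keep, , drop = FALSE]
  df$birth_date <- bdate[keep]
  df$event_date <- edate[keep]
  df$event_type <- etype[keep]
  first <- !duplicated(df$animal_id)
  hdr <- df[first, c("animal_id", "herd", "birth_date", "sire", "dam")]
  key <- paste(df$herd, format(df$birth_date), df$sire, df$dam)
  hkey <- stats::setNames(key[first], hdr$animal_id)
  bad <- key != unname(hkey[df$animal_id])
  note(df$.row[bad], df$animal_id[bad], "inconsistent header")
  df <- df[!bad, , drop = FALSE]

  # per-animal, per-type strict date ordering; CALVING lactation increasing
  df <- df[order(df$animal_id, df$event_date, df$.row), , drop = FALSE]
  bad <- logical(nrow(df))
  for (tp in c("SERVICE", "CALVING", "DIAGNOSIS")) {
    sel <- which(df$event_type == tp)
    if (length(sel) > 1L) {
      same <- df$animal_id[sel[-1L]] == df$animal_id[sel[-length(sel)]]
      dup <- c(FALSE, same & diff(as.integer(df$event_date[sel])) <= 0L)
      bad[sel[dup]] <- TRUE
    }
  }
  note(df$.row[bad], df$animal_id[bad], "duplicate or out-of-order event date")
  df <- df[!bad, , drop = FALSE]
  sel <- which(df$event_type == "CALVING")
  if (length(sel) > 1L) {
    lact <- as.integer(df$event_value[sel])
    same <- df$animal_id[sel[-1L]] == df$animal_id[sel[-length(sel)]]
    bad <- c(FALSE, same & diff(lact) <= 0L)
    if (any(bad)) {
      note(df$.row[sel[bad]], df$animal_id[sel[bad]], "non-increasing lactation number")
      df <- df[-sel[bad], , drop = FALSE]
    }
  }

  sire <- hdr$sire; dam <- hdr$dam
  sire[is.na(sire) | sire == dialect$unknown_parent] <- NA_character_
  dam[is.na(dam) | dam == dialect$unknown_parent] <- NA_character_
  animals <- data.frame(animal_id = hdr$animal_id, herd = hdr$herd,
                        birth_date = hdr$birth_date, sire = sire, dam = dam,
                        stringsAsFactors = FALSE)
  ev <- df[, c("animal_id", "event_type", "event_date", "event_value")]
  ev$event_value <- ifelse(ev$event_type == "SERVICE" & is.na(ev$event_value),
                           "unknown", tolower(ev$event_value))
  ev$event_value[ev$event_type == "CALVING"] <-
    df$event_value[df$event_type == "CALVING"]
  rownames(animals) <- rownames(ev) <- NULL
  reject <- reject[order(reject$row), , drop = FALSE]
  rownames(reject) <- NULL
  structure(list(animals = animals, events = ev, edit_log = reject),
            class = "herd_records")
}

#' Write service records
#'
#' Inverse of [read_service_records()]: emits the same one-row-per-event
#' schema, so write-then-read is the identity on valid records.
#'
#' @param herd a `herd_records` object.
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @export
write_service_records <- function(herd, path, dialect = table_dialect()) {
  an <- herd$animals
  ev <- herd$events
  m <- match(ev$animal_id, an$animal_id)
  out <- data.frame(animal_id = ev$animal_id, herd = an$herd[m],
                    birth_date = format(an$birth_date[m], dialect$date_format),
                    sire = ifelse(is.na(an$sire[m]), dialect$unknown_parent, an$sire[m]),
                    dam = ifelse(is.na(an$dam[m]), dialect$unknown_parent, an$dam[m]),
                    event_type = ev$event_type,
                    event_date = format(ev$event_date, dialect$date_format),
                    event_value = ev$event_value, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, na = dialect$missing_token)
  invisible(path)
}

#' Read a pedigree file
#'
#' Columns `animal`, `sire`, `dam`, `birth_date`; unknown parents use the
#' dialect's sentinel (default `"0"`).  Referenced parents without a row of
#' their own are added as founders.  Duplicate animal ids are an error.
#'
#' @param path path to the pedigree file.
#' @param dialect a [table_dialect()].
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", na.strings = dialect$missing_token,
                           stringsAsFactors = FALSE)
  require_columns(raw, c("animal", "sire", "dam", "birth_date"), path)
  raw$sire[raw$sire == dialect$unknown_parent] <- NA_character_
  raw$dam[raw$dam == dialect$unknown_parent] <- NA_character_
  pedigree(raw$animal, raw$sire, raw$dam, parse_dates(raw$birth_date, dialect))
}

#' Write a pedigree file
#'
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @export
write_pedigree <- function(ped, path, dialect = table_dialect()) {
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), dialect$unknown_parent, ped$sire),
                    dam = ifelse(is.na(ped$dam), dialect$unknown_parent, ped$dam),
                    birth_date = ifelse(is.na(ped$birth_date), dialect$missing_token,
                                        format(ped$birth_date, dialect$date_format)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, na = dialect$missing_token)
  invisible(path)
}

#' Write a posterior summary as matrix and long tables
#'
#' Emits two files: `<prefix>_matrix.csv`, a square trait-by-trait layout
#' with heritabilities on the diagonal, genetic correlations above and
#' phenotypic correlations below (each cell `mean (sd)`), and
#' `<prefix>_long.csv` with columns `trait_a`, `trait_b`, `statistic`
#' (`h2`/`rg`/`rp`), `posterior_mean`, `posterior_sd`.
#'
#' @param summary a `posterior_summary` from [summarize_chain()].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(summary, prefix) {
  stopifnot(inherits(summary, "posterior_summary"))
  tr <- summary$traits
  t <- length(tr)
  cell <- function(m, s) sprintf("%.6f (%.6f)", m, s)
  M <- matrix("", t, t, dimnames = list(tr, tr))
  for (i in seq_len(t)) {
    M[i, i] <- cell(summary$h2$mean[i], summary$h2$sd[i])
    if (i < t) for (j in seq((i + 1), t)) {
      M[i, j] <- cell(summary$rg$mean[i, j], summary$rg$sd[i, j])
      M[j, i] <- cell(summary$rp$mean[i, j], summary$rp$sd[i, j])
    }
  }
  matrix_path <- paste0(prefix, "_matrix.csv")
  utils::write.csv(as.data.frame(M), matrix_path, quote = TRUE)

  rows <- data.frame(trait_a = tr, trait_b = tr, statistic = "h2",
                     posterior_mean = summary$h2$mean,
                     posterior_sd = summary$h2$sd, stringsAsFactors = FALSE)
  if (t > 1L) {
    for (i in seq_len(t - 1L)) for (j in seq(i + 1L, t)) {
      rows <- rbind(rows,
        data.frame(trait_a = tr[i], trait_b = tr[j],
                   statistic = c("rg", "rp"),
                   posterior_mean = c(summary$rg$mean[i, j], summary$rp$mean[i, j]),
                   posterior_sd = c(summary$rg$sd[i, j], summary$rp$sd[i, j]),
                   stringsAsFactors = FALSE))
    }
  }
  long_path <- paste0(prefix, "_long.csv")
  utils::write.csv(rows, long_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix = matrix_path, long = long_path))
}

#' Read back the long-format results table
#'
#' @param path path to a `*_long.csv` written by [write_results()].
#' @return Data frame with the long-format columns.
#' @export
read_results_long <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.herd_records <- function(x, ...) {
  cat(sprintf("herd_records: %d animals, %d events (%d rejected rows)\n",
              nrow(x$animals), nrow(x$events), nrow(x$edit_log)))
  invisible(x)
}
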