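#' Read and validate isotope CSV tables
#'
#' Reads one of the three canonical CSV tables (food sources, consumers,
#' atmospheric CO2 series), enforces the schema and the physical-range
#' invariants, and returns only the valid rows. Rows violating row-level
#' invariants are dropped and reported, with row numbers, in the
#' `"validation"` attribute (see [validation_errors()]). A missing required
#' column is a fatal schema error.
#'
#' Delta values are screened against broad physical windows
#' (\eqn{\delta^{13}}C in \[-40, 0\] permil VPDB, \eqn{\delta^{15}}N in
#' \[-10, 30\] permil AIR); values outside are treated as parse/entry errors,
#' not data. `pct_C`/`pct_N` must lie in (0, 100\] when present (empty cells
#' allowed; substitution is handled downstream). Source groups must be
#' habitat-consistent (`marine_*` groups in marine habitat and vice versa).
#'
#' For the consumer schema a `rank_by_d13C` column is assigned after
#' validation: ranks 1..N by ascending \eqn{\delta^{13}}C, ties broken by
#' `consumer_id` lexicographic order, so that individual orderings in
#' summary figures are deterministic.
#'
#' @param path Path to a CSV file (UTF-8, one header row, "." decimal).
#' @param schema One of `"sources"`, `"consumers"`, `"atmosphere"`.
#' @return A tibble of valid records with a `"validation"` attribute (a
#'   tibble with columns `row`, `field`, `message`; zero rows when clean).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' readr::write_csv(generate_sources(synthetic_design(seed = 1)), p)
#' src <- read_isotope_csv(p, "sources")
#' validation_errors(src)
#' @export
read_isotope_csv <- function(path, schema = c("sources", "consumers", "atmosphere")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  required <- switch(schema,
    sources = c("sample_id", "taxon", "tissue", "group", "habitat",
                "d13C", "d15N", "pct_C", "pct_N", "collection_year"),
    consumers = c("consumer_id", "sex", "d13C", "d15N"),
    atmosphere = c("year", "mean_d13C_CO2")
  )
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error in ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  switch(schema,
    sources = validate_sources(raw),
    consumers = validate_consumers(raw),
    atmosphere = validate_atmosphere(raw)
  )
}

#' @rdname read_isotope_csv
#' @export
read_sources <- function(path) read_isotope_csv(path, "sources")

#' @rdname read_isotope_csv
#' @export
read_consumers <- function(path) read_isotope_csv(path, "consumers")

#' @rdname read_isotope_csv
#' @export
read_atmosphere <- function(path) read_isotope_csv(path, "atmosphere")

#' Validation report of a table read with [read_isotope_csv()]
#'
#' @param x A tibble returned by [read_isotope_csv()] or a validator.
#' @return Tibble with columns `row`, `field`, `message` (zero rows if the
#'   input file was fully valid).
#' @export
validation_errors <- function(x) {
  v <- attr(x, "validation")
  if (is.null(v)) v <- tibble::tibble(row = integer(), field = character(),
                                      message = character())
  v
}

new_error_report <- function() {
  list(row = integer(), field = character(), message = character())
}

add_error <- function(rep, rows, field, message) {
  rep$row <- c(rep$row, rows)
  rep$field <- c(rep$field, rep(field, length(rows)))
  rep$message <- c(rep$message, rep(message, length(rows)))
  rep
}

finish_report <- function(rep) {
  tibble::tibble(row = rep$row, field = rep$field, message = rep$message)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Shared delta-range screen; returns logical 'bad' vector (NA counts as bad).
bad_delta <- function(x, lo, hi) is.na(x) | x < lo | x > hi

#' @rdname read_isotope_csv
#' @param data A raw tibble (character columns) to validate in place of a
#'   file; used by the readers and by the synthetic generator round-trips.
#' @export
validate_sources <- function(data) {
  rep <- new_error_report()
  n <- nrow(data)
  d13C <- num_or_na(data$d13C)
  d15N <- num_or_na(data$d15N)
  pct_C <- num_or_na(data$pct_C)
  pct_N <- num_or_na(data$pct_N)
  bad <- rep(FALSE, n)

  b <- bad_delta(d13C, -40, 0)
  rep <- add_error(rep, which(b), "d13C", "d13C outside [-40, 0] permil or unparseable")
  bad <- bad | b
  b <- bad_delta(d15N, -10, 30)
  rep <- add_error(rep, which(b), "d15N", "d15N outside [-10, 30] permil or unparseable")
  bad <- bad | b
  b <- !is.na(data$pct_C) & data$pct_C != "" & (is.na(pct_C) | pct_C <= 0 | pct_C > 100)
  rep <- add_error(rep, which(b), "pct_C", "pct_C outside (0, 100]")
  bad <- bad | b
  b <- !is.na(data$pct_N) & data$pct_N != "" & (is.na(pct_N) | pct_N <= 0 | pct_N > 100)
  rep <- add_error(rep, which(b), "pct_N", "pct_N outside (0, 100]")
  bad <- bad | b
  b <- !(data$group %in% SOURCE_GROUPS)
  rep <- add_error(rep, which(b), "group", "unknown source group")
  bad <- bad | b
  ok_grp <- data$group %in% SOURCE_GROUPS
  b <- ok_grp & data$habitat != unname(GROUP_HABITAT[data$group])
  b[is.na(b)] <- TRUE & ok_grp[is.na(b)]
  rep <- add_error(rep, which(b), "habitat", "habitat inconsistent with group")
  bad <- bad | b

  out <- tibble::tibble(
    sample_id = as.character(data$sample_id),
    taxon = as.character(data$taxon),
    tissue = as.character(data$tissue),
    group = as.character(data$group),
    habitat = as.character(data$habitat),
    d13C = d13C, d15N = d15N,
    pct_C = ifelse(is.na(data$pct_C) | data$pct_C == "", NA_real_, pct_C),
    pct_N = ifelse(is.na(data$pct_N) | data$pct_N == "", NA_real_, pct_N),
    collection_year = as.character(data$collection_year)
  )[!bad, ]
  attr(out, "validation") <- finish_report(rep)
  out
}

#' @rdname read_isotope_csv
#' @export
validate_consumers <- function(data) {
  rep <- new_error_report()
  d13C <- num_or_na(data$d13C)
  d15N <- num_or_na(data$d15N)
  bad <- rep(FALSE, nrow(data))

  b <- bad_delta(d13C, -40, 0)
  rep <- add_error(rep, which(b), "d13C", "d13C outside [-40, 0] permil or unparseable")
  bad <- bad | b
  b <- bad_delta(d15N, -10, 30)
  rep <- add_error(rep, which(b), "d15N", "d15N outside [-10, 30] permil or unparseable")
  bad <- bad | b
  sex <- as.character(data$sex)
  b <- !(sex %in% c("M", "F", "unknown"))
  rep <- add_error(rep, which(b), "sex", "sex must be M, F or unknown")
  bad <- bad | b

  out <- tibble::tibble(
    consumer_id = as.character(data$consumer_id),
    sex = sex, d13C = d13C, d15N = d15N
  )[!bad, ]
  out <- rank_consumers(out)
  attr(out, "validation") <- finish_report(rep)
  out
}

#' @rdname read_isotope_csv
#' @export
validate_atmosphere <- function(data) {
  rep <- new_error_report()
  year <- suppressWarnings(as.integer(data$year))
  mean_d13C <- num_or_na(data$mean_d13C_CO2)
  bad <- rep(FALSE, nrow(data))

  b <- is.na(year)
  rep <- add_error(rep, which(b), "year", "unparseable year")
  bad <- bad | b
  b <- bad_delta(mean_d13C, -40, 0)
  rep <- add_error(rep, which(b), "mean_d13C_CO2", "atmospheric d13C outside [-40, 0] permil")
  bad <- bad | b

  out <- tibble::tibble(year = year, mean_d13C_CO2 = mean_d13C)[!bad, ]
  if (anyDuplicated(out$year)) abort("atmosphere series must have one record per year")
  out <- dplyr::arrange(out, .data$year)
  attr(out, "validation") <- finish_report(rep)
  out
}

#' Rank consumers by ascending delta13C
#'
#' Assigns `rank_by_d13C` = 1..N ordered by ascending \eqn{\delta^{13}}C,
#' ties broken by `consumer_id` lexicographic order (a fixed convention so
#' that per-individual ID numbering is deterministic).
#'
#' @param consumers Tibble with at least `consumer_id` and `d13C`.
#' @return The input with a `rank_by_d13C` integer column (re)assigned.
#' @export
rank_consumers <- function(consumers) {
  ord <- order(consumers$d13C, consumers$consumer_id)
  consumers$rank_by_d13C <- integer(nrow(consumers))
  consumers$rank_by_d13C[ord] <- seq_len(nrow(consumers))
  consumers
}

#' Range summary of an isotope field
#'
#' @param records Tibble of records (sources or consumers).
#' @param field `"d13C"` or `"d15N"`.
#' @return One-row tibble with `min`, `max` and `width` (= max - min,
#'   reported to 1 decimal, the precision of the underlying measurements).
#' @examples
#' summarize_range(tibble::tibble(d13C = c(-17.9, -10.6)), "d13C")
#' @export
summarize_range <- function(records, field = c("d13C", "d15N")) {
  field <- match.arg(field)
  x <- records[[field]]
  if (is.null(x) || length(x) == 0) abort("summarize_range: empty collection")
  tibble::tibble(
    field = field,
    min = min(x), max = max(x),
    width = round(max(x) - min(x), 1)
  )
}

#' Write an isotope table to CSV
#'
#' Writes the canonical CSV representation (UTF-8, "." decimal, empty cell
#' for missing percent values) such that reading it back with
#' [read_isotope_csv()] round-trips field-for-field.
#'
#' @param data Tibble of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(data, path) {
  data <- dplyr::select(data, -dplyr::any_of("rank_by_d13C"))
  readr::write_csv(data, path, na = "")
  invisible(path)
}
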