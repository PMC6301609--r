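#' Suess-effect configuration
#'
#' Parameters for the atmospheric Suess-effect correction: the
#' pre-industrial atmospheric CO2 \eqn{\delta^{13}}C reference (-6.48
#' permil), the marine attenuation scalar (0.65, the ocean-surface carbon
#' pool tracks the atmospheric decline only partially), and the sample-age
#' threshold below which a sample is considered modern and corrected
#' (200 years).
#'
#' @param preindustrial_ref Pre-industrial atmospheric CO2 d13C, permil VPDB.
#' @param marine_scale Fraction of the terrestrial correction applied to
#'   marine-habitat samples; must lie in (0, 1].
#' @param age_threshold_years Ages (years before present) below this count
#'   as modern; must be positive.
#' @return A list of class `"suess_config"`.
#' @export
suess_config <- function(preindustrial_ref = -6.48, marine_scale = 0.65,
                         age_threshold_years = 200) {
  if (!(marine_scale > 0 && marine_scale <= 1)) {
    abort("marine_scale must lie in (0, 1]")
  }
  if (age_threshold_years <= 0) abort("age_threshold_years must be positive")
  structure(
    list(preindustrial_ref = preindustrial_ref, marine_scale = marine_scale,
         age_threshold_years = age_threshold_years),
    class = "suess_config"
  )
}

#' Suess-effect correction factor for one or more years
#'
#' The Suess effect is the decline of atmospheric CO2
#' \eqn{\delta^{13}}C since ~1860 from fossil-fuel burning. Comparability of
#' modern tissues with pre-industrial material requires raising modern
#' \eqn{\delta^{13}}C back toward the pre-industrial baseline, so the
#' correction is additive and non-negative for any post-1860 year in a
#' physically plausible series:
#' terrestrial correction = preindustrial_ref - mean atmospheric d13C of the
#' collection year; marine correction = marine_scale times the terrestrial
#' one. \eqn{\delta^{15}}N is never Suess-corrected.
#'
#' @param year Integer vector of collection years.
#' @param habitat Character vector, `"marine"` or `"terrestrial"` (recycled).
#' @param series Atmospheric series tibble (`year`, `mean_d13C_CO2`), one
#'   record per year, e.g. from [read_atmosphere()].
#' @param cfg A [suess_config()].
#' @return Numeric vector of additive corrections (permil) to be added to
#'   sample \eqn{\delta^{13}}C.
#' @examples
#' atm <- tibble::tibble(year = 2010L, mean_d13C_CO2 = -8.48)
#' suess_correction(2010, "terrestrial", atm)  # +2.00
#' suess_correction(2010, "marine", atm)       # +1.30
#' @export
suess_correction <- function(year, habitat, series, cfg = suess_config()) {
  idx <- match(year, series$year)
  if (anyNA(idx)) {
    abort(paste0("no atmospheric record for year(s): ",
                 paste(unique(year[is.na(idx)]), collapse = ", ")))
  }
  if (!all(habitat %in% c("marine", "terrestrial"))) {
    abort("habitat must be 'marine' or 'terrestrial'")
  }
  terr <- cfg$preindustrial_ref - series$mean_d13C_CO2[idx]
  ifelse(rep_len(habitat, length(terr)) == "marine", cfg$marine_scale * terr, terr)
}

#' Tissue-to-tissue isotopic offset table
#'
#' Builds/validates a table of tissue conversion offsets
#' (\eqn{\varepsilon_{to-from}} = \eqn{\delta_{to} - \delta_{from}}), applied
#' additively when converting records between tissue bases (e.g. hair to
#' bone-collagen equivalent, bone collagen to flesh equivalent). Offsets are
#' sanity-bounded at 6 permil in magnitude. `taxon_pattern` is a regular
#' expression restricting which taxa an offset applies to (default all).
#'
#' @param name Short label for the offset.
#' @param tissue_from,tissue_to Tissue the offset converts from / to.
#' @param d13C_offset,d15N_offset Signed offsets (permil) added to delta
#'   values.
#' @param taxon_pattern Regular expression matched against `taxon`
#'   (default `".*"`).
#' @return One-row tibble (rows may be bound into an offsets table).
#' @examples
#' tissue_offset("collagen-keratin", "hair", "bone collagen", -0.3, 0.4)
#' @export
tissue_offset <- function(name, tissue_from, tissue_to,
                          d13C_offset, d15N_offset, taxon_pattern = ".*") {
  if (abs(d13C_offset) > 6 || abs(d15N_offset) > 6) {
    abort("tissue offsets above 6 permil in magnitude fail the sanity bound")
  }
  tibble::tibble(
    name = name, tissue_from = tissue_from, tissue_to = tissue_to,
    d13C_offset = d13C_offset, d15N_offset = d15N_offset,
    taxon_pattern = taxon_pattern
  )
}

#' Read a tissue-offset configuration table from CSV
#'
#' Columns: `name, tissue_from, tissue_to, d13C_offset, d15N_offset` and
#' optionally `taxon_pattern`.
#'
#' @param path CSV path.
#' @return Offsets tibble (validated through [tissue_offset()]).
#' @export
read_offsets <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(raw$taxon_pattern)) raw$taxon_pattern <- ".*"
  purrr::pmap_dfr(
    raw[, c("name", "tissue_from", "tissue_to", "d13C_offset",
            "d15N_offset", "taxon_pattern")],
    tissue_offset
  )
}

#' Apply one tissue offset to matching records
#'
#' Adds the signed offsets to `d13C`/`d15N` of every record whose `tissue`
#' equals `tissue_from` (and whose `taxon` matches `taxon_pattern`), and
#' relabels the tissue as `tissue_to`. Raw values are retained in
#' `d13C_raw`/`d15N_raw` for audit. Errors if no record matches the
#' conversion (tissue mismatch).
#'
#' @param data Tibble of samples or consumers with `tissue` (and optionally
#'   `taxon`) columns.
#' @param offset One-row offsets tibble from [tissue_offset()].
#' @return Corrected tibble.
#' @export
apply_tissue_offset <- function(data, offset) {
  stopifnot(nrow(offset) == 1)
  if (is.null(data$tissue)) abort("records carry no tissue column")
  hit <- data$tissue == offset$tissue_from
  if (!is.null(data$taxon)) hit <- hit & grepl(offset$taxon_pattern, data$taxon)
  if (!any(hit)) {
    abort(paste0("tissue mismatch: no record has tissue '", offset$tissue_from,
                 "' matching pattern '", offset$taxon_pattern, "'"))
  }
  if (!("d13C_raw" %in% names(data))) data$d13C_raw <- data$d13C
  if (!("d15N_raw" %in% names(data))) data$d15N_raw <- data$d15N
  data$d13C[hit] <- data$d13C[hit] + offset$d13C_offset
  data$d15N[hit] <- data$d15N[hit] + offset$d15N_offset
  data$tissue[hit] <- offset$tissue_to
  data
}

#' Correct a sample table onto a common pre-industrial basis
#'
#' Applies, in order: (1) the Suess correction to \eqn{\delta^{13}}C of all
#' modern samples (collection year numeric and within `age_threshold_years`
#' of the most recent year in the series; records marked
#' `"archaeological"` are exempt), and (2) any configured tissue offsets.
#' \eqn{\delta^{15}}N is never Suess-corrected. Every adjustment is logged
#' in an audit tibble (`sample_id`, `kind`, `element`, `magnitude`)
#' attached as the `"audit"` attribute (see [correction_audit()]).
#'
#' @param samples Sources tibble from [read_sources()] (columns `sample_id`,
#'   `habitat`, `d13C`, `d15N`, `collection_year`, `tissue`, `taxon`).
#' @param series Atmospheric series tibble.
#' @param offsets Offsets tibble (zero-row or `NULL` for none).
#' @param cfg A [suess_config()].
#' @return Corrected tibble with `d13C_raw`/`d15N_raw` retained and the
#'   audit log attached.
#' @export
apply_corrections <- function(samples, series, offsets = NULL,
                              cfg = suess_config()) {
  year <- suppressWarnings(as.integer(samples$collection_year))
  archaeological <- !is.na(samples$collection_year) &
    samples$collection_year == "archaeological"
  missing_year <- is.na(year) & !archaeological
  if (any(missing_year)) {
    abort(paste0("modern samples missing collection_year: ",
                 paste(samples$sample_id[missing_year], collapse = ", ")))
  }
  present <- max(series$year)
  modern <- !archaeological & (present - year) < cfg$age_threshold_years

  out <- samples
  out$d13C_raw <- out$d13C
  out$d15N_raw <- out$d15N
  audit <- tibble::tibble(sample_id = character(), kind = character(),
                          element = character(), magnitude = double())
  if (any(modern)) {
    corr <- suess_correction(year[modern], out$habitat[modern], series, cfg)
    out$d13C[modern] <- out$d13C[modern] + corr
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      sample_id = out$sample_id[modern], kind = "suess",
      element = "C", magnitude = corr
    ))
  }
  if (!is.null(offsets) && nrow(offsets) > 0) {
    for (i in seq_len(nrow(offsets))) {
      off <- offsets[i, ]
      hit <- out$tissue == off$tissue_from & grepl(off$taxon_pattern, out$taxon)
      if (!any(hit)) next
      out$d13C[hit] <- out$d13C[hit] + off$d13C_offset
      out$d15N[hit] <- out$d15N[hit] + off$d15N_offset
      out$tissue[hit] <- off$tissue_to
      audit <- dplyr::bind_rows(audit,
        tibble::tibble(sample_id = out$sample_id[hit], kind = off$name,
                       element = "C", magnitude = off$d13C_offset),
        tibble::tibble(sample_id = out$sample_id[hit], kind = off$name,
                       element = "N", magnitude = off$d15N_offset))
    }
  }
  attr(out, "audit") <- audit
  out
}

#' Audit log of [apply_corrections()]
#'
#' @param x Tibble returned by [apply_corrections()].
#' @return Audit tibble (`sample_id`, `kind`, `element`, `magnitude`).
#' @export
correction_audit <- function(x) {
  a <- attr(x, "audit")
  if (is.null(a)) {
    a <- tibble::tibble(sample_id = character(), kind = character(),
                        element = character(), magnitude = double())
  }
  a
}
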