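#' Relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation — the
#' precision, repeatability and stability metric throughout the package.
#'
#' @param values At least two positive measurements.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(9, 10, 11))
rsd <- function(values) {
  abort_if(length(values) < 2, "need >= 2 values for an RSD.")
  abort_if(any(!is.finite(values)), "`values` contains non-finite entries.")
  m <- mean(values)
  abort_if(m <= 0, "mean of `values` must be > 0.")
  100 * stats::sd(values) / m
}

#' Intraday and interday precision from replicate injections
#'
#' Intraday precision is the RSD of the first day's replicate injections;
#' interday precision pools all replicates across days into one RSD (the
#' stricter of the two common conventions, since it absorbs the between-day
#' shift rather than averaging it away).
#'
#' @param data A data frame with `day`, `area` and optionally `analyte_id`.
#' @return A tibble per analyte: `intraday_rsd`, `interday_rsd` (%).
#' @export
precision <- function(data) {
  check_columns(data, c("day", "area"), "`data`")
  if (!"analyte_id" %in% names(data)) data$analyte_id <- "analyte"
  one <- function(d, id) {
    days <- sort(unique(d$day))
    abort_if(length(days) < 2,
             sprintf("analyte '%s': interday precision needs >= 2 days.", id))
    day1 <- d$area[d$day == days[1]]
    abort_if(length(day1) < 2,
             sprintf("analyte '%s': intraday precision needs >= 2 replicates on day 1.",
                     id))
    tibble::tibble(analyte_id = id,
                   intraday_rsd = rsd(day1),
                   interday_rsd = rsd(d$area))
  }
  data |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::group_map(~ one(.x, .y$analyte_id)) |>
    dplyr::bind_rows()
}

#' Spike recovery
#'
#' Marginal recovery of a known added amount:
#' `100 * (measured_total - base_amount) / spiked_amount`. All three
#' arguments must share a unit (mg here); the result is unit-free.
#'
#' @param measured_total Total amount found in the spiked sample.
#' @param base_amount Amount natively present (from the unspiked assay).
#' @param spiked_amount Amount added (> 0).
#' @return Recovery in percent (vectorised).
#' @export
#' @examples
#' recovery(measured_total = 1.95, base_amount = 1, spiked_amount = 1)
recovery <- function(measured_total, base_amount, spiked_amount) {
  abort_if(any(!is.finite(spiked_amount)) || any(spiked_amount <= 0),
           "`spiked_amount` must be finite and > 0.")
  100 * (measured_total - base_amount) / spiked_amount
}

#' Solution stability over storage time
#'
#' RSD of a solution's peak areas re-measured over a storage series
#' (typically 0-24 h at room temperature); a drift-free, precise assay keeps
#' this at the injection-noise level.
#'
#' @param areas Peak areas at successive timepoints (>= 2).
#' @return RSD in percent.
#' @export
stability <- function(areas) {
  rsd(areas)
}

#' Full method-validation battery on a synthetic study
#'
#' Assembles the standard validation report from a [generate_study()] bundle:
#' intraday/interday precision of repeated standard injections, repeatability
#' across six independent preparations, 24 h solution stability, and spike
#' recovery at 100% of native content (analytes with no native content are
#' reported as `NA`). Recovery converts areas to amounts through each
#' analyte's calibration curve and the recovery prep recorded in the study.
#'
#' @param study A `qams_study`.
#' @param curves A [fit_calibration()] object (needed for recovery).
#' @return A tibble per analyte: `intraday_rsd`, `interday_rsd`,
#'   `repeatability_rsd`, `stability_rsd`, `recovery_percent`,
#'   `recovery_rsd` (all %).
#' @export
validate_study <- function(study, curves) {
  stopifnot(inherits(study, "qams_study"))
  prec <- precision(study$precision)
  repe <- study$repeatability |>
    dplyr::filter(.data$area > 0) |>
    dplyr::summarise(repeatability_rsd = rsd(.data$area), .by = "analyte_id")
  stab <- study$stability |>
    dplyr::filter(.data$area > 0) |>
    dplyr::summarise(stability_rsd = rsd(.data$area), .by = "analyte_id")

  rec <- study$recovery |>
    dplyr::filter(.data$spike_mg > 0) |>
    invert_calibration(curves) |>
    dplyr::mutate(
      measured_mg = pmax(.data$concentration, 0) * .data$volume_ml / 1000,
      rec = recovery(.data$measured_mg, .data$base_mg, .data$spike_mg)
    ) |>
    dplyr::summarise(
      recovery_percent = mean(.data$rec),
      recovery_rsd = rsd(.data$rec),
      .by = "analyte_id"
    )

  prec |>
    dplyr::left_join(repe, by = "analyte_id") |>
    dplyr::left_join(stab, by = "analyte_id") |>
    dplyr::left_join(rec, by = "analyte_id")
}
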