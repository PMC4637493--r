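#' Sample preparation parameters
#'
#' The prep arithmetic that links extract concentration to seed content:
#' `mass_g` grams of powdered seed are extracted and made up to `volume_ml`
#' millilitres, so content (mg/g) = concentration (µg/mL) x volume / (mass x
#' 1000). The assay default is 0.1 g made up to 10 mL.
#'
#' @param mass_g Powder mass, grams.
#' @param volume_ml Final extract volume, millilitres.
#' @return A list of class `sample_prep`.
#' @export
sample_prep <- function(mass_g = 0.1, volume_ml = 10) {
  check_scalar_positive(mass_g, "mass_g")
  check_scalar_positive(volume_ml, "volume_ml")
  structure(list(mass_g = mass_g, volume_ml = volume_ml),
            class = "sample_prep")
}

#' Convert an extract concentration to seed content
#'
#' @param concentration Extract concentration, µg/mL (vectorised).
#' @param prep A [sample_prep()].
#' @return Content in mg per g of powdered seed.
#' @export
content_from_concentration <- function(concentration, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  concentration * prep$volume_ml / (prep$mass_g * 1000)
}

#' Convert peak areas to contents via each analyte's own calibration curve
#'
#' The external-standard step: invert the analyte's calibration line and apply
#' the prep arithmetic. Concentrations below the quantification limit are kept
#' (clamped at zero) but flagged `below_loq`, mirroring how such cells are
#' dashed out in content reports; values above the fitted range are
#' extrapolated and flagged `above_range`.
#'
#' @param data A data frame with columns `analyte_id` and `area` (one row per
#'   measurement; average replicates first or use [quantify_batch()]).
#' @param curves A [fit_calibration()] object covering every analyte in `data`.
#' @param prep A [sample_prep()].
#' @return `data` with `concentration` (µg/mL), `content` (mg/g),
#'   `qualifier` and `method = "external_standard"` columns added.
#' @export
content_from_area <- function(data, curves, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  invert_calibration(data, curves) |>
    dplyr::mutate(
      concentration = pmax(.data$concentration, 0),
      content = content_from_concentration(.data$concentration, prep),
      method = "external_standard"
    )
}

#' External-standard quantification of a batch of sample injections
#'
#' Averages replicate injections per (sample, analyte), inverts each
#' analyte's own calibration curve and converts to mg/g content. Output is
#' ordered by sample then by the panel order of `curves`, one row per
#' (sample, analyte) pair.
#'
#' @param records Injection records: a data frame with `sample_id`,
#'   `analyte_id`, `area` and optionally `replicate`.
#' @param curves A [fit_calibration()] object; every analyte in `records`
#'   must have a curve.
#' @param prep A [sample_prep()].
#' @return A tibble with `sample_id`, `analyte_id`, `method`, `area` (mean of
#'   replicates), `concentration`, `content`, `qualifier`.
#' @export
quantify_batch <- function(records, curves, prep) {
  check_columns(records, c("sample_id", "analyte_id", "area"), "`records`")
  missing <- setdiff(unique(records$analyte_id), curves$analyte_id)
  abort_if(
    length(missing) > 0,
    sprintf("no calibration curve for analyte(s): %s.",
            paste(missing, collapse = ", "))
  )
  records |>
    dplyr::summarise(area = mean(.data$area),
                     .by = c("sample_id", "analyte_id")) |>
    content_from_area(curves, prep) |>
    dplyr::mutate(
      analyte_id = factor(.data$analyte_id, levels = curves$analyte_id)
    ) |>
    dplyr::arrange(.data$sample_id, .data$analyte_id) |>
    dplyr::mutate(analyte_id = as.character(.data$analyte_id)) |>
    dplyr::select("sample_id", "analyte_id", "method", "area",
                  "concentration", "content", "qualifier")
}
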