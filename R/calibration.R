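#' Fit per-analyte linear calibration curves
#'
#' Fits ordinary least squares of peak area on standard concentration for each
#' analyte and derives the quantities a calibration report carries: slope,
#' intercept, coefficient of determination, residual standard deviation
#' (n - 2 denominator), the linear range actually covered by the standards,
#' and limits of detection and quantification from the residual noise
#' (see [lod_loq()]).
#'
#' @param data A data frame of calibration points with columns `analyte_id`,
#'   `concentration` (µg/mL) and `area` (detector area units).
#' @return A tibble of class `qams_calibration`, one row per analyte:
#'   `analyte_id`, `slope`, `intercept`, `r_squared`, `residual_sd`,
#'   `range_low`, `range_high`, `lod`, `loq`, `n_levels`, `n_points`.
#'   The calibration points are retained in the `"points"` attribute for
#'   plotting.
#' @details At least three distinct concentration levels per analyte are
#'   required; `r_squared` is the squared Pearson correlation between
#'   concentration and area. Weighted or nonlinear calibration is out of
#'   scope.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   analyte_id = "x", concentration = c(1, 2, 3), area = c(3, 5, 7)
#' )
#' fit_calibration(pts)
fit_calibration <- function(data) {
  check_columns(data, c("analyte_id", "concentration", "area"),
                "calibration data")
  abort_if(any(!is.finite(data$concentration)) || any(!is.finite(data$area)),
           "calibration data contains non-finite concentrations or areas.")

  fit_one <- function(d, id) {
    n_levels <- dplyr::n_distinct(d$concentration)
    abort_if(
      n_levels < 3,
      sprintf("analyte '%s': need >= 3 distinct concentration levels, got %d.",
              id, n_levels)
    )
    abort_if(
      stats::var(d$concentration) == 0,
      sprintf("analyte '%s': zero concentration variance.", id)
    )
    fit <- stats::lm(area ~ concentration, data = d)
    slope <- unname(stats::coef(fit)[2])
    # n - 2 denominator; computed directly so an exact fit stays silent
    sigma <- sqrt(sum(stats::residuals(fit)^2) / (nrow(d) - 2))
    limits <- lod_loq(sigma, slope)
    tibble::tibble(
      analyte_id = id,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = stats::cor(d$concentration, d$area)^2,
      residual_sd = sigma,
      range_low = min(d$concentration),
      range_high = max(d$concentration),
      lod = limits$lod,
      loq = limits$loq,
      n_levels = n_levels,
      n_points = nrow(d)
    )
  }

  out <- data |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::group_map(~ fit_one(.x, .y$analyte_id)) |>
    dplyr::bind_rows()
  structure(out,
            points = tibble::as_tibble(
              data[, c("analyte_id", "concentration", "area")]
            ),
            class = c("qams_calibration", class(out)))
}

#' Limits of detection and quantification from regression residual noise
#'
#' Uses the 3-sigma / 10-sigma convention: LOD = 3 s / b and LOQ = 10 s / b,
#' where s is the residual standard deviation of the calibration regression
#' and b its slope, so LOQ / LOD is 10/3 by construction.
#'
#' @param residual_sd Residual standard deviation of the calibration fit
#'   (area units); vectorised.
#' @param slope Calibration slope (area per µg/mL); must be positive.
#' @return A tibble with columns `lod` and `loq` (µg/mL).
#' @export
lod_loq <- function(residual_sd, slope) {
  abort_if(any(!is.finite(slope)) || any(slope <= 0),
           "`slope` must be finite and > 0.")
  abort_if(any(!is.finite(residual_sd)) || any(residual_sd < 0),
           "`residual_sd` must be finite and >= 0.")
  tibble::tibble(lod = 3 * residual_sd / slope,
                 loq = 10 * residual_sd / slope)
}

#' Convert peak areas to concentrations via fitted calibration curves
#'
#' Inverts each analyte's calibration line, concentration =
#' (area - intercept) / slope, and attaches a qualifier: `"below_loq"` when
#' the concentration falls under the quantification limit, `"above_range"`
#' when it exceeds the fitted range (extrapolated but flagged rather than
#' rejected), `"ok"` otherwise. Below-LOQ concentrations are returned, not
#' censored; downstream content conversion decides how to report them.
#'
#' @param data A data frame with columns `analyte_id` and `area`.
#' @param curves A `qams_calibration` object from [fit_calibration()].
#' @return `data` with `concentration` (µg/mL) and `qualifier` columns added.
#' @export
invert_calibration <- function(data, curves) {
  check_columns(data, c("analyte_id", "area"), "peak data")
  check_columns(curves, c("analyte_id", "slope", "intercept", "loq",
                          "range_high"), "`curves`")
  abort_if(any(!is.finite(data$area)), "`area` contains non-finite values.")
  missing <- setdiff(unique(data$analyte_id), curves$analyte_id)
  abort_if(
    length(missing) > 0,
    sprintf("no calibration curve for analyte(s): %s.",
            paste(missing, collapse = ", "))
  )
  data |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(curves), "analyte_id", "slope",
                    "intercept", "loq", "range_high"),
      by = "analyte_id"
    ) |>
    dplyr::mutate(
      concentration = (.data$area - .data$intercept) / .data$slope,
      qualifier = dplyr::case_when(
        .data$concentration < .data$loq ~ "below_loq",
        .data$concentration > .data$range_high ~ "above_range",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select(-"slope", -"intercept", -"loq", -"range_high")
}

#' @method tidy qams_calibration
#' @export
tidy.qams_calibration <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("analyte_id", "slope", "intercept") |>
    tidyr::pivot_longer(c("slope", "intercept"),
                        names_to = "term", values_to = "estimate")
}

#' @method glance qams_calibration
#' @export
glance.qams_calibration <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::transmute(
      .data$analyte_id,
      r.squared = .data$r_squared,
      sigma = .data$residual_sd,
      nobs = .data$n_points
    )
}

#' @method autoplot qams_calibration
#' @export
autoplot.qams_calibration <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(.data$concentration, .data$area)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(
      data = tibble::as_tibble(object),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      linewidth = 0.3, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~analyte_id, scales = "free") +
    ggplot2::labs(x = "concentration (µg/mL)", y = "peak area")
}
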