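#' Relative correction factor between a marker and an analyte
#'
#' The correction factor is the ratio of concentration-normalised detector
#' responses,
#' \deqn{f = \frac{W_k \, A_m}{W_m \, A_k},}
#' where \eqn{W_k, A_k} are the concentration and peak area of the marker
#' standard and \eqn{W_m, A_m} those of the analyte standard measured in the
#' same run. Once f is known, the analyte can be quantified from the marker's
#' standard alone (see [qams_concentration()]).
#'
#' @param w_k Marker standard concentration, µg/mL.
#' @param a_k Marker peak area.
#' @param w_m Analyte standard concentration, µg/mL.
#' @param a_m Analyte peak area.
#' @return The dimensionless correction factor (vectorised).
#' @export
#' @examples
#' compute_rcf(w_k = 100, a_k = 2806972, w_m = 100, a_m = 953528)
compute_rcf <- function(w_k, a_k, w_m, a_m) {
  for (nm in c("w_k", "a_k", "w_m", "a_m")) {
    x <- get(nm, inherits = FALSE)
    abort_if(any(!is.finite(x)) || any(x <= 0),
             sprintf("`%s` must be finite and > 0.", nm))
  }
  (w_k * a_m) / (w_m * a_k)
}

#' Single-marker concentration estimate
#'
#' Inverts the correction-factor definition: given the marker's concentration
#' and area on a sample run and the analyte's area on the same run,
#' \deqn{W_m = \frac{W_k \, A_m}{f \, A_k}.}
#'
#' @param f Mean correction factor for the analyte (> 0).
#' @param a_m Analyte peak area in the sample run.
#' @param w_k Marker concentration in the same run (from the marker's own
#'   calibration curve), µg/mL.
#' @param a_k Marker peak area in the same run.
#' @return Analyte concentration, µg/mL (vectorised).
#' @export
qams_concentration <- function(f, a_m, w_k, a_k) {
  abort_if(any(!is.finite(f)) || any(f <= 0), "`f` must be finite and > 0.")
  abort_if(any(!is.finite(a_k)) || any(a_k <= 0),
           "`a_k` must be finite and > 0.")
  (w_k * a_m) / (f * a_k)
}

#' Correction factors from standard injections
#'
#' Computes the per-condition correction factor of every QAMS analyte against
#' the marker from standard-mixture injections. Replicate injections are
#' averaged within each condition (instrument x column x injection volume)
#' before the ratio is taken; marker and analyte always come from the same
#' run, never across volumes.
#'
#' @param standards Standard injection records: `analyte_id`, `concentration`
#'   (µg/mL), `area`, plus any of `instrument_id`, `column_id`,
#'   `injection_volume_ul`, `replicate`.
#' @param marker_id Analyte used as the single marker.
#' @param exclude Analytes to leave out of QAMS (defaults to the panel's
#'   `excluded` role: analytes whose separation or abundance is too poor for
#'   a stable factor).
#' @param panel Analyte panel used for the default exclusions.
#' @return A tibble with the condition columns plus `analyte_id`,
#'   `marker_id`, `f`.
#' @export
estimate_rcf <- function(standards, marker_id = "neobavaisoflavone",
                         exclude = NULL, panel = pc_panel()) {
  check_columns(standards, c("analyte_id", "concentration", "area"),
                "`standards`")
  abort_if(!marker_id %in% standards$analyte_id,
           sprintf("marker '%s' has no standard injections.", marker_id))
  if (is.null(exclude)) {
    exclude <- panel$analyte_id[panel$qams_role == "excluded"]
  }
  cond_cols <- intersect(
    c("instrument_id", "column_id", "injection_volume_ul"),
    names(standards)
  )
  means <- standards |>
    dplyr::summarise(
      concentration = mean(.data$concentration),
      area = mean(.data$area),
      .by = dplyr::all_of(c(cond_cols, "analyte_id"))
    )
  marker <- means |>
    dplyr::filter(.data$analyte_id == marker_id) |>
    dplyr::rename(w_k = "concentration", a_k = "area") |>
    dplyr::select(-"analyte_id")
  analytes <- dplyr::filter(means,
                            !.data$analyte_id %in% c(marker_id, exclude))
  joined <- if (length(cond_cols)) {
    dplyr::left_join(analytes, marker, by = cond_cols)
  } else {
    dplyr::cross_join(analytes, marker)
  }
  joined |>
    dplyr::mutate(
      marker_id = marker_id,
      f = compute_rcf(.data$w_k, .data$a_k, .data$concentration, .data$area)
    ) |>
    dplyr::select(dplyr::all_of(cond_cols), "analyte_id", "marker_id", "f")
}

#' Summarise correction factors over conditions
#'
#' Condenses per-condition correction factors into the reported per-analyte
#' mean and relative standard deviation. The mean f is what single-marker
#' quantification uses; its RSD across injection volumes (or systems) is the
#' usual gauge of whether the factor is stable enough to rely on.
#'
#' @param data Per-condition factors: a data frame with `f` and (optionally)
#'   `analyte_id`, `marker_id`; any other columns label the conditions.
#' @return A tibble of class `rcf_estimate`: `analyte_id`, `marker_id`, `n`,
#'   `mean_f`, `rsd_percent` (sample SD, n - 1). The per-condition values are
#'   kept in the `"values"` attribute, in input order.
#' @export
#' @examples
#' rcf_volume_table() |> rcf_summary()
rcf_summary <- function(data) {
  check_columns(data, "f", "`data`")
  abort_if(any(!is.finite(data$f)) || any(data$f <= 0),
           "`f` values must be finite and > 0.")
  if (!"analyte_id" %in% names(data)) data$analyte_id <- "analyte"
  if (!"marker_id" %in% names(data)) data$marker_id <- NA_character_
  counts <- dplyr::count(data, .data$analyte_id)
  abort_if(any(counts$n < 2),
           sprintf("need >= 2 f values per analyte; too few for: %s.",
                   paste(counts$analyte_id[counts$n < 2], collapse = ", ")))
  out <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_f = mean(.data$f),
      rsd_percent = 100 * stats::sd(.data$f) / mean(.data$f),
      .by = c("analyte_id", "marker_id")
    )
  structure(out, values = tibble::as_tibble(data),
            class = c("rcf_estimate", class(out)))
}

#' Robustness of correction factors across chromatographic systems
#'
#' Compares per-system correction factors (e.g. instrument x column
#' combinations) and reports, per analyte, the factor spread
#' `100 * (max - min) / mean` — the usual summary of whether f transfers
#' between systems.
#'
#' @param data A data frame with `analyte_id`, `f` and one or more grouping
#'   columns (default `instrument_id`, `column_id`).
#' @param group_cols Columns identifying a system.
#' @return A tibble with `analyte_id`, `n_groups`, `f_min`, `f_max`,
#'   `f_mean`, `spread_percent`.
#' @export
#' @examples
#' rcf_condition_table() |> rcf_robustness()
rcf_robustness <- function(data, group_cols = c("instrument_id", "column_id")) {
  check_columns(data, c("analyte_id", "f", group_cols), "`data`")
  abort_if(any(!is.finite(data$f)), "`f` contains non-finite values.")
  groups <- dplyr::distinct(data[, group_cols, drop = FALSE])
  abort_if(nrow(groups) < 2, "need >= 2 systems to compare.")
  data |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      f_min = min(.data$f),
      f_max = max(.data$f),
      f_mean = mean(.data$f),
      spread_percent = 100 * (max(.data$f) - min(.data$f)) / mean(.data$f),
      .by = "analyte_id"
    )
}

#' Single-marker quantification of a batch of sample injections
#'
#' Quantifies every QAMS analyte from the marker's calibration curve alone:
#' replicate areas are averaged per (sample, analyte); the marker
#' concentration on each sample run comes from its own curve; each analyte's
#' concentration is then `W_k * A_m / (f * A_k)` with that analyte's mean
#' correction factor, and the prep arithmetic converts to mg/g.
#'
#' @param records Sample injection records (`sample_id`, `analyte_id`, `area`,
#'   optional `replicate`).
#' @param rcf An [rcf_summary()] result (or any tibble with `analyte_id`,
#'   `marker_id`, `mean_f`).
#' @param curves Calibration covering the marker (only the marker's curve is
#'   used — the premise of the method).
#' @param prep A [sample_prep()].
#' @return A tibble with `sample_id`, `analyte_id`, `method = "qams"`,
#'   `concentration`, `content` (mg/g), `qualifier` (inherited from the
#'   marker's inversion: a sample whose marker response is itself below the
#'   quantification limit cannot anchor the others).
#' @export
quantify_qams <- function(records, rcf, curves, prep) {
  check_columns(records, c("sample_id", "analyte_id", "area"), "`records`")
  check_columns(rcf, c("analyte_id", "marker_id", "mean_f"), "`rcf`")
  stopifnot(inherits(prep, "sample_prep"))
  marker_id <- unique(rcf$marker_id)
  abort_if(length(marker_id) != 1,
           "`rcf` must use a single marker.")
  abort_if(!marker_id %in% curves$analyte_id,
           sprintf("no calibration curve for marker '%s'.", marker_id))
  abort_if(any(rcf$mean_f <= 0), "`mean_f` must be > 0.")

  means <- records |>
    dplyr::summarise(area = mean(.data$area),
                     .by = c("sample_id", "analyte_id"))
  marker <- means |>
    dplyr::filter(.data$analyte_id == marker_id) |>
    invert_calibration(curves) |>
    dplyr::transmute(
      .data$sample_id,
      a_k = .data$area,
      w_k = pmax(.data$concentration, 0),
      marker_qualifier = .data$qualifier
    )
  missing <- setdiff(unique(means$sample_id), marker$sample_id)
  abort_if(
    length(missing) > 0,
    sprintf("sample(s) without a marker ('%s') peak: %s.",
            marker_id, paste(missing, collapse = ", "))
  )
  means |>
    dplyr::inner_join(dplyr::select(tibble::as_tibble(rcf), "analyte_id",
                                    "mean_f"),
                      by = "analyte_id") |>
    dplyr::left_join(marker, by = "sample_id") |>
    dplyr::mutate(
      concentration = qams_concentration(.data$mean_f, .data$area,
                                         .data$w_k, .data$a_k),
      content = content_from_concentration(pmax(.data$concentration, 0),
                                           prep),
      method = "qams",
      qualifier = .data$marker_qualifier
    ) |>
    dplyr::arrange(.data$sample_id, .data$analyte_id) |>
    dplyr::select("sample_id", "analyte_id", "method", "area",
                  "concentration", "content", "qualifier")
}

#' Accuracy of single-marker contents against external-standard contents
#'
#' @param w_qams Content from single-marker quantification, mg/g (> 0).
#' @param w_es Content from the external-standard method, mg/g (> 0).
#' @return `100 * w_qams / w_es`, rounded to 4 significant figures
#'   (vectorised).
#' @export
#' @examples
#' accuracy(4.229, 4.367)
accuracy <- function(w_qams, w_es) {
  abort_if(any(!is.finite(w_es)) || any(w_es <= 0),
           "`w_es` must be finite and > 0.")
  abort_if(any(!is.finite(w_qams)) || any(w_qams <= 0),
           "`w_qams` must be finite and > 0.")
  signif(100 * w_qams / w_es, 4)
}

#' Pair single-marker and external-standard results and compute accuracies
#'
#' Joins the two quantification outputs on (sample, analyte) and reports the
#' accuracy of each cell. Cells flagged below the quantification limit in
#' either method, or missing from one of them, are skipped rather than
#' imputed.
#'
#' @param qams_results Output of [quantify_qams()].
#' @param es_results Output of [quantify_batch()].
#' @return A tibble with `sample_id`, `analyte_id`, `content_qams`,
#'   `content_es`, `accuracy_percent`.
#' @export
compare_methods <- function(qams_results, es_results) {
  q <- qams_results |>
    dplyr::filter(.data$qualifier != "below_loq", .data$content > 0) |>
    dplyr::select("sample_id", "analyte_id", content_qams = "content")
  e <- es_results |>
    dplyr::filter(.data$qualifier != "below_loq", .data$content > 0) |>
    dplyr::select("sample_id", "analyte_id", content_es = "content")
  dplyr::inner_join(q, e, by = c("sample_id", "analyte_id")) |>
    dplyr::mutate(
      accuracy_percent = accuracy(.data$content_qams, .data$content_es)
    )
}
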