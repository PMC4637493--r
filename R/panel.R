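#' Default nine-flavonoid analyte panel
#'
#' The panel of nine prenylated flavonoids quantified in *Psoralea corylifolia*
#' seed extracts by HPLC-DAD at 250 nm, with the published per-analyte linear
#' calibration parameters (detector area per µg/mL), linear ranges and
#' detection/quantification limits. These parameters double as the simulation
#' ground truth of [study_truth()].
#'
#' `qams_role` records how each analyte participates in single-marker
#' quantification: neobavaisoflavone is the marker (commercially available,
#' stable content across batches); corylin and bavachalcone are excluded
#' because their separation and abundance are too poor for a reliable
#' correction factor; the remaining six are QAMS analytes.
#'
#' @return A tibble with one row per analyte: `peak` (elution order),
#'   `analyte_id`, `analyte`, `slope` (area per µg/mL), `intercept` (area),
#'   `range_low`, `range_high` (µg/mL), `lod_ref`, `loq_ref` (µg/mL, published
#'   reference values), `rt_min` (nominal retention time, minutes) and
#'   `qams_role` (`"marker"`, `"analyte"` or `"excluded"`).
#' @export
#' @examples
#' pc_panel()
pc_panel <- function() {
  tibble::tibble(
    peak = 1:9,
    analyte_id = c(
      "isobavachin", "neobavaisoflavone", "bavachin", "corylin",
      "bavachalcone", "bavachinin", "isobavachalcone", "corylifol_a",
      "methylbavachalcone"
    ),
    analyte = c(
      "Isobavachin", "Neobavaisoflavone", "Bavachin", "Corylin",
      "Bavachalcone", "Bavachinin", "Isobavachalcone", "Corylifol A",
      "4'-O-Methylbavachalcone"
    ),
    slope = c(6094.2, 28072, 9536.0, 52057, 10586, 8039.5, 9564.5, 19363, 13683),
    intercept = c(-47.492, -228.09, -72.258, -175.41, -84.429, -89.087,
                  -112.19, -148.88, 0.876),
    range_low = c(18.75, 16.88, 9.375, 7.500, 12.50, 28.13, 22.50, 12.50, 7.656),
    range_high = c(300.0, 270.0, 300.0, 120.0, 200.0, 450.9, 360.0, 200.0, 245.0),
    lod_ref = c(2.615, 0.5610, 2.612, 0.4780, 1.809, 2.805, 2.704, 1.014, 1.853),
    loq_ref = c(8.718, 1.872, 8.706, 1.594, 6.029, 9.349, 9.012, 3.381, 6.178),
    rt_min = c(24.5, 27.8, 30.6, 33.4, 36.9, 41.2, 44.6, 48.3, 52.7),
    qams_role = c(
      "analyte", "marker", "analyte", "excluded", "excluded",
      "analyte", "analyte", "analyte", "analyte"
    )
  )
}

#' Published relative correction factors by injection volume
#'
#' Per-volume relative correction factors (f) of the six QAMS analytes against
#' the neobavaisoflavone marker, determined at seven injection volumes
#' (triplicate injections each). These are the printed per-condition values
#' that [rcf_summary()] condenses into the reported means and RSDs.
#'
#' @return A tibble with `injection_volume_ul`, `analyte_id`, `marker_id`, `f`.
#' @seealso [rcf_summary()], [rcf_condition_table()]
#' @export
rcf_volume_table <- function() {
  volumes <- c(1, 2, 4, 6, 10, 16, 20)
  f <- list(
    isobavachin        = c(0.712, 0.702, 0.699, 0.687, 0.672, 0.651, 0.656),
    bavachin           = c(3.03, 2.95, 2.95, 2.91, 2.89, 2.80, 2.86),
    bavachinin         = c(0.859, 0.852, 0.849, 0.833, 0.827, 0.803, 0.806),
    isobavachalcone    = c(1.94, 1.94, 1.92, 2.00, 2.00, 2.01, 2.04),
    corylifol_a        = c(0.734, 0.745, 0.745, 0.776, 0.774, 0.780, 0.786),
    methylbavachalcone = c(1.38, 1.42, 1.34, 1.43, 1.46, 1.47, 1.48)
  )
  tidyr::expand_grid(
    analyte_id = names(f),
    injection_volume_ul = volumes
  ) |>
    dplyr::mutate(
      marker_id = "neobavaisoflavone",
      f = unlist(f, use.names = FALSE)
    ) |>
    dplyr::select("injection_volume_ul", "analyte_id", "marker_id", "f")
}

#' Published relative correction factors by instrument and column
#'
#' Relative correction factors of the six QAMS analytes measured on two
#' instruments crossed with two C18 columns, used to check robustness of f
#' to the chromatographic system.
#'
#' @return A tibble with `instrument_id`, `column_id`, `analyte_id`,
#'   `marker_id`, `f`.
#' @export
rcf_condition_table <- function() {
  grid <- tibble::tibble(
    instrument_id = rep(c("Agilent 1100", "Agilent 1100",
                          "Waters 2695", "Waters 2695"), each = 6),
    column_id = rep(c("Purospher C18", "Alltima C18",
                      "Purospher C18", "Alltima C18"), each = 6),
    analyte_id = rep(c("isobavachin", "bavachin", "bavachinin",
                       "isobavachalcone", "corylifol_a",
                       "methylbavachalcone"), times = 4),
    f = c(
      0.683, 2.916, 0.833, 1.98, 0.763, 1.46,
      0.676, 2.928, 0.814, 2.07, 0.778, 1.52,
      0.672, 2.956, 0.799, 2.02, 0.774, 1.44,
      0.688, 2.935, 0.803, 2.12, 0.780, 1.48
    )
  )
  dplyr::mutate(grid, marker_id = "neobavaisoflavone", .before = "f")
}

#' Published external-standard contents for thirteen seed batches
#'
#' Contents (mg analyte per g of powdered seed) of the nine panel analytes in
#' thirteen commercial batches, determined by the external-standard method.
#' Cells reported as "---" (below the quantification limit or not integrated)
#' are `NA`. These contents are the default per-sample ground truth of the
#' synthetic study generator.
#'
#' @return A tidy tibble with `sample_id`, `analyte_id`, `content` (mg/g,
#'   `NA` where not reported).
#' @export
content_reference <- function() {
  ids <- pc_panel()$analyte_id
  rows <- list(
    S1  = c(NA,    9.124, 4.367, 0.7310, 2.478, 8.251, 8.013,  6.616, NA),
    S2  = c(NA,    9.647, 5.043, 0.7800, 2.368, 12.18, 11.61,  7.749, NA),
    S3  = c(NA,    9.538, 5.280, 1.031,  2.983, 9.386, 11.17,  7.432, 1.049),
    S4  = c(6.847, 9.677, 5.623, 1.610,  4.040, 9.178, 12.605, 6.997, 1.818),
    S5  = c(8.115, 9.058, 3.503, 1.187,  3.328, 6.416, 8.731,  7.237, 2.004),
    S6  = c(4.846, 8.202, 5.570, 2.011,  6.741, 7.707, 9.729,  6.624, 2.582),
    S7  = c(8.915, 7.837, 4.075, 1.478,  3.744, 7.547, 7.948,  5.962, 2.024),
    S8  = c(8.411, 14.66, 7.026, 1.452,  4.260, 10.94, 13.68,  9.726, 5.393),
    S9  = c(NA,    10.29, 4.517, 0.6540, 2.122, 10.70, 12.43,  7.185, 2.120),
    S10 = c(NA,    5.413, 3.437, 1.349,  2.928, 4.229, 7.519,  4.892, 1.466),
    S11 = c(NA,    7.326, 3.149, 0.694,  3.958, 9.948, 8.287,  5.792, 2.981),
    S12 = c(NA,    5.474, 3.145, 0.638,  1.768, 6.040, 6.964,  3.437, 1.208),
    S13 = c(NA,    8.281, 3.142, 1.231,  2.921, 6.367, 7.120,  7.247, 1.479)
  )
  tibble::tibble(
    sample_id = rep(names(rows), each = length(ids)),
    analyte_id = rep(ids, times = length(rows)),
    content = unlist(rows, use.names = FALSE)
  )
}

#' Published single-marker (QAMS) contents paired with external-standard contents
#'
#' Per-sample QAMS contents (mg/g) together with the external-standard content
#' of the numerically matching cell and the accuracy as printed. The two
#' published tables label their columns inconsistently; pairs here follow
#' numerical consistency (the printed accuracy equals the printed content
#' ratio for almost every cell) and are named by the external-standard table's
#' analyte. `accuracy_printed` is kept verbatim, and `consistent` marks the
#' cells whose printed accuracy agrees with the content ratio to the printed
#' resolution; the handful that do not (a publication-internal discrepancy)
#' stay visible but should not serve as numeric fixtures.
#'
#' @return A tibble with `sample_id`, `analyte_id`, `content_qams`,
#'   `content_es` (both mg/g), `accuracy_printed` (%) and `consistent`.
#' @seealso [accuracy()], [compare_methods()]
#' @export
qams_reference <- function() {
  # columns: isobavachin, neobavaisoflavone, bavachin, isobavachalcone,
  # corylifol_a, methylbavachalcone; each cell is c(qams_mg_g, accuracy_pct)
  rows <- list(
    S1  = list(NULL, c(9.393, 102.9), c(4.229, 96.84), c(8.092, 99.86),  c(6.750, 102.0),  NULL),
    S2  = list(NULL, c(9.476, 98.23), c(4.773, 94.65), c(11.52, 99.33),  c(7.650, 98.73),  NULL),
    S3  = list(NULL, c(9.665, 101.3), c(5.195, 98.39), c(11.41, 102.1),  c(7.541, 101.5),  c(1.064, 101.5)),
    S4  = list(c(6.755, 98.66), c(9.846, 101.7), c(5.607, 99.72), c(13.07, 103.7), c(7.070, 101.0), c(1.853, 102.0)),
    S5  = list(c(8.682, 107.0), c(9.740, 107.5), c(3.383, 96.57), c(9.231, 105.7), c(7.809, 107.9), c(2.168, 108.2)),
    S6  = list(c(4.660, 96.15), c(8.448, 103.0), c(5.705, 102.4), c(10.09, 103.7), c(6.839, 103.2), c(2.714, 105.1)),
    S7  = list(c(9.329, 104.6), c(8.045, 102.7), c(3.349, 96.92), c(8.028, 101.0), c(6.080, 102.0), c(2.124, 105.0)),
    S8  = list(c(8.300, 98.69), c(15.03, 102.5), c(7.057, 100.4), c(13.97, 102.1), c(9.932, 102.1), c(5.386, 99.87)),
    S9  = list(NULL, c(10.31, 100.2), c(4.252, 94.13), c(12.61, 101.5),  c(7.136, 99.33),  c(2.116, 99.82)),
    S10 = list(NULL, c(5.152, 94.88), c(3.720, 108.2), c(7.773, 103.4),  c(5.030, 97.26),  c(1.495, 102.0)),
    S11 = list(NULL, c(7.159, 97.73), c(2.925, 92.89), c(8.077, 97.46),  c(5.640, 97.38),  c(3.015, 101.1)),
    S12 = list(NULL, c(5.597, 102.2), c(2.985, 94.92), c(7.200, 103.4),  c(3.284, 95.57),  c(1.323, 109.5)),
    S13 = list(NULL, c(9.052, 109.3), c(3.016, 96.00), c(7.309, 102.6),  c(7.852, 108.35), c(1.609, 108.8))
  )
  cols <- c("isobavachin", "neobavaisoflavone", "bavachin",
            "isobavachalcone", "corylifol_a", "methylbavachalcone")
  out <- purrr::imap(rows, function(cells, sid) {
    keep <- !purrr::map_lgl(cells, is.null)
    tibble::tibble(
      sample_id = sid,
      analyte_id = cols[keep],
      content_qams = purrr::map_dbl(cells[keep], 1),
      accuracy_printed = purrr::map_dbl(cells[keep], 2)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::inner_join(
      dplyr::rename(content_reference(), content_es = "content"),
      by = c("sample_id", "analyte_id")
    ) |>
    dplyr::mutate(
      # printed accuracies carry 4 significant figures (0.1 resolution near
      # 100%); allow half a unit in the last place
      consistent = abs(accuracy(.data$content_qams, .data$content_es) -
                         .data$accuracy_printed) <= 0.055
    ) |>
    dplyr::select("sample_id", "analyte_id", "content_qams", "content_es",
                  "accuracy_printed", "consistent")
}

#' Published method-validation summary
#'
#' Intraday and interday precision, repeatability (n = 6 each) and spike
#' recovery reported for the nine panel analytes. Used as a plausibility
#' reference for the simulated validation battery, not as a recomputable
#' target (the underlying raw areas were never published).
#'
#' @return A tibble with `analyte_id`, `intraday_rsd`, `interday_rsd`,
#'   `repeatability_rsd` (all %) and `recovery` (%).
#' @export
validation_reference <- function() {
  tibble::tibble(
    analyte_id = pc_panel()$analyte_id,
    intraday_rsd = c(0.33, 0.18, 0.20, 0.16, 1.3, 1.4, 0.30, 1.4, 1.1),
    interday_rsd = c(1.6, 2.6, 0.82, 1.3, 2.8, 2.5, 2.3, 2.5, 2.2),
    repeatability_rsd = c(1.8, 1.0, 1.3, 1.0, 1.1, 1.1, 0.56, 0.64, 2.1),
    recovery = c(97.23, 96.43, 95.61, 103.5, 100.4, 97.79, 94.94, 95.52, 98.45)
  )
}
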