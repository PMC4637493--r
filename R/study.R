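#' Define the ground truth of a synthetic quantification study
#'
#' Collects everything the synthetic study generator needs: the analyte panel
#' with its linear detector response (slope, intercept), per-sample true
#' contents, the sample preparation arithmetic (0.1 g of powdered seed
#' extracted and made up to 10 mL), the injection-volume series used for the
#' correction-factor determination, and the multiplicative area noise level.
#'
#' Defaults reproduce the published study conditions: the nine-analyte panel
#' with its published calibration parameters as detector truth, the thirteen
#' batch contents as sample truth (unreported cells treated as true zeros),
#' seven injection volumes from 1 to 20 µL around the 10 µL reference, and a
#' 2% area coefficient of variation, consistent with the published intraday
#' precision scale.
#'
#' @param panel Analyte panel (see [pc_panel()]); `slope`/`intercept` are used
#'   as the true detector response.
#' @param contents Tidy tibble of true contents (`sample_id`, `analyte_id`,
#'   `content` mg/g); `NA` is treated as 0 (a true blank).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   area noise; must lie in \[0, 0.2\].
#' @param mass_g,volume_ml Sample prep: powder mass (g) and final extract
#'   volume (mL).
#' @param injection_volumes Volumes (µL) at which standard mixtures are
#'   injected for the correction-factor series.
#' @param reference_volume Volume (µL) all other injections use and to which
#'   areas scale linearly.
#' @param n_replicates Replicate injections per run.
#' @param calibration_levels Number of calibration levels, spaced
#'   geometrically across each analyte's linear range.
#' @param standard_concentration Optional named vector of standard-mix
#'   concentrations (µg/mL) per analyte; defaults to the geometric midpoint
#'   of each linear range.
#' @param conditions Tibble of chromatographic systems (`instrument_id`,
#'   `column_id`); the first row is the reference system.
#' @param condition_cv CV of the per-analyte response difference between
#'   non-reference systems and the reference system.
#' @param day_cv CV of the shared between-day response shift in the precision
#'   arm.
#' @param prep_cv CV of the preparation-to-preparation extraction effect in
#'   the repeatability and recovery arms.
#' @param stability_drift Fractional signal drift of a stored solution over
#'   24 h (0 = drift-free).
#' @param seed Default RNG seed for [generate_study()].
#' @return A list of class `study_truth`.
#' @export
study_truth <- function(panel = pc_panel(),
                        contents = content_reference(),
                        noise_cv = 0.02,
                        mass_g = 0.1,
                        volume_ml = 10,
                        injection_volumes = c(1, 2, 4, 6, 10, 16, 20),
                        reference_volume = 10,
                        n_replicates = 3,
                        calibration_levels = 6,
                        standard_concentration = NULL,
                        conditions = tibble::tibble(
                          instrument_id = "Agilent 1100",
                          column_id = "Purospher C18"
                        ),
                        condition_cv = 0.01,
                        day_cv = 0.015,
                        prep_cv = 0.01,
                        stability_drift = 0,
                        seed = 1L) {
  check_columns(panel, c("analyte_id", "slope", "intercept", "range_low",
                         "range_high", "qams_role"), "`panel`")
  check_columns(contents, c("sample_id", "analyte_id", "content"),
                "`contents`")
  check_scalar_positive(mass_g, "mass_g")
  check_scalar_positive(volume_ml, "volume_ml")
  check_positive(injection_volumes, "injection_volumes")
  abort_if(noise_cv < 0 || noise_cv > 0.2,
           "`noise_cv` must lie in [0, 0.2].")
  contents <- dplyr::mutate(
    contents,
    content = dplyr::coalesce(.data$content, 0)
  )
  abort_if(any(contents$content < 0), "true contents must be >= 0.")
  if (is.null(standard_concentration)) {
    standard_concentration <- stats::setNames(
      sqrt(panel$range_low * panel$range_high), panel$analyte_id
    )
  }
  structure(
    list(
      panel = panel, contents = contents, noise_cv = noise_cv,
      mass_g = mass_g, volume_ml = volume_ml,
      injection_volumes = injection_volumes,
      reference_volume = reference_volume,
      n_replicates = n_replicates,
      calibration_levels = calibration_levels,
      standard_concentration = standard_concentration,
      conditions = tibble::as_tibble(conditions),
      condition_cv = condition_cv, day_cv = day_cv, prep_cv = prep_cv,
      stability_drift = stability_drift,
      seed = as.integer(seed)
    ),
    class = "study_truth"
  )
}

# lognormal multiplicative noise with unit mean and coefficient of variation cv
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# noise-free detector area at a given concentration and injection volume
expected_area <- function(conc, slope, intercept, volume, reference_volume,
                          gain = 1) {
  (slope * conc + intercept) * (volume / reference_volume) * gain
}

#' Generate a full synthetic quantification study
#'
#' Simulates every data set the pipeline consumes, with known ground truth:
#' a calibration series per analyte, the multi-volume / multi-system standard
#' injections that determine relative correction factors, replicate sample
#' injections for the thirteen-batch quantification, and the validation arms
#' (intraday/interday precision, repeatability, stability, spike recovery).
#'
#' Areas follow the linear detector model
#' `area = (slope * concentration + intercept) * volume / reference_volume`,
#' multiplied by unit-mean lognormal noise with the study's CV. Sample
#' extract concentrations derive from the prep arithmetic
#' `conc (µg/mL) = content (mg/g) * mass (g) * 1000 / volume (mL)`.
#' Non-reference chromatographic systems perturb each analyte's response by a
#' small lognormal gain, which is what makes correction factors differ across
#' instrument/column combinations. The recovery arm spikes sample S7 (or the
#' first sample) at 100% of its native content using a 0.5 g / 50 mL prep so
#' spiked extracts stay inside the calibration ranges.
#'
#' The bundle is deterministic: the same `truth` and `seed` give a
#' bit-identical result.
#'
#' @param truth A [study_truth()] object.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return A list of class `qams_study` with elements `truth`, `calibration`,
#'   `standards`, `samples`, `precision`, `repeatability`, `stability`,
#'   `recovery`.
#' @export
#' @examples
#' study <- generate_study(study_truth(noise_cv = 0))
#' curves <- fit_calibration(study$calibration)
#' head(quantify_batch(study$samples, curves, sample_prep()))
generate_study <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "study_truth"))
  withr::local_seed(as.integer(seed))
  panel <- truth$panel
  rv <- truth$reference_volume
  cv <- truth$noise_cv

  # --- calibration series -------------------------------------------------
  calibration <- panel |>
    dplyr::select("analyte_id", "slope", "intercept", "range_low",
                  "range_high") |>
    dplyr::rowwise() |>
    dplyr::reframe(
      analyte_id = .data$analyte_id,
      level = seq_len(truth$calibration_levels),
      concentration = exp(seq(log(.data$range_low), log(.data$range_high),
                              length.out = truth$calibration_levels)),
      mu = expected_area(.data$concentration, .data$slope, .data$intercept,
                         rv, rv)
    ) |>
    dplyr::mutate(area = .data$mu * lognoise(dplyr::n(), cv)) |>
    dplyr::select("analyte_id", "level", "concentration", "area")

  # --- per-system response gains (reference system has gain 1) ------------
  conditions <- dplyr::mutate(truth$conditions,
                              .condition = dplyr::row_number())
  gains <- tidyr::expand_grid(
    .condition = conditions$.condition,
    analyte_id = panel$analyte_id
  )
  gains$gain <- ifelse(gains$.condition == 1, 1,
                       lognoise(nrow(gains), truth$condition_cv))

  # --- standard-mix injections across volumes and systems -----------------
  std_conc <- tibble::tibble(
    analyte_id = names(truth$standard_concentration),
    concentration = unname(truth$standard_concentration)
  )
  standards <- tidyr::expand_grid(
    .condition = conditions$.condition,
    injection_volume_ul = truth$injection_volumes,
    replicate = seq_len(truth$n_replicates),
    analyte_id = panel$analyte_id
  ) |>
    dplyr::left_join(conditions, by = ".condition") |>
    dplyr::left_join(gains, by = c(".condition", "analyte_id")) |>
    dplyr::left_join(std_conc, by = "analyte_id") |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept",
                                   "rt_min"),
                     by = "analyte_id") |>
    dplyr::mutate(
      run_id = sprintf("std_c%d_v%02d_r%d", .data$.condition,
                       .data$injection_volume_ul, .data$replicate),
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           .data$injection_volume_ul, rv, .data$gain) *
        lognoise(dplyr::n(), cv),
      retention_time_min = .data$rt_min
    ) |>
    dplyr::select("run_id", "instrument_id", "column_id",
                  "injection_volume_ul", "replicate", "analyte_id",
                  "retention_time_min", "concentration", "area")

  # --- sample injections (reference system, reference volume) -------------
  ref_cond <- conditions[1, ]
  samples <- tidyr::expand_grid(
    sample_id = unique(truth$contents$sample_id),
    replicate = seq_len(truth$n_replicates),
    analyte_id = panel$analyte_id
  ) |>
    dplyr::left_join(truth$contents, by = c("sample_id", "analyte_id")) |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept",
                                   "rt_min", "range_low", "range_high"),
                     by = "analyte_id") |>
    dplyr::mutate(
      content = dplyr::coalesce(.data$content, 0)
    ) |>
    dplyr::mutate(
      run_id = sprintf("%s_r%d", .data$sample_id, .data$replicate),
      instrument_id = ref_cond$instrument_id,
      column_id = ref_cond$column_id,
      injection_volume_ul = rv,
      content = dplyr::coalesce(.data$content, 0),
      concentration = .data$content * truth$mass_g * 1000 / truth$volume_ml,
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           rv, rv) * lognoise(dplyr::n(), cv),
      in_range = .data$concentration >= .data$range_low &
        .data$concentration <= .data$range_high,
      retention_time_min = .data$rt_min
    ) |>
    dplyr::select("run_id", "sample_id", "instrument_id", "column_id",
                  "injection_volume_ul", "replicate", "analyte_id",
                  "retention_time_min", "area", "in_range")
  n_out <- sum(!samples$in_range)
  if (n_out > 0) {
    rlang::warn(
      sprintf(
        "%d simulated sample record(s) fall outside the calibration range (see `in_range`).",
        n_out
      ),
      class = "qamskit_range_warning"
    )
  }

  # --- precision arm: one standard mix, 6 injections on each of 2 days ----
  precision <- tidyr::expand_grid(
    day = 1:2, replicate = 1:6, analyte_id = panel$analyte_id
  ) |>
    dplyr::left_join(std_conc, by = "analyte_id") |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept"),
                     by = "analyte_id")
  day_shift <- tibble::tibble(
    day = 1:2,
    shift = c(1, lognoise(1, truth$day_cv))
  )
  precision <- precision |>
    dplyr::left_join(day_shift, by = "day") |>
    dplyr::mutate(
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           rv, rv) * .data$shift * lognoise(dplyr::n(), cv)
    ) |>
    dplyr::select("day", "replicate", "analyte_id", "area")

  # --- repeatability: 6 independent preparations of one sample ------------
  rep_sample <- if ("S7" %in% truth$contents$sample_id) "S7" else
    truth$contents$sample_id[1]
  prep_effect <- tibble::tibble(prep = 1:6,
                                effect = lognoise(6, truth$prep_cv))
  repeatability <- tidyr::expand_grid(prep = 1:6,
                                      analyte_id = panel$analyte_id) |>
    dplyr::left_join(
      dplyr::filter(truth$contents, .data$sample_id == rep_sample),
      by = "analyte_id"
    ) |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept"),
                     by = "analyte_id") |>
    dplyr::left_join(prep_effect, by = "prep") |>
    dplyr::mutate(
      concentration = .data$content * truth$mass_g * 1000 / truth$volume_ml,
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           rv, rv) * .data$effect * lognoise(dplyr::n(), cv)
    ) |>
    dplyr::select("prep", "analyte_id", "area")

  # --- stability: one solution re-injected over 24 h ----------------------
  timepoints <- c(0, 2, 4, 8, 12, 24)
  stability <- tidyr::expand_grid(time_h = timepoints,
                                  analyte_id = panel$analyte_id) |>
    dplyr::left_join(
      dplyr::filter(truth$contents, .data$sample_id == rep_sample),
      by = "analyte_id"
    ) |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept"),
                     by = "analyte_id") |>
    dplyr::mutate(
      content = dplyr::coalesce(.data$content, 0),
      concentration = .data$content * truth$mass_g * 1000 / truth$volume_ml,
      drift = 1 + truth$stability_drift * .data$time_h / 24,
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           rv, rv) * .data$drift * lognoise(dplyr::n(), cv)
    ) |>
    dplyr::select("time_h", "analyte_id", "area")

  # --- spike recovery: S7 spiked at 100% of native content ----------------
  rec_mass <- 0.5
  rec_volume <- 50
  rec_effect <- tibble::tibble(replicate = 1:6,
                               effect = lognoise(6, truth$prep_cv))
  recovery <- tidyr::expand_grid(replicate = 1:6,
                                 analyte_id = panel$analyte_id) |>
    dplyr::left_join(
      dplyr::filter(truth$contents, .data$sample_id == rep_sample),
      by = "analyte_id"
    ) |>
    dplyr::left_join(dplyr::select(panel, "analyte_id", "slope", "intercept"),
                     by = "analyte_id") |>
    dplyr::left_join(rec_effect, by = "replicate") |>
    dplyr::mutate(
      content = dplyr::coalesce(.data$content, 0),
      base_mg = .data$content * rec_mass,
      spike_mg = .data$base_mg,
      concentration = (.data$base_mg + .data$spike_mg) * 1000 / rec_volume,
      area = expected_area(.data$concentration, .data$slope, .data$intercept,
                           rv, rv) * .data$effect * lognoise(dplyr::n(), cv),
      mass_g = rec_mass,
      volume_ml = rec_volume
    ) |>
    dplyr::select("replicate", "analyte_id", "base_mg", "spike_mg",
                  "mass_g", "volume_ml", "area")

  structure(
    list(
      truth = truth, seed = as.integer(seed),
      calibration = calibration, standards = standards, samples = samples,
      precision = precision, repeatability = repeatability,
      stability = stability, recovery = recovery
    ),
    class = "qams_study"
  )
}

#' @export
print.qams_study <- function(x, ...) {
  cat(sprintf(
    paste0("<qams_study> seed %d: %d calibration points, %d standard runs, ",
           "%d sample records (%d samples), noise CV %.1f%%\n"),
    x$seed, nrow(x$calibration), dplyr::n_distinct(x$standards$run_id),
    nrow(x$samples), dplyr::n_distinct(x$samples$sample_id),
    100 * x$truth$noise_cv
  ))
  invisible(x)
}
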