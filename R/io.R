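peak_table_cols <- c("run_id", "sample_id", "instrument_id", "column_id",
                     "injection_volume_ul", "analyte_id",
                     "retention_time_min", "area")

#' Read a peak table
#'
#' Reads the package's peak-table CSV layout (one row per detected peak per
#' run) and validates it: required columns present, numeric fields parseable,
#' analyte ids drawn from the panel, and no duplicate (run, analyte) rows.
#' Malformed rows are reported with their line numbers. A header-only file
#' returns an empty tibble with a warning.
#'
#' @param path CSV file with columns `run_id`, `sample_id`, `instrument_id`,
#'   `column_id`, `injection_volume_ul`, `analyte_id`, `retention_time_min`,
#'   `area`.
#' @param panel Analyte panel used to validate `analyte_id` (`NULL` skips the
#'   check).
#' @return A tibble of injection records.
#' @export
read_peak_table <- function(path, panel = pc_panel()) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  # parse problems are re-reported below with line numbers
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      run_id = readr::col_character(),
      sample_id = readr::col_character(),
      instrument_id = readr::col_character(),
      column_id = readr::col_character(),
      injection_volume_ul = readr::col_double(),
      analyte_id = readr::col_character(),
      retention_time_min = readr::col_double(),
      area = readr::col_double()
    ),
    progress = FALSE
  ))
  check_columns(raw, peak_table_cols, sprintf("peak table '%s'", path))
  if (nrow(raw) == 0) {
    rlang::warn(sprintf("peak table '%s' has a header but no rows.", path))
    return(raw)
  }
  probs <- readr::problems(raw)
  bad <- unique(c(
    if (nrow(probs) > 0) probs$row + 1L,
    which(!stats::complete.cases(
      raw[, c("run_id", "injection_volume_ul", "analyte_id", "area")]
    )) + 1L
  ))
  abort_if(
    length(bad) > 0,
    sprintf("malformed row(s) in '%s' at line(s): %s.",
            path, paste(sort(bad), collapse = ", "))
  )
  if (!is.null(panel)) {
    unknown <- setdiff(unique(raw$analyte_id), panel$analyte_id)
    abort_if(
      length(unknown) > 0,
      sprintf("unknown analyte id(s) in '%s': %s.",
              path, paste(unknown, collapse = ", "))
    )
  }
  dup <- duplicated(raw[, c("run_id", "analyte_id")])
  abort_if(
    any(dup),
    sprintf("duplicate (run_id, analyte_id) row(s) in '%s' at line(s): %s.",
            path, paste(which(dup) + 1L, collapse = ", "))
  )
  raw
}

#' Write a peak table
#'
#' @param records A data frame containing at least the peak-table columns
#'   (extra columns are dropped).
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(records, path) {
  check_columns(records, peak_table_cols, "`records`")
  readr::write_csv(records[, peak_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a calibration series
#'
#' @param path CSV with columns `analyte_id`, `concentration_ug_per_ml`,
#'   `area`.
#' @return A tibble with `analyte_id`, `concentration`, `area`, ready for
#'   [fit_calibration()].
#' @export
read_calibration_series <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      analyte_id = readr::col_character(),
      concentration_ug_per_ml = readr::col_double(),
      area = readr::col_double()
    ),
    progress = FALSE
  )
  check_columns(raw, c("analyte_id", "concentration_ug_per_ml", "area"),
                sprintf("calibration file '%s'", path))
  dplyr::rename(raw, concentration = "concentration_ug_per_ml")
}

#' Write a calibration series
#'
#' @param series Data frame with `analyte_id`, `concentration`, `area`.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_calibration_series <- function(series, path) {
  check_columns(series, c("analyte_id", "concentration", "area"), "`series`")
  series |>
    dplyr::select("analyte_id",
                  concentration_ug_per_ml = "concentration", "area") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Write a calibration report
#'
#' One row per analyte with slope, intercept, R-squared, fitted range and
#' detection/quantification limits.
#'
#' @param curves A [fit_calibration()] object.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(curves, path) {
  tibble::as_tibble(curves) |>
    dplyr::select("analyte_id", "slope", "intercept", "r_squared",
                  "range_low", "range_high", "lod", "loq") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Write contents as a wide sample-by-analyte table
#'
#' Contents are rendered to 4 significant figures; cells flagged below the
#' quantification limit (or absent) are written as an em dash.
#'
#' @param results Output of [quantify_batch()] or [quantify_qams()].
#' @param path Destination CSV.
#' @param analyte_order Column order; defaults to the panel order.
#' @return `path`, invisibly.
#' @export
write_contents_wide <- function(results, path,
                                analyte_order = pc_panel()$analyte_id) {
  check_columns(results, c("sample_id", "analyte_id", "content", "qualifier"),
                "`results`")
  wide <- results |>
    dplyr::mutate(
      cell = ifelse(.data$qualifier == "below_loq", "—",
                    signif_chr(.data$content, 4)),
      analyte_id = factor(.data$analyte_id,
                          levels = intersect(analyte_order,
                                             unique(.data$analyte_id)))
    ) |>
    dplyr::select("sample_id", "analyte_id", "cell") |>
    tidyr::pivot_wider(names_from = "analyte_id", values_from = "cell",
                       names_sort = TRUE)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a correction-factor summary table
#'
#' Per-condition f values (3 significant figures) with the per-analyte mean
#' and RSD appended, in the layout of a per-volume f report.
#'
#' @param rcf Per-condition factors (see [estimate_rcf()]).
#' @param path Destination CSV.
#' @param condition_col Column labelling the condition rows.
#' @return `path`, invisibly.
#' @export
write_rcf_table <- function(rcf, path,
                            condition_col = "injection_volume_ul") {
  check_columns(rcf, c(condition_col, "analyte_id", "f"), "`rcf`")
  values <- rcf |>
    dplyr::mutate(cell = signif_chr(.data$f, 3)) |>
    dplyr::select(dplyr::all_of(condition_col), "analyte_id", "cell") |>
    tidyr::pivot_wider(names_from = "analyte_id", values_from = "cell") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(condition_col), as.character))
  summ <- rcf_summary(rcf)
  footer <- tibble::tibble(
    !!condition_col := c("Mean", "RSD%"),
  )
  for (a in setdiff(names(values), condition_col)) {
    s <- summ[summ$analyte_id == a, ]
    footer[[a]] <- c(signif_chr(s$mean_f, 3),
                     formatC(s$rsd_percent, digits = 2, format = "fg"))
  }
  readr::write_csv(dplyr::bind_rows(values, footer), path, progress = FALSE)
  invisible(path)
}

#' Write a method-comparison (accuracy) table
#'
#' @param comparison Output of [compare_methods()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_accuracy_table <- function(comparison, path) {
  check_columns(comparison,
                c("sample_id", "analyte_id", "content_qams", "content_es",
                  "accuracy_percent"), "`comparison`")
  comparison |>
    dplyr::mutate(
      content_qams = signif(.data$content_qams, 4),
      content_es = signif(.data$content_es, 4),
      accuracy_percent = signif(.data$accuracy_percent, 4)
    ) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [study_truth()]
#' (`noise_cv`, `mass_g`, `volume_ml`, `injection_volumes`, `seed`, ...),
#' plus optional `contents` (list of `sample_id: {analyte_id: content}`) and
#' `conditions` (list of `{instrument_id, column_id}`).
#'
#' @param path YAML file.
#' @return A [study_truth()] object.
#' @export
read_study_config <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(study_truth)))]
  if (!is.null(cfg$contents)) {
    args$contents <- purrr::imap_dfr(cfg$contents, function(row, sid) {
      tibble::tibble(sample_id = sid,
                     analyte_id = names(row),
                     content = as.numeric(unlist(row)))
    })
  }
  if (!is.null(cfg$conditions)) {
    args$conditions <- dplyr::bind_rows(cfg$conditions)
  }
  if (!is.null(args$injection_volumes)) {
    args$injection_volumes <- as.numeric(args$injection_volumes)
  }
  do.call(study_truth, args)
}

#' Run the full quantification workflow and write its reports
#'
#' End-to-end orchestration on a synthetic study: calibration fitting,
#' external-standard quantification, correction-factor estimation at every
#' injection volume, single-marker quantification, the validation battery,
#' and the method-accuracy comparison. Writes one CSV per report plus a JSON
#' provenance record (seed, configuration hash, package and R versions).
#' Outputs are deterministic for a fixed truth and seed.
#'
#' @param truth A [study_truth()] (or a ready-made `qams_study` from
#'   [generate_study()]).
#' @param out_dir Output directory, created if needed.
#' @param marker_id Single-marker analyte; must be in the panel.
#' @return Invisibly, a list with the in-memory results (`curves`,
#'   `es_results`, `rcf`, `rcf_summary`, `qams_results`, `comparison`,
#'   `validation`) and the written `files`.
#' @export
run_pipeline <- function(truth = study_truth(), out_dir,
                         marker_id = "neobavaisoflavone") {
  study <- if (inherits(truth, "qams_study")) truth else generate_study(truth)
  tr <- study$truth
  abort_if(!marker_id %in% tr$panel$analyte_id,
           sprintf("marker '%s' is not in the analyte panel.", marker_id))
  abort_if(!marker_id %in% study$standards$analyte_id,
           sprintf("no standard injections for marker '%s'; cannot anchor QAMS.",
                   marker_id))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- sample_prep(tr$mass_g, tr$volume_ml)

  curves <- fit_calibration(study$calibration)
  es <- quantify_batch(study$samples, curves, prep)

  ref_std <- study$standards |>
    dplyr::filter(.data$instrument_id == tr$conditions$instrument_id[1],
                  .data$column_id == tr$conditions$column_id[1])
  rcf <- estimate_rcf(ref_std, marker_id = marker_id, panel = tr$panel) |>
    dplyr::select("injection_volume_ul", "analyte_id", "marker_id", "f")
  rcf_sum <- rcf_summary(rcf)
  qams <- quantify_qams(study$samples, rcf_sum, curves, prep)
  comparison <- compare_methods(qams, es)
  validation <- validate_study(study, curves)

  rcf_systems <- estimate_rcf(
    dplyr::summarise(
      study$standards,
      concentration = mean(.data$concentration), area = mean(.data$area),
      .by = c("instrument_id", "column_id", "analyte_id")
    ),
    marker_id = marker_id, panel = tr$panel
  )

  files <- c(
    calibration = file.path(out_dir, "calibration_report.csv"),
    contents_es = file.path(out_dir, "contents_external_standard.csv"),
    contents_qams = file.path(out_dir, "contents_qams.csv"),
    rcf_volumes = file.path(out_dir, "rcf_by_volume.csv"),
    rcf_systems = file.path(out_dir, "rcf_by_system.csv"),
    accuracy = file.path(out_dir, "qams_accuracy.csv"),
    validation = file.path(out_dir, "validation_report.csv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_calibration_report(curves, files[["calibration"]])
  write_contents_wide(es, files[["contents_es"]])
  write_contents_wide(qams, files[["contents_qams"]])
  write_rcf_table(rcf, files[["rcf_volumes"]])
  readr::write_csv(
    dplyr::mutate(rcf_systems, f = signif(.data$f, 3)),
    files[["rcf_systems"]], progress = FALSE
  )
  write_accuracy_table(comparison, files[["accuracy"]])
  readr::write_csv(
    dplyr::mutate(validation,
                  dplyr::across(-"analyte_id", ~ signif(.x, 4))),
    files[["validation"]], progress = FALSE
  )
  jsonlite::write_json(
    list(
      seed = study$seed,
      marker_id = marker_id,
      config_hash = rlang::hash(tr),
      n_samples = dplyr::n_distinct(study$samples$sample_id),
      package = as.character(utils::packageVersion("qamskit")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    ),
    files[["provenance"]], auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    study = study, curves = curves, es_results = es, rcf = rcf,
    rcf_summary = rcf_sum, qams_results = qams, comparison = comparison,
    validation = validation, files = files
  ))
}
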