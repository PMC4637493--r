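#' Describe one chromatographic peak
#'
#' A peak is modelled as a Gaussian with analytic area
#' `true_amount * height_scale`: `true_amount` is the mass on column (µg) and
#' `height_scale` the detector response per µg, so simulated areas can be
#' checked against a closed form. Real peaks tail; a plain Gaussian is used
#' because downstream quantification consumes areas only.
#'
#' @param analyte_id Analyte identifier.
#' @param retention_time Apex position, minutes (> 0).
#' @param width_sigma Gaussian standard deviation, minutes (> 0).
#' @param true_amount Mass on column, µg (>= 0).
#' @param height_scale Detector response per µg of analyte.
#' @return A one-row tibble; bind rows to build a multi-peak spec.
#' @export
peak_spec <- function(analyte_id, retention_time, width_sigma, true_amount,
                      height_scale = 1) {
  abort_if(any(retention_time <= 0), "`retention_time` must be > 0.")
  abort_if(any(width_sigma <= 0), "`width_sigma` must be > 0.")
  abort_if(any(true_amount < 0), "`true_amount` must be >= 0.")
  tibble::tibble(
    analyte_id = analyte_id,
    retention_time = retention_time,
    width_sigma = width_sigma,
    true_amount = true_amount,
    height_scale = height_scale
  )
}

#' Simulate a detector trace from peak specifications
#'
#' The signal is the sum of Gaussian peaks, a linear baseline and i.i.d.
#' Gaussian detector noise on a uniform time grid. Each peak's analytic area
#' equals `true_amount * height_scale`, which anchors the integration tests.
#'
#' @param specs A data frame of peaks as built by [peak_spec()]; peaks may
#'   overlap. May have zero rows (blank run).
#' @param t_min,t_max Grid limits, minutes.
#' @param dt Grid spacing, minutes (> 0).
#' @param noise_sd Detector noise standard deviation (signal units).
#' @param baseline_start Baseline level at `t_min`.
#' @param baseline_drift Baseline slope, signal units per minute.
#' @param seed Optional integer; fixing it makes the trace reproducible.
#' @return An object of class `chromatogram`: a list with `trace` (tibble of
#'   `time`, `signal`), `truth` (the peak specs), and the noise/baseline
#'   parameters.
#' @export
#' @examples
#' sp <- peak_spec("a", retention_time = 5, width_sigma = 0.1, true_amount = 2)
#' ch <- simulate_chromatogram(sp, t_min = 0, t_max = 10, dt = 0.005)
#' integrate_peaks(ch, peak_windows(sp))
simulate_chromatogram <- function(specs, t_min = 0, t_max = 60, dt = 0.01,
                                  noise_sd = 0, baseline_start = 0,
                                  baseline_drift = 0, seed = NULL) {
  abort_if(!is.numeric(dt) || length(dt) != 1 || dt <= 0,
           "grid spacing `dt` must be a single positive number.")
  abort_if(t_max <= t_min, "`t_max` must exceed `t_min`.")
  abort_if(noise_sd < 0, "`noise_sd` must be >= 0.")
  specs <- tibble::as_tibble(specs)
  if (nrow(specs) > 0) {
    check_columns(specs, c("analyte_id", "retention_time", "width_sigma",
                           "true_amount", "height_scale"), "`specs`")
    abort_if(any(specs$width_sigma <= 0), "`width_sigma` must be > 0.")
    lo <- specs$retention_time - 5 * specs$width_sigma
    hi <- specs$retention_time + 5 * specs$width_sigma
    if (any(lo < t_min) || any(hi > t_max)) {
      rlang::warn("grid does not cover all peaks to +/- 5 sigma; areas will be truncated.")
    }
  }

  time <- seq(t_min, t_max, by = dt)
  signal <- baseline_start + baseline_drift * (time - t_min)
  if (nrow(specs) > 0) {
    for (i in seq_len(nrow(specs))) {
      signal <- signal + specs$true_amount[i] * specs$height_scale[i] *
        stats::dnorm(time, specs$retention_time[i], specs$width_sigma[i])
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    signal <- signal + stats::rnorm(length(time), sd = noise_sd)
  }
  structure(
    list(
      trace = tibble::tibble(time = time, signal = signal),
      truth = specs,
      noise_sd = noise_sd,
      baseline_start = baseline_start,
      baseline_drift = baseline_drift,
      seed = seed
    ),
    class = "chromatogram"
  )
}

#' Default integration windows for a set of peaks
#'
#' @param specs Peak specifications (see [peak_spec()]).
#' @param k Half-width of each window in units of the peak's sigma.
#' @return A tibble with `analyte_id`, `t_start`, `t_end`.
#' @export
peak_windows <- function(specs, k = 5) {
  tibble::tibble(
    analyte_id = specs$analyte_id,
    t_start = specs$retention_time - k * specs$width_sigma,
    t_end = specs$retention_time + k * specs$width_sigma
  )
}

trapezoid <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Integrate peak areas from a chromatogram
#'
#' For each retention-time window the local baseline is the straight line
#' through the signal at the window endpoints; the area is the trapezoidal
#' integral of the baseline-corrected signal. Negative integrals (possible in
#' noisy blanks) are clipped to zero and flagged.
#'
#' @param chrom A [simulate_chromatogram()] object (or any list with a
#'   `trace` tibble of `time` and `signal`).
#' @param windows A data frame with `analyte_id`, `t_start`, `t_end`;
#'   windows must not overlap and must lie inside the time grid.
#' @return A tibble with `analyte_id`, `area`, `clipped` (logical).
#' @export
integrate_peaks <- function(chrom, windows) {
  check_columns(windows, c("analyte_id", "t_start", "t_end"), "`windows`")
  trace <- chrom$trace
  abort_if(any(windows$t_end <= windows$t_start),
           "each window must have t_end > t_start.")
  out_of_grid <- windows$t_start < min(trace$time) |
    windows$t_end > max(trace$time)
  abort_if(
    any(out_of_grid),
    sprintf("window(s) outside the time grid: %s.",
            paste(windows$analyte_id[out_of_grid], collapse = ", "))
  )
  w <- windows[order(windows$t_start), ]
  abort_if(any(w$t_start[-1] < w$t_end[-nrow(w)]) && nrow(w) > 1,
           "integration windows overlap.")

  purrr::pmap_dfr(
    windows[, c("analyte_id", "t_start", "t_end")],
    function(analyte_id, t_start, t_end) {
      idx <- which(trace$time >= t_start & trace$time <= t_end)
      abort_if(length(idx) < 2,
               sprintf("window for '%s' contains fewer than 2 grid points.",
                       analyte_id))
      tt <- trace$time[idx]
      yy <- trace$signal[idx]
      base <- yy[1] + (yy[length(yy)] - yy[1]) *
        (tt - tt[1]) / (tt[length(tt)] - tt[1])
      a <- trapezoid(tt, yy - base)
      tibble::tibble(analyte_id = analyte_id,
                     area = max(a, 0),
                     clipped = a < 0)
    }
  )
}

#' Signal-to-noise ratio of a chromatographic peak
#'
#' Peak height above the local linear baseline of its window, divided by the
#' standard deviation of the signal in a peak-free noise region. A noiseless
#' trace yields `Inf` with a warning rather than an error.
#'
#' @param chrom A chromatogram.
#' @param window Numeric `c(t_start, t_end)` containing the peak.
#' @param noise_region Numeric `c(t_start, t_end)` containing no peaks.
#' @return A single S/N ratio.
#' @export
snr <- function(chrom, window, noise_region) {
  trace <- chrom$trace
  pk <- which(trace$time >= window[1] & trace$time <= window[2])
  nz <- which(trace$time >= noise_region[1] & trace$time <= noise_region[2])
  abort_if(length(pk) < 2, "peak window is empty.")
  abort_if(length(nz) < 2, "noise region is empty.")
  tt <- trace$time[pk]
  yy <- trace$signal[pk]
  base <- yy[1] + (yy[length(yy)] - yy[1]) *
    (tt - tt[1]) / (tt[length(tt)] - tt[1])
  height <- max(yy - base)
  noise <- stats::sd(trace$signal[nz])
  if (noise == 0) {
    rlang::warn("noise region has zero variance; S/N is infinite.")
    return(Inf)
  }
  height / noise
}

#' @method autoplot chromatogram
#' @export
autoplot.chromatogram <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace, ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "detector response")
  if (nrow(object$truth) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$truth,
      ggplot2::aes(xintercept = .data$retention_time),
      linetype = "dotted", colour = "grey60"
    )
  }
  p
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %d points over %.2f-%.2f min, %d peak(s), noise sd %g\n",
    nrow(x$trace), min(x$trace$time), max(x$trace$time), nrow(x$truth),
    x$noise_sd
  ))
  invisible(x)
}
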