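test_that("a noiseless Gaussian peak integrates to its analytic area", {
  sp <- peak_spec("a", retention_time = 10, width_sigma = 0.15,
                  true_amount = 3, height_scale = 7)
  ch <- simulate_chromatogram(sp, t_min = 0, t_max = 20, dt = 0.005)
  analytic <- 3 * 7
  whole <- with(ch$trace, sum(diff(time) * (signal[-1] + signal[-length(signal)]) / 2))
  expect_lt(abs(whole - analytic) / analytic, 0.001)
  got <- integrate_peaks(ch, peak_windows(sp))
  expect_lt(abs(got$area - analytic) / analytic, 0.005)
  expect_false(got$clipped)
})

test_that("a blank run reproduces its baseline exactly", {
  ch <- simulate_chromatogram(peak_spec("x", 1, 1, 0)[0, ],
                              t_min = 0, t_max = 5, dt = 0.01,
                              baseline_start = 2, baseline_drift = 0.5)
  expect_equal(ch$trace$signal, 2 + 0.5 * ch$trace$time)
  flat <- integrate_peaks(ch, tibble::tibble(analyte_id = "w",
                                             t_start = 1, t_end = 4))
  expect_equal(flat$area, 0, tolerance = 1e-12)
})

test_that("overlapping peaks integrate to the sum of analytic areas (quadrature oracle)", {
  specs <- dplyr::bind_rows(
    peak_spec("a", retention_time = 10.0, width_sigma = 0.2, true_amount = 2,
              height_scale = 5),
    peak_spec("b", retention_time = 10.4, width_sigma = 0.2, true_amount = 1,
              height_scale = 5)
  )
  ch <- simulate_chromatogram(specs, t_min = 5, t_max = 15, dt = 0.002)
  total <- with(ch$trace, sum(diff(time) * (signal[-1] + signal[-length(signal)]) / 2))
  f <- function(t) {
    2 * 5 * stats::dnorm(t, 10.0, 0.2) + 1 * 5 * stats::dnorm(t, 10.4, 0.2)
  }
  oracle <- stats::integrate(f, 5, 15, rel.tol = 1e-10)$value
  expect_equal(total, oracle, tolerance = 1e-4)
  expect_equal(oracle, 2 * 5 + 1 * 5, tolerance = 1e-6)
})

test_that("invalid peak and grid parameters are rejected", {
  expect_error(peak_spec("a", retention_time = -1, width_sigma = 0.1,
                         true_amount = 1), "retention_time")
  expect_error(peak_spec("a", retention_time = 1, width_sigma = 0,
                         true_amount = 1), "width_sigma")
  sp <- peak_spec("a", 5, 0.1, 1)
  expect_error(simulate_chromatogram(sp, dt = 0), "dt")
  expect_error(simulate_chromatogram(sp, t_min = 3, t_max = 2), "t_max")
})

test_that("windows outside the grid raise an error naming the window", {
  sp <- peak_spec("a", 5, 0.1, 1)
  ch <- simulate_chromatogram(sp, t_min = 0, t_max = 10, dt = 0.01)
  expect_error(
    integrate_peaks(ch, tibble::tibble(analyte_id = "late",
                                       t_start = 9, t_end = 12)),
    "late"
  )
  expect_error(
    integrate_peaks(ch, tibble::tibble(analyte_id = c("a", "b"),
                                       t_start = c(4, 4.5),
                                       t_end = c(5, 5.5))),
    "overlap"
  )
})

test_that("signal-to-noise matches brute-force recomputation and handles zero noise", {
  sp <- peak_spec("a", retention_time = 5, width_sigma = 0.1,
                  true_amount = 100 * 0.1 * sqrt(2 * pi), height_scale = 1)
  # height at apex = amount * scale / (sigma * sqrt(2*pi)) = 100
  ch <- simulate_chromatogram(sp, t_min = 0, t_max = 10, dt = 0.005,
                              noise_sd = 5, seed = 42)
  got <- snr(ch, window = c(4.5, 5.5), noise_region = c(7, 9))
  # brute force from the raw arrays
  tr <- ch$trace
  pk <- tr[tr$time >= 4.5 & tr$time <= 5.5, ]
  base <- pk$signal[1] + (pk$signal[nrow(pk)] - pk$signal[1]) *
    (pk$time - pk$time[1]) / (pk$time[nrow(pk)] - pk$time[1])
  nz <- tr$signal[tr$time >= 7 & tr$time <= 9]
  expect_equal(got, max(pk$signal - base) / stats::sd(nz))
  expect_equal(got, 20, tolerance = 0.25)

  quiet <- simulate_chromatogram(sp, t_min = 0, t_max = 10, dt = 0.005)
  expect_warning(sn <- snr(quiet, c(4.5, 5.5), c(9, 10)), "infinite")
  expect_identical(sn, Inf)
  expect_error(snr(quiet, c(20, 21), c(9, 10)), "empty")
})
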