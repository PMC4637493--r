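test_that("the correction factor follows its defining ratio", {
  expect_equal(compute_rcf(w_k = 5, a_k = 9, w_m = 5, a_m = 9), 1)
  f0 <- compute_rcf(100, 2000, 80, 1500)
  expect_equal(compute_rcf(100, 2000, 80, 3000), 2 * f0)
  expect_equal(compute_rcf(100, 4000, 80, 1500), f0 / 2)
  # noiseless published-slope responses at 100 ug/mL
  f <- compute_rcf(w_k = 100, a_k = 28072 * 100 - 228.09,
                   w_m = 100, a_m = 9536 * 100 - 72.258)
  expect_equal(f, 953527.742 / 2806971.91, tolerance = 1e-12)
  expect_equal(round(f, 5), 0.33970)
  expect_error(compute_rcf(-1, 1, 1, 1), "w_k")
  expect_error(compute_rcf(1, 1, 1, 0), "a_m")
})

test_that("correction factor and single-marker inversion are exact inverses", {
  withr::local_seed(21)
  for (i in 1:20) {
    w_k <- runif(1, 1, 500); a_k <- runif(1, 1e3, 1e7)
    w_m <- runif(1, 1, 500); a_m <- runif(1, 1e3, 1e7)
    f <- compute_rcf(w_k, a_k, w_m, a_m)
    expect_equal(qams_concentration(f, a_m, w_k, a_k), w_m,
                 tolerance = 1e-12)
  }
  expect_equal(qams_concentration(f = 1, a_m = 7, w_k = 42, a_k = 7), 42)
  expect_error(qams_concentration(0, 1, 1, 1), "`f`")
})

test_that("f is invariant to common detector-gain and concentration rescalings", {
  f0 <- compute_rcf(120, 3.3e6, 95, 8.1e5)
  expect_equal(compute_rcf(120, 3.3e6 * 4.2, 95, 8.1e5 * 4.2), f0)
  expect_equal(compute_rcf(120 * 0.3, 3.3e6, 95 * 0.3, 8.1e5), f0)
})

test_that("per-volume f values condense to published means and RSDs", {
  tab <- rcf_volume_table()
  s <- rcf_summary(tab)
  iso <- s[s$analyte_id == "isobavachin", ]
  expect_equal(round(iso$mean_f, 3), 0.683)
  expect_equal(round(iso$rsd_percent, 1), 3.5)
  ibc <- s[s$analyte_id == "isobavachalcone", ]
  expect_equal(round(ibc$mean_f, 2), 1.98)
  expect_equal(round(ibc$rsd_percent, 1), 2.3)
  # per-condition values preserved in input order
  expect_identical(attr(s, "values")$f, tab$f)
  expect_equal(rcf_summary(tibble::tibble(f = c(2, 2, 2)))$rsd_percent, 0)
  expect_error(rcf_summary(tibble::tibble(f = 1)), ">= 2")
})

test_that("system-to-system spread matches hand arithmetic", {
  rob <- rcf_robustness(rcf_condition_table())
  iso <- rob[rob$analyte_id == "isobavachin", ]
  expect_equal(iso$spread_percent, 100 * (0.688 - 0.672) / 0.67975,
               tolerance = 1e-9)
  expect_equal(round(iso$spread_percent, 2), 2.35)

  same <- tibble::tibble(instrument_id = c("i1", "i2"), column_id = "c",
                         analyte_id = "a", f = c(1, 1))
  expect_equal(rcf_robustness(same)$spread_percent, 0)
  two <- tibble::tibble(instrument_id = c("i1", "i2"), column_id = "c",
                        analyte_id = "a", f = c(1.0, 1.1))
  expect_equal(rcf_robustness(two)$spread_percent, 100 * 0.1 / 1.05,
               tolerance = 1e-9)
  expect_error(rcf_robustness(two[1, ]), ">= 2")
})

test_that("estimate_rcf pairs marker and analyte within the same condition", {
  st <- gen_study(study_truth(noise_cv = 0))
  rcf <- estimate_rcf(st$standards, panel = st$truth$panel)
  # noiseless + matched volumes: f reduces to the same value at every volume
  spread <- rcf |>
    dplyr::summarise(d = max(f) - min(f), .by = "analyte_id")
  expect_true(all(spread$d < 1e-12))
  # excluded analytes and the marker itself never get a factor
  expect_false(any(rcf$analyte_id %in%
                     c("neobavaisoflavone", "corylin", "bavachalcone")))
  # manual check at one volume
  one <- st$standards |>
    dplyr::filter(injection_volume_ul == 10, replicate == 1)
  k <- one[one$analyte_id == "neobavaisoflavone", ]
  m <- one[one$analyte_id == "bavachin", ]
  f_manual <- compute_rcf(k$concentration, k$area, m$concentration, m$area)
  f_pkg <- rcf$f[rcf$analyte_id == "bavachin" &
                   rcf$injection_volume_ul == 10]
  expect_equal(f_pkg, f_manual, tolerance = 1e-12)
})

test_that("accuracy reproduces published cells and handles edge cases", {
  expect_equal(accuracy(4.229, 4.367), 96.84)
  expect_equal(accuracy(1.323, 1.208), 109.5)
  expect_equal(accuracy(5, 5), 100)
  expect_error(accuracy(1, 0), "w_es")
  expect_error(accuracy(-1, 1), "w_qams")
})

test_that("single-marker quantification needs the marker on every run", {
  st <- gen_study(study_truth(noise_cv = 0))
  curves <- fit_calibration(st$calibration)
  rcf <- rcf_summary(estimate_rcf(st$standards, panel = st$truth$panel))
  no_marker <- dplyr::filter(st$samples,
                             !(sample_id == "S3" &
                                 analyte_id == "neobavaisoflavone"))
  expect_error(quantify_qams(no_marker, rcf, curves, sample_prep()), "S3")
})
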