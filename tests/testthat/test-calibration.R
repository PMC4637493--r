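test_that("an exact line is recovered exactly", {
  pts <- tibble::tibble(analyte_id = "x", concentration = c(1, 2, 3),
                        area = c(3, 5, 7))
  cv <- fit_calibration(pts)
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 1)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$residual_sd, 0)
  expect_equal(cv$lod, 0)
  expect_equal(cv$loq, 0)
  expect_equal(cv$n_levels, 3L)
})

test_that("noiseless levels generated from a published curve recover its parameters", {
  conc <- exp(seq(log(16.88), log(270), length.out = 6))
  pts <- tibble::tibble(analyte_id = "neobavaisoflavone",
                        concentration = conc,
                        area = 28072 * conc - 228.09)
  cv <- fit_calibration(pts)
  expect_equal(cv$slope, 28072, tolerance = 1e-9)
  expect_equal(cv$intercept, -228.09, tolerance = 1e-6)
  expect_equal(cv$range_low, 16.88)
  expect_equal(cv$range_high, 270)
})

test_that("noisy fits agree with a hand-coded normal-equations oracle", {
  withr::local_seed(7)
  for (i in 1:5) {
    x <- runif(8, 5, 300)
    y <- 900 * x + 50 + rnorm(8, sd = 40)
    cv <- fit_calibration(tibble::tibble(analyte_id = "z",
                                         concentration = x, area = y))
    o <- ols_oracle(x, y)
    expect_equal(cv$slope, o$slope, tolerance = 1e-10)
    expect_equal(cv$intercept, o$intercept, tolerance = 1e-10)
  }
})

test_that("detection and quantification limits keep the 10:3 convention", {
  out <- lod_loq(residual_sd = c(0, 12.5, 3.1), slope = c(100, 100, 7))
  expect_equal(out$lod[1], 0)
  expect_equal(out$loq[1], 0)
  expect_equal(out$loq[-1] / out$lod[-1], c(10 / 3, 10 / 3))
  expect_error(lod_loq(1, 0), "slope")
  expect_error(lod_loq(-1, 10), "residual_sd")
  # published isobavachin pair is consistent with the same convention
  expect_equal(8.718 / 2.615, 10 / 3, tolerance = 0.01)
})

test_that("inversion round-trips the fit and flags out-of-range areas", {
  conc <- c(10, 20, 50, 100, 200)
  cv <- fit_calibration(tibble::tibble(analyte_id = "a", concentration = conc,
                                       area = 500 * conc - 30))
  probe <- tibble::tibble(analyte_id = "a",
                          area = 500 * c(15, 120, 350) - 30)
  got <- invert_calibration(probe, cv)
  expect_equal(got$concentration, c(15, 120, 350), tolerance = 1e-9)
  expect_equal(got$qualifier, c("ok", "ok", "above_range"))

  at_intercept <- invert_calibration(
    tibble::tibble(analyte_id = "a", area = cv$intercept), cv
  )
  expect_equal(at_intercept$concentration, 0)
  expect_equal(at_intercept$qualifier, "below_loq")
  expect_error(invert_calibration(tibble::tibble(analyte_id = "a", area = NA_real_), cv),
               "non-finite")
  expect_error(invert_calibration(tibble::tibble(analyte_id = "nope", area = 1), cv),
               "nope")
})

test_that("a published-scale area inverts to the hand-computed concentration", {
  conc <- exp(seq(log(16.88), log(270), length.out = 6))
  cv <- fit_calibration(tibble::tibble(
    analyte_id = "neobavaisoflavone", concentration = conc,
    area = 28072 * conc - 228.09
  ))
  got <- invert_calibration(
    tibble::tibble(analyte_id = "neobavaisoflavone", area = 2579000), cv
  )
  expect_equal(got$concentration, (2579000 + 228.09) / 28072, tolerance = 1e-9)
  expect_equal(round(got$concentration, 2), 91.88)
})

test_that("noise never pushes R-squared above one", {
  withr::local_seed(11)
  for (i in 1:10) {
    x <- seq(10, 100, length.out = 6)
    y <- 50 * x + 10 + rnorm(6, sd = 20)
    cv <- fit_calibration(tibble::tibble(analyte_id = "a",
                                         concentration = x, area = y))
    expect_lte(cv$r_squared, 1)
    expect_gte(cv$r_squared, 0)
  }
})

test_that("degenerate designs fail naming the analyte", {
  expect_error(
    fit_calibration(tibble::tibble(analyte_id = "few",
                                   concentration = c(1, 2), area = c(1, 2))),
    "few"
  )
  expect_error(
    fit_calibration(tibble::tibble(analyte_id = "flat",
                                   concentration = c(1, 1, 1),
                                   area = c(1, 2, 3))),
    "flat"
  )
})

test_that("tidy and glance expose broom-style summaries", {
  st <- gen_study(study_truth(noise_cv = 0))
  cv <- fit_calibration(st$calibration)
  td <- tidy(cv)
  expect_setequal(unique(td$term), c("slope", "intercept"))
  expect_equal(nrow(td), 2 * nrow(cv))
  gl <- glance(cv)
  expect_true(all(gl$r.squared > 0.999))
  expect_s3_class(autoplot(cv), "ggplot")
})
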