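test_that("content conversion follows the prep dimensional analysis", {
  expect_equal(content_from_concentration(43.67, sample_prep(0.1, 10)), 4.367)
  expect_equal(content_from_concentration(50, sample_prep(0.5, 10)), 1.000)
  expect_equal(content_from_concentration(0, sample_prep()), 0)
  expect_error(sample_prep(mass_g = -1), "mass_g")
})

test_that("the noiseless external-standard pipeline recovers every true content", {
  tr <- study_truth(noise_cv = 0)
  st <- gen_study(tr)
  curves <- fit_calibration(st$calibration)
  es <- quantify_batch(st$samples, curves, sample_prep(tr$mass_g, tr$volume_ml))
  chk <- dplyr::left_join(
    es, dplyr::rename(tr$contents, truth = content),
    by = c("sample_id", "analyte_id")
  )
  pos <- chk$truth > 0
  expect_lt(max(abs(chk$content[pos] - chk$truth[pos]) / chk$truth[pos]), 1e-9)
  # true blanks come back flagged, not imputed
  expect_true(all(chk$qualifier[chk$truth == 0] == "below_loq"))
  expect_true(all(chk$content[chk$truth == 0] < 1e-12))
})

test_that("one below-LOQ analyte does not disturb the others", {
  conc <- c(10, 50, 100)
  cal <- tidyr::expand_grid(analyte_id = c("a", "b"), concentration = conc) |>
    dplyr::mutate(area = 100 * concentration)
  curves <- fit_calibration(cal)
  recs <- tibble::tibble(
    sample_id = "s", analyte_id = c("a", "b"), area = c(100 * 50, 0)
  )
  out <- quantify_batch(recs, curves, sample_prep())
  expect_equal(out$qualifier, c("ok", "below_loq"))
  expect_equal(out$content[1], content_from_concentration(50, sample_prep()))
})

test_that("output has one row per (sample, analyte) in panel order", {
  st <- gen_study(study_truth(noise_cv = 0.02), seed = 3)
  curves <- fit_calibration(st$calibration)
  es <- quantify_batch(st$samples, curves, sample_prep())
  expect_equal(nrow(es),
               dplyr::n_distinct(st$samples$sample_id) *
                 dplyr::n_distinct(st$samples$analyte_id))
  expect_equal(unique(es$analyte_id[es$sample_id == "S1"]),
               curves$analyte_id)
})

test_that("contents are invariant to a common rescaling of area units", {
  st <- gen_study(study_truth(noise_cv = 0.01), seed = 8)
  curves1 <- fit_calibration(st$calibration)
  es1 <- quantify_batch(st$samples, curves1, sample_prep())
  scaled_cal <- dplyr::mutate(st$calibration, area = area * 7.3)
  scaled_samples <- dplyr::mutate(st$samples, area = area * 7.3)
  es2 <- quantify_batch(scaled_samples, fit_calibration(scaled_cal),
                        sample_prep())
  expect_equal(es2$content, es1$content, tolerance = 1e-12)
})

test_that("replicate areas are averaged before inversion", {
  cal <- tibble::tibble(analyte_id = "a", concentration = c(10, 50, 100),
                        area = 100 * c(10, 50, 100))
  curves <- fit_calibration(cal)
  reps <- tibble::tibble(sample_id = "s", analyte_id = "a",
                         replicate = 1:2, area = c(4000, 6000))
  single <- tibble::tibble(sample_id = "s", analyte_id = "a", area = 5000)
  expect_equal(quantify_batch(reps, curves, sample_prep())$content,
               quantify_batch(single, curves, sample_prep())$content)
})

test_that("a missing curve fails listing the analytes", {
  cal <- tibble::tibble(analyte_id = "a", concentration = c(10, 50, 100),
                        area = 100 * c(10, 50, 100))
  curves <- fit_calibration(cal)
  recs <- tibble::tibble(sample_id = "s", analyte_id = c("a", "mystery"),
                         area = c(1000, 1000))
  expect_error(quantify_batch(recs, curves, sample_prep()), "mystery")
})
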