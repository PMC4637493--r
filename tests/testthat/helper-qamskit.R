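# generate a study while muffling the expected out-of-range note
# (low-content cells legitimately fall under some calibration ranges)
gen_study <- function(truth, seed = truth$seed) {
  withCallingHandlers(
    generate_study(truth, seed),
    qamskit_range_warning = function(w) invokeRestart("muffleWarning")
  )
}

# independent closed-form OLS via the normal equations (oracle; never calls
# the package's fitting path)
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# end-to-end single-marker run on a study bundle; returns the accuracy table
run_comparison <- function(study) {
  curves <- fit_calibration(study$calibration)
  prep <- sample_prep(study$truth$mass_g, study$truth$volume_ml)
  es <- quantify_batch(study$samples, curves, prep)
  rcf <- estimate_rcf(study$standards, panel = study$truth$panel)
  qams <- quantify_qams(study$samples, rcf_summary(rcf), curves, prep)
  compare_methods(qams, es)
}

zero_intercept_panel <- function() {
  p <- pc_panel()
  p$intercept <- 0
  p
}
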