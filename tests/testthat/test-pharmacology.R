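test_that("normalization to the first response is exact and idempotent", {
  m <- tibble::tibble(roi_id = rep("a", 3), trial_index = 1:3,
                      amplitude_pct = c(4, 4, 10))
  nm <- normalize_amplitudes(m)
  expect_equal(nm$norm_amplitude_pct, c(100, 100, 250))

  # idempotence: renormalizing the normalized values is the identity
  m2 <- nm
  m2$amplitude_pct <- m2$norm_amplitude_pct
  expect_equal(normalize_amplitudes(m2)$norm_amplitude_pct,
               nm$norm_amplitude_pct)
})

test_that("ROIs with non-positive first response are excluded with warning", {
  m <- tibble::tibble(roi_id = rep(c("a", "b"), each = 2),
                      trial_index = rep(1:2, 2),
                      amplitude_pct = c(5, 6, -0.2, 3))
  expect_warning(nm <- normalize_amplitudes(m), "b")
  expect_identical(unique(nm$roi_id), "a")
})

test_that("trial-1 normalized amplitude is identically 100%", {
  sim <- scenario_pharm_slice(n_rois = 8, drug_factor = 1.43, seed = 3)
  prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
  m <- measure_amplitude_at_cohort_peak(prep$epochs, 120, smooth_s = 45)
  nm <- normalize_amplitudes(m)
  expect_true(all(nm$norm_amplitude_pct[nm$trial_index == 1] == 100))
})

test_that("identical responses across trials raise no flags", {
  m <- tibble::tibble(roi_id = rep(letters[1:6], each = 3),
                      trial_index = rep(1:3, 6),
                      amplitude_pct = rep(c(5, 5, 5), 6))
  sc <- summarize_condition(normalize_amplitudes(m))
  expect_true(all(!sc$sig_vs_trial1))
  expect_true(all(!sc$sig_vs_trial2))
  expect_true(all(sc$flags == ""))
  expect_equal(sc$mean_norm_pct, rep(100, 3))
})

test_that("a yohimbine-like drug factor is recovered and flagged", {
  sim <- scenario_pharm_slice(n_rois = 21, drug_factor = 1.43, seed = 19)
  prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
  m <- measure_amplitude_at_cohort_peak(prep$epochs, 120, smooth_s = 45)
  sc <- summarize_condition(normalize_amplitudes(m),
                            experiment_design(c("control", "control",
                                                "drug"),
                                              drug = "alpha2 antagonist"))
  t3 <- sc[sc$trial_index == 3, ]
  expect_lt(abs(t3$mean_norm_pct - 143) / 143, 0.15)
  expect_true(t3$sig_vs_trial1)
  expect_true(t3$sig_vs_trial2)
  expect_equal(t3$flags, "*+")
  expect_equal(t3$condition, "drug")
  # control trials are never flagged against themselves
  expect_false(sc$sig_vs_trial1[1])
})

test_that("a null drug trial is not flagged at the nominal rate", {
  # light calibration here; the acceptance suite runs 50 seeds
  flags <- vapply(1:10, function(s) {
    sim <- scenario_pharm_slice(n_rois = 20, drug_factor = 1, seed = s)
    prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
    m <- measure_amplitude_at_cohort_peak(prep$epochs, 120, smooth_s = 45)
    sc <- summarize_condition(normalize_amplitudes(m))
    sc$sig_vs_trial1[sc$trial_index == 3]
  }, logical(1))
  expect_lte(sum(flags), qbinom(0.999, 10, 0.05) + 1)
})

test_that("fewer than three ROIs suppresses the tests but not the summary", {
  m <- tibble::tibble(roi_id = rep(c("a", "b"), each = 3),
                      trial_index = rep(1:3, 2),
                      amplitude_pct = c(4, 4, 9, 5, 5, 12))
  sc <- summarize_condition(normalize_amplitudes(m))
  expect_true(all(is.na(sc$p_vs_trial1)))
  expect_equal(sc$mean_norm_pct[3], mean(c(900 / 4, 1200 / 5)))
})

test_that("fsk_fraction relates the response to the saturation plateau", {
  expect_equal(round(fsk_fraction(7.4, 25.7), 3), 0.288)
  expect_equal(fsk_fraction(25.7, 25.7), 1)
  expect_equal(fsk_fraction(0, 25.7), 0)
  expect_true(is.na(fsk_fraction(7.4, NA)))
  expect_error(fsk_fraction(7.4, 0), "> 0")
})

test_that("a slowed drug-trial kernel shifts the modal time-to-peak bin", {
  slow <- response_kernel(7.4, 25, 189.2, form = "piecewise",
                          rise_duration_s = 105)
  sim <- scenario_pharm_slice(n_rois = 12, drug_factor = 2.51,
                              drug_kernel = slow, seed = 8)
  prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
  mk <- epoch_kinetics(prep$epochs, 150, smooth_s = 45)
  rep_ <- kinetics_shift_report(mk)
  expect_equal(rep_$modal_bin[1], "[60-90]")
  expect_equal(rep_$modal_bin[3], "[90-120]")
  expect_true(rep_$sig_peak_vs_trial1[3])
  expect_true(rep_$sig_peak_vs_trial2[3])
  expect_false(rep_$sig_peak_vs_trial1[2])

  # identical kinetics across trials: no flags
  sim0 <- scenario_pharm_slice(n_rois = 12, drug_factor = 1, seed = 8)
  prep0 <- preprocess_traceset(sim0$traces, analysis_defaults("slice"))
  mk0 <- epoch_kinetics(prep0$epochs, 120, smooth_s = 45)
  rep0 <- kinetics_shift_report(mk0)
  expect_false(any(rep0$sig_peak_vs_trial1[3]))
})

test_that("trials whose decay fits all failed report tau as absent", {
  m <- tibble::tibble(
    roi_id = rep(c("a", "b", "c"), each = 2),
    trial_index = rep(1:2, 3),
    t_peak_s = rep(75, 6),
    decay_tau_s = c(170, NA, 180, NA, 175, NA),
    decay_status = rep(c("ok", "failed"), 3))
  rep_ <- kinetics_shift_report(m)
  expect_false(is.na(rep_$mean_decay_tau_s[1]))
  expect_true(is.na(rep_$mean_decay_tau_s[2]))
  expect_equal(rep_$n_decay, c(3, 0))
})

test_that("experiment designs are validated", {
  expect_error(experiment_design(c("drug", "control")), "control")
  d <- experiment_design(c("control", "saline", "drug"),
                         drug = "propranolol", dose = "4 mg/kg")
  expect_equal(d$condition, c("control", "saline", "drug"))
  expect_equal(d$drug[3], "propranolol")
})
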