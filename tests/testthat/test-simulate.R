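test_that("noiseless FRET ratio recovers the injected signal exactly", {
  for (gamma in c(0, 0.37, 1)) {
    prot <- slice_protocol(2)
    pop <- population_spec(3, 1)
    acq <- acquisition_spec(1 / 15, 1400, mode = "fret", noise_sd_pct = 0,
                            fret_gain_split = gamma, seed = 7)
    sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
    norm <- normalize_to_baseline(compute_ratio(sim$traces))
    tt <- sim$traces$time_s
    unit <- response_kernel(1, 15, 178.4, form = "piecewise",
                            rise_duration_s = 75)
    for (i in 1:3) {
      realized <- sim$ground_truth$trials[
        sim$ground_truth$trials$roi_id == sim$ground_truth$rois$roi_id[i], ]
      injected <- realized$realized_amplitude_pct[1] *
        response_kernel_eval(unit, tt, 120) +
        realized$realized_amplitude_pct[2] *
        response_kernel_eval(unit, tt, 720)
      expect_lt(max(abs(norm$signal_pct[i, ] - injected) /
                      pmax(abs(injected), 1)), 1e-9)
    }
  }
})

test_that("gamma = 1 puts the whole signal on the acceptor channel", {
  prot <- slice_protocol(1)
  pop <- population_spec(2, 1)
  acq <- acquisition_spec(1 / 15, 700, mode = "fret", noise_sd_pct = 0,
                          fret_gain_split = 1, seed = 2)
  sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
  don <- sim$traces$channels$donor
  expect_equal(max(don) - min(don), 0, tolerance = 1e-12)
})

test_that("non-responders have zero realized amplitude in all trials", {
  prot <- quick_protocol(3)
  pop <- population_spec(50, responder_fraction = 0)
  acq <- acquisition_spec(2, 300, mode = "single", noise_sd_pct = 1,
                          seed = 5)
  sim <- simulate_traceset(prot, pop, acq,
                           response_kernel(5, 5, 25, form = "piecewise",
                                           rise_duration_s = 15))
  expect_true(all(sim$ground_truth$trials$realized_amplitude_pct == 0))
  expect_true(all(!sim$ground_truth$rois$responsive))
})

test_that("realized amplitudes obey the multiplicative model exactly", {
  prot <- slice_protocol(5)
  pop <- population_spec(12, 0.7,
                         rundown_factors = rundown_layer5(),
                         drug_schedule = c(1, 1, 2.51, 1, 0.5))
  acq <- acquisition_spec(1 / 15, 3200, mode = "fret", seed = 11)
  sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
  gt <- sim$ground_truth
  base <- gt$rois$base_amplitude_pct[match(gt$trials$roi_id,
                                           gt$rois$roi_id)]
  expect_equal(gt$trials$realized_amplitude_pct,
               base * gt$trials$rundown_factor * gt$trials$drug_factor,
               tolerance = 1e-12)
  # layer-V defaults: trial 3 / trial 1 realized ratio for responders
  resp <- gt$rois$roi_id[gt$rois$responsive]
  tr <- gt$trials[gt$trials$roi_id %in% resp, ]
  r31 <- tr$realized_amplitude_pct[tr$trial_index == 3] /
    tr$realized_amplitude_pct[tr$trial_index == 1]
  expect_equal(unique(round(r31 / 2.51, 6)), 0.994)
})

test_that("identical seeds reproduce bit-identical trace sets", {
  s1 <- quick_sim(10, 5, seed = 99)
  s2 <- quick_sim(10, 5, seed = 99)
  expect_identical(s1$traces$channels, s2$traces$channels)
  expect_identical(s1$ground_truth$trials, s2$ground_truth$trials)
  s3 <- quick_sim(10, 5, seed = 100)
  expect_false(identical(s1$traces$channels, s3$traces$channels))
})

test_that("population mean amplitude converges to the specified mean", {
  prot <- stimulus_protocol(5, 10, 5, 60)
  pop <- population_spec(4000, 1, amplitude_cv = 0.3)
  acq <- acquisition_spec(1 / 15, 300, mode = "single", noise_sd_pct = 0,
                          seed = 31)
  sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
  m <- mean(sim$ground_truth$rois$base_amplitude_pct)
  se <- 7.4 * 0.3 / sqrt(4000)
  expect_lt(abs(m - 7.4), 4 * se)
  expect_gt(sd(sim$ground_truth$rois$base_amplitude_pct) /
              m, 0.25)  # CV close to requested
})

test_that("configurations driving the donor non-positive are rejected", {
  prot <- stimulus_protocol(5, 10, 5, 60)
  pop <- population_spec(1, 1, amplitude_cv = 0)
  acq <- acquisition_spec(1, 300, mode = "single", seed = 1)
  kern <- response_kernel(-150, 10, 100, form = "piecewise",
                          rise_duration_s = 60)
  expect_error(simulate_traceset(prot, pop, acq, kern), "rejected")
})

test_that("recording must cover onsets plus a decay window", {
  prot <- stimulus_protocol(5, 10, 5, c(60, 660))
  pop <- population_spec(1)
  acq <- acquisition_spec(1 / 15, 700, mode = "fret", seed = 1)
  expect_error(simulate_traceset(prot, pop, acq, slice_kernel(7.4)),
               "decay window")
})

test_that("FSK plateau follows the saturating exponential", {
  acq <- acquisition_spec(1 / 15, 1800, mode = "fret", noise_sd_pct = 0,
                          seed = 4)
  ts <- simulate_fsk_plateau(acq, 25.7, 120, 300)
  norm <- normalize_to_baseline(compute_ratio(ts), c(240, 300))
  tt <- ts$time_s
  # at u = tau_sat the signal is plateau * (1 - 1/e)
  expect_equal(unname(norm$signal_pct[1, tt == 420]),
               25.7 * (1 - exp(-1)),
               tolerance = 1e-6)
  # long after application the signal approaches the plateau, no decay
  expect_equal(unname(norm$signal_pct[1, length(tt)]), 25.7,
               tolerance = 1e-3)
  expect_true(all(diff(norm$signal_pct[1, tt >= 300]) >= -1e-9))
  expect_error(simulate_fsk_plateau(acq, 25.7, 120, 2000), "within")
})
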