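test_that("amplitude is the signed extremum with earliest-tie breaking", {
  rel <- seq(-10, 29, by = 1)
  y1 <- numeric(40)
  y1[rel == 5] <- 3
  y1[rel == 12] <- 3  # tie: earliest wins
  y2 <- numeric(40)
  y2[rel == 8] <- -5  # inverted transient
  ep <- fake_epochs(rbind(y1, y2, 0), rel)
  m <- measure_amplitude(ep, 25)
  expect_equal(m$amplitude_pct, c(3, -5, 0))
  expect_equal(m$t_peak_s, c(5, 8, 0))  # all-zero epoch peaks at first frame
})

test_that("noiseless piecewise amplitude matches the generator within a frame", {
  sim <- noiseless_slice(n_rois = 1, amplitude_pct = 7.4, n_trials = 2)
  prep <- preprocess_traceset(sim$traces,
                              utils::modifyList(analysis_defaults("slice"),
                                                list(smooth_s = NULL)))
  m <- measure_amplitude(prep$epochs, 120)
  # continuous peak is A(1 - exp(-75/15)); sampling can only miss by the
  # within-frame rise/decay, well under 0.15%
  expect_true(all(abs(m$amplitude_pct - 7.4) < 0.15))
  expect_true(all(m$t_peak_s == 75))

  # sign symmetry: inverted kernel gives the negated amplitude
  prot <- slice_protocol(1)
  pop <- population_spec(1, 1, amplitude_cv = 0)
  acq <- acquisition_spec(1 / 15, 700, mode = "single", noise_sd_pct = 0,
                          seed = 1)
  kern <- response_kernel(-5, 15, 178.4, form = "piecewise",
                          rise_duration_s = 75)
  simn <- simulate_traceset(prot, pop, acq, kern)
  norm <- normalize_to_baseline(simn$traces)
  epn <- segment_by_stimulus(norm, 60, 480)
  mn <- measure_amplitude(epn, 120)
  expect_equal(mn$amplitude_pct, -5 * (1 - exp(-75 / 15)),
               tolerance = 1e-9)
})

test_that("time-to-peak bins are half-open, contain the peak and partition", {
  b <- time_to_peak_bin(c(77, 90, 0), 30)
  expect_equal(b$bin_lower_s, c(60, 90, 0))
  expect_equal(b$bin_upper_s, c(90, 120, 30))
  expect_equal(b$bin_label[1], "[60-90]")

  set.seed(7)
  tp <- c(runif(200, 0, 400), seq(0, 390, by = 30))  # include boundaries
  bb <- time_to_peak_bin(tp, 30)
  expect_true(all(tp >= bb$bin_lower_s & tp < bb$bin_upper_s))
  # bins tile [0, inf) with width w
  expect_true(all(bb$bin_upper_s - bb$bin_lower_s == 30))
  expect_true(all(bb$bin_lower_s %% 30 == 0))
  expect_error(time_to_peak_bin(-1), ">= 0")
})

test_that("noiseless fits recover the generator constants to 1e-6", {
  sim <- noiseless_slice(n_rois = 1, n_trials = 1)
  norm <- normalize_to_baseline(compute_ratio(sim$traces))
  ep <- segment_by_stimulus(norm, 60, 480)
  pk <- measure_amplitude(ep, 120)
  de <- fit_decay(ep, peaks = pk)
  expect_equal(de$decay_status, "ok")
  expect_lt(abs(de$decay_tau_s - 178.4) / 178.4, 1e-6)
  on <- fit_onset(ep, peaks = pk)
  expect_equal(on$onset_status, "ok")
  expect_lt(abs(on$onset_tau_s - 15) / 15, 1e-6)

  # in vivo kernel at 6.2 Hz, same exactness for the 14.7-s rise
  prot <- invivo_protocol(1)
  pop <- population_spec(1, 1, amplitude_cv = 0)
  acq <- acquisition_spec(6.2, 400, mode = "single", noise_sd_pct = 0,
                          seed = 1)
  siv <- simulate_traceset(prot, pop, acq, invivo_kernel(5.7))
  niv <- normalize_to_baseline(siv$traces)
  epv <- segment_by_stimulus(niv, 10, 240)
  pkv <- measure_amplitude(epv, 60)
  onv <- fit_onset(epv, peaks = pkv)
  expect_lt(abs(onv$onset_tau_s - 14.7) / 14.7, 1e-6)
  dev <- fit_decay(epv, peaks = pkv)
  expect_lt(abs(dev$decay_tau_s - 154.1) / 154.1, 1e-6)
})

test_that("degenerate epochs fail the fits cleanly", {
  rel <- seq(-10, 100, by = 5)
  flat <- fake_epochs(matrix(0, 1, length(rel)), rel)
  de <- fit_decay(flat, response_window_s = 50)
  expect_equal(de$decay_status, "failed")
  expect_true(is.na(de$decay_tau_s))

  falling <- fake_epochs(rbind(seq(5, 0, length.out = length(rel))), rel)
  on <- fit_onset(falling, response_window_s = 50)
  expect_equal(on$onset_status, "failed")
})

test_that("tau estimate RMSE decreases as noise decreases", {
  taus_rmse <- vapply(c(2, 1, 0.5, 0.25), function(ns) {
    sim <- scenario_slice_layer5(n_rois = 10, noise_sd_pct = ns,
                                 n_trials = 1, seed = 55)
    prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
    de <- fit_decay(prep$epochs, response_window_s = 120, smooth_s = 45)
    ok <- de$decay_status == "ok"
    sqrt(mean((de$decay_tau_s[ok] - 178.4)^2))
  }, numeric(1))
  expect_true(all(diff(taus_rmse) < 0))
})

test_that("pooled mean trace averages pointwise with SEM", {
  rel <- seq(-5, 20, by = 1)
  y <- sin(rel / 5)
  ep <- fake_epochs(rbind(y, y, y), rel)
  pm <- pool_mean_trace(ep)
  expect_equal(pm$mean_pct, y)
  expect_true(all(pm$sem_pct == 0))

  ep2 <- fake_epochs(rbind(y, -y), rel)
  expect_true(all(pool_mean_trace(ep2)$mean_pct == 0))

  single <- fake_epochs(rbind(y), rel)
  expect_true(all(is.na(pool_mean_trace(single)$sem_pct)))
})

test_that("peak of the mean trace cannot exceed the mean of peaks", {
  sim <- scenario_slice_layer5(n_rois = 15, seed = 29)
  prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
  m <- measure_amplitude(prep$epochs, 120)
  pooled <- measure_amplitude(pooled_epoch(prep$epochs), 120)
  expect_lte(pooled$amplitude_pct, mean(m$amplitude_pct) + 1e-9)
})

test_that("epoch_kinetics joins amplitudes, bins and both fits", {
  sim <- scenario_slice_layer5(n_rois = 4, n_trials = 2, seed = 13)
  prep <- preprocess_traceset(sim$traces, analysis_defaults("slice"))
  mk <- epoch_kinetics(prep$epochs, 120, smooth_s = 45)
  expect_equal(nrow(mk), 8)
  expect_true(all(c("amplitude_pct", "t_peak_bin", "onset_tau_s",
                    "decay_tau_s", "decay_status") %in% names(mk)))
  ok <- mk$decay_status == "ok"
  expect_true(all(mk$t_peak_s[ok] >= mk$t_peak_bin_lower_s[ok] &
                    mk$t_peak_s[ok] < mk$t_peak_bin_upper_s[ok]))
})
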