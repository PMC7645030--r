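make_fret_ts <- function(acc, don, time_s = NULL, protocol = NULL) {
  acc <- rbind(acc)
  don <- rbind(don)
  if (is.null(time_s)) time_s <- seq(0, by = 15, length.out = ncol(acc))
  traceset(time_s, list(acceptor = acc, donor = don),
           tibble::tibble(roi_id = sprintf("roi%03d", seq_len(nrow(acc))),
                          compartment = "soma"),
           protocol = protocol, mode = "fret")
}

test_that("compute_ratio forms the elementwise ratio and scales as expected", {
  f <- matrix(runif(40, 800, 1200), nrow = 2)
  ts <- make_fret_ts(f, f)
  expect_true(all(compute_ratio(ts)$channels$ratio == 1))

  # doubling the acceptor and halving the donor quadruples the ratio
  ts1 <- make_fret_ts(f, f * 0.8)
  ts2 <- make_fret_ts(2 * f, 0.4 * f)
  expect_equal(compute_ratio(ts2)$channels$ratio,
               4 * compute_ratio(ts1)$channels$ratio, tolerance = 1e-12)
})

test_that("ROIs with non-positive donor samples are excluded with warning", {
  f <- matrix(1000, nrow = 3, ncol = 10)
  d <- f
  d[2, 4] <- 0
  ts <- make_fret_ts(f, d)
  expect_warning(r <- compute_ratio(ts), "roi002")
  expect_equal(nrow(r$roi_meta), 2)
  expect_false("roi002" %in% r$roi_meta$roi_id)
})

test_that("baseline normalization yields percent change with zero baseline", {
  prot <- stimulus_protocol(5, 10, 5, 90)
  x <- matrix(1000, nrow = 1, ncol = 20)
  x[1, 11:20] <- 1074  # baseline * 1.074 after the stimulus
  ts <- traceset(seq(0, by = 15, length.out = 20), list(green = x),
                 tibble::tibble(roi_id = "r1", compartment = "soma"),
                 protocol = prot, mode = "single")
  norm <- normalize_to_baseline(ts, c(0, 90))
  expect_equal(max(norm$signal_pct), 7.4, tolerance = 1e-9)
  expect_equal(mean(norm$signal_pct[1, 1:7]), 0, tolerance = 1e-12)

  # constant trace gives identically zero signal
  tsc <- traceset(seq(0, 285, by = 15),
                  list(green = matrix(500, 1, 20)),
                  tibble::tibble(roi_id = "r1", compartment = "soma"),
                  mode = "single")
  expect_true(all(normalize_to_baseline(tsc, c(0, 90))$signal_pct == 0))

  # a 2% dip maps to -2%
  xd <- matrix(1000, 1, 20)
  xd[1, 15] <- 980
  tsd <- traceset(seq(0, 285, by = 15), list(green = xd),
                  tibble::tibble(roi_id = "r1", compartment = "soma"),
                  mode = "single")
  expect_equal(min(normalize_to_baseline(tsd, c(0, 90))$signal_pct), -2,
               tolerance = 1e-12)
})

test_that("normalization is invariant to common intensity scaling", {
  sim <- quick_sim(4, 5, seed = 3)
  ts <- sim$traces
  ts2 <- ts
  ts2$channels$green <- ts$channels$green * 37.5
  n1 <- normalize_to_baseline(ts)
  n2 <- normalize_to_baseline(ts2)
  expect_equal(n1$signal_pct, n2$signal_pct, tolerance = 1e-12)
})

test_that("baseline window validation rejects bad windows", {
  sim <- quick_sim(2, 5, seed = 3)
  expect_error(normalize_to_baseline(sim$traces, c(-50, -10)), "outside")
  expect_error(normalize_to_baseline(sim$traces, c(50, 70)),
               "precede the first trial onset")
  expect_error(normalize_to_baseline(sim$traces, c(59.2, 60)),
               "at least 3 frames")
})

test_that("bleach correction recovers the generator bleach constant", {
  prot <- slice_protocol(2)
  pop <- population_spec(2, responder_fraction = 0)
  acq <- acquisition_spec(1 / 15, 1400, mode = "single", noise_sd_pct = 0,
                          bleach_tau_s = c(green = 2000), seed = 8)
  sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
  bc <- bleach_correct(sim$traces)
  expect_true(all(abs(bc$bleach_fit$tau_s - 2000) / 2000 < 1e-3))
  # corrected trace is flat again
  expect_lt(diff(range(bc$traces$channels$green[1, ])) / 1000, 1e-6)

  # noisy recovery within 10%
  acqn <- acquisition_spec(1 / 15, 1400, mode = "single", noise_sd_pct = 0.2,
                           bleach_tau_s = c(green = 2000), seed = 9)
  simn <- simulate_traceset(prot, pop, acqn, slice_kernel(7.4))
  bcn <- bleach_correct(simn$traces)
  expect_true(all(abs(bcn$bleach_fit$tau_s - 2000) / 2000 < 0.1))
})

test_that("without bleaching the fitted rate is negligible", {
  prot <- slice_protocol(2)
  pop <- population_spec(1, responder_fraction = 0)
  acq <- acquisition_spec(1 / 15, 1400, mode = "single", noise_sd_pct = 0,
                          seed = 8)
  sim <- simulate_traceset(prot, pop, acq, slice_kernel(7.4))
  bc <- bleach_correct(sim$traces)
  expect_true(all(bc$bleach_fit$rate_per_s <= 1e-4))
})

test_that("equal bleaching in both channels leaves the FRET ratio unchanged", {
  prot <- slice_protocol(2)
  pop <- population_spec(2, 1, amplitude_cv = 0)
  mk <- function(tau) {
    acq <- acquisition_spec(1 / 15, 1400, mode = "fret", noise_sd_pct = 0,
                            bleach_tau_s = c(acceptor = tau, donor = tau),
                            seed = 12)
    simulate_traceset(prot, pop, acq, slice_kernel(7.4))$traces
  }
  r_bleached <- compute_ratio(mk(1500))$channels$ratio
  r_clean <- compute_ratio(mk(Inf))$channels$ratio
  expect_equal(r_bleached, r_clean, tolerance = 1e-9)
})

test_that("segmentation yields one epoch per ROI and trial on a shared grid", {
  sim <- quick_sim(90, 5, seed = 17)
  ep <- quick_epochs(sim)
  expect_equal(nrow(ep$signal), 270)
  expect_equal(nrow(ep$info), 270)
  # per-epoch re-baselining: pre-window mean is zero by construction
  pre_means <- rowMeans(ep$signal[, ep$rel_time_s < 0])
  expect_true(all(abs(pre_means) < 1e-10))
})

test_that("overlapping epoch windows are rejected with the feasible maximum", {
  sim <- quick_sim(2, 5, seed = 17)  # trials 80 s apart
  norm <- normalize_to_baseline(sim$traces)
  expect_error(segment_by_stimulus(norm, 15, 75),
               "maximum feasible post window is 65")
  expect_silent(segment_by_stimulus(norm, 15, 60))
})

test_that("tail subtraction removes the preceding-trial residual", {
  # noiseless two-trial slice: trial-2 epoch sits on trial-1's tail
  sim <- noiseless_slice(n_rois = 1, n_trials = 2)
  norm <- normalize_to_baseline(compute_ratio(sim$traces))
  ep <- segment_by_stimulus(norm, 60, 480)
  raw_amp <- measure_amplitude(ep, 120)
  det <- subtract_trial_tails(ep, 120)
  cor_amp <- measure_amplitude(det, 120)
  true_peak <- 7.4 * (1 - exp(-75 / 15))
  # uncorrected trial 2 underestimates; corrected is within 0.5% of truth
  expect_lt(cor_amp$amplitude_pct[cor_amp$trial_index == 2] - true_peak,
            0.02)
  expect_lt(abs(cor_amp$amplitude_pct[cor_amp$trial_index == 2] - true_peak),
            abs(raw_amp$amplitude_pct[raw_amp$trial_index == 2] - true_peak))
  # trial 1 untouched
  expect_equal(cor_amp$amplitude_pct[cor_amp$trial_index == 1],
               raw_amp$amplitude_pct[raw_amp$trial_index == 1])
})
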