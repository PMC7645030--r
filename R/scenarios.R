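#' Reference run-down profiles for slice cohorts
#'
#' Per-trial multiplicative amplitude factors over five consecutive
#' stimulation trials, normalized to the first trial, for layer II/III
#' (marked run-down) and layer V (roughly stable) pyramidal-cell cohorts.
#'
#' @return Numeric vector of length 5 with first entry 1.
#' @export
rundown_layer5 <- function() c(1, 0.914, 0.994, 0.858, 0.996)

#' @rdname rundown_layer5
#' @export
rundown_layer23 <- function() c(1, 0.776, 0.5836, 0.597, 0.531)

#' Default response kernels for the two imaging regimes
#'
#' Piecewise kernels (saturating-exponential rise, single-exponential
#' decay). The slice kernel peaks 75 s after train onset (time-to-peak bin
#' 60-90 s) and decays with tau = 178.4 s; the in vivo kernel rises with
#' tau = 14.7 s over 60 s and decays with tau = 154.1 s.
#'
#' @param amplitude_pct Population mean peak amplitude, % of baseline.
#' @return A [response_kernel()].
#' @export
slice_kernel <- function(amplitude_pct = 7.4) {
  response_kernel(amplitude_pct, tau_rise_s = 15, tau_decay_s = 178.4,
                  form = "piecewise", rise_duration_s = 75)
}

#' @rdname slice_kernel
#' @export
invivo_kernel <- function(amplitude_pct = 5.7) {
  response_kernel(amplitude_pct, tau_rise_s = 14.7, tau_decay_s = 154.1,
                  form = "piecewise", rise_duration_s = 60)
}

#' Default stimulation protocols for the two regimes
#'
#' Slice: 5-ms pulses at 10 Hz for 5 s, trains ~10 min apart. In vivo:
#' 5-ms pulses at 20 Hz for 10 s, trains 5 min apart.
#'
#' @param n_trials Number of stimulation trials.
#' @param first_onset_s Time of the first train onset, s.
#' @param interval_s Interval between train onsets, s.
#' @return A [stimulus_protocol()].
#' @export
slice_protocol <- function(n_trials = 5, first_onset_s = 120,
                           interval_s = 600) {
  stimulus_protocol(5, 10, 5,
                    train_onsets_s = first_onset_s +
                      interval_s * (seq_len(n_trials) - 1),
                    label = "slice burst")
}

#' @rdname slice_protocol
#' @export
invivo_protocol <- function(n_trials = 3, first_onset_s = 90,
                            interval_s = 300) {
  stimulus_protocol(5, 20, 10,
                    train_onsets_s = first_onset_s +
                      interval_s * (seq_len(n_trials) - 1),
                    label = "in vivo burst")
}

#' Per-regime analysis parameter presets
#'
#' Bundles the window and estimator settings the pipeline uses for the two
#' imaging regimes.
#'
#' Slice (FRET, 15-s frame interval): 60-s baseline and per-epoch
#' pre-window, 480-s post window, 120-s peak-search window, 45-s (3-frame)
#' moving average for the peak search. In vivo (single channel, 6.2 Hz):
#' 10-s pre-window, 240-s post window, 60-s peak search, 5-s moving
#' average. Both use 30-s time-to-peak bins, a rank-sum responsiveness test
#' at alpha = 0.05, a 2% peak threshold, and preceding-trial tail
#' subtraction ([subtract_trial_tails()]).
#'
#' The moving average controls the positive bias of the max statistic on
#' noisy traces; see the methods vignette for the choice of spans.
#'
#' @param mode `"slice"` or `"invivo"`.
#' @return Named list of analysis parameters.
#' @export
analysis_defaults <- function(mode = c("slice", "invivo")) {
  mode <- match.arg(mode)
  if (mode == "slice") {
    list(mode = "slice", baseline_s = 60, pre_window_s = 60,
         post_window_s = 480, response_window_s = 120, smooth_s = 45,
         bin_width_s = 30, alpha = 0.05, threshold_pct = 2,
         test = "ranksum", offset = FALSE, detrend_tails = TRUE)
  } else {
    list(mode = "invivo", baseline_s = 60, pre_window_s = 10,
         post_window_s = 240, response_window_s = 60, smooth_s = 5,
         bin_width_s = 30, alpha = 0.05, threshold_pct = 2,
         test = "ranksum", offset = TRUE, detrend_tails = TRUE)
  }
}

#' Canned simulation scenarios
#'
#' Convenience constructors bundling protocol, population, acquisition and
#' kernel for the standard study conditions; each returns the
#' `list(traces, ground_truth)` of [simulate_traceset()].
#'
#' * `scenario_slice_layer5()`: FRET cohort of somatic ROIs at a 15-s frame
#'   interval, five trials with the layer-V run-down profile, mean
#'   first-trial amplitude 7.4%.
#' * `scenario_invivo_dendrites()`: single-channel dendritic cohort at
#'   6.2 Hz, three trials, mean amplitude 5.7%.
#' * `scenario_pharm_slice()`: two control trials plus one drug trial with
#'   multiplicative drug factor `drug_factor`, unit run-down; optionally a
#'   different kernel on the drug trial (`drug_kernel`) for reuptake-block
#'   kinetics.
#' * `scenario_fsk()`: forskolin-saturation FRET recording (returns a
#'   `pk_traceset` only).
#'
#' Default per-frame noise SDs (as % of channel baseline): 0.2 in the slice
#' regime, 1.0 in vivo.
#'
#' @param n_rois Number of ROIs.
#' @param amplitude_pct Population mean amplitude, %.
#' @param responder_fraction Responder probability.
#' @param rundown Per-trial run-down factors.
#' @param noise_sd_pct Per-channel per-frame noise SD, % of baseline.
#' @param n_trials Number of trials.
#' @param seed RNG seed.
#' @return See above.
#' @export
scenario_slice_layer5 <- function(n_rois = 18, amplitude_pct = 7.4,
                                  responder_fraction = 1,
                                  rundown = rundown_layer5(),
                                  noise_sd_pct = 0.2, n_trials = 5,
                                  seed = 1L) {
  prot <- slice_protocol(n_trials)
  pop <- population_spec(n_rois, responder_fraction,
                         compartment_labels = "soma",
                         rundown_factors = rundown[seq_len(n_trials)])
  acq <- acquisition_spec(1 / 15,
                          max(prot$train_onsets_s) + 540,
                          mode = "fret", noise_sd_pct = noise_sd_pct,
                          seed = seed)
  simulate_traceset(prot, pop, acq, slice_kernel(amplitude_pct))
}

#' @rdname scenario_slice_layer5
#' @export
scenario_invivo_dendrites <- function(n_rois = 320, amplitude_pct = 5.7,
                                      responder_fraction = 1,
                                      noise_sd_pct = 1, n_trials = 3,
                                      seed = 1L) {
  prot <- invivo_protocol(n_trials)
  pop <- population_spec(n_rois, responder_fraction,
                         compartment_labels = "dendrite")
  acq <- acquisition_spec(6.2,
                          max(prot$train_onsets_s) + 250,
                          mode = "single", noise_sd_pct = noise_sd_pct,
                          seed = seed)
  simulate_traceset(prot, pop, acq, invivo_kernel(amplitude_pct))
}

#' @rdname scenario_slice_layer5
#' @param drug_factor Multiplicative drug factor applied on the last trial.
#' @param drug_kernel Optional [response_kernel()] replacing the kinetics on
#'   the drug trial.
#' @export
scenario_pharm_slice <- function(n_rois, drug_factor,
                                 amplitude_pct = 7.4, noise_sd_pct = 0.2,
                                 n_trials = 3, drug_kernel = NULL,
                                 seed = 1L) {
  prot <- slice_protocol(n_trials)
  drug <- c(rep(1, n_trials - 1), drug_factor)
  pop <- population_spec(n_rois, 1, compartment_labels = "soma",
                         rundown_factors = rep(1, n_trials),
                         drug_schedule = drug)
  acq <- acquisition_spec(1 / 15, max(prot$train_onsets_s) + 540,
                          mode = "fret", noise_sd_pct = noise_sd_pct,
                          seed = seed)
  trial_kernels <- if (!is.null(drug_kernel)) {
    c(vector("list", n_trials - 1), list(drug_kernel))
  }
  simulate_traceset(prot, pop, acq, slice_kernel(amplitude_pct),
                    trial_kernels = trial_kernels)
}

#' @rdname scenario_slice_layer5
#' @param plateau_pct FSK plateau amplitude, %.
#' @param tau_sat_s Saturation time constant, s.
#' @param application_time_s Bath-application time, s.
#' @param duration_s Recording length, s.
#' @export
scenario_fsk <- function(plateau_pct = 25.7, tau_sat_s = 120,
                         application_time_s = 300, duration_s = 1800,
                         n_rois = 1, noise_sd_pct = 0.2, seed = 1L) {
  acq <- acquisition_spec(1 / 15, duration_s, mode = "fret",
                          noise_sd_pct = noise_sd_pct, seed = seed)
  simulate_fsk_plateau(acq, plateau_pct, tau_sat_s, application_time_s,
                       n_rois = n_rois)
}

#' Preprocess a trace set with a regime's default parameters
#'
#' Runs [compute_ratio()] (FRET mode), optional [bleach_correct()],
#' [normalize_to_baseline()] and [segment_by_stimulus()] in sequence.
#'
#' @param ts A `pk_traceset`.
#' @param params An [analysis_defaults()] list (or a modified copy).
#' @param bleach Apply bleach correction before normalization.
#' @return A list with `normalized` (`pk_normalized`) and `epochs`
#'   (`pk_epochs`).
#' @export
preprocess_traceset <- function(ts, params, bleach = FALSE) {
  stopifnot(inherits(ts, "pk_traceset"))
  if (ts$mode == "fret" && length(ts$channels) == 2) {
    ts <- compute_ratio(ts)
  }
  if (bleach) ts <- bleach_correct(ts)$traces
  on1 <- ts$protocol$train_onsets_s[1]
  norm <- normalize_to_baseline(ts, c(max(on1 - params$baseline_s, 0), on1))
  epochs <- segment_by_stimulus(norm, params$pre_window_s,
                                params$post_window_s)
  if (isTRUE(params$detrend_tails)) {
    epochs <- subtract_trial_tails(epochs, params$response_window_s,
                                   params$smooth_s)
  }
  list(normalized = norm, epochs = epochs)
}
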