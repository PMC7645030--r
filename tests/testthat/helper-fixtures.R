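# Shared fixture builders; everything is generated in code at test time.

# quick single-channel protocol/acquisition at 2 Hz for cheap Monte-Carlo
quick_protocol <- function(n_trials = 3, first_onset_s = 60,
                           interval_s = 80) {
  stimulus_protocol(5, 20, 10,
                    train_onsets_s = first_onset_s +
                      interval_s * (seq_len(n_trials) - 1))
}

quick_sim <- function(n_rois, amplitude_pct, noise_sd_pct = 1,
                      responder_fraction = 1, seed = 1L, n_trials = 3,
                      tau_rise = 5, tau_decay = 25, rise_duration = 15) {
  prot <- quick_protocol(n_trials)
  pop <- population_spec(n_rois, responder_fraction,
                         compartment_labels = "dendrite")
  acq <- acquisition_spec(2, max(prot$train_onsets_s) + 70,
                          mode = "single", noise_sd_pct = noise_sd_pct,
                          seed = seed)
  kern <- response_kernel(amplitude_pct, tau_rise, tau_decay,
                          form = "piecewise",
                          rise_duration_s = rise_duration)
  simulate_traceset(prot, pop, acq, kern)
}

quick_epochs <- function(sim, pre = 15, post = 60) {
  norm <- normalize_to_baseline(sim$traces)
  segment_by_stimulus(norm, pre, post)
}

# hand-built pk_epochs for unit tests of the per-epoch operations
fake_epochs <- function(signal, rel_time_s, trial_index = NULL,
                        roi_id = NULL) {
  signal <- rbind(signal)
  n <- nrow(signal)
  if (is.null(trial_index)) trial_index <- rep(1L, n)
  if (is.null(roi_id)) roi_id <- sprintf("roi%03d", seq_len(n))
  structure(
    list(rel_time_s = rel_time_s, signal = signal,
         info = tibble::tibble(
           epoch_id = paste0(roi_id, "_t", trial_index),
           roi_id = roi_id, trial_index = trial_index,
           compartment = "soma"),
         pre_window_s = -min(rel_time_s), post_window_s = max(rel_time_s),
         trial_onsets_s = NULL, mode = "single"),
    class = "pk_epochs")
}

# noiseless slice fixture shared by the exact-recovery tests
noiseless_slice <- function(n_rois = 1, amplitude_pct = 7.4, seed = 1L,
                            n_trials = 2) {
  prot <- slice_protocol(n_trials)
  pop <- population_spec(n_rois, 1, amplitude_cv = 0,
                         rundown_factors = rep(1, n_trials))
  acq <- acquisition_spec(1 / 15, max(prot$train_onsets_s) + 540,
                          mode = "fret", noise_sd_pct = 0, seed = seed)
  simulate_traceset(prot, pop, acq, slice_kernel(amplitude_pct))
}
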