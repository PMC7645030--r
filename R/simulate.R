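#' Simulate a ground-truthed fluorescence trace set
#'
#' Generates per-ROI fluorescence traces with the statistical structure the
#' analysis pipeline assumes: stimulus-locked PKA transients described by a
#' parametric kernel, per-ROI amplitude heterogeneity, trial-to-trial
#' run-down, per-trial drug modulation, mono-exponential photobleaching, and
#' additive noise. The paired ground truth records, for every ROI and trial,
#' the realized kernel amplitude `base_amplitude * rundown * drug_factor`,
#' so every downstream estimate can be checked against known values.
#'
#' Each ROI is a responder with probability `population$responder_fraction`;
#' responder base amplitudes are log-normal with mean `kernel$amplitude_pct`
#' and CV `population$amplitude_cv` (the sign of the kernel amplitude is
#' carried through). The noiseless fractional signal `s(t)` (in %) is the
#' sum over trials of kernels scaled by the realized amplitudes. In FRET
#' mode the acceptor channel is scaled by `1 + gamma * s/100` and the donor
#' by `(1 + gamma * s/100) / (1 + s/100)`, so that the bleach-free,
#' noise-free ratio change equals `s` exactly for any gamma
#' (`acquisition_spec(fret_gain_split = )`). In single mode one channel is
#' scaled by `1 + s/100`.
#'
#' @param protocol A [stimulus_protocol()]. The recording must cover all
#'   trial onsets plus one decay window.
#' @param population A [population_spec()]. `rundown_factors` and
#'   `drug_schedule` are recycled from length 1, otherwise must match the
#'   number of trials.
#' @param acq An [acquisition_spec()]; carries mode, noise, bleach and the
#'   RNG seed (simulation is bit-reproducible for a fixed seed).
#' @param kernel A [response_kernel()] shared by all ROIs.
#' @param trial_kernels Optional list (indexed by trial) of per-trial kernel
#'   overrides, e.g. to slow the rise on a drug trial. Overrides replace the
#'   kinetics only; amplitudes still come from the population model.
#' @return A list with components `traces` (a [traceset()]) and
#'   `ground_truth` (class `pk_ground_truth`, with per-ROI and per-trial
#'   tables).
#' @examples
#' prot <- stimulus_protocol(5, 10, 5, train_onsets_s = c(120, 720))
#' pop <- population_spec(4)
#' acq <- acquisition_spec(1 / 15, 1300, mode = "fret", seed = 7)
#' kern <- response_kernel(7.4, 15, 178.4, form = "piecewise",
#'                         rise_duration_s = 75)
#' sim <- simulate_traceset(prot, pop, acq, kern)
#' sim$ground_truth$trials
#' @export
simulate_traceset <- function(protocol, population, acq, kernel,
                              trial_kernels = NULL) {
  stopifnot(inherits(protocol, "pk_protocol"),
            inherits(population, "pk_population"),
            inherits(acq, "pk_acquisition"),
            inherits(kernel, "pk_kernel"))
  onsets <- protocol$train_onsets_s
  n_trials <- length(onsets)
  if (max(onsets) + kernel$tau_decay_s > acq$duration_s) {
    stop("`duration_s` must cover all trial onsets plus one decay window",
         call. = FALSE)
  }
  rundown <- recycle_trial_factors(population$rundown_factors, n_trials,
                                   "rundown_factors")
  drug <- recycle_trial_factors(
    if (is.null(population$drug_schedule)) 1 else population$drug_schedule,
    n_trials, "drug_schedule")

  t <- time_grid(acq)
  n <- population$n_rois

  withr::local_seed(acq$seed)
  responsive <- stats::runif(n) < population$responder_fraction
  base_amp <- draw_amplitudes(n, kernel$amplitude_pct,
                              population$amplitude_cv)
  base_amp[!responsive] <- 0

  # realized amplitude obeys the multiplicative model exactly
  realized <- outer(base_amp, rundown * drug)

  signal <- matrix(0, nrow = n, ncol = length(t))
  for (k in seq_len(n_trials)) {
    kern_k <- if (!is.null(trial_kernels) && length(trial_kernels) >= k &&
                  !is.null(trial_kernels[[k]])) trial_kernels[[k]] else kernel
    unit <- unit_kernel_eval(kern_k, t, onsets[k])
    signal <- signal + realized[, k] %o% unit
  }

  channels <- emit_channels(signal, t, acq)

  roi_meta <- tibble::tibble(
    roi_id = sprintf("roi%03d", seq_len(n)),
    compartment = population$compartment_labels)

  truth_rois <- tibble::tibble(
    roi_id = roi_meta$roi_id,
    compartment = roi_meta$compartment,
    responsive = responsive,
    base_amplitude_pct = base_amp)
  truth_trials <- tibble::tibble(
    roi_id = rep(roi_meta$roi_id, times = n_trials),
    trial_index = rep(seq_len(n_trials), each = n),
    rundown_factor = rep(rundown, each = n),
    drug_factor = rep(drug, each = n),
    realized_amplitude_pct = as.vector(realized))

  list(
    traces = traceset(t, channels, roi_meta, protocol = protocol,
                      mode = acq$mode, seed = acq$seed),
    ground_truth = structure(
      list(rois = truth_rois, trials = truth_trials, kernel = kernel,
           seed = acq$seed),
      class = "pk_ground_truth")
  )
}

#' Simulate a forskolin-saturation trace set
#'
#' Bath application of forskolin drives adenylate cyclase maximally and
#' saturates the PKA sensor; the signal rises as
#' `plateau_pct * (1 - exp(-u/tau_sat_s))` after the application time and
#' does not decay. The resulting plateau serves as a per-cell maximal
#' response reference.
#'
#' @param acq An [acquisition_spec()].
#' @param plateau_pct Plateau amplitude, in % of baseline.
#' @param tau_sat_s Saturation time constant, in s.
#' @param application_time_s Drug application time, in s; must lie within
#'   the recording.
#' @param n_rois Number of ROIs (default 1).
#' @param compartment Compartment tag for all ROIs.
#' @return A [traceset()] whose protocol marks the application time as a
#'   single "trial" onset, so the standard epoching machinery applies.
#' @export
simulate_fsk_plateau <- function(acq, plateau_pct, tau_sat_s,
                                 application_time_s, n_rois = 1,
                                 compartment = "soma") {
  stopifnot(inherits(acq, "pk_acquisition"))
  check_number(plateau_pct, "plateau_pct")
  check_number(tau_sat_s, "tau_sat_s", positive = TRUE)
  check_number(application_time_s, "application_time_s", positive = TRUE)
  if (application_time_s >= acq$duration_s) {
    stop("`application_time_s` must lie within the recording", call. = FALSE)
  }
  t <- time_grid(acq)
  u <- pmax(t - application_time_s, 0)
  s <- plateau_pct * (1 - exp(-u / tau_sat_s))
  signal <- matrix(rep(s, each = n_rois), nrow = n_rois)

  withr::local_seed(acq$seed)
  channels <- emit_channels(signal, t, acq)
  roi_meta <- tibble::tibble(roi_id = sprintf("roi%03d", seq_len(n_rois)),
                             compartment = rep_len(compartment, n_rois))
  protocol <- stimulus_protocol(1, 1, 1,
                                train_onsets_s = application_time_s,
                                label = "FSK bath application")
  traceset(t, channels, roi_meta, protocol = protocol, mode = acq$mode,
           seed = acq$seed)
}

# ---- internals ------------------------------------------------------------

time_grid <- function(acq) {
  n_fr <- floor(acq$duration_s * acq$frame_rate_hz) + 1
  seq(0, by = 1 / acq$frame_rate_hz, length.out = n_fr)
}

recycle_trial_factors <- function(x, n_trials, name) {
  if (length(x) == 1) return(rep(x, n_trials))
  if (length(x) < n_trials) {
    stop(sprintf("`%s` must have one entry per trial (%d)", name, n_trials),
         call. = FALSE)
  }
  x[seq_len(n_trials)]
}

# log-normal amplitudes with mean |m| and coefficient of variation cv,
# carrying the sign of m; cv = 0 degenerates to the constant |m|
draw_amplitudes <- function(n, mean_amplitude, cv) {
  m <- abs(mean_amplitude)
  if (m == 0 || cv == 0) return(rep(mean_amplitude, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  sign(mean_amplitude) * stats::rlnorm(n, meanlog, sdlog)
}

# unit-amplitude kernel evaluation (both forms are linear in amplitude)
unit_kernel_eval <- function(kernel, times, onset) {
  k1 <- kernel
  k1$amplitude_pct <- 1
  class(k1) <- "pk_kernel"
  response_kernel_eval(k1, times, onset)
}

# turn the fractional signal matrix (in %) into noisy intensity channels
emit_channels <- function(signal, t, acq) {
  s <- signal / 100
  if (any(1 + s <= 0)) {
    stop("signal reaches -100% of baseline; configuration rejected",
         call. = FALSE)
  }
  gamma <- acq$fret_gain_split
  factors <- if (acq$mode == "fret") {
    donor <- (1 + gamma * s) / (1 + s)
    if (any(donor <= 0)) {
      stop("signal drives the donor channel to non-positive intensity; ",
           "configuration rejected", call. = FALSE)
    }
    list(acceptor = 1 + gamma * s, donor = donor)
  } else {
    list(green = 1 + s)
  }
  out <- vector("list", length(factors))
  names(out) <- names(factors)
  for (ch in names(factors)) {
    base <- acq$baseline_intensity[[ch]]
    tau_b <- acq$bleach_tau_s[[ch]]
    bleach <- if (is.finite(tau_b)) exp(-t / tau_b) else rep(1, length(t))
    clean <- base * factors[[ch]] *
      matrix(rep(bleach, each = nrow(s)), nrow = nrow(s))
    noisy <- if (acq$noise_sd_pct > 0) {
      if (acq$poisson_noise) {
        lambda <- (base * acq$noise_sd_pct / 100)^2  # shot-noise variance match
        clean + (stats::rpois(length(clean), lambda) - lambda) *
          (base * acq$noise_sd_pct / 100) / sqrt(lambda)
      } else {
        clean + stats::rnorm(length(clean),
                             sd = base * acq$noise_sd_pct / 100)
      }
    } else clean
    out[[ch]] <- matrix(noisy, nrow = nrow(s))
  }
  out
}

#' @export
print.pk_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<pk_ground_truth> %d ROI(s) (%d responder(s)), %d trial(s), seed %s\n",
    nrow(x$rois), sum(x$rois$responsive),
    max(x$trials$trial_index), format(x$seed)))
  invisible(x)
}
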