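#' Stimulation protocol description
#'
#' A photostimulation protocol is a train of brief light pulses (e.g. 5-ms
#' pulses at 10 Hz for 5 s) delivered repeatedly; each train constitutes one
#' stimulation trial. Trial onsets are expressed on the recording clock.
#'
#' @param pulse_width_ms Width of a single light pulse, in ms.
#' @param pulse_rate_hz Pulse rate within a train, in Hz. The duty cycle
#'   `pulse_width_ms * pulse_rate_hz` must not exceed 1000 (i.e. 100%).
#' @param train_duration_s Duration of one pulse train, in s.
#' @param train_onsets_s Strictly increasing numeric vector of trial start
#'   times, in s.
#' @param label Free-text label for the protocol.
#' @return An object of class `pk_protocol`.
#' @examples
#' stimulus_protocol(5, 10, 5, train_onsets_s = c(120, 720, 1320))
#' @export
stimulus_protocol <- function(pulse_width_ms, pulse_rate_hz, train_duration_s,
                              train_onsets_s, label = "") {
  check_number(pulse_width_ms, "pulse_width_ms", positive = TRUE)
  check_number(pulse_rate_hz, "pulse_rate_hz", positive = TRUE)
  check_number(train_duration_s, "train_duration_s", positive = TRUE)
  if (pulse_width_ms * pulse_rate_hz > 1000) {
    stop("duty cycle exceeds 1: pulse_width_ms * pulse_rate_hz must be <= 1000",
         call. = FALSE)
  }
  if (!is.numeric(train_onsets_s) || length(train_onsets_s) < 1 ||
      any(!is.finite(train_onsets_s)) || any(train_onsets_s <= 0)) {
    stop("`train_onsets_s` must be a vector of positive, finite times",
         call. = FALSE)
  }
  if (is.unsorted(train_onsets_s, strictly = TRUE)) {
    stop("`train_onsets_s` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(pulse_width_ms = pulse_width_ms, pulse_rate_hz = pulse_rate_hz,
         train_duration_s = train_duration_s,
         train_onsets_s = as.numeric(train_onsets_s), label = label),
    class = "pk_protocol"
  )
}

#' @export
print.pk_protocol <- function(x, ...) {
  cat(sprintf(
    "<pk_protocol> %s\n  %g-ms pulses at %g Hz for %g s; %d trial(s) at t = %s s\n",
    x$label, x$pulse_width_ms, x$pulse_rate_hz, x$train_duration_s,
    length(x$train_onsets_s),
    paste(signif(x$train_onsets_s, 6), collapse = ", ")))
  invisible(x)
}

#' Parametric stimulus-locked response kernel
#'
#' Describes the shape of a single PKA transient evoked by one stimulation
#' trial, in percent of baseline fluorescence (or FRET ratio). Two forms are
#' supported:
#'
#' * `"diff_exp"`: a difference of exponentials
#'   `s(u) = A c (exp(-u/tau_decay) - exp(-u/tau_rise))`, with `c` chosen so
#'   the peak equals `A`; requires `tau_decay_s > tau_rise_s`.
#' * `"piecewise"`: a saturating-exponential rise
#'   `A (1 - exp(-u/tau_rise))` for `u` in `[0, rise_duration_s]`, followed
#'   by a single-exponential decay with constant `tau_decay_s` from the value
#'   reached at the end of the rise. The peak is
#'   `A (1 - exp(-rise_duration_s/tau_rise_s))`, i.e. equals `A` up to the
#'   saturation factor of the rise.
#'
#' `u` is time since `trial onset + latency_s`; the kernel is zero before
#' that.
#'
#' @param amplitude_pct Peak fractional change, in % of baseline. May be
#'   negative (inverted transients, e.g. under beta-adrenergic blockade).
#' @param tau_rise_s,tau_decay_s Rise and decay time constants, in s.
#' @param latency_s Delay between trial onset and response start, in s.
#' @param form `"piecewise"` or `"diff_exp"`.
#' @param rise_duration_s Duration of the rise phase (piecewise form only), s.
#' @return An object of class `pk_kernel`.
#' @seealso [response_kernel_eval()], [kernel_peak_time()]
#' @export
response_kernel <- function(amplitude_pct, tau_rise_s, tau_decay_s,
                            latency_s = 0,
                            form = c("piecewise", "diff_exp"),
                            rise_duration_s = NULL) {
  form <- match.arg(form)
  for (v in c("amplitude_pct", "tau_rise_s", "tau_decay_s", "latency_s")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      stop(sprintf("`%s` must be a single finite number", v), call. = FALSE)
    }
  }
  if (tau_rise_s <= 0 || tau_decay_s <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  if (latency_s < 0) stop("`latency_s` must be >= 0", call. = FALSE)
  if (form == "diff_exp" && tau_decay_s <= tau_rise_s) {
    stop("diff_exp form requires tau_decay_s > tau_rise_s", call. = FALSE)
  }
  if (form == "piecewise") {
    if (is.null(rise_duration_s) || !is.finite(rise_duration_s) ||
        rise_duration_s <= 0) {
      stop("piecewise form requires a positive `rise_duration_s`",
           call. = FALSE)
    }
  } else {
    rise_duration_s <- NULL
  }
  structure(
    list(amplitude_pct = amplitude_pct, tau_rise_s = tau_rise_s,
         tau_decay_s = tau_decay_s, latency_s = latency_s, form = form,
         rise_duration_s = rise_duration_s),
    class = "pk_kernel"
  )
}

#' @export
print.pk_kernel <- function(x, ...) {
  extra <- if (x$form == "piecewise") {
    sprintf(", rise duration %g s", x$rise_duration_s)
  } else ""
  cat(sprintf(
    "<pk_kernel> %s: A = %g%%, tau_rise = %g s, tau_decay = %g s, latency = %g s%s\n",
    x$form, x$amplitude_pct, x$tau_rise_s, x$tau_decay_s, x$latency_s, extra))
  invisible(x)
}

#' Evaluate a response kernel on a time grid
#'
#' @param kernel A [response_kernel()].
#' @param times Sorted numeric vector of sample times, in s.
#' @param trial_onset Trial onset time on the same clock, in s.
#' @return Numeric vector of the signal in % of baseline, zero before
#'   `trial_onset + latency_s`.
#' @examples
#' k <- response_kernel(5.7, 14.7, 154.1, form = "piecewise",
#'                      rise_duration_s = 50)
#' response_kernel_eval(k, seq(0, 300, by = 5), trial_onset = 30)
#' @export
response_kernel_eval <- function(kernel, times, trial_onset = 0) {
  stopifnot(inherits(kernel, "pk_kernel"))
  if (!is.numeric(times) || any(!is.finite(times))) {
    stop("`times` must be finite numeric", call. = FALSE)
  }
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  check_number(trial_onset, "trial_onset")
  u <- times - trial_onset - kernel$latency_s
  s <- numeric(length(u))
  A <- kernel$amplitude_pct
  tr <- kernel$tau_rise_s
  td <- kernel$tau_decay_s
  if (kernel$form == "diff_exp") {
    tpk <- diff_exp_peak_time(tr, td)
    cnorm <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
    pos <- u > 0
    s[pos] <- A * cnorm * (exp(-u[pos] / td) - exp(-u[pos] / tr))
  } else {
    R <- kernel$rise_duration_s
    rise <- u > 0 & u <= R
    dec <- u > R
    s[rise] <- A * (1 - exp(-u[rise] / tr))
    y_end <- A * (1 - exp(-R / tr))
    s[dec] <- y_end * exp(-(u[dec] - R) / td)
  }
  s
}

#' Closed-form peak time of a response kernel
#'
#' For the difference-of-exponentials form the argmax after response start is
#' `tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`; for the piecewise
#' form the peak sits at the end of the rise phase. Latency is included.
#'
#' @param kernel A [response_kernel()].
#' @return Peak time in s, measured from trial onset.
#' @export
kernel_peak_time <- function(kernel) {
  stopifnot(inherits(kernel, "pk_kernel"))
  tpk <- if (kernel$form == "diff_exp") {
    diff_exp_peak_time(kernel$tau_rise_s, kernel$tau_decay_s)
  } else {
    kernel$rise_duration_s
  }
  kernel$latency_s + tpk
}

diff_exp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' ROI population specification for the synthetic generator
#'
#' Describes the statistical structure of a simulated ROI cohort: how many
#' ROIs, which fraction responds at all, how variable per-ROI amplitudes are,
#' and the per-trial multiplicative modulation of amplitude by run-down and
#' by drug application.
#'
#' Per-ROI amplitudes are drawn log-normal with mean equal to the kernel
#' amplitude and coefficient of variation `amplitude_cv` (responses to a
#' Gs-coupled agonist are non-negative; signed drug effects are expressed
#' through `drug_schedule`).
#'
#' @param n_rois Number of ROIs.
#' @param responder_fraction Probability that an ROI is a responder, in
#'   `[0, 1]`. Non-responders have zero realized amplitude in every trial.
#' @param amplitude_cv Coefficient of variation of per-ROI amplitudes.
#' @param compartment_labels Per-ROI compartment tag (`"soma"` or
#'   `"dendrite"`), recycled to `n_rois`.
#' @param rundown_factors Per-trial multiplicative amplitude factors; the
#'   first entry must equal 1 (trial 1 defines the reference amplitude).
#' @param drug_schedule Optional per-trial multiplicative drug factor delta
#'   (1 = no drug). Recycled checking happens at simulation time against the
#'   protocol's trial count.
#' @return An object of class `pk_population`.
#' @export
population_spec <- function(n_rois, responder_fraction = 1,
                            amplitude_cv = 0.3,
                            compartment_labels = "soma",
                            rundown_factors = 1,
                            drug_schedule = NULL) {
  check_number(n_rois, "n_rois", positive = TRUE)
  if (n_rois != round(n_rois)) stop("`n_rois` must be an integer count",
                                    call. = FALSE)
  check_number(responder_fraction, "responder_fraction")
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("`responder_fraction` must lie in [0, 1]", call. = FALSE)
  }
  check_number(amplitude_cv, "amplitude_cv")
  if (amplitude_cv < 0) stop("`amplitude_cv` must be >= 0", call. = FALSE)
  if (!all(compartment_labels %in% c("soma", "dendrite"))) {
    stop("`compartment_labels` must be 'soma' or 'dendrite'", call. = FALSE)
  }
  if (!is.numeric(rundown_factors) || any(!is.finite(rundown_factors)) ||
      any(rundown_factors < 0)) {
    stop("`rundown_factors` must be finite and >= 0", call. = FALSE)
  }
  if (rundown_factors[1] != 1) {
    stop("`rundown_factors[1]` must equal 1", call. = FALSE)
  }
  if (!is.null(drug_schedule)) {
    if (!is.numeric(drug_schedule) || any(!is.finite(drug_schedule)) ||
        any(drug_schedule < 0)) {
      stop("`drug_schedule` must be finite and >= 0", call. = FALSE)
    }
  }
  structure(
    list(n_rois = as.integer(n_rois),
         responder_fraction = responder_fraction,
         amplitude_cv = amplitude_cv,
         compartment_labels = rep_len(compartment_labels, n_rois),
         rundown_factors = rundown_factors,
         drug_schedule = drug_schedule),
    class = "pk_population"
  )
}

#' Acquisition specification for the synthetic generator
#'
#' @param frame_rate_hz Sampling rate, in Hz.
#' @param duration_s Recording length, in s.
#' @param mode `"fret"` (two channels, acceptor/donor) or `"single"`.
#' @param baseline_intensity Named per-channel baseline fluorescence, in
#'   arbitrary units. Defaults to 1000 AU per channel.
#' @param noise_sd_pct SD of additive Gaussian noise per frame, as % of the
#'   channel baseline.
#' @param bleach_tau_s Named per-channel mono-exponential bleach time
#'   constant, in s (`Inf` = no bleaching).
#' @param fret_gain_split gamma in `[0, 1]` partitioning the FRET signal
#'   between an acceptor increase and a donor decrease; the donor factor is
#'   chosen so the noiseless, bleach-free ratio change equals the injected
#'   signal exactly. `gamma = 1` puts the whole signal on the acceptor.
#' @param poisson_noise If `TRUE`, replace Gaussian noise by Poisson (shot)
#'   noise with the same baseline variance. Off by default.
#' @param seed Integer RNG seed.
#' @return An object of class `pk_acquisition`.
#' @export
acquisition_spec <- function(frame_rate_hz, duration_s,
                             mode = c("fret", "single"),
                             baseline_intensity = NULL,
                             noise_sd_pct = 0.2,
                             bleach_tau_s = NULL,
                             fret_gain_split = 0.5,
                             poisson_noise = FALSE,
                             seed = 1L) {
  mode <- match.arg(mode)
  check_number(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(noise_sd_pct, "noise_sd_pct")
  if (noise_sd_pct < 0) stop("`noise_sd_pct` must be >= 0", call. = FALSE)
  check_number(fret_gain_split, "fret_gain_split")
  if (fret_gain_split < 0 || fret_gain_split > 1) {
    stop("`fret_gain_split` must lie in [0, 1]", call. = FALSE)
  }
  chans <- if (mode == "fret") c("acceptor", "donor") else "green"
  if (is.null(baseline_intensity)) {
    baseline_intensity <- stats::setNames(rep(1000, length(chans)), chans)
  }
  if (is.null(names(baseline_intensity)) ||
      !setequal(names(baseline_intensity), chans)) {
    stop(sprintf("`baseline_intensity` must be named: %s",
                 paste(chans, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(baseline_intensity)) || any(baseline_intensity <= 0)) {
    stop("`baseline_intensity` must be finite and > 0", call. = FALSE)
  }
  if (is.null(bleach_tau_s)) {
    bleach_tau_s <- stats::setNames(rep(Inf, length(chans)), chans)
  }
  if (is.null(names(bleach_tau_s)) || !setequal(names(bleach_tau_s), chans)) {
    stop(sprintf("`bleach_tau_s` must be named: %s",
                 paste(chans, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(bleach_tau_s)) || any(bleach_tau_s <= 0)) {
    stop("`bleach_tau_s` must be > 0 (Inf allowed)", call. = FALSE)
  }
  structure(
    list(frame_rate_hz = frame_rate_hz, duration_s = duration_s, mode = mode,
         channels = chans,
         baseline_intensity = baseline_intensity[chans],
         noise_sd_pct = noise_sd_pct,
         bleach_tau_s = bleach_tau_s[chans],
         fret_gain_split = fret_gain_split,
         poisson_noise = isTRUE(poisson_noise),
         seed = as.integer(seed)),
    class = "pk_acquisition"
  )
}

# single-number argument check shared by the constructors
check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
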