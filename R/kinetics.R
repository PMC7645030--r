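#' Measure the peak amplitude of each epoch
#'
#' The amplitude is the signed extremum (the value of largest magnitude) of
#' the epoch signal within the response window, relative to the epoch's own
#' re-baselined zero; ties are broken by the earliest time. Time to peak is
#' measured from the trial onset (relative time 0).
#'
#' Because the maximum of a noisy trace is positively biased, an optional
#' centred moving average (`smooth_s`, in seconds) can be applied before the
#' peak search; the amplitude is then read from the smoothed trace at the
#' smoothed argmax. The per-regime presets in [analysis_defaults()] choose a
#' smoothing span of about three frames in the slice regime and ~5 s at
#' high in vivo frame rates.
#'
#' @param epochs A `pk_epochs` from [segment_by_stimulus()].
#' @param response_window_s Length of the search window after trial onset,
#'   in s.
#' @param smooth_s Optional moving-average span in s (`NULL` = raw trace).
#' @return Tibble with one row per epoch: `epoch_id`, `roi_id`,
#'   `trial_index`, `compartment`, `amplitude_pct`, `t_peak_s`.
#' @export
measure_amplitude <- function(epochs, response_window_s, smooth_s = NULL) {
  stopifnot(inherits(epochs, "pk_epochs"))
  check_number(response_window_s, "response_window_s", positive = TRUE)
  rel <- epochs$rel_time_s
  idx <- which(rel >= 0 & rel <= response_window_s)
  if (length(idx) < 1) stop("response window is empty", call. = FALSE)
  sig <- smooth_epochs(epochs$signal, rel, smooth_s)
  win <- sig[, idx, drop = FALSE]
  pk <- apply(win, 1, function(y) {
    j <- which.max(abs(y))  # first index on ties = earliest time
    c(y[j], j)
  })
  out <- epochs$info
  out$amplitude_pct <- unname(pk[1, ])
  out$t_peak_s <- rel[idx[pk[2, ]]]
  out
}

#' Measure per-epoch amplitudes at the cohort peak latency
#'
#' Alternative amplitude estimator for condition contrasts: for every trial
#' the pooled mean trace across ROIs is smoothed and its peak latency
#' located, and each ROI's (smoothed) signal is then read at that fixed
#' latency. Unlike the per-epoch extremum of [measure_amplitude()], a
#' fixed-latency read-out has zero-mean noise, so it stays unbiased when a
#' drug abolishes the response and the window maximum would otherwise
#' measure pure noise. This is the estimator the pharmacology summary uses.
#'
#' @inheritParams measure_amplitude
#' @return Tibble shaped like [measure_amplitude()]'s result; `t_peak_s`
#'   holds the trial's cohort peak latency.
#' @export
measure_amplitude_at_cohort_peak <- function(epochs, response_window_s,
                                             smooth_s = NULL) {
  stopifnot(inherits(epochs, "pk_epochs"))
  check_number(response_window_s, "response_window_s", positive = TRUE)
  rel <- epochs$rel_time_s
  idx <- which(rel >= 0 & rel <= response_window_s)
  if (length(idx) < 1) stop("response window is empty", call. = FALSE)
  sig <- smooth_epochs(epochs$signal, rel, smooth_s)
  out <- epochs$info
  out$amplitude_pct <- NA_real_
  out$t_peak_s <- NA_real_
  for (k in unique(out$trial_index)) {
    rows <- which(out$trial_index == k)
    pooled <- colMeans(sig[rows, , drop = FALSE])
    j <- idx[which.max(abs(pooled[idx]))]
    out$amplitude_pct[rows] <- unname(sig[rows, j])
    out$t_peak_s[rows] <- rel[j]
  }
  out
}

#' Report the time-to-peak as a fixed-width bin
#'
#' Times to peak are reported as half-open bins `[k w, (k+1) w)` of width
#' `w` (default 30 s), matching the resolution imposed by slow frame
#' acquisition. A peak exactly on a boundary goes into the upper bin.
#'
#' @param t_peak_s Numeric vector of peak times (>= 0), in s.
#' @param bin_width_s Bin width, in s.
#' @return Tibble with `t_peak_s`, `bin_lower_s`, `bin_upper_s`, and a
#'   printable `bin_label` such as `"[60-90]"`.
#' @examples
#' time_to_peak_bin(c(0, 77, 90))
#' @export
time_to_peak_bin <- function(t_peak_s, bin_width_s = 30) {
  check_number(bin_width_s, "bin_width_s", positive = TRUE)
  if (any(t_peak_s < 0)) stop("`t_peak_s` must be >= 0", call. = FALSE)
  lo <- floor(t_peak_s / bin_width_s) * bin_width_s
  tibble::tibble(
    t_peak_s = t_peak_s,
    bin_lower_s = lo,
    bin_upper_s = lo + bin_width_s,
    bin_label = sprintf("[%g-%g]", lo, lo + bin_width_s))
}

#' Fit a single-exponential decay from the empirical peak
#'
#' Least-squares fit of `y(v) = y0 exp(-v / tau) (+ d)` on the epoch segment
#' from the measured peak to the end of the epoch (`v` = time since peak).
#' The optional additive offset `d` absorbs the superposed tails of
#' preceding trials, which share the decay constant, and residual baseline
#' drift; by default the pure two-parameter model is fitted. Negative-going transients are fitted after sign inversion and
#' reported with a negative `y0`.
#'
#' Initialization is analytic (log-linear regression of the decay segment);
#' the refinement uses [minpack.lm::nlsLM()] with `tau` bounded to
#' `[1, 1e4]` s. Fits with `R^2 < 0.5` are flagged `"poor"`; non-convergence
#' or a boundary tau yields `"failed"` with `tau = NA`.
#'
#' @param epochs A `pk_epochs`.
#' @param peaks Optional result of [measure_amplitude()] (recomputed with
#'   `response_window_s`/`smooth_s` when omitted).
#' @param response_window_s,smooth_s Passed to [measure_amplitude()] when
#'   `peaks` is missing.
#' @param offset Fit an additive offset (default `FALSE`, the pure
#'   single-exponential model). Enable it when epochs from consecutive
#'   trials carry superposed tails of earlier responses (they share the
#'   decay constant, so the offset model is then exact); the in vivo
#'   preset in [analysis_defaults()] does.
#' @param min_frames Minimum number of frames after the peak (default 5).
#' @return Tibble with one row per epoch: identifiers, `decay_tau_s`,
#'   `decay_r2`, `decay_se`, `decay_status` (`"ok"`, `"poor"`, `"failed"`),
#'   and `decay_y0`, the fitted (signed) value at the peak.
#' @export
fit_decay <- function(epochs, peaks = NULL, response_window_s = NULL,
                      smooth_s = NULL, offset = FALSE, min_frames = 5) {
  stopifnot(inherits(epochs, "pk_epochs"))
  if (is.null(peaks)) {
    if (is.null(response_window_s)) {
      stop("give `peaks` or `response_window_s`", call. = FALSE)
    }
    peaks <- measure_amplitude(epochs, response_window_s, smooth_s)
  }
  rel <- epochs$rel_time_s
  res <- vector("list", nrow(epochs$signal))
  for (i in seq_len(nrow(epochs$signal))) {
    tp <- peaks$t_peak_s[i]
    idx <- which(rel >= tp)
    fit <- if (length(idx) < min_frames) {
      failed_fit()
    } else {
      fit_exp_decay(rel[idx] - tp, epochs$signal[i, idx],
                    sign = sign_or_one(peaks$amplitude_pct[i]),
                    offset = offset)
    }
    res[[i]] <- tibble::tibble(decay_tau_s = fit$tau, decay_r2 = fit$r2,
                               decay_se = fit$se, decay_status = fit$status,
                               decay_y0 = fit$y0 %||% NA_real_)
  }
  dplyr::bind_cols(peaks[, c("epoch_id", "roi_id", "trial_index",
                             "compartment")],
                   dplyr::bind_rows(res))
}

#' Fit a saturating-exponential onset up to the empirical peak
#'
#' Least-squares fit of `y(u) = P (1 - exp(-u / tau)) (+ d)` between trial
#' onset (`u = 0`) and the measured peak. Same conventions, bounds and
#' status flags as [fit_decay()]; a fitted plateau `P` of the wrong sign
#' (e.g. on a monotone-decreasing epoch) is reported as `"failed"`.
#'
#' @inheritParams fit_decay
#' @param min_frames Minimum number of frames between onset and peak.
#' @return Tibble with `onset_tau_s`, `onset_r2`, `onset_se`,
#'   `onset_status` per epoch.
#' @export
fit_onset <- function(epochs, peaks = NULL, response_window_s = NULL,
                      smooth_s = NULL, offset = FALSE, min_frames = 5) {
  stopifnot(inherits(epochs, "pk_epochs"))
  if (is.null(peaks)) {
    if (is.null(response_window_s)) {
      stop("give `peaks` or `response_window_s`", call. = FALSE)
    }
    peaks <- measure_amplitude(epochs, response_window_s, smooth_s)
  }
  rel <- epochs$rel_time_s
  res <- vector("list", nrow(epochs$signal))
  for (i in seq_len(nrow(epochs$signal))) {
    tp <- peaks$t_peak_s[i]
    idx <- which(rel >= 0 & rel <= tp)
    fit <- if (length(idx) < min_frames) {
      failed_fit()
    } else {
      fit_sat_rise(rel[idx], epochs$signal[i, idx],
                   sign = sign_or_one(peaks$amplitude_pct[i]),
                   offset = offset)
    }
    res[[i]] <- tibble::tibble(onset_tau_s = fit$tau, onset_r2 = fit$r2,
                               onset_se = fit$se, onset_status = fit$status)
  }
  dplyr::bind_cols(peaks[, c("epoch_id", "roi_id", "trial_index",
                             "compartment")],
                   dplyr::bind_rows(res))
}

#' Pointwise mean and SEM across epochs
#'
#' @param epochs A `pk_epochs` sharing one relative time grid.
#' @return Tibble with `rel_time_s`, `mean_pct`, `sem_pct`, `n`. With a
#'   single epoch the SEM is reported as `NA`.
#' @export
pool_mean_trace <- function(epochs) {
  stopifnot(inherits(epochs, "pk_epochs"))
  m <- epochs$signal
  n <- nrow(m)
  tibble::tibble(
    rel_time_s = epochs$rel_time_s,
    mean_pct = colMeans(m),
    sem_pct = if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else
      rep(NA_real_, ncol(m)),
    n = n)
}

#' Wrap the pooled mean trace as a one-epoch object
#'
#' Convenience for fitting kinetics on the grand-average response (the
#' "fit-on-the-mean" reading of cohort time constants), reusing the same
#' [measure_amplitude()], [fit_onset()] and [fit_decay()] machinery.
#'
#' @param epochs A `pk_epochs`.
#' @return A `pk_epochs` containing the single pooled mean trace.
#' @export
pooled_epoch <- function(epochs) {
  pm <- pool_mean_trace(epochs)
  epochs$signal <- matrix(pm$mean_pct, nrow = 1)
  epochs$info <- tibble::tibble(
    epoch_id = "pooled", roi_id = "pooled", trial_index = 0L,
    compartment = paste(unique(epochs$info$compartment), collapse = "+"))
  epochs
}

#' Full per-epoch kinetics table
#'
#' One-stop wrapper running [measure_amplitude()], [time_to_peak_bin()],
#' [fit_onset()] and [fit_decay()] and joining the results into a single
#' response-metrics table.
#'
#' @param epochs A `pk_epochs`.
#' @param response_window_s Peak-search window, s.
#' @param smooth_s Moving-average span for the peak search (`NULL` = raw).
#' @param bin_width_s Time-to-peak bin width, s.
#' @param offset Offset term in both fits (see [fit_decay()]).
#' @return Tibble with amplitude, peak time and bin, onset and decay fits.
#' @export
epoch_kinetics <- function(epochs, response_window_s, smooth_s = NULL,
                           bin_width_s = 30, offset = FALSE) {
  pk <- measure_amplitude(epochs, response_window_s, smooth_s)
  bins <- time_to_peak_bin(pk$t_peak_s, bin_width_s)
  pk$t_peak_bin_lower_s <- bins$bin_lower_s
  pk$t_peak_bin_upper_s <- bins$bin_upper_s
  pk$t_peak_bin <- bins$bin_label
  on <- fit_onset(epochs, peaks = pk, offset = offset)
  de <- fit_decay(epochs, peaks = pk, offset = offset)
  out <- dplyr::left_join(pk, on[, c("epoch_id", "onset_tau_s", "onset_r2",
                                     "onset_se", "onset_status")],
                          by = "epoch_id")
  dplyr::left_join(out, de[, c("epoch_id", "decay_tau_s", "decay_r2",
                               "decay_se", "decay_status")],
                   by = "epoch_id")
}

# ---- internals ------------------------------------------------------------

sign_or_one <- function(x) if (is.na(x) || x >= 0) 1 else -1

failed_fit <- function() {
  list(tau = NA_real_, r2 = NA_real_, se = NA_real_, status = "failed",
       y0 = NA_real_)
}

TAU_BOUNDS <- c(1, 1e4)

# centred moving average, partial windows at the edges
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- k %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

smooth_epochs <- function(sig, rel, smooth_s) {
  if (is.null(smooth_s) || smooth_s <= 0) return(sig)
  dt <- stats::median(diff(rel))
  k <- max(1, round(smooth_s / dt))
  if (k %% 2 == 0) k <- k + 1
  if (k <= 1) return(sig)
  t(apply(sig, 1, moving_average, k = k))
}

fit_quality <- function(y, fitted_y, fit, par) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(failed_fit())
  r2 <- 1 - sum((y - fitted_y)^2) / ss_tot
  se <- tryCatch(summary(fit)$coefficients[par, "Std. Error"],
                 error = function(e) NA_real_)
  tau <- stats::coef(fit)[[par]]
  status <- if (tau <= TAU_BOUNDS[1] * 1.0001 ||
                tau >= TAU_BOUNDS[2] * 0.9999) {
    "failed"
  } else if (r2 < 0.5) "poor" else "ok"
  if (status == "failed") {
    list(tau = NA_real_, r2 = r2, se = se, status = "failed")
  } else {
    list(tau = tau, r2 = r2, se = se, status = status)
  }
}

fit_exp_decay <- function(v, y, sign = 1, offset = TRUE) {
  y <- sign * y
  if (stats::sd(y) == 0) return(failed_fit())
  d0 <- if (offset) min(y) - 1e-6 else 0
  yy <- pmax(y - d0, 1e-9)
  sl <- stats::coef(stats::lm(log(yy) ~ v))
  tau0 <- min(max(-1 / min(sl[[2]], -1e-6), TAU_BOUNDS[1]), TAU_BOUNDS[2])
  y00 <- max(exp(sl[[1]]), 1e-6)
  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(y ~ y0 * exp(-v / tau) + d,
                        start = list(y0 = y00, tau = tau0, d = d0),
                        lower = c(y0 = 0, tau = TAU_BOUNDS[1], d = -Inf),
                        upper = c(y0 = Inf, tau = TAU_BOUNDS[2], d = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(y ~ y0 * exp(-v / tau),
                        start = list(y0 = y00, tau = tau0),
                        lower = c(y0 = 0, tau = TAU_BOUNDS[1]),
                        upper = c(y0 = Inf, tau = TAU_BOUNDS[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed_fit())
  out <- fit_quality(y, stats::fitted(fit), fit, "tau")
  out$y0 <- if (out$status == "failed") NA_real_ else
    sign * stats::coef(fit)[["y0"]]
  out
}

fit_sat_rise <- function(u, y, sign = 1, offset = TRUE) {
  y <- sign * y
  if (stats::sd(y) == 0) return(failed_fit())
  p0 <- max(y[length(y)], 1e-6)
  tau0 <- min(max(max(u) / 3, TAU_BOUNDS[1]), TAU_BOUNDS[2])
  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(y ~ p * (1 - exp(-u / tau)) + d,
                        start = list(p = p0, tau = tau0, d = 0),
                        lower = c(p = -Inf, tau = TAU_BOUNDS[1], d = -Inf),
                        upper = c(p = Inf, tau = TAU_BOUNDS[2], d = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(y ~ p * (1 - exp(-u / tau)),
                        start = list(p = p0, tau = tau0),
                        lower = c(p = -Inf, tau = TAU_BOUNDS[1]),
                        upper = c(p = Inf, tau = TAU_BOUNDS[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed_fit())
  if (stats::coef(fit)[["p"]] <= 0) return(failed_fit())
  fit_quality(y, stats::fitted(fit), fit, "tau")
}
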