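#' Compute the FRET emission ratio
#'
#' Forms the ratio `R = acceptor / donor` elementwise (for AKAR3EV-like
#' sensors, R = F535/F480) and returns a single-channel trace set carrying
#' the same metadata. ROIs with any zero or negative donor sample cannot be
#' ratioed and are excluded with a warning.
#'
#' @param ts A two-channel `pk_traceset`.
#' @param acceptor,donor Channel names.
#' @return A single-channel `pk_traceset` with channel `"ratio"`.
#' @export
compute_ratio <- function(ts, acceptor = "acceptor", donor = "donor") {
  stopifnot(inherits(ts, "pk_traceset"))
  if (!all(c(acceptor, donor) %in% names(ts$channels))) {
    stop(sprintf("channels '%s' and '%s' must both be present",
                 acceptor, donor), call. = FALSE)
  }
  don <- ts$channels[[donor]]
  bad <- rowSums(don <= 0) > 0
  if (any(bad)) {
    warning(sprintf("excluding %d ROI(s) with non-positive donor samples: %s",
                    sum(bad),
                    paste(ts$roi_meta$roi_id[bad], collapse = ", ")),
            call. = FALSE)
    ts <- drop_rois(ts, ts$roi_meta$roi_id[bad])
    don <- ts$channels[[donor]]
  }
  ratio <- ts$channels[[acceptor]] / don
  traceset(ts$time_s, list(ratio = ratio), ts$roi_meta,
           protocol = ts$protocol, mode = "fret", seed = ts$seed)
}

#' Normalize traces to a pre-stimulus baseline
#'
#' Converts a single-channel trace set (a FRET ratio or a raw fluorescence
#' channel) into percent change relative to the per-ROI mean over a baseline
#' window: `signal_pct = 100 * (x - x_baseline) / x_baseline`. This is the
#' dR/R0 (FRET) or dF/F0 (single-channel) scale on which all downstream
#' amplitudes are expressed.
#'
#' ROIs with any non-finite or non-positive raw sample are dropped with a
#' warning, never imputed.
#'
#' @param ts A single-channel `pk_traceset`.
#' @param baseline_window_s Numeric `c(start, end)` in s. Must contain at
#'   least 3 frames and, when a protocol is attached, precede the first
#'   trial onset. Default: the 60 s preceding the first trial onset.
#' @return An object of class `pk_normalized` with fields `time_s`,
#'   `signal_pct` (ROI x frame matrix), `roi_meta`, `protocol`, `mode`,
#'   `baseline_window_s`.
#' @export
normalize_to_baseline <- function(ts, baseline_window_s = NULL) {
  stopifnot(inherits(ts, "pk_traceset"))
  if (length(ts$channels) != 1) {
    stop("`ts` must be single-channel; run compute_ratio() first for FRET",
         call. = FALSE)
  }
  if (is.null(baseline_window_s)) {
    if (is.null(ts$protocol)) {
      stop("no protocol attached: give `baseline_window_s` explicitly",
           call. = FALSE)
    }
    on1 <- ts$protocol$train_onsets_s[1]
    baseline_window_s <- c(max(on1 - 60, 0), on1)
  }
  if (length(baseline_window_s) != 2 ||
      baseline_window_s[2] <= baseline_window_s[1]) {
    stop("`baseline_window_s` must be c(start, end) with end > start",
         call. = FALSE)
  }
  if (baseline_window_s[1] < ts$time_s[1] ||
      baseline_window_s[2] > ts$time_s[length(ts$time_s)]) {
    stop("baseline window falls outside the recording", call. = FALSE)
  }
  if (!is.null(ts$protocol) &&
      baseline_window_s[2] > ts$protocol$train_onsets_s[1]) {
    stop("baseline window must precede the first trial onset", call. = FALSE)
  }
  in_win <- ts$time_s >= baseline_window_s[1] &
    ts$time_s <= baseline_window_s[2]
  if (sum(in_win) < 3) {
    stop("baseline window must contain at least 3 frames", call. = FALSE)
  }
  x <- ts$channels[[1]]
  bad <- rowSums(!is.finite(x) | x <= 0) > 0
  if (any(bad)) {
    warning(sprintf(
      "excluding %d ROI(s) with non-finite or non-positive samples: %s",
      sum(bad), paste(ts$roi_meta$roi_id[bad], collapse = ", ")),
      call. = FALSE)
    ts <- drop_rois(ts, ts$roi_meta$roi_id[bad])
    x <- ts$channels[[1]]
  }
  f0 <- rowMeans(x[, in_win, drop = FALSE])
  signal_pct <- 100 * sweep(sweep(x, 1, f0, "-"), 1, f0, "/")
  structure(
    list(time_s = ts$time_s, signal_pct = signal_pct,
         roi_meta = ts$roi_meta, protocol = ts$protocol, mode = ts$mode,
         baseline_window_s = baseline_window_s),
    class = "pk_normalized"
  )
}

#' @export
print.pk_normalized <- function(x, ...) {
  cat(sprintf(
    "<pk_normalized> %s mode: %d ROI(s) x %d frames, baseline [%g, %g] s\n",
    x$mode, nrow(x$roi_meta), length(x$time_s),
    x$baseline_window_s[1], x$baseline_window_s[2]))
  invisible(x)
}

#' Correct mono-exponential photobleaching
#'
#' Fits, for every ROI and channel, a mono-exponential decay
#' `I(t) = I0 exp(-k t)` on "quiet" frames only -- the pre-stimulus period
#' and the last `tail_s` seconds of each inter-trial interval and of the
#' recording -- then divides the trace by the fitted decay (normalized to 1
#' at the first frame). Minutes-long recordings need this before amplitudes
#' from late trials can be compared with early ones; for FRET pairs with
#' equal bleaching in both channels the ratio is unaffected either way.
#'
#' The rate is initialized by log-linear regression and refined with
#' [minpack.lm::nlsLM()]; if the refinement fails to converge the correction
#' is skipped for that trace with a warning.
#'
#' @param ts A `pk_traceset` with an attached protocol.
#' @param tail_s Length of the late inter-trial window used per gap, in s.
#' @return A list with `traces` (corrected `pk_traceset`) and `bleach_fit`
#'   (tibble: `roi_id`, `channel`, `rate_per_s`, `tau_s`, `converged`).
#' @export
bleach_correct <- function(ts, tail_s = 60) {
  stopifnot(inherits(ts, "pk_traceset"))
  if (is.null(ts$protocol)) {
    stop("`ts` must carry a protocol to locate quiet frames", call. = FALSE)
  }
  t <- ts$time_s
  onsets <- ts$protocol$train_onsets_s
  quiet <- t < onsets[1]
  bounds <- c(onsets[-1], max(t))
  for (b in bounds) quiet <- quiet | (t >= b - tail_s & t < b)
  quiet <- quiet | t >= max(t) - tail_s
  if (sum(quiet) < 5) {
    stop("fewer than 5 quiet frames available for the bleach fit",
         call. = FALSE)
  }
  fits <- list()
  for (ch in names(ts$channels)) {
    m <- ts$channels[[ch]]
    for (i in seq_len(nrow(m))) {
      y <- m[i, quiet]
      tq <- t[quiet]
      fit <- fit_bleach_rate(tq, y)
      if (fit$converged && fit$rate_per_s > 0) {
        corr <- exp(-fit$rate_per_s * (t - t[1]))
        m[i, ] <- m[i, ] / corr
      } else if (!fit$converged) {
        warning(sprintf(
          "bleach fit did not converge for %s / %s; correction skipped",
          ts$roi_meta$roi_id[i], ch), call. = FALSE)
      }
      fits[[length(fits) + 1]] <- tibble::tibble(
        roi_id = ts$roi_meta$roi_id[i], channel = ch,
        rate_per_s = fit$rate_per_s,
        tau_s = ifelse(fit$rate_per_s > 0, 1 / fit$rate_per_s, Inf),
        converged = fit$converged)
    }
    ts$channels[[ch]] <- m
  }
  list(traces = ts, bleach_fit = dplyr::bind_rows(fits))
}

fit_bleach_rate <- function(t, y) {
  # log-linear start; exact on noiseless data
  sl <- stats::coef(stats::lm(log(y) ~ t))
  k0 <- max(-sl[[2]], 0)
  i0 <- exp(sl[[1]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-k * t),
                      start = list(i0 = i0, k = k0),
                      lower = c(i0 = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(rate_per_s = NA_real_, converged = FALSE)
  } else {
    list(rate_per_s = stats::coef(fit)[["k"]], converged = TRUE)
  }
}

#' Segment normalized traces into stimulus-aligned epochs
#'
#' Cuts one epoch per ROI and trial, spanning `[-pre_window_s,
#' +post_window_s)` around each trial onset on a shared relative time grid,
#' and re-baselines every epoch to the mean of its own pre-window (so late
#' trials are not biased by incomplete recovery from earlier ones).
#'
#' @param norm A `pk_normalized`.
#' @param pre_window_s,post_window_s Window lengths, in s. Their sum must
#'   fit between consecutive trial onsets; otherwise the call is rejected
#'   and the error reports the maximum feasible post window.
#' @return An object of class `pk_epochs`: `rel_time_s` (shared grid),
#'   `signal` (epoch x time matrix, re-baselined), `info` (tibble:
#'   `epoch_id`, `roi_id`, `trial_index`, `compartment`), plus the window
#'   lengths and mode.
#' @export
segment_by_stimulus <- function(norm, pre_window_s, post_window_s) {
  stopifnot(inherits(norm, "pk_normalized"))
  if (is.null(norm$protocol)) stop("no protocol attached", call. = FALSE)
  check_number(pre_window_s, "pre_window_s", positive = TRUE)
  check_number(post_window_s, "post_window_s", positive = TRUE)
  onsets <- norm$protocol$train_onsets_s
  t <- norm$time_s
  if (length(onsets) > 1) {
    min_gap <- min(diff(onsets))
    if (pre_window_s + post_window_s > min_gap) {
      stop(sprintf(
        paste0("epoch windows overlap consecutive trials: with pre = %g s ",
               "the maximum feasible post window is %g s"),
        pre_window_s, min_gap - pre_window_s), call. = FALSE)
    }
  }
  rate <- frame_rate(norm)
  n_pre <- round(pre_window_s * rate)
  n_post <- round(post_window_s * rate)
  if (n_pre < 1 || n_post < 1) {
    stop("windows must contain at least one frame each", call. = FALSE)
  }
  rel <- seq(-n_pre, n_post - 1) / rate
  n_roi <- nrow(norm$roi_meta)
  n_trial <- length(onsets)
  sig <- matrix(NA_real_, nrow = n_roi * n_trial, ncol = length(rel))
  info <- vector("list", n_trial)
  for (k in seq_len(n_trial)) {
    i0 <- which.min(abs(t - onsets[k]))
    idx <- seq(i0 - n_pre, i0 + n_post - 1)
    if (idx[1] < 1 || idx[length(idx)] > length(t)) {
      stop(sprintf("epoch window for trial %d falls outside the recording", k),
           call. = FALSE)
    }
    block <- norm$signal_pct[, idx, drop = FALSE]
    pre_mean <- rowMeans(block[, rel < 0, drop = FALSE])
    block <- sweep(block, 1, pre_mean, "-")
    rows <- (k - 1) * n_roi + seq_len(n_roi)
    sig[rows, ] <- block
    info[[k]] <- tibble::tibble(
      roi_id = norm$roi_meta$roi_id,
      trial_index = k,
      compartment = norm$roi_meta$compartment)
  }
  info <- dplyr::bind_rows(info)
  info$epoch_id <- paste0(info$roi_id, "_t", info$trial_index)
  structure(
    list(rel_time_s = rel, signal = sig,
         info = info[, c("epoch_id", "roi_id", "trial_index", "compartment")],
         pre_window_s = pre_window_s, post_window_s = post_window_s,
         trial_onsets_s = onsets, mode = norm$mode),
    class = "pk_epochs"
  )
}

#' Subtract the extrapolated decay tail of the preceding trial
#'
#' With inter-trial intervals of a few decay time constants, each epoch
#' after the first sits on the residual exponential tail of the preceding
#' response. Per-epoch re-baselining removes the tail's level at the
#' pre-window but not its continued decay, which deflates measured
#' amplitudes by a small constant -- immaterial for full-sized responses
#' but a large relative error for near-abolished ones (e.g. under
#' beta1-adrenoceptor blockade). This step removes the residual: for every
#' ROI it fits the single-exponential decay of trial `k - 1`, extrapolates
#' it into trial `k`'s window, and subtracts it (minus its own pre-window
#' mean, matching the re-baselining convention). Trials are corrected
#' sequentially so the fit of trial `k - 1` is itself tail-free. Epochs
#' whose preceding fit failed are left uncorrected.
#'
#' @param epochs A `pk_epochs` from [segment_by_stimulus()].
#' @param response_window_s Peak-search window for the per-epoch decay
#'   fits, in s.
#' @param smooth_s Moving-average span for the peak search (see
#'   [measure_amplitude()]).
#' @return The corrected `pk_epochs`.
#' @export
subtract_trial_tails <- function(epochs, response_window_s,
                                 smooth_s = NULL) {
  stopifnot(inherits(epochs, "pk_epochs"))
  onsets <- epochs$trial_onsets_s
  if (is.null(onsets) || length(onsets) < 2) return(epochs)
  rel <- epochs$rel_time_s
  pre_idx <- which(rel < 0)
  info <- epochs$info
  for (k in 2:length(onsets)) {
    prev_rows <- which(info$trial_index == k - 1)
    cur_rows <- which(info$trial_index == k)
    if (length(prev_rows) == 0 || length(cur_rows) == 0) next
    prev <- epochs_subset(epochs, prev_rows)
    pk <- measure_amplitude(prev, response_window_s, smooth_s)
    fits <- fit_decay(prev, peaks = pk, offset = FALSE)
    gap <- onsets[k] - onsets[k - 1]
    key <- match(info$roi_id[cur_rows], fits$roi_id)
    for (j in seq_along(cur_rows)) {
      f <- fits[key[j], ]
      if (is.na(key[j]) || f$decay_status == "failed" ||
          is.na(f$decay_tau_s) || is.na(f$decay_y0)) next
      tail_pred <- f$decay_y0 *
        exp(-(gap + rel - pk$t_peak_s[key[j]]) / f$decay_tau_s)
      epochs$signal[cur_rows[j], ] <- epochs$signal[cur_rows[j], ] -
        (tail_pred - mean(tail_pred[pre_idx]))
    }
  }
  epochs
}

#' @export
print.pk_epochs <- function(x, ...) {
  cat(sprintf(
    "<pk_epochs> %d epoch(s) (%d ROI(s) x %d trial(s)), window [-%g, +%g) s\n",
    nrow(x$signal), length(unique(x$info$roi_id)),
    length(unique(x$info$trial_index)), x$pre_window_s, x$post_window_s))
  invisible(x)
}

#' Subset epochs by row index or predicate on the info table
#'
#' @param epochs A `pk_epochs`.
#' @param rows Integer or logical index into the epochs.
#' @return A `pk_epochs` with the selected epochs.
#' @export
epochs_subset <- function(epochs, rows) {
  stopifnot(inherits(epochs, "pk_epochs"))
  epochs$signal <- epochs$signal[rows, , drop = FALSE]
  epochs$info <- epochs$info[rows, ]
  epochs
}
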