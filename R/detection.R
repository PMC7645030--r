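#' Per-epoch statistical responsiveness test and threshold classification
#'
#' For each ROI x trial epoch, compares the response-window samples against
#' the pre-stimulus baseline samples with a two-sided rank-sum
#' (Mann-Whitney) test -- optionally Welch's t -- and, in parallel, applies
#' the fixed percent-of-baseline peak threshold used to select dendritic
#' ROIs for quantitative analysis. Frames within a window are treated as
#' exchangeable samples; for high frame rates a `subsample` step decimates
#' both windows to mitigate serial correlation.
#'
#' @param epochs A `pk_epochs` (the pre-window is the baseline sample).
#' @param response_window_s Length of the response window after onset, s.
#' @param alpha Test level (per ROI, uncorrected by default).
#' @param method `"ranksum"` (default) or `"welch"`.
#' @param threshold_pct Peak threshold in % of baseline (strict `>`).
#' @param subsample Keep every `subsample`-th frame in both windows.
#' @param adjust Optional p-value adjustment across epochs (any method of
#'   [stats::p.adjust()], e.g. `"BH"`); `"none"` by default.
#' @return Tibble with one row per epoch: `epoch_id`, `roi_id`,
#'   `trial_index`, `compartment`, `p_value`, `is_test_responsive`,
#'   `peak_signal_pct`, `passes_threshold`, `degenerate`.
#' @export
test_responsiveness <- function(epochs, response_window_s, alpha = 0.05,
                                method = c("ranksum", "welch"),
                                threshold_pct = 2, subsample = 1,
                                adjust = "none") {
  stopifnot(inherits(epochs, "pk_epochs"))
  method <- match.arg(method)
  check_number(response_window_s, "response_window_s", positive = TRUE)
  rel <- epochs$rel_time_s
  base_idx <- which(rel < 0)
  resp_idx <- which(rel >= 0 & rel <= response_window_s)
  if (subsample > 1) {
    base_idx <- base_idx[seq(1, length(base_idx), by = subsample)]
    resp_idx <- resp_idx[seq(1, length(resp_idx), by = subsample)]
  }
  if (length(base_idx) < 3 || length(resp_idx) < 3) {
    stop("both windows must contain at least 3 frames", call. = FALSE)
  }
  n <- nrow(epochs$signal)
  p <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    b <- epochs$signal[i, base_idx]
    r <- epochs$signal[i, resp_idx]
    if (length(unique(c(b, r))) == 1) {
      p[i] <- 1
      degenerate[i] <- TRUE
    } else if (method == "ranksum") {
      p[i] <- stats::wilcox.test(r, b, exact = FALSE)$p.value
    } else {
      p[i] <- stats::t.test(r, b)$p.value
    }
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  thr <- threshold_classify(epochs, response_window_s, threshold_pct)
  out <- epochs$info
  out$p_value <- p
  out$is_test_responsive <- p_adj < alpha & !degenerate
  out$peak_signal_pct <- thr$peak_signal_pct
  out$passes_threshold <- thr$passes_threshold
  out$degenerate <- degenerate
  attr(out, "alpha") <- alpha
  attr(out, "threshold_pct") <- threshold_pct
  out
}

#' Classify epochs against a percent-of-baseline peak threshold
#'
#' The peak is the maximum of the signal within the response window; an
#' epoch passes when the peak strictly exceeds `threshold_pct`.
#'
#' @inheritParams test_responsiveness
#' @return Tibble with `epoch_id`, `peak_signal_pct`, `passes_threshold`.
#' @export
threshold_classify <- function(epochs, response_window_s, threshold_pct = 2) {
  stopifnot(inherits(epochs, "pk_epochs"))
  rel <- epochs$rel_time_s
  idx <- which(rel >= 0 & rel <= response_window_s)
  if (length(idx) < 1) stop("response window is empty", call. = FALSE)
  peak <- apply(epochs$signal[, idx, drop = FALSE], 1, max)
  tibble::tibble(epoch_id = epochs$info$epoch_id,
                 peak_signal_pct = peak,
                 passes_threshold = peak > threshold_pct)
}

#' Concordance between the statistical test and the peak threshold
#'
#' Computes both conditional fractions over pooled ROI x trial results: the
#' fraction of test-positive epochs whose peak also exceeds the threshold,
#' and the fraction of above-threshold epochs that also pass the test.
#' Undefined fractions (empty denominator) are reported as `NA`, not 0.
#'
#' @param results A results table from [test_responsiveness()] (all rows
#'   must share the same alpha and threshold).
#' @return A list of class `pk_concordance`: `n_test_positive`,
#'   `n_above_threshold`, `n_both`, `frac_test_positive_above_threshold`,
#'   `frac_above_threshold_test_positive`.
#' @export
concordance <- function(results) {
  stopifnot(all(c("is_test_responsive", "passes_threshold") %in%
                  names(results)))
  n_test <- sum(results$is_test_responsive)
  n_thr <- sum(results$passes_threshold)
  n_both <- sum(results$is_test_responsive & results$passes_threshold)
  structure(
    list(n_test_positive = n_test,
         n_above_threshold = n_thr,
         n_both = n_both,
         frac_test_positive_above_threshold =
           if (n_test > 0) n_both / n_test else NA_real_,
         frac_above_threshold_test_positive =
           if (n_thr > 0) n_both / n_thr else NA_real_),
    class = "pk_concordance")
}

#' @export
print.pk_concordance <- function(x, ...) {
  cat(sprintf(
    paste0("<pk_concordance> test+: %d, >threshold: %d, both: %d\n",
           "  P(>thr | test+) = %s; P(test+ | >thr) = %s\n"),
    x$n_test_positive, x$n_above_threshold, x$n_both,
    format(x$frac_test_positive_above_threshold, digits = 4),
    format(x$frac_above_threshold_test_positive, digits = 4)))
  invisible(x)
}

#' Repeated-responder statistics across trials
#'
#' Fraction of ROIs classified responsive in every trial (the intersection
#' across trials), plus per-trial responsive counts. Every ROI must carry a
#' result for every trial.
#'
#' @param results A results table from [test_responsiveness()].
#' @param criterion Column used as the responsiveness verdict
#'   (`"is_test_responsive"` or `"passes_threshold"`).
#' @return A list: `n_rois`, `n_trials`, `n_all_trials`,
#'   `frac_all_trials`, and `per_trial` (tibble of per-trial counts).
#' @export
repeated_responders <- function(results,
                                criterion = c("is_test_responsive",
                                              "passes_threshold")) {
  criterion <- match.arg(criterion)
  tab <- table(results$roi_id, results$trial_index)
  if (any(tab != 1)) {
    stop("every ROI must have exactly one result per trial", call. = FALSE)
  }
  flag <- results[[criterion]]
  per_roi <- tapply(flag, results$roi_id, all)
  per_trial <- dplyr::summarise(
    dplyr::group_by(results, .data$trial_index),
    n_responsive = sum(.data[[criterion]]), n_rois = dplyr::n(),
    .groups = "drop")
  list(n_rois = length(per_roi),
       n_trials = length(unique(results$trial_index)),
       n_all_trials = sum(per_roi),
       frac_all_trials = mean(per_roi),
       per_trial = per_trial)
}
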