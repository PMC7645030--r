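#' Describe a repeated-stimulation pharmacology design
#'
#' The canonical slice design is two photostimulation trials in control
#' condition (to assess response stability) followed by a third trial in the
#' presence of a bath-applied drug; the in vivo variant inserts a saline
#' injection between control and drug. Time-resolved post-injection
#' snapshots map to additional drug trials.
#'
#' @param conditions Character vector, one entry per trial, each one of
#'   `"control"`, `"saline"`, `"drug"`.
#' @param drug Drug name (label only).
#' @param dose Dose text (label only).
#' @return A tibble of class `pk_design` with columns `trial_index`,
#'   `condition`, `drug`, `dose`.
#' @examples
#' experiment_design(c("control", "control", "drug"),
#'                   drug = "yohimbine", dose = "1 uM")
#' @export
experiment_design <- function(conditions, drug = "", dose = "") {
  if (!all(conditions %in% c("control", "saline", "drug"))) {
    stop("conditions must be 'control', 'saline' or 'drug'", call. = FALSE)
  }
  if (conditions[1] != "control") {
    stop("the first trial must be a control trial", call. = FALSE)
  }
  first_drug <- match("drug", conditions)
  if (!is.na(first_drug) && first_drug == 1) {
    stop("drug trials must follow at least one control trial", call. = FALSE)
  }
  out <- tibble::tibble(
    trial_index = seq_along(conditions),
    condition = conditions,
    drug = ifelse(conditions == "drug", drug, ""),
    dose = ifelse(conditions == "drug", dose, ""))
  class(out) <- c("pk_design", class(out))
  out
}

#' Normalize per-trial amplitudes to each ROI's first response
#'
#' Expresses every amplitude as a percentage of the same ROI's trial-1
#' amplitude (`value_k = 100 * A_k / A_1`), the scale on which
#' repeated-stimulation drug effects are reported. ROIs whose first-trial
#' amplitude is zero or negative cannot be normalized and are excluded with
#' a warning. Applying the function to an already-normalized table is the
#' identity.
#'
#' @param metrics Tibble with columns `roi_id`, `trial_index`,
#'   `amplitude_pct` (e.g. from [measure_amplitude()] or
#'   [epoch_kinetics()]).
#' @return The table restricted to normalizable ROIs, with an added column
#'   `norm_amplitude_pct`.
#' @export
normalize_amplitudes <- function(metrics) {
  stopifnot(all(c("roi_id", "trial_index", "amplitude_pct") %in%
                  names(metrics)))
  first <- metrics[metrics$trial_index == min(metrics$trial_index), ]
  bad <- first$roi_id[first$amplitude_pct <= 0]
  if (length(bad) > 0) {
    warning(sprintf(
      "excluding %d ROI(s) with non-positive first-trial amplitude: %s",
      length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    metrics <- metrics[!(metrics$roi_id %in% bad), ]
    first <- first[!(first$roi_id %in% bad), ]
  }
  a1 <- stats::setNames(first$amplitude_pct, first$roi_id)
  metrics$norm_amplitude_pct <- unname(100 * metrics$amplitude_pct /
                                         a1[metrics$roi_id])
  metrics
}

#' Summarize a pharmacology design across ROIs
#'
#' Per-trial mean and SEM of the normalized amplitudes across ROIs, with
#' paired two-sided significance tests of each trial against trial 1
#' (flagged `*`) and against trial 2 (flagged `+`), following the
#' two-control-then-drug reporting convention. The default paired test is
#' the Wilcoxon signed-rank across ROIs; Welch's paired t is available.
#' With fewer than 3 ROIs the summaries are computed but the tests are
#' suppressed.
#'
#' @param normalized Output of [normalize_amplitudes()].
#' @param design Optional [experiment_design()]; condition labels are
#'   joined into the summary.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param alpha Significance level for the flags.
#' @return A tibble of class `pk_pharm_summary`: one row per trial with
#'   `n`, `mean_norm_pct`, `sem_norm_pct`, `p_vs_trial1`, `p_vs_trial2`,
#'   `sig_vs_trial1`, `sig_vs_trial2`, `flags`.
#' @export
summarize_condition <- function(normalized, design = NULL,
                                test = c("wilcoxon", "t"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot("norm_amplitude_pct" %in% names(normalized))
  trials <- sort(unique(normalized$trial_index))
  wide <- tidyr::pivot_wider(
    normalized[, c("roi_id", "trial_index", "norm_amplitude_pct")],
    names_from = "trial_index", values_from = "norm_amplitude_pct")
  values <- function(k) wide[[as.character(k)]]
  do_tests <- nrow(wide) >= 3
  paired_p <- function(k, ref) {
    if (!do_tests || k == ref || !(ref %in% trials)) return(NA_real_)
    x <- values(k); y <- values(ref)
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || all(x[ok] == y[ok])) return(NA_real_)
    if (test == "wilcoxon") {
      stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::t.test(x[ok], y[ok], paired = TRUE)$p.value
    }
  }
  rows <- lapply(trials, function(k) {
    v <- values(k)
    v <- v[!is.na(v)]
    p1 <- paired_p(k, trials[1])
    p2 <- if (length(trials) >= 2) paired_p(k, trials[2]) else NA_real_
    tibble::tibble(
      trial_index = k, n = length(v), mean_norm_pct = mean(v),
      sem_norm_pct = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
        else NA_real_,
      p_vs_trial1 = p1, p_vs_trial2 = p2,
      sig_vs_trial1 = !is.na(p1) & p1 < alpha,
      sig_vs_trial2 = !is.na(p2) & p2 < alpha)
  })
  out <- dplyr::bind_rows(rows)
  out$flags <- paste0(ifelse(out$sig_vs_trial1, "*", ""),
                      ifelse(out$sig_vs_trial2, "+", ""))
  if (!is.null(design)) {
    out <- dplyr::left_join(out,
                            design[, c("trial_index", "condition", "drug")],
                            by = "trial_index")
  }
  class(out) <- c("pk_pharm_summary", class(out))
  out
}

#' Response amplitude as a fraction of the forskolin plateau
#'
#' The forskolin (FSK) plateau is the sensor's maximal response; expressing
#' the stimulus-evoked amplitude as a fraction of it makes amplitudes
#' comparable across sensors and preparations.
#'
#' @param response_amplitude_pct Mean stimulus response amplitude, %.
#' @param fsk_amplitude_pct Mean FSK plateau amplitude, % (must be > 0).
#' @return The ratio (dimensionless), or `NA` if the FSK amplitude is
#'   missing.
#' @examples
#' fsk_fraction(7.4, 25.7)
#' @export
fsk_fraction <- function(response_amplitude_pct, fsk_amplitude_pct) {
  if (is.null(fsk_amplitude_pct) || is.na(fsk_amplitude_pct)) {
    return(NA_real_)
  }
  if (fsk_amplitude_pct <= 0) {
    stop("`fsk_amplitude_pct` must be > 0", call. = FALSE)
  }
  response_amplitude_pct / fsk_amplitude_pct
}

#' Per-trial kinetics comparison for a pharmacology design
#'
#' Reports, per trial, the modal time-to-peak bin and the mean decay time
#' constant over epochs with an `"ok"` decay fit, with the same paired
#' significance flags as [summarize_condition()] applied to peak times and
#' decay constants. A trial in which every decay fit failed has its tau
#' reported absent (`NA`).
#'
#' @param metrics Output of [epoch_kinetics()] (needs `t_peak_s`,
#'   `t_peak_bin`, `decay_tau_s`, `decay_status`).
#' @param bin_width_s Bin width used for the modal bin, s.
#' @param test,alpha As in [summarize_condition()].
#' @return Tibble with one row per trial: `modal_bin`, `n_peak`,
#'   `mean_decay_tau_s`, `sem_decay_tau_s`, `n_decay`, and significance
#'   flags for the peak-time shift.
#' @export
kinetics_shift_report <- function(metrics, bin_width_s = 30,
                                  test = c("wilcoxon", "t"), alpha = 0.05) {
  test <- match.arg(test)
  trials <- sort(unique(metrics$trial_index))
  wide_tp <- tidyr::pivot_wider(
    metrics[, c("roi_id", "trial_index", "t_peak_s")],
    names_from = "trial_index", values_from = "t_peak_s")
  paired_p <- function(k, ref) {
    if (k == ref || !(ref %in% trials) || nrow(wide_tp) < 3) {
      return(NA_real_)
    }
    x <- wide_tp[[as.character(k)]]
    y <- wide_tp[[as.character(ref)]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || all(x[ok] == y[ok])) return(NA_real_)
    if (test == "wilcoxon") {
      stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::t.test(x[ok], y[ok], paired = TRUE)$p.value
    }
  }
  rows <- lapply(trials, function(k) {
    mk <- metrics[metrics$trial_index == k, ]
    bins <- time_to_peak_bin(mk$t_peak_s, bin_width_s)$bin_label
    modal <- names(sort(table(bins), decreasing = TRUE))[1]
    ok_decay <- mk$decay_status %in% "ok"
    taus <- mk$decay_tau_s[ok_decay]
    p1 <- paired_p(k, trials[1])
    p2 <- if (length(trials) >= 2) paired_p(k, trials[2]) else NA_real_
    tibble::tibble(
      trial_index = k, modal_bin = modal, n_peak = nrow(mk),
      mean_decay_tau_s = if (length(taus) > 0) mean(taus) else NA_real_,
      sem_decay_tau_s = if (length(taus) > 1)
        stats::sd(taus) / sqrt(length(taus)) else NA_real_,
      n_decay = length(taus),
      p_peak_vs_trial1 = p1, p_peak_vs_trial2 = p2,
      sig_peak_vs_trial1 = !is.na(p1) & p1 < alpha,
      sig_peak_vs_trial2 = !is.na(p2) & p2 < alpha)
  })
  dplyr::bind_rows(rows)
}
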