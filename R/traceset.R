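#' Construct a trace set
#'
#' A trace set holds per-ROI, per-frame fluorescence intensities for one or
#' more channels, together with the sample clock, ROI metadata and the
#' stimulation protocol. It is the common container produced by the
#' synthetic generator, by ROI extraction from image stacks, and by the CSV
#' readers.
#'
#' @param time_s Strictly increasing numeric vector of frame times, in s.
#' @param channels Named list of ROI-by-frame intensity matrices (rows =
#'   ROIs, columns = frames). All matrices must share dimensions; values must
#'   be finite and > 0.
#' @param roi_meta Tibble with one row per ROI: `roi_id`, `compartment`
#'   (optionally more columns, e.g. a layer tag). Row order matches matrix
#'   rows.
#' @param protocol A [stimulus_protocol()], or `NULL` for unstimulated
#'   recordings.
#' @param mode `"fret"` or `"single"`.
#' @param seed Optional integer recording the generator seed.
#' @return An object of class `pk_traceset`.
#' @export
traceset <- function(time_s, channels, roi_meta, protocol = NULL,
                     mode = c("fret", "single"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(time_s) || is.unsorted(time_s, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) {
    stop("all channel matrices must share dimensions", call. = FALSE)
  }
  if (dims[[1]][2] != length(time_s)) {
    stop("channel matrices must have one column per frame", call. = FALSE)
  }
  for (ch in names(channels)) {
    if (any(!is.finite(channels[[ch]]))) {
      stop(sprintf("channel '%s' contains non-finite intensities", ch),
           call. = FALSE)
    }
  }
  roi_meta <- tibble::as_tibble(roi_meta)
  if (!all(c("roi_id", "compartment") %in% names(roi_meta))) {
    stop("`roi_meta` needs columns roi_id and compartment", call. = FALSE)
  }
  if (nrow(roi_meta) != dims[[1]][1]) {
    stop("`roi_meta` must have one row per ROI", call. = FALSE)
  }
  if (anyDuplicated(roi_meta$roi_id)) {
    stop("`roi_meta$roi_id` must be unique", call. = FALSE)
  }
  channels <- lapply(channels, function(m) {
    rownames(m) <- roi_meta$roi_id
    m
  })
  structure(
    list(time_s = as.numeric(time_s), channels = channels,
         roi_meta = roi_meta, protocol = protocol, mode = mode, seed = seed),
    class = "pk_traceset"
  )
}

#' @export
print.pk_traceset <- function(x, ...) {
  cat(sprintf(
    "<pk_traceset> %s mode: %d ROI(s) x %d frames, channels: %s\n",
    x$mode, nrow(x$roi_meta), length(x$time_s),
    paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$protocol)) print(x$protocol)
  invisible(x)
}

#' Number of ROIs / frames in a trace set
#' @param ts A `pk_traceset`.
#' @return Integer count.
#' @export
n_rois <- function(ts) nrow(ts$roi_meta)

#' @rdname n_rois
#' @export
n_frames <- function(ts) length(ts$time_s)

#' Frame rate of a trace set (Hz), from the median frame interval
#' @param ts A `pk_traceset` or `pk_normalized`.
#' @return Frame rate in Hz.
#' @export
frame_rate <- function(ts) 1 / stats::median(diff(ts$time_s))

#' Drop ROIs from a trace set
#'
#' @param ts A `pk_traceset`.
#' @param roi_ids Character vector of ROI ids to drop.
#' @return The trace set without those ROIs.
#' @export
drop_rois <- function(ts, roi_ids) {
  keep <- !(ts$roi_meta$roi_id %in% roi_ids)
  if (!any(keep)) stop("dropping all ROIs", call. = FALSE)
  ts$channels <- lapply(ts$channels, function(m) m[keep, , drop = FALSE])
  ts$roi_meta <- ts$roi_meta[keep, ]
  ts
}
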