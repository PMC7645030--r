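#' Write a trace set as wide CSV plus JSON sidecar
#'
#' The CSV holds one `time_s` column followed by one `<roi_id>__<channel>`
#' column per trace. The sidecar records mode, ROI metadata, protocol, seed,
#' and (optionally) the simulation ground truth, so a written trace set can
#' be read back losslessly with [read_traceset()].
#'
#' @param ts A `pk_traceset`.
#' @param path CSV path; the sidecar goes to `<path without .csv>.json`.
#' @param ground_truth Optional `pk_ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_traceset <- function(ts, path, ground_truth = NULL) {
  stopifnot(inherits(ts, "pk_traceset"))
  cols <- list(time_s = ts$time_s)
  for (ch in names(ts$channels)) {
    m <- ts$channels[[ch]]
    for (i in seq_len(nrow(m))) {
      cols[[paste0(ts$roi_meta$roi_id[i], "__", ch)]] <- m[i, ]
    }
  }
  df <- tibble::as_tibble(cols)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    mode = ts$mode,
    seed = ts$seed,
    roi_meta = ts$roi_meta,
    protocol = if (!is.null(ts$protocol)) unclass(ts$protocol),
    ground_truth = if (!is.null(ground_truth)) list(
      rois = ground_truth$rois,
      trials = ground_truth$trials,
      kernel = unclass(ground_truth$kernel),
      seed = ground_truth$seed))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a trace set written by [write_traceset()] or a plain CSV
#'
#' Wide CSVs (`time_s` + `<roi>__<channel>` columns) are recognized by
#' their header; long CSVs need columns `roi_id`, `time_s`, `channel`,
#' `intensity`. When the JSON sidecar is present, metadata, protocol, seed
#' and ground truth are restored; otherwise ROIs default to `"soma"`
#' compartments and no protocol.
#'
#' @param path CSV path.
#' @param mode Fallback mode when no sidecar exists.
#' @return A `pk_traceset`; a restored ground truth, if any, is attached as
#'   attribute `"ground_truth"`.
#' @export
read_traceset <- function(path, mode = c("fret", "single")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("CSV must contain a `time_s` column", call. = FALSE)
  }
  long_form <- all(c("roi_id", "channel", "intensity") %in% names(df))
  if (long_form) {
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(df),
      id_cols = "time_s",
      names_from = c("roi_id", "channel"), names_sep = "__",
      values_from = "intensity")
    df <- as.data.frame(wide, check.names = FALSE)
  }
  trace_cols <- setdiff(names(df), "time_s")
  if (!all(grepl("__", trace_cols))) {
    stop("trace columns must be named <roi_id>__<channel>", call. = FALSE)
  }
  parts <- strsplit(trace_cols, "__")
  roi_ids <- unique(vapply(parts, `[`, "", 1))
  chans <- unique(vapply(parts, `[`, "", 2))
  channels <- lapply(chans, function(ch) {
    m <- t(as.matrix(df[, paste0(roi_ids, "__", ch), drop = FALSE]))
    rownames(m) <- roi_ids
    m
  })
  names(channels) <- chans

  side_file <- sidecar_path(path)
  roi_meta <- tibble::tibble(roi_id = roi_ids, compartment = "soma")
  protocol <- NULL
  seed <- NULL
  gt <- NULL
  if (file.exists(side_file)) {
    side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
    mode <- side$mode
    seed <- side$seed
    roi_meta <- tibble::as_tibble(side$roi_meta)
    if (!is.null(side$protocol)) {
      protocol <- stimulus_protocol(
        side$protocol$pulse_width_ms, side$protocol$pulse_rate_hz,
        side$protocol$train_duration_s, side$protocol$train_onsets_s,
        side$protocol$label %||% "")
    }
    if (!is.null(side$ground_truth)) {
      kern <- side$ground_truth$kernel
      gt <- structure(
        list(rois = tibble::as_tibble(side$ground_truth$rois),
             trials = tibble::as_tibble(side$ground_truth$trials),
             kernel = response_kernel(
               kern$amplitude_pct, kern$tau_rise_s, kern$tau_decay_s,
               kern$latency_s, kern$form,
               rise_duration_s = kern$rise_duration_s),
             seed = side$ground_truth$seed),
        class = "pk_ground_truth")
    }
  }
  ts <- traceset(df$time_s, channels, roi_meta, protocol = protocol,
                 mode = mode, seed = seed)
  attr(ts, "ground_truth") <- gt
  ts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-ROI mean intensity traces from an image stack
#'
#' Averages pixel intensities over each ROI mask in every frame. Stacks are
#' given per channel as `y * x * frame` arrays (or a single array for one
#' channel); a TIFF path is accepted when the `tiff` package is installed.
#' ROIs are either a label matrix (pixel value = ROI index, 0 = background)
#' or a named list of logical masks.
#'
#' @param stack Named list of 3-D arrays, one per channel; a single 3-D
#'   array (channel `"green"`); or a file path to a (possibly multi-page)
#'   TIFF.
#' @param rois Label matrix or named list of logical masks matching the
#'   frame dimensions.
#' @param time_s Frame times; default `frame / frame_rate_hz`.
#' @param frame_rate_hz Used when `time_s` is missing.
#' @param compartments Per-ROI compartment tags (recycled).
#' @param protocol Optional [stimulus_protocol()] to attach.
#' @param mode Trace-set mode.
#' @return A `pk_traceset`.
#' @export
extract_roi_traces <- function(stack, rois, time_s = NULL,
                               frame_rate_hz = 1, compartments = "soma",
                               protocol = NULL,
                               mode = c("single", "fret")) {
  mode <- match.arg(mode)
  if (is.character(stack)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF stacks requires the 'tiff' package", call. = FALSE)
    }
    pages <- tiff::readTIFF(stack, all = TRUE)
    stack <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2],
                                          length(pages)))
  }
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- list(green = stack)
  }
  if (!is.list(stack) || is.null(names(stack))) {
    stop("`stack` must be a named list of y*x*frame arrays", call. = FALSE)
  }
  frame_dim <- dim(stack[[1]])[1:2]
  n_fr <- dim(stack[[1]])[3]
  masks <- rois_as_masks(rois, frame_dim)
  if (is.null(time_s)) time_s <- (seq_len(n_fr) - 1) / frame_rate_hz
  channels <- lapply(stack, function(arr) {
    flat <- matrix(arr, nrow = prod(frame_dim), ncol = n_fr)
    t(vapply(masks, function(msk) colMeans(flat[msk, , drop = FALSE]),
             numeric(n_fr)))
  })
  roi_meta <- tibble::tibble(
    roi_id = names(masks),
    compartment = rep_len(compartments, length(masks)))
  traceset(time_s, channels, roi_meta, protocol = protocol, mode = mode)
}

rois_as_masks <- function(rois, frame_dim) {
  if (is.matrix(rois)) {
    labels <- sort(setdiff(unique(as.vector(rois)), 0))
    if (length(labels) == 0) stop("label image contains no ROIs",
                                  call. = FALSE)
    masks <- lapply(labels, function(l) which(as.vector(rois) == l))
    names(masks) <- sprintf("roi%03d", labels)
  } else if (is.list(rois)) {
    if (is.null(names(rois))) names(rois) <- sprintf("roi%03d",
                                                     seq_along(rois))
    masks <- lapply(rois, function(m) {
      if (is.logical(m)) which(as.vector(m)) else as.integer(m)
    })
  } else {
    stop("`rois` must be a label matrix or a list of masks", call. = FALSE)
  }
  for (nm in names(masks)) {
    idx <- masks[[nm]]
    if (length(idx) == 0) {
      stop(sprintf("ROI '%s' has an empty mask", nm), call. = FALSE)
    }
    if (any(idx < 1) || any(idx > prod(frame_dim))) {
      stop(sprintf("ROI '%s' falls outside the image bounds", nm),
           call. = FALSE)
    }
  }
  masks
}

#' Render a trace set as a synthetic movie of disk-shaped ROIs
#'
#' Draws each ROI as a disk whose pixel intensity follows the ROI's trace,
#' on a dark background; used for end-to-end tests of
#' [extract_roi_traces()].
#'
#' @param ts A single-channel `pk_traceset`.
#' @param image_size Edge length of the square frame, pixels.
#' @param radius Disk radius, pixels.
#' @param background Background intensity.
#' @return A list with `stack` (y*x*frame array, scaled to `[0, 1)` by
#'   `scale_max`), `labels` (label matrix) and `scale_max`.
#' @export
render_roi_movie <- function(ts, image_size = 64, radius = 3,
                             background = 0) {
  stopifnot(inherits(ts, "pk_traceset"), length(ts$channels) == 1)
  n <- n_rois(ts)
  per_row <- max(1, floor(image_size / (2 * radius + 3)))
  if (n > per_row^2) stop("image too small for the ROI count", call. = FALSE)
  centers <- cbind(
    x = ((seq_len(n) - 1) %% per_row) * (2 * radius + 3) + radius + 2,
    y = ((seq_len(n) - 1) %/% per_row) * (2 * radius + 3) + radius + 2)
  labels <- matrix(0L, image_size, image_size)
  xg <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  yg <- matrix(seq_len(image_size), image_size, image_size)
  for (i in seq_len(n)) {
    inside <- (xg - centers[i, "x"])^2 + (yg - centers[i, "y"])^2 <=
      radius^2
    labels[inside] <- i
  }
  traces <- ts$channels[[1]]
  scale_max <- max(traces) * 1.05
  stack <- array(background / scale_max,
                 dim = c(image_size, image_size, n_frames(ts)))
  flat_n <- image_size^2
  for (i in seq_len(n)) {
    idx <- which(labels == i)
    for (f in seq_len(n_frames(ts))) {
      stack[idx + (f - 1) * flat_n] <- traces[i, f] / scale_max
    }
  }
  list(stack = stack, labels = labels, scale_max = scale_max)
}
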