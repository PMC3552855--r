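#' Pipeline configuration
#'
#' Bundles the per-run acquisition and processing parameters used by
#' [process_stack()]. Defaults correspond to epifluorescence imaging of
#' 50 x 500 µm channels with a 20x objective: 0.3225 µm/pixel, one frame
#' every 7 s, and a minimum object size of one platelet.
#'
#' @param pixel_size Pixel size, µm/pixel.
#' @param frame_interval Time between frames, s.
#' @param platelet_diameter Nominal platelet diameter, µm; sets the default
#'   small-object cutoff.
#' @param min_area Minimum connected-component area kept, in pixels.
#'   Default: the projected area of a single platelet,
#'   `round(pi * (platelet_diameter/2)^2 / pixel_size^2)` (47 px at defaults).
#' @param connectivity Pixel connectivity for component labelling, 4 or 8.
#' @param threshold_mode `"per_frame"` (each frame thresholded from its own
#'   histogram, the default) or `"global"` (one threshold from the pooled
#'   histogram of the whole stack).
#' @return A list of class `mfa_config`.
#' @examples
#' mfa_config()$min_area
#' @export
mfa_config <- function(pixel_size = 0.3225,
                       frame_interval = 7,
                       platelet_diameter = 2.5,
                       min_area = NULL,
                       connectivity = 8,
                       threshold_mode = c("per_frame", "global")) {
  stopifnot(pixel_size > 0, frame_interval > 0, platelet_diameter > 0)
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(min_area))
    min_area <- max(1L, as.integer(round(
      pi * (platelet_diameter / 2)^2 / pixel_size^2)))
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 platelet_diameter = platelet_diameter,
                 min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity),
                 threshold_mode = threshold_mode),
            class = "mfa_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys match the arguments of [mfa_config()]; missing keys take
#' the defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return An `mfa_config`.
#' @export
read_mfa_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mfa_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(mfa_config, vals)
}

#' Convert an RGB frame to 8-bit grayscale
#'
#' Applies the standard luminance weights (0.2989, 0.5870, 0.1140) to an
#' H x W x 3 array and rounds to integers; already-gray H x W input is passed
#' through unchanged.
#'
#' @param frame Numeric matrix (H x W, already gray) or H x W x 3 array with
#'   values in 0..255.
#' @return H x W numeric matrix of integers in 0..255.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) return(frame[, , 1])
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an H x W matrix or an H x W x 3 RGB array", call. = FALSE)
  w <- c(0.2989, 0.5870, 0.1140)
  g <- round(w[1] * frame[, , 1] + w[2] * frame[, , 2] + w[3] * frame[, , 3])
  dim(g) <- d[1:2]
  g
}

#' Triangle (Zack) threshold of an intensity histogram
#'
#' Geometric threshold selection for skewed, dark-background fluorescence
#' histograms. A line is drawn from the histogram peak to the far end of the
#' bright tail (the last nonzero bin); the threshold is the bin whose
#' (normalized) histogram point lies at maximal perpendicular distance from
#' that line. Counts are normalized by the peak count and bin positions by
#' the peak-to-tail span, so the choice does not depend on image size or bit
#' scaling. Ties are broken toward the brighter bin (a conservative
#' threshold, fewer foreground pixels). A histogram whose peak is the last
#' nonzero bin has no bright tail; the peak bin is returned with a warning.
#'
#' @param histogram Vector of 256 nonnegative counts for intensities 0..255.
#' @return The threshold intensity level (0..255). Segmentation keeps pixels
#'   with intensity strictly greater than this level.
#' @examples
#' h <- c(0, 500, 200, 80, 30, 10, 5, 2, rep(0, 246)); h[101] <- 4
#' triangle_threshold(h)
#' @export
triangle_threshold <- function(histogram) {
  if (!is.numeric(histogram) || length(histogram) != 256L)
    stop("histogram must have 256 bins (intensities 0..255)", call. = FALSE)
  if (any(histogram < 0) || any(!is.finite(histogram)))
    stop("histogram counts must be finite and nonnegative", call. = FALSE)
  nz <- which(histogram > 0)
  if (length(nz) == 0L)
    stop("degenerate histogram: all bins are zero", call. = FALSE)
  if (length(nz) == 1L) return(nz[1] - 1L)
  peak <- which.max(histogram)          # lowest index among tied peaks
  tail_bin <- nz[length(nz)]            # far end of the bright tail
  if (tail_bin <= peak) {
    warning("histogram peak is at the bright end; returning the peak bin")
    return(peak - 1L)
  }
  idx <- peak:tail_bin
  # normalized coordinates: x in [0,1] over the peak-to-tail span, y by peak
  x <- (idx - peak) / (tail_bin - peak)
  y <- histogram[idx] / histogram[peak]
  y1 <- 1                               # peak point (0, 1)
  y2 <- histogram[tail_bin] / histogram[peak]
  # perpendicular distance of (x, y) to the line (0,y1)-(1,y2)
  d <- abs((y2 - y1) * x - (y - y1)) / sqrt((y2 - y1)^2 + 1)
  if (max(d) < 1e-12) {  # flat/uniform histogram: no triangle geometry
    warning("degenerate (flat) histogram; returning the peak bin")
    return(peak - 1L)
  }
  best <- idx[which(d == max(d))]
  best[length(best)] - 1L               # tie -> brighter bin; 0-based level
}

#' Threshold a frame and remove sub-platelet objects
#'
#' Binarizes a grayscale frame at `frame > level`, labels connected
#' components, and removes every component smaller than `min_area` pixels
#' (isolated specks smaller than one platelet are noise). The filter is
#' idempotent: reapplying it changes nothing.
#'
#' @param frame H x W numeric matrix of intensities.
#' @param level Threshold intensity; pixels strictly above are foreground.
#' @param min_area Minimum component area kept, pixels (>= 1).
#' @param connectivity 4 or 8 (default 8).
#' @return A `binary_mask`: list with `mask` (H x W logical),
#'   `threshold_used`, `min_area_used`, `connectivity`.
#' @examples
#' f <- matrix(0, 20, 20); f[5:10, 5:14] <- 120
#' m <- binarize_and_filter(f, level = 50, min_area = 47)
#' surface_coverage(m)
#' @export
binarize_and_filter <- function(frame, level, min_area = 1L,
                                connectivity = 8L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a numeric matrix", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  min_area <- as.integer(min_area)
  if (is.na(min_area) || min_area < 1L)
    stop("min_area must be >= 1", call. = FALSE)
  mask <- frame > level
  if (min_area > 1L && any(mask)) {
    lab <- .label_components(mask, as.integer(connectivity))
    keep <- c(FALSE, tabulate(lab) >= min_area)  # slot 1 = background
    mask <- array(keep[lab + 1L], dim = dim(mask))
  }
  structure(list(mask = mask,
                 threshold_used = level,
                 min_area_used = min_area,
                 connectivity = as.integer(connectivity)),
            class = "binary_mask")
}

#' Percent surface coverage of a binary mask
#'
#' @param mask A `binary_mask` or a logical matrix.
#' @return 100 * (foreground pixels) / (total pixels).
#' @export
surface_coverage <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!is.logical(m) || is.null(dim(m)))
    stop("mask must be a logical matrix or binary_mask", call. = FALSE)
  if (length(m) == 0L)
    stop("mask has zero size", call. = FALSE)
  100 * sum(m) / length(m)
}

#' Process a time-lapse stack into a surface-coverage time series
#'
#' The full per-run segmentation pipeline: grayscale conversion if needed,
#' triangle thresholding (per frame by default, or one pooled global
#' threshold), removal of sub-platelet components, and the area fraction of
#' the surviving foreground. Thresholds are recorded per frame so any run is
#' reproducible from its output.
#'
#' @param stack An [image_stack()].
#' @param config An [mfa_config()].
#' @param keep_masks If `TRUE`, attach the per-frame `binary_mask`s as
#'   attribute `"masks"` of the result.
#' @return An `sc_timeseries`: data frame with columns `time_s`,
#'   `sc_percent`, `threshold_level`, carrying `frame_interval`, `pixel_size`
#'   and `metadata` attributes.
#' @export
process_stack <- function(stack, config = mfa_config(), keep_masks = FALSE) {
  if (!inherits(stack, "image_stack"))
    stop("stack must be an image_stack", call. = FALSE)
  if (!inherits(config, "mfa_config"))
    stop("config must be an mfa_config", call. = FALSE)
  n <- n_frames(stack)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- tryCatch(to_grayscale(get_frame(stack, i)), error = function(e)
      stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE))
    if (anyNA(f) || any(f < 0) || any(f > 255))
      stop(sprintf("frame %d: intensities outside 0..255", i), call. = FALSE)
    frames[[i]] <- f
  }
  global_level <- if (config$threshold_mode == "global") {
    pooled <- Reduce(`+`, lapply(frames, function(f)
      tabulate(as.integer(f) + 1L, nbins = 256L)))
    triangle_threshold(pooled)
  } else NA_integer_
  sc <- numeric(n)
  lev <- integer(n)
  masks <- if (keep_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    lev[i] <- if (config$threshold_mode == "global") global_level else
      triangle_threshold(tabulate(as.integer(frames[[i]]) + 1L, nbins = 256L))
    bm <- binarize_and_filter(frames[[i]], lev[i],
                              min_area = config$min_area,
                              connectivity = config$connectivity)
    sc[i] <- surface_coverage(bm)
    if (keep_masks) masks[[i]] <- bm
  }
  out <- sc_timeseries(
    time_s = (seq_len(n) - 1L) * stack$frame_interval,
    sc_percent = sc,
    threshold_level = lev,
    frame_interval = stack$frame_interval,
    metadata = stack$metadata)
  if (keep_masks) attr(out, "masks") <- masks
  out
}
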