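#' Time-lapse image stack
#'
#' Container for one channel's time-lapse: an 8-bit frame array plus the
#' acquisition parameters the downstream analysis needs.
#'
#' @param frames H x W x T numeric array (gray) or H x W x 3 x T (RGB), with
#'   intensities in 0..255. A single H x W matrix is treated as T = 1.
#' @param frame_interval Time between frames, s (default 7).
#' @param pixel_size Pixel size, µm/pixel (default 0.3225).
#' @param metadata Named list (e.g. shear rate, donor id, channel id, seed).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 7, pixel_size = 0.3225,
                        metadata = list()) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (!length(d) %in% c(3L, 4L))
    stop("frames must be H x W x T or H x W x 3 x T", call. = FALSE)
  if (length(d) == 4L && d[3] != 3L)
    stop("RGB stacks must have 3 colour planes", call. = FALSE)
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 255)
    stop("intensities must lie in 0..255", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, metadata = metadata),
            class = "image_stack")
}

#' Number of frames in a stack
#' @param stack An `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  d <- dim(stack$frames)
  as.integer(d[length(d)])
}

#' Extract one frame from a stack
#' @param stack An `image_stack`.
#' @param i Frame index (1-based).
#' @return H x W matrix (gray) or H x W x 3 array (RGB).
#' @export
get_frame <- function(stack, i) {
  d <- dim(stack$frames)
  if (i < 1L || i > d[length(d)])
    stop(sprintf("frame index %d out of range 1..%d", i, d[length(d)]),
         call. = FALSE)
  if (length(d) == 3L) stack$frames[, , i] else stack$frames[, , , i]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  kind <- if (length(d) == 4L) "RGB" else "gray"
  cat(sprintf("image_stack: %d x %d px, %d frames (%s), dt = %g s, %g um/px\n",
              d[1], d[2], d[length(d)], kind, x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Read a multipage TIFF into an image stack
#'
#' Accepts 8-bit grayscale or RGB multipage TIFFs; intensities are rescaled
#' from the reader's 0-1 range back to 0..255.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, frame_interval = 7, pixel_size = 0.3225,
                             metadata = list()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("empty TIFF: ", path, call. = FALSE)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf("corrupt stack: frame %d has inconsistent dimensions", i),
           call. = FALSE)
  arr <- if (length(d1) == 2L) {
    array(unlist(pages), dim = c(d1, length(pages)))
  } else {
    array(unlist(pages), dim = c(d1, length(pages)))
  }
  image_stack(round(arr * 255), frame_interval = frame_interval,
              pixel_size = pixel_size, metadata = metadata)
}

#' Write an image stack (or binary masks) as a multipage TIFF
#'
#' @param stack An `image_stack`, or a list of `binary_mask` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  imgs <- if (inherits(stack, "image_stack")) {
    lapply(seq_len(n_frames(stack)), function(i) get_frame(stack, i) / 255)
  } else if (is.list(stack) && all(vapply(stack, inherits, TRUE, "binary_mask"))) {
    lapply(stack, function(m) m$mask * 1)
  } else stop("stack must be an image_stack or a list of binary_mask",
              call. = FALSE)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Surface-coverage time series
#'
#' @param time_s Frame times, s, strictly increasing from 0.
#' @param sc_percent Percent surface coverage per frame, each in 0..100.
#' @param threshold_level Per-frame threshold used (NA if not applicable).
#' @param frame_interval Sampling interval, s.
#' @param metadata Named list (shear rate, donor id, ...).
#' @return Data frame of class `sc_timeseries`.
#' @export
sc_timeseries <- function(time_s, sc_percent,
                          threshold_level = NA_integer_,
                          frame_interval = NULL, metadata = list()) {
  if (length(time_s) != length(sc_percent))
    stop("time_s and sc_percent lengths differ", call. = FALSE)
  if (length(time_s) == 0L) stop("empty time series", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (any(sc_percent < 0 | sc_percent > 100))
    stop("sc_percent must lie in [0, 100]", call. = FALSE)
  if (is.null(frame_interval))
    frame_interval <- if (length(time_s) > 1L) time_s[2] - time_s[1] else 7
  out <- data.frame(time_s = time_s, sc_percent = sc_percent,
                    threshold_level = threshold_level)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "metadata") <- metadata
  class(out) <- c("sc_timeseries", "data.frame")
  out
}

#' Write / read a surface-coverage time series as CSV
#'
#' Columns: `time_s`, `sc_percent`, `threshold_level`.
#'
#' @param ts An `sc_timeseries`.
#' @param path CSV file path.
#' @return `path` (write) or an `sc_timeseries` (read).
#' @export
write_sc_csv <- function(ts, path) {
  stopifnot(inherits(ts, "sc_timeseries"))
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sc_csv
#' @param frame_interval,metadata Passed to [sc_timeseries()] on read.
#' @export
read_sc_csv <- function(path, frame_interval = NULL, metadata = list()) {
  d <- read.csv(path)
  if (!all(c("time_s", "sc_percent") %in% names(d)))
    stop("CSV must have columns time_s and sc_percent", call. = FALSE)
  sc_timeseries(d$time_s, d$sc_percent,
                threshold_level = if ("threshold_level" %in% names(d))
                  d$threshold_level else NA_integer_,
                frame_interval = frame_interval, metadata = metadata)
}
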