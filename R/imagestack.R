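# ImageStack: the universal raster input. frames is an H x W x T double
# array; calibration (pixel_size um/px, frame_interval s) travels with it.
# Coordinate convention, used package-wide: row-major, 0-based pixel
# indices; a pixel's position is its center; physical position (um) =
# 0-based index * pixel_size. x runs along columns, y along rows.

#' Construct an image stack
#'
#' @param frames Numeric matrix (single frame) or `H x W x T` array of
#'   non-negative finite intensities.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param frame_interval Frame interval in seconds (> 0 when `T > 1`).
#' @param t0 Acquisition start offset in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = 1, t0 = 0) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3L)
    stop("frames must be a matrix or an H x W x T array")
  if (any(dim(frames) < 1L)) stop("empty image stack")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  n_t <- dim(frames)[3]
  if (n_t > 1L && (!is.numeric(frame_interval) || frame_interval <= 0))
    stop("frame_interval must be positive for multi-frame stacks")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, t0 = t0),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, %.4g um/px, dt = %g s\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `image_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Frame times of a stack (seconds)
#' @param stack An `image_stack`.
#' @export
frame_times <- function(stack)
  stack$t0 + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval

#' Extract one frame as a matrix
#' @param stack An `image_stack`.
#' @param i Frame index (1-based).
#' @export
get_frame <- function(stack, i) {
  if (i < 1L || i > n_frames(stack)) stop("frame index out of range")
  stack$frames[, , i]
}

#' Rectangular region of interest
#'
#' @param row,col 0-based pixel indices of the ROI origin (top-left corner).
#' @param height,width ROI extent in pixels (> 0).
#' @export
roi <- function(row, col, height, width) {
  stopifnot(height > 0, width > 0, row >= 0, col >= 0)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

#' Crop an image stack to a region of interest
#'
#' Pixel values are copied bit-exactly; calibration metadata is preserved.
#'
#' @param stack An `image_stack`.
#' @param r A [roi()]; must lie fully inside the stack's frames.
#' @export
crop_roi <- function(stack, r) {
  stopifnot(inherits(stack, "image_stack"), inherits(r, "roi"))
  d <- dim(stack$frames)
  if (r$row + r$height > d[1] || r$col + r$width > d[2])
    stop("roi extends past the image edge (", r$row + r$height, " x ",
         r$col + r$width, " > ", d[1], " x ", d[2], ")")
  out <- stack$frames[r$row + seq_len(r$height), r$col + seq_len(r$width), ,
                      drop = FALSE]
  image_stack(out, stack$pixel_size, stack$frame_interval, stack$t0)
}

#' Read an image stack from a TIFF file
#'
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @param pixel_size Pixel size in um/px (> 0); always user-supplied because
#'   camera calibration is not reliably stored in the files this pipeline
#'   consumes.
#' @param frame_interval Frame interval in seconds.
#' @param t0 Acquisition start offset in seconds.
#' @return An [image_stack()] with frames ordered by page index, converted
#'   to double precision.
#' @export
read_stack <- function(path, pixel_size, frame_interval = 1, t0 = 0) {
  arr <- read_tiff(path)
  st <- image_stack(array(as.numeric(arr), dim = dim(arr)), pixel_size,
                    frame_interval, t0)
  st$source_bit_depth <- attr(arr, "bit_depth")
  st
}

#' Write an image stack to a (multi-page) TIFF file
#'
#' @param stack An `image_stack`.
#' @param path Output path.
#' @param dtype Sample type passed to [write_tiff()]; `"float64"` is
#'   lossless for double data.
#' @export
write_stack <- function(stack, path, dtype = "float64") {
  write_tiff(stack$frames, path, dtype = dtype)
}

#' Write / read tracks as delimited text
#'
#' The on-disk track format is a plain CSV with a one-line header and
#' columns `track_id, frame, t_s, x_um, y_um` (plus `gap_before` if
#' present). Frames are 1-based in memory and on disk.
#'
#' @param tracks Track data frame as produced by [link_tracks()].
#' @param path File path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a flow-vector table as CSV
#'
#' Columns: `toi_index, x_um, y_um, vx, vy, speed, directionality`
#' (velocities in um/min).
#'
#' @param field A `flow_field` (see [compute_flow_field()]).
#' @param path File path.
#' @export
write_flow_csv <- function(field, path) {
  utils::write.csv(field$vectors[, c("toi_index", "x_um", "y_um", "vx",
                                     "vy", "speed", "directionality")],
                   path, row.names = FALSE)
  invisible(path)
}
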