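# Spatio-temporal image correlation spectroscopy (STICS).
#
# For each square subregion of the movie and each sliding time-of-interest
# (TOI) window, the spatial cross-correlation between frame pairs separated
# by a temporal lag is computed (FFT, circular); the displacement of its
# peak as a function of lag gives the local flow velocity. Subtracting the
# TOI-mean image beforehand removes the immobile population, so static
# structures do not pin the correlation peak at zero shift.

#' STICS configuration
#'
#' Defaults follow the actin settings (16-px subregions shifted by 4 px,
#' 20-s TOI shifted by 2 s); for myosin use `toi_window = 60`,
#' `toi_shift = 6`.
#'
#' @param subregion Subregion edge length in px (>= 8).
#' @param subregion_shift Shift between subregions in px.
#' @param toi_window TOI window length in seconds.
#' @param toi_shift TOI shift in seconds.
#' @param max_lag Largest temporal lag (frames) used for the velocity fit.
#' @param min_peak_correlation Vector rejection threshold, as a fraction of
#'   the lag-0 correlation peak.
#' @export
stics_config <- function(subregion = 16L, subregion_shift = 4L,
                         toi_window = 20, toi_shift = 2, max_lag = 5L,
                         min_peak_correlation = 0.2) {
  stopifnot(subregion >= 8L, subregion_shift > 0L, toi_shift > 0,
            max_lag >= 1L, min_peak_correlation >= 0)
  structure(list(subregion = as.integer(subregion),
                 subregion_shift = as.integer(subregion_shift),
                 toi_window = toi_window, toi_shift = toi_shift,
                 max_lag = as.integer(max_lag),
                 min_peak_correlation = min_peak_correlation),
            class = "stics_config")
}

# fftshift for a 2D correlation map: put the zero-shift value at the center
# pixel (floor(s/2) + 1).
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  rr <- c(seq(floor(h / 2) + 1L, h), seq_len(floor(h / 2)))
  cc <- c(seq(floor(w / 2) + 1L, w), seq_len(floor(w / 2)))
  m[rr, cc]
}

#' Spatial cross-correlation map at a temporal lag
#'
#' Normalized circular cross-correlation of mean-subtracted intensities
#' between all frame pairs separated by `lag`, averaged over the stack.
#' The zero-shift value sits at the map center, index
#' `(floor(s/2) + 1, floor(s/2) + 1)`.
#'
#' @param sub_stack `s x s x T` numeric array (one subregion's movie).
#' @param lag Temporal lag in frames (`0 <= lag < T`).
#' @param mean_subtract Subtract the temporal mean image first (immobile
#'   filtering); default `TRUE`.
#' @return `s x s` correlation map.
#' @export
stics_correlation <- function(sub_stack, lag, mean_subtract = TRUE) {
  stopifnot(length(dim(sub_stack)) == 3L)
  n_t <- dim(sub_stack)[3]
  if (lag < 0L || lag >= n_t)
    stop("lag must satisfy 0 <= lag < T (got lag = ", lag, ", T = ", n_t, ")")
  x <- sub_stack
  if (mean_subtract) {
    mean_img <- apply(x, c(1, 2), mean)
    x <- sweep(x, c(1, 2), mean_img)
  }
  h <- dim(x)[1]; w <- dim(x)[2]
  acc <- matrix(0, h, w)
  n_pairs <- n_t - lag
  ffts <- lapply(seq_len(n_t), function(i) stats::fft(x[, , i]))
  norms <- vapply(seq_len(n_t), function(i) sqrt(sum(x[, , i]^2)),
                  numeric(1))
  for (t in seq_len(n_pairs)) {
    a <- ffts[[t]]; b <- ffts[[t + lag]]
    cc <- Re(stats::fft(Conj(a) * b, inverse = TRUE)) / (h * w)
    denom <- norms[t] * norms[t + lag]
    if (denom > 0) acc <- acc + cc / denom
  }
  fftshift2(acc / n_pairs)
}

# Correlation maps for lags 0..max_lag with the frame FFTs computed once
# (compute_flow_field hot path; stics_correlation is the reference
# single-lag implementation and the two agree to rounding).
stics_maps <- function(sub_stack, max_lag) {
  h <- dim(sub_stack)[1]; w <- dim(sub_stack)[2]; n_t <- dim(sub_stack)[3]
  flat <- matrix(sub_stack, h * w, n_t)
  flat <- flat - rowMeans(flat)           # immobile filter (TOI mean)
  ffts <- vector("list", n_t)
  norms <- numeric(n_t)
  for (i in seq_len(n_t)) {
    m <- matrix(flat[, i], h, w)
    ffts[[i]] <- stats::fft(m)
    norms[i] <- sqrt(sum(m^2))
  }
  lapply(0:max_lag, function(lag) {
    acc <- matrix(0, h, w)
    for (t in seq_len(n_t - lag)) {
      denom <- norms[t] * norms[t + lag]
      if (denom == 0) next
      acc <- acc + Re(stats::fft(Conj(ffts[[t]]) * ffts[[t + lag]],
                                 inverse = TRUE)) / (h * w * denom)
    }
    fftshift2(acc / (n_t - lag))
  })
}

# Sub-pixel peak localisation in a correlation map: 1D Gaussian (3-point
# log-parabola) refinement per axis around the integer peak -- exact for a
# Gaussian-shaped peak of any width; quadratic (non-log) fallback when a
# flanking value is non-positive; centroid fallback at map borders.
# Returns (row, col) offsets relative to the map center plus the peak value.
subpixel_peak <- function(map) {
  h <- nrow(map); w <- ncol(map)
  cr <- floor(h / 2) + 1L; cc <- floor(w / 2) + 1L
  pk <- which(map == max(map), arr.ind = TRUE)[1, ]
  r0 <- unname(pk[1]); c0 <- unname(pk[2])
  refine_axis <- function(vm, v0, vp) {
    if (vm > 0 && v0 > 0 && vp > 0) {
      lm_ <- log(vm); l0 <- log(v0); lp <- log(vp)
      den <- lm_ - 2 * l0 + lp
      if (den < 0) return(0.5 * (lm_ - lp) / den)
    }
    den <- vm - 2 * v0 + vp
    if (den < 0) {
      d <- 0.5 * (vm - vp) / den
      if (abs(d) <= 1) return(d)
    }
    0
  }
  off <- c(0, 0)
  if (r0 > 1L && r0 < h)
    off[1] <- refine_axis(map[r0 - 1L, c0], map[r0, c0], map[r0 + 1L, c0])
  if (c0 > 1L && c0 < w)
    off[2] <- refine_axis(map[r0, c0 - 1L], map[r0, c0], map[r0, c0 + 1L])
  off[!is.finite(off) | abs(off) > 1] <- 0
  c(row = r0 - cr + off[1], col = c0 - cc + off[2],
    value = max(map))
}

#' Compute a STICS flow field
#'
#' For every subregion fully inside the mask and every TOI window, tracks
#' the correlation-peak displacement across lags `1..max_lag` and converts
#' the least-squares slope (through the origin) of displacement versus lag
#' time into a velocity in um/min. Subregions whose lag-1 peak correlation
#' falls below `min_peak_correlation` times the lag-0 peak yield no vector.
#'
#' @param stack An [image_stack()].
#' @param mask A [cell_mask()] delimiting the analysis region; also defines
#'   the cell center used for directionality (mask centroid, fixed across
#'   TOIs).
#' @param config A [stics_config()].
#' @param start_frame First frame of the analysis window (1-based), e.g.
#'   the frame of maximum spread area.
#' @param max_duration Cap on the analysed duration in seconds (default
#'   300 s = 5 min after `start_frame`).
#' @return A `flow_field`: list with `vectors` (data frame: `toi_index`,
#'   `x_um`, `y_um`, `vx`, `vy`, `speed` (um/min), `directionality`),
#'   `cell_center_um`, and `config`.
#' @export
compute_flow_field <- function(stack, mask, config = stics_config(),
                               start_frame = 1L, max_duration = 300) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "cell_mask"))
  dt <- stack$frame_interval
  px <- stack$pixel_size
  toi_len <- max(2L, as.integer(round(config$toi_window / dt)))
  toi_step <- max(1L, as.integer(round(config$toi_shift / dt)))
  last_frame <- min(n_frames(stack),
                    start_frame + as.integer(floor(max_duration / dt)))
  if (last_frame - start_frame + 1L < toi_len)
    stop("stack spans less than one TOI window")
  if (toi_len <= config$max_lag)
    stop("TOI window must exceed max_lag frames")

  s <- config$subregion
  h <- dim(stack$frames)[1]; w <- dim(stack$frames)[2]
  row_starts <- seq(1L, h - s + 1L, by = config$subregion_shift)
  col_starts <- seq(1L, w - s + 1L, by = config$subregion_shift)
  # subregions fully inside the mask
  sub_ok <- outer(row_starts, col_starts, Vectorize(function(r, c)
    all(mask$mask[r:(r + s - 1L), c:(c + s - 1L)])))
  if (!any(sub_ok)) stop("no subregion lies fully inside the mask")

  center_um <- c(x = unname(mask$centroid_px["col"]) * px,
                 y = unname(mask$centroid_px["row"]) * px)
  toi_starts <- seq(start_frame, last_frame - toi_len + 1L, by = toi_step)
  lags <- seq_len(config$max_lag)

  rows_out <- list()
  for (ti in seq_along(toi_starts)) {
    fr <- toi_starts[ti] + seq_len(toi_len) - 1L
    for (i in seq_along(row_starts)) for (j in seq_along(col_starts)) {
      if (!sub_ok[i, j]) next
      r0 <- row_starts[i]; c0 <- col_starts[j]
      sub <- stack$frames[r0:(r0 + s - 1L), c0:(c0 + s - 1L), fr,
                          drop = FALSE]
      maps <- stics_maps(sub, config$max_lag)
      v0 <- max(maps[[1]])
      if (v0 <= 0) next
      disp <- matrix(NA_real_, length(lags), 2)
      ok <- logical(length(lags))
      for (l in lags) {
        pk <- subpixel_peak(maps[[l + 1L]])
        if (pk["value"] >= config$min_peak_correlation * v0 &&
            max(abs(pk[c("row", "col")])) < s / 2 - 1) {
          disp[l, ] <- pk[c("row", "col")]
          ok[l] <- TRUE
        }
      }
      if (sum(ok) < 2L) next
      lag_t <- lags[ok] * dt
      # slope through the origin, per component (px/s)
      v_row <- sum(disp[ok, 1] * lag_t) / sum(lag_t^2)
      v_col <- sum(disp[ok, 2] * lag_t) / sum(lag_t^2)
      # px/s -> um/min; x along columns, y along rows
      vx <- v_col * px * 60
      vy <- v_row * px * 60
      pos_x <- (c0 - 1 + (s - 1) / 2) * px
      pos_y <- (r0 - 1 + (s - 1) / 2) * px
      speed <- sqrt(vx^2 + vy^2)
      to_center <- c(center_um["x"] - pos_x, center_um["y"] - pos_y)
      nrm <- sqrt(sum(to_center^2))
      directionality <- if (speed > 0 && nrm > 0)
        sum(c(vx, vy) * to_center) / (speed * nrm) else NA_real_
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        toi_index = ti, x_um = pos_x, y_um = pos_y,
        vx = vx, vy = vy, speed = speed, directionality = directionality)
    }
  }
  if (length(rows_out) == 0L) stop("no valid flow vectors recovered")
  structure(list(vectors = do.call(rbind, rows_out),
                 cell_center_um = center_um, config = config),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d vectors, median speed %.3g um/min\n",
              nrow(x$vectors), stats::median(x$vectors$speed)))
  invisible(x)
}

#' Fraction of inward-directed flow vectors
#'
#' Vectors with directionality above `threshold` (cosine of the angle to
#' the cell center) count as inward flow.
#'
#' @param field A `flow_field`.
#' @param threshold Directionality cutoff (default 0.9).
#' @return Proportion in `[0, 1]`.
#' @export
inward_fraction <- function(field, threshold = 0.9) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$vectors$directionality
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop("empty flow field")
  mean(d > threshold)
}
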