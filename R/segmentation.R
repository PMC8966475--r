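# Cell-footprint segmentation and spreading kinetics.
#
# IRM frames of a spreading T cell show the contact zone as a dark,
# roughly circular patch. The footprint is segmented by Canny edge
# detection, morphological closing, hole filling and keeping the largest
# connected component. Footprint areas over time follow
# A(t) = A0 * tanh(alpha * (t - t_contact)), whose rate constant alpha is
# the spreading rate. Fixed-cell actin images are partitioned into a
# central disk and a peripheral annulus by eroding the mask with a disk of
# radius `erosion_fraction` times the cell's equivalent circular radius;
# the center/annulus MFI ratio quantifies central actin depletion.

#' Segment the cell footprint in a single frame
#'
#' Canny edges -> morphological closing -> hole filling -> largest
#' connected component. Designed for one cell per field of view.
#'
#' @param frame Numeric matrix (one image frame).
#' @param pixel_size Pixel size in um/px.
#' @param low,high Canny hysteresis thresholds on gradient magnitude;
#'   `NULL` (default) picks `high` by Otsu's method on the gradient
#'   magnitude and `low = 0.4 * high`.
#' @param closing_radius Disk radius (px) used to seal gaps in the edge
#'   contour before hole filling.
#' @param sigma Gaussian pre-smoothing sigma (px) for the edge detector.
#' @param min_area_px Smallest acceptable component size; anything below is
#'   treated as "no cell found".
#' @param min_contrast Minimum ratio of the high threshold to the median
#'   gradient magnitude; below it the frame is considered edge-free (pure
#'   noise) and a no-cell error is raised.
#' @return A `cell_mask`: list with `mask` (logical H x W), `centroid_px`
#'   (0-based `(row, col)` center of mass), `area_um2`,
#'   `equiv_radius_um = sqrt(area/pi)` and `pixel_size`.
#' @export
segment_cell <- function(frame, pixel_size, low = NULL, high = NULL,
                         closing_radius = 5, sigma = 1.4,
                         min_area_px = 25, min_contrast = 4) {
  stopifnot(is.matrix(frame), pixel_size > 0)
  if (max(frame) == min(frame))
    stop("no_cell: frame is constant, nothing to segment")
  edges <- canny_edges(frame, low = low, high = high, sigma = sigma)
  if (is.null(high) &&
      attr(edges, "high") < min_contrast * attr(edges, "median_mag"))
    stop("no_cell: gradient contrast too low (edge-free frame)")
  filled <- close_and_fill(edges, disk_kernel(closing_radius))
  lab <- label_components(filled, connectivity = 8L)
  if (max(lab) == 0L) stop("no_cell: no foreground component found")
  mask <- lab == 1L    # labels are size-ordered; 1 is the largest
  area_px <- sum(mask)
  if (area_px < min_area_px)
    stop("no_cell: largest component has only ", area_px, " px")
  # half-pixel digitisation correction: the edge contour sits on the
  # gradient maximum, so the filled region carries the boundary line's
  # outer half; averaging with the 1-px-eroded area removes the ~0.5 px
  # radial bias
  area_corr <- (area_px + sum(binary_erode(mask, disk_kernel(1)))) / 2
  cell_mask(mask, pixel_size, area_px = area_corr)
}

#' Build a cell mask object from a logical matrix
#'
#' @param mask Logical matrix with a single foreground component.
#' @param pixel_size um/px.
#' @param area_px Effective area in pixels; defaults to the mask pixel
#'   count. [segment_cell()] passes a digitisation-corrected value.
#' @export
cell_mask <- function(mask, pixel_size, area_px = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size > 0)
  if (is.null(area_px)) area_px <- sum(mask)
  if (sum(mask) == 0L) stop("no_cell: empty mask")
  idx <- which(mask)
  rows <- ((idx - 1L) %% nrow(mask))       # 0-based
  cols <- ((idx - 1L) %/% nrow(mask))
  area_um2 <- area_px * pixel_size^2
  structure(list(mask = mask,
                 centroid_px = c(row = mean(rows), col = mean(cols)),
                 area_um2 = area_um2,
                 equiv_radius_um = sqrt(area_um2 / pi),
                 pixel_size = pixel_size),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d px, %.1f um^2, r_eq = %.2f um\n",
              sum(x$mask), x$area_um2, x$equiv_radius_um))
  invisible(x)
}

#' Segment every frame of a stack into an area series
#'
#' Frames where no cell is found contribute area 0 (a cell not yet in
#' contact has no footprint).
#'
#' @param stack An [image_stack()].
#' @param ... Passed to [segment_cell()].
#' @return An `area_series`: list with `times` (s) and `areas` (um^2).
#' @export
measure_spreading <- function(stack, ...) {
  times <- frame_times(stack)
  areas <- vapply(seq_len(n_frames(stack)), function(i) {
    m <- tryCatch(segment_cell(get_frame(stack, i), stack$pixel_size, ...),
                  error = function(e) {
                    if (grepl("^no_cell", conditionMessage(e))) NULL
                    else stop(e)
                  })
    if (is.null(m)) 0 else m$area_um2
  }, numeric(1))
  area_series(times, areas)
}

#' Area-versus-time series
#' @param times Strictly increasing times in seconds.
#' @param areas Non-negative areas in um^2.
#' @export
area_series <- function(times, areas) {
  stopifnot(length(times) == length(areas), all(diff(times) > 0),
            all(areas >= 0))
  structure(list(times = as.numeric(times), areas = as.numeric(areas)),
            class = "area_series")
}

#' Fit hyperbolic-tangent spreading kinetics
#'
#' Least-squares fit of `A(t) = A0 * tanh(alpha * (t - t_contact))` for
#' `t >= t_contact` (A = 0 before). `t_contact` defaults to the frame
#' immediately preceding the first time the area exceeds 5% of the series
#' maximum (the contact onset: the model has A(t_contact) = 0, so the first
#' frame already above 5% is one frame late); set `fit_t_contact = TRUE`
#' to fit it as a free offset instead. A0 is profiled out linearly, so the
#' optimisation is one-dimensional in alpha (golden-section search).
#'
#' @param series An [area_series()] with at least 5 points and at least one
#'   positive area.
#' @param fit_t_contact Fit the contact time as a free parameter.
#' @param alpha_range Search interval for alpha (1/s).
#' @return A `spread_fit`: list with `A0` (um^2), `alpha_spread` (1/s),
#'   `t_contact` (s) and `goodness` (R^2).
#' @export
fit_spreading <- function(series, fit_t_contact = FALSE,
                          alpha_range = c(1e-6, 10)) {
  stopifnot(inherits(series, "area_series"))
  t <- series$times; a <- series$areas
  if (length(t) < 5L) stop("need at least 5 time points")
  if (all(a == 0)) stop("all areas are zero; nothing to fit")
  if (stats::sd(a) == 0)
    stop("constant area series: spreading rate unidentifiable")

  i1 <- which(a > 0.05 * max(a))[1]
  t_contact0 <- if (i1 > 1L) t[i1 - 1L] else t[1L]

  sse_given <- function(alpha, tc) {
    f <- tanh(alpha * pmax(t - tc, 0))
    denom <- sum(f^2)
    A0 <- if (denom > 0) sum(a * f) / denom else 0
    if (A0 <= 0) return(list(sse = sum(a^2), A0 = NA_real_))
    list(sse = sum((a - A0 * f)^2), A0 = A0)
  }
  fit_alpha_1d <- function(tc) {
    opt <- stats::optimize(function(la) sse_given(exp(la), tc)$sse,
                           interval = log(alpha_range), tol = 1e-12)
    alpha <- exp(opt$minimum)
    c(alpha = alpha, sse = opt$objective, tc = tc)
  }
  if (fit_t_contact) {
    tc_grid <- seq(min(t), stats::quantile(t, 0.5, names = FALSE),
                   length.out = 25)
    fits <- vapply(tc_grid, fit_alpha_1d, numeric(3))
    best <- fits[, which.min(fits["sse", ])]
    # refine around the best grid point
    opt <- stats::optimize(function(tc) fit_alpha_1d(tc)["sse"],
                           interval = best["tc"] + c(-1, 1) *
                             diff(range(t)) / 24, tol = 1e-10)
    best <- fit_alpha_1d(opt$minimum)
  } else {
    best <- fit_alpha_1d(t_contact0)
  }
  alpha <- unname(best["alpha"])
  res <- sse_given(alpha, unname(best["tc"]))
  sst <- sum((a - mean(a))^2)
  goodness <- 1 - res$sse / sst
  if (!is.finite(res$A0) || res$A0 <= 0 || alpha <= alpha_range[1] * 1.0001)
    stop("spreading fit did not converge (alpha at bound or A0 <= 0)")
  structure(list(A0 = res$A0, alpha_spread = alpha,
                 t_contact = unname(best["tc"]), goodness = goodness),
            class = "spread_fit")
}

#' @export
print.spread_fit <- function(x, ...) {
  cat(sprintf(
    "<spread_fit> A0 = %.1f um^2, alpha = %.4g 1/s, t_contact = %.1f s, R^2 = %.4f\n",
    x$A0, x$alpha_spread, x$t_contact, x$goodness))
  invisible(x)
}

#' Partition a cell mask into a central region and an annulus
#'
#' The center is the mask eroded by a disk of radius
#' `erosion_fraction * equivalent radius` (rounded to the nearest pixel);
#' the annulus is the remainder. The equivalent circular radius
#' `sqrt(area/pi)` stands in for "the radius of the cell" on non-circular
#' masks.
#'
#' @param mask A [cell_mask()].
#' @param erosion_fraction Fraction of the equivalent radius (default 0.3).
#' @return A `region_partition`: list with logical `center_mask`,
#'   `annulus_mask`, and `erosion_fraction`.
#' @export
partition_center_annulus <- function(mask, erosion_fraction = 0.3) {
  stopifnot(inherits(mask, "cell_mask"), erosion_fraction >= 0)
  if (erosion_fraction == 0) {
    return(structure(list(center_mask = mask$mask,
                          annulus_mask = mask$mask & FALSE,
                          erosion_fraction = 0),
                     class = "region_partition"))
  }
  r_px <- as.integer(round(erosion_fraction * mask$equiv_radius_um /
                             mask$pixel_size))
  r_px <- max(r_px, 1L)
  center <- binary_erode(mask$mask, disk_kernel(r_px))
  if (!any(center))
    stop("erosion annihilated the mask (cell smaller than the structuring ",
         "element, radius ", r_px, " px)")
  structure(list(center_mask = center,
                 annulus_mask = mask$mask & !center,
                 erosion_fraction = erosion_fraction),
            class = "region_partition")
}

#' Center/annulus fluorescence intensity ratio
#'
#' MFI of a region is its total intensity divided by its pixel count. The
#' published quantity is the MFI ratio center/annulus; the raw total
#' intensity ratio is reported alongside.
#'
#' @param frame Numeric matrix, same geometry as the partition.
#' @param partition A [partition_center_annulus()] result.
#' @return An `intensity_ratio`: list with `mfi_center`, `mfi_annulus`,
#'   `ratio` (MFI ratio) and `total_ratio`.
#' @export
intensity_ratio <- function(frame, partition) {
  stopifnot(inherits(partition, "region_partition"), is.matrix(frame))
  if (!all(dim(frame) == dim(partition$center_mask)))
    stop("frame and partition geometry differ")
  n_c <- sum(partition$center_mask)
  n_a <- sum(partition$annulus_mask)
  if (n_c == 0L) stop("empty center region")
  if (n_a == 0L) stop("empty annulus region")
  tot_c <- sum(frame[partition$center_mask])
  tot_a <- sum(frame[partition$annulus_mask])
  mfi_c <- tot_c / n_c
  mfi_a <- tot_a / n_a
  if (mfi_a <= 0) stop("annulus MFI is zero; ratio undefined")
  structure(list(mfi_center = mfi_c, mfi_annulus = mfi_a,
                 ratio = mfi_c / mfi_a,
                 total_ratio = tot_c / tot_a),
            class = "intensity_ratio")
}
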