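# Traction force microscopy: bead-displacement estimation by normalized
# cross-correlation template matching, and regularized Fourier-transform
# traction cytometry (FTTC).
#
# The forward model is the Boussinesq surface solution of a semi-infinite,
# homogeneous, isotropic linear-elastic half space: in Fourier space the
# surface displacement is u(k) = G(k) T(k) with the 2x2 kernel
#
#   G(k) = 2 (1 + nu) / (E k) * [ (1 - nu) I + nu (I - k_hat k_hat^T) ]
#
# (k in rad/um, E in Pa, u in um, T in Pa). The inverse adds Tikhonov
# damping per wave vector, T = (G^2 + lambda^2 s^2 I)^-1 G u, where s is
# the largest eigenvalue of G over the grid, so lambda is dimensionless
# (regularization relative to the normalized operator). The zero-frequency
# mode is set to zero: the recovered field carries no net force.

#' Elastic substrate properties
#'
#' @param youngs_modulus Young's modulus E in Pa (the study's gels span
#'   700-1200 Pa).
#' @param poisson_ratio Poisson ratio (default 0.5, incompressible
#'   polyacrylamide).
#' @param thickness Gel thickness in um; recorded as metadata. The Green
#'   tensor is always the semi-infinite one: at the study's gel heights
#'   (tens of um) versus displacement features of a cell radius (~7 um),
#'   k*h >> 1 and finite-thickness corrections are negligible.
#' @export
gel_properties <- function(youngs_modulus, poisson_ratio = 0.5,
                           thickness = NULL) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio <= 0.5,
            is.null(thickness) || thickness > 0)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio, thickness = thickness),
            class = "gel_properties")
}

# k grids (rad/um) for an n x m field with node spacing h (um).
# Returns list(kx matrix, ky matrix, k magnitude) in unshifted FFT order.
fourier_grids <- function(n_row, n_col, spacing) {
  fr <- function(n) {
    f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
    2 * pi * f / spacing
  }
  ky <- matrix(fr(n_row), n_row, n_col)          # rows vary -> y
  kx <- matrix(fr(n_col), n_row, n_col, byrow = TRUE)
  k <- sqrt(kx^2 + ky^2)
  list(kx = kx, ky = ky, k = k)
}

# Apply a function of the Boussinesq kernel per wave vector:
# given fx, fy (complex FFT matrices of the x/y field components) and the
# two kernel eigenvalue transforms gl(k) (longitudinal) and gt(k)
# (transverse), return the transformed pair. Decomposition into components
# parallel/perpendicular to k_hat diagonalizes G.
.apply_kernel <- function(fx, fy, grids, gl, gt) {
  kx <- grids$kx; ky <- grids$ky; k <- grids$k
  khx <- ifelse(k > 0, kx / k, 0)
  khy <- ifelse(k > 0, ky / k, 0)
  par <- fx * khx + fy * khy
  ox <- gl * par * khx + gt * (fx - par * khx)
  oy <- gl * par * khy + gt * (fy - par * khy)
  ox[1, 1] <- 0; oy[1, 1] <- 0     # no net (rigid) component
  list(x = ox, y = oy)
}

# Boussinesq eigenvalues (um/Pa) at wave number k: longitudinal and
# transverse responses. k = 0 entries return 0.
.boussinesq_eigs <- function(k, gel) {
  E <- gel$youngs_modulus; nu <- gel$poisson_ratio
  pref <- ifelse(k > 0, 2 * (1 + nu) / (E * k), 0)
  list(gl = pref * (1 - nu), gt = pref)
}

#' Forward elastic problem: displacement from traction
#'
#' Surface displacement of the semi-infinite half space under the given
#' traction field, evaluated spectrally (FFT). Serves as the forward
#' oracle for the FTTC inversion.
#'
#' @param traction A `traction_field` (list with `tx`, `ty` Pa matrices and
#'   `spacing_um`), e.g. from [traction_field()].
#' @param gel A [gel_properties()].
#' @return A `displacement_field`: list with `ux`, `uy` (um matrices),
#'   `spacing_um`, `quality` (all 1).
#' @export
forward_displacement <- function(traction, gel) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(gel, "gel_properties"))
  n_row <- nrow(traction$tx); n_col <- ncol(traction$tx)
  grids <- fourier_grids(n_row, n_col, traction$spacing_um)
  eig <- .boussinesq_eigs(grids$k, gel)
  out <- .apply_kernel(stats::fft(traction$tx), stats::fft(traction$ty),
                       grids, eig$gl, eig$gt)
  ux <- Re(stats::fft(out$x, inverse = TRUE)) / (n_row * n_col)
  uy <- Re(stats::fft(out$y, inverse = TRUE)) / (n_row * n_col)
  displacement_field(ux, uy, traction$spacing_um)
}

#' Construct a displacement field
#' @param ux,uy Displacement component matrices (um).
#' @param spacing_um Node spacing (um).
#' @param quality Per-node correlation quality (optional).
#' @export
displacement_field <- function(ux, uy, spacing_um, quality = NULL) {
  stopifnot(all(dim(ux) == dim(uy)), spacing_um > 0)
  if (is.null(quality)) quality <- matrix(1, nrow(ux), ncol(ux))
  structure(list(ux = ux, uy = uy, spacing_um = spacing_um,
                 quality = quality),
            class = "displacement_field")
}

#' Construct a traction field
#' @param tx,ty Traction component matrices (Pa).
#' @param spacing_um Node spacing (um).
#' @export
traction_field <- function(tx, ty, spacing_um) {
  stopifnot(all(dim(tx) == dim(ty)), spacing_um > 0)
  if (any(!is.finite(tx)) || any(!is.finite(ty)))
    stop("traction field must be finite everywhere")
  structure(list(tx = tx, ty = ty, spacing_um = spacing_um,
                 magnitude = sqrt(tx^2 + ty^2)),
            class = "traction_field")
}

#' Regularized FTTC inversion: traction from displacement
#'
#' Per wave vector, `T = (G^T G + lambda^2 s^2 I)^-1 G^T u` with the
#' Boussinesq kernel G and `s` the largest kernel eigenvalue on the grid
#' (so `lambda` is dimensionless). The zero-frequency mode is suppressed:
#' the recovered field has zero spatial mean.
#'
#' @param displacement A [displacement_field()].
#' @param gel A [gel_properties()].
#' @param lambda Dimensionless Tikhonov parameter (default 1e-4).
#' @return A [traction_field()] in Pa.
#' @export
solve_fttc <- function(displacement, gel, lambda = 1e-4) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(gel, "gel_properties"), lambda >= 0)
  n_row <- nrow(displacement$ux); n_col <- ncol(displacement$ux)
  if (n_row < 2L || n_col < 2L) stop("degenerate displacement grid")
  grids <- fourier_grids(n_row, n_col, displacement$spacing_um)
  eig <- .boussinesq_eigs(grids$k, gel)
  s <- max(eig$gt)                      # largest eigenvalue over the grid
  inv_l <- ifelse(eig$gl > 0, eig$gl / (eig$gl^2 + (lambda * s)^2), 0)
  inv_t <- ifelse(eig$gt > 0, eig$gt / (eig$gt^2 + (lambda * s)^2), 0)
  out <- .apply_kernel(stats::fft(displacement$ux),
                       stats::fft(displacement$uy), grids, inv_l, inv_t)
  tx <- Re(stats::fft(out$x, inverse = TRUE)) / (n_row * n_col)
  ty <- Re(stats::fft(out$y, inverse = TRUE)) / (n_row * n_col)
  traction_field(tx, ty, displacement$spacing_um)
}

#' Integrate a traction field into a scalar force
#'
#' Sum of stress magnitudes times node area, converted to nano-newtons
#' (1 Pa um^2 = 1 pN = 1e-3 nN).
#'
#' @param traction A [traction_field()].
#' @param node_roi Optional [roi()] in node indices (0-based) restricting
#'   the integration; default integrates the whole field.
#' @return Force in nN.
#' @export
integrate_force <- function(traction, node_roi = NULL) {
  stopifnot(inherits(traction, "traction_field"))
  mag <- traction$magnitude
  if (!is.null(node_roi)) {
    stopifnot(inherits(node_roi, "roi"))
    if (node_roi$row + node_roi$height > nrow(mag) ||
        node_roi$col + node_roi$width > ncol(mag))
      stop("roi outside the traction grid")
    mag <- mag[node_roi$row + seq_len(node_roi$height),
               node_roi$col + seq_len(node_roi$width), drop = FALSE]
    if (length(mag) == 0L) stop("empty roi")
  }
  sum(mag) * traction$spacing_um^2 * 1e-3
}

#' Estimate a bead displacement field by template matching
#'
#' For each node of a regular grid, a `template x template` patch of the
#' reference image is matched against the deformed image by normalized
#' cross-correlation over shifts up to `max_disp` px, with per-axis
#' quadratic sub-pixel refinement.
#'
#' @param reference,deformed Congruent numeric matrices; `reference` is the
#'   relaxed (cell-free) bead image.
#' @param pixel_size um/px.
#' @param template Template edge length in px (default 32).
#' @param max_disp Maximum displacement searched, px (default 16).
#' @param grid_spacing Node spacing in px (default `template / 2`).
#' @return A [displacement_field()] (um units, spacing in um) with
#'   per-node peak correlation in `quality` and node image coordinates in
#'   `node_row_px` / `node_col_px` (0-based).
#' @export
estimate_displacement <- function(reference, deformed, pixel_size,
                                  template = 32L, max_disp = 16L,
                                  grid_spacing = template %/% 2L) {
  if (!all(dim(reference) == dim(deformed)))
    stop("reference and deformed images differ in size")
  h <- nrow(reference); w <- ncol(reference)
  th <- template %/% 2L
  margin <- th + max_disp
  rows <- seq(margin + 1L, h - margin, by = grid_spacing)
  cols <- seq(margin + 1L, w - margin, by = grid_spacing)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("image too small for the template/search geometry")

  n_sr <- template + 2L * max_disp           # search window edge
  ux <- uy <- qual <- matrix(NA_real_, length(rows), length(cols))
  ones <- matrix(1, template, template)
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    r <- rows[i]; c <- cols[j]
    tpl <- reference[(r - th):(r - th + template - 1L),
                     (c - th):(c - th + template - 1L)]
    win <- deformed[(r - th - max_disp):(r - th - max_disp + n_sr - 1L),
                    (c - th - max_disp):(c - th - max_disp + n_sr - 1L)]
    tpl0 <- tpl - mean(tpl)
    st <- sqrt(sum(tpl0^2))
    if (st == 0) next
    # raw correlation of the (zero-mean) template with the window,
    # plus local window sums for per-shift normalisation
    cross <- conv2_valid_corr(win, tpl0)
    wsum <- conv2_valid_corr(win, ones)
    wsum2 <- conv2_valid_corr(win^2, ones)
    n_tpl <- template^2
    sw <- sqrt(pmax(wsum2 - wsum^2 / n_tpl, 0))
    ncc <- ifelse(sw > 0, cross / (st * sw), 0)
    pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
    dr <- pk[1] - (max_disp + 1L)
    dc <- pk[2] - (max_disp + 1L)
    off <- c(0, 0)
    if (pk[1] > 1L && pk[1] < nrow(ncc) && pk[2] > 1L && pk[2] < ncol(ncc)) {
      denom_r <- ncc[pk[1] - 1, pk[2]] - 2 * ncc[pk[1], pk[2]] +
        ncc[pk[1] + 1, pk[2]]
      denom_c <- ncc[pk[1], pk[2] - 1] - 2 * ncc[pk[1], pk[2]] +
        ncc[pk[1], pk[2] + 1]
      if (denom_r < 0)
        off[1] <- 0.5 * (ncc[pk[1] - 1, pk[2]] - ncc[pk[1] + 1, pk[2]]) /
          denom_r
      if (denom_c < 0)
        off[2] <- 0.5 * (ncc[pk[1], pk[2] - 1] - ncc[pk[1], pk[2] + 1]) /
          denom_c
      off[abs(off) > 1] <- 0
    }
    uy[i, j] <- (dr + off[1]) * pixel_size
    ux[i, j] <- (dc + off[2]) * pixel_size
    qual[i, j] <- max(ncc)
  }
  fld <- displacement_field(ux, uy, grid_spacing * pixel_size,
                            quality = qual)
  fld$node_row_px <- rows - 1L     # 0-based node coordinates in the image
  fld$node_col_px <- cols - 1L
  fld
}

# "valid"-mode cross-correlation of window with kernel (no flip), via FFT:
# out[s] = sum_x win[x + s - 1] * k[x], for all fully-overlapping shifts.
conv2_valid_corr <- function(win, k) {
  hw <- nrow(win); ww <- ncol(win)
  hk <- nrow(k); wk <- ncol(k)
  ph <- hw; pw <- ww
  kp <- matrix(0, ph, pw); kp[1:hk, 1:wk] <- k
  full <- Re(stats::fft(Conj(stats::fft(kp)) * stats::fft(win),
                        inverse = TRUE)) / (ph * pw)
  full[seq_len(hw - hk + 1L), seq_len(ww - wk + 1L)]
}

#' Per-frame traction force from a bead movie
#'
#' Each frame is compared against the cell-free reference image
#' (template-matching displacement, FTTC inversion, force integration).
#'
#' @param stack Bead-image [image_stack()] acquired during cell engagement.
#' @param reference Cell-free bead image (matrix), acquired after
#'   detachment.
#' @param gel A [gel_properties()].
#' @param lambda Tikhonov parameter for [solve_fttc()].
#' @param ... Passed to [estimate_displacement()].
#' @return A `force_series`: list with `times` (s), `force_nN`, and
#'   `metrics` (`max`, `mean`, `median`).
#' @export
force_timeseries <- function(stack, reference, gel, lambda = 1e-4, ...) {
  stopifnot(inherits(stack, "image_stack"), is.matrix(reference))
  if (!all(dim(reference) == dim(stack$frames)[1:2]))
    stop("reference image does not match the stack geometry")
  force <- vapply(seq_len(n_frames(stack)), function(f) {
    disp <- estimate_displacement(reference, get_frame(stack, f),
                                  stack$pixel_size, ...)
    integrate_force(solve_fttc(disp, gel, lambda))
  }, numeric(1))
  structure(list(times = frame_times(stack), force_nN = force,
                 metrics = list(max = max(force), mean = mean(force),
                                median = stats::median(force))),
            class = "force_series")
}

#' Force ratio across a treatment window
#'
#' Force at the end of treatment divided by force at its onset
#' (nearest-sample lookup).
#'
#' @param series A `force_series`.
#' @param t_onset,t_end Times in seconds, `t_end > t_onset`, both inside
#'   the series.
#' @export
treatment_force_ratio <- function(series, t_onset, t_end) {
  stopifnot(inherits(series, "force_series"))
  if (t_end <= t_onset) stop("t_end must be after t_onset")
  rng <- range(series$times)
  if (t_onset < rng[1] || t_end > rng[2])
    stop("treatment window outside the series")
  i0 <- which.min(abs(series$times - t_onset))
  i1 <- which.min(abs(series$times - t_end))
  f0 <- series$force_nN[i0]
  if (f0 == 0) stop("force at treatment onset is zero; ratio undefined")
  series$force_nN[i1] / f0
}
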