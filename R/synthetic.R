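# Synthetic-scene generators: every input modality the pipeline consumes,
# with machine-readable ground truth, so each analysis stage can be
# validated by parameter recovery without any raw microscopy data.
#
# Conventions shared by all generators: one global RNG seeding per scene
# (set.seed(seed) at entry, so a fixed seed gives bit-identical output);
# emitters rendered as isotropic Gaussians with sigma = diameter / 2.355
# (FWHM convention, matching the detector's scale assumption); noise is
# applied last; intensities are clipped at zero so stacks remain valid.

# Render Gaussian spots (amplitude `amp`, s.d. `sigma` px) at positions
# given in 0-based px coordinates onto an h x w canvas.
render_spots <- function(h, w, rows_px, cols_px, sigma, amp = 1) {
  img <- matrix(0, h, w)
  r_ext <- ceiling(4 * sigma)
  if (length(amp) == 1L) amp <- rep(amp, length(rows_px))
  for (i in seq_along(rows_px)) {
    r <- rows_px[i]; c <- cols_px[i]
    r0 <- max(1L, floor(r + 1 - r_ext)); r1 <- min(h, ceiling(r + 1 + r_ext))
    c0 <- max(1L, floor(c + 1 - r_ext)); c1 <- min(w, ceiling(c + 1 + r_ext))
    if (r0 > r1 || c0 > c1) next
    rr <- (r0:r1) - 1 - r
    cc <- (c0:c1) - 1 - c
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      amp[i] * exp(-rr^2 / (2 * sigma^2)) %o% exp(-cc^2 / (2 * sigma^2))
  }
  img
}

add_noise <- function(frames, gaussian_sd = 0, poisson = FALSE,
                      photon_scale = 100) {
  if (poisson) {
    frames <- array(stats::rpois(length(frames),
                                 pmax(frames, 0) * photon_scale) /
                      photon_scale, dim = dim(frames))
  }
  if (gaussian_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0, gaussian_sd),
                             dim = dim(frames))
  pmax(frames, 0)
}

#' Generate a speckle movie advected by a prescribed flow
#'
#' Gaussian emitters are advected frame-to-frame by the flow field and
#' re-seeded to keep the density stationary: uniform flow wraps emitters
#' around the field of view; radial flows respawn emitters that reach the
#' center (inward) or leave the frame (outward) at random positions.
#'
#' @param size_px Image edge length in px.
#' @param n_frames Number of frames.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param flow One of `"uniform"`, `"radial_in"`, `"radial_out"`,
#'   `"rotational"`, `"none"`.
#' @param speed_um_min Flow speed magnitude in um/min.
#' @param direction_deg Direction of uniform flow (degrees; 0 = +x).
#' @param density Emitters per px^2 (default 0.05; must be >= 0.01).
#' @param psf_sigma_px Emitter Gaussian s.d. in px.
#' @param noise_sd Gaussian read-noise s.d. (emitter amplitude = 1).
#' @param lifetime_s Mean emitter lifetime in seconds (exponential
#'   turnover; an emitter that dies respawns at a random position). The
#'   default `Inf` keeps emitters permanent: turnover adds number
#'   fluctuations that inflate the (non-negative) median recovered speed
#'   far more than the immobile-filter smear it removes.
#' @param seed RNG seed.
#' @return List: `stack` ([image_stack()]), `truth` (flow kind, speed,
#'   direction, per-frame displacement px).
#' @export
generate_speckle_movie <- function(size_px = 64L, n_frames = 30L,
                                   pixel_size = 0.1067, frame_interval = 1,
                                   flow = c("uniform", "radial_in",
                                            "radial_out", "rotational",
                                            "none"),
                                   speed_um_min = 2, direction_deg = 0,
                                   density = 0.05, psf_sigma_px = 1.3,
                                   noise_sd = 0.02, lifetime_s = Inf,
                                   seed = 1L) {
  flow <- match.arg(flow)
  stopifnot(density >= 0.01)
  set.seed(seed)
  speed_px_frame <- speed_um_min / 60 * frame_interval / pixel_size
  # aliasing guard: per-frame displacement must stay below subregion/4
  if (speed_px_frame >= 4)
    stop("per-frame displacement ", round(speed_px_frame, 2),
         " px exceeds the aliasing guard (subregion/4)")
  n_emit <- round(density * size_px^2)
  pos <- matrix(stats::runif(2 * n_emit, 0, size_px - 1), ncol = 2) # row,col
  center <- (size_px - 1) / 2
  theta <- direction_deg * pi / 180
  frames <- array(0, dim = c(size_px, size_px, n_frames))
  for (f in seq_len(n_frames)) {
    frames[, , f] <- render_spots(size_px, size_px, pos[, 1], pos[, 2],
                                  psf_sigma_px)
    step <- switch(flow,
      none = matrix(0, n_emit, 2),
      uniform = matrix(rep(speed_px_frame * c(sin(theta), cos(theta)),
                           each = n_emit), ncol = 2),
      radial_in = {
        d <- cbind(center - pos[, 1], center - pos[, 2])
        nr <- sqrt(rowSums(d^2)); nr[nr == 0] <- 1
        d / nr * speed_px_frame
      },
      radial_out = {
        d <- cbind(pos[, 1] - center, pos[, 2] - center)
        nr <- sqrt(rowSums(d^2)); nr[nr == 0] <- 1
        d / nr * speed_px_frame
      },
      rotational = {
        d <- cbind(pos[, 1] - center, pos[, 2] - center)
        cbind(-d[, 2], d[, 1]) /
          pmax(sqrt(rowSums(d^2)), 1e-9) * speed_px_frame *
          pmin(sqrt(rowSums(d^2)) / center, 1)
      })
    pos <- pos + step
    if (is.finite(lifetime_s)) {
      died <- stats::runif(n_emit) < frame_interval / lifetime_s
      if (any(died))
        pos[died, ] <- matrix(stats::runif(2 * sum(died), 0, size_px - 1),
                              ncol = 2)
    }
    if (flow == "uniform") {
      pos <- pos %% size_px
    } else {
      # respawn emitters that left the field or collapsed onto the center
      dead <- pos[, 1] < 0 | pos[, 1] > size_px - 1 |
        pos[, 2] < 0 | pos[, 2] > size_px - 1
      if (flow == "radial_in") {
        r <- sqrt((pos[, 1] - center)^2 + (pos[, 2] - center)^2)
        dead <- dead | r < 2
      }
      if (any(dead))
        pos[dead, ] <- matrix(stats::runif(2 * sum(dead), 0, size_px - 1),
                              ncol = 2)
    }
  }
  frames <- add_noise(frames, gaussian_sd = noise_sd)
  list(stack = image_stack(frames, pixel_size, frame_interval),
       truth = list(flow = flow, speed_um_min = speed_um_min,
                    direction_deg = direction_deg,
                    speed_px_frame = speed_px_frame,
                    center_px = c(center, center), seed = seed))
}

#' Simulate 2D particle trajectories with known motion model
#'
#' Discrete-time trajectories: Brownian steps are isotropic normal with
#' per-axis variance `2 D dt`; directed motion adds a constant drift
#' `v dt`; confined motion reflects at the walls of a square box of side
#' `box_um`. Reported positions optionally carry Gaussian localization
#' noise.
#'
#' @param n_tracks Number of tracks.
#' @param n_points Points per track.
#' @param frame_interval s/frame.
#' @param model `"brownian"`, `"directed"` or `"confined"`.
#' @param D Diffusion coefficient, um^2/s.
#' @param speed_um_s Drift speed for directed motion, um/s.
#' @param direction_deg Drift direction (degrees; 0 = +x).
#' @param box_um Confinement box side, um.
#' @param arena_um Side of the square region in which tracks start.
#' @param loc_sigma Localization noise s.d., um.
#' @param seed RNG seed.
#' @return List: `tracks` (track data frame as from [link_tracks()]),
#'   `truth` (model parameters).
#' @export
simulate_tracks <- function(n_tracks = 10L, n_points = 50L,
                            frame_interval = 0.1,
                            model = c("brownian", "directed", "confined"),
                            D = 0.05, speed_um_s = 0.2, direction_deg = 0,
                            box_um = 1, arena_um = 20, loc_sigma = 0,
                            seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_tracks >= 1L, n_points >= 2L)
  set.seed(seed)
  theta <- direction_deg * pi / 180
  drift <- if (model == "directed")
    speed_um_s * frame_interval * c(cos(theta), sin(theta)) else c(0, 0)
  step_sd <- sqrt(2 * D * frame_interval)
  out <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    x <- numeric(n_points); y <- numeric(n_points)
    if (model == "confined") {
      x0 <- stats::runif(1, 0, box_um); y0 <- stats::runif(1, 0, box_um)
    } else {
      x0 <- stats::runif(1, 0, arena_um); y0 <- stats::runif(1, 0, arena_um)
    }
    x[1] <- x0; y[1] <- y0
    for (i in 2:n_points) {
      dx <- stats::rnorm(1, 0, step_sd) + drift[1]
      dy <- stats::rnorm(1, 0, step_sd) + drift[2]
      nx <- x[i - 1] + dx; ny <- y[i - 1] + dy
      if (model == "confined") {
        # reflect at the box walls
        nx <- abs(nx); nx <- box_um - abs(box_um - nx)
        ny <- abs(ny); ny <- box_um - abs(box_um - ny)
      }
      x[i] <- nx; y[i] <- ny
    }
    if (loc_sigma > 0) {
      x <- x + stats::rnorm(n_points, 0, loc_sigma)
      y <- y + stats::rnorm(n_points, 0, loc_sigma)
    }
    out[[k]] <- data.frame(track_id = k, frame = seq_len(n_points),
                           t_s = (seq_len(n_points) - 1) * frame_interval,
                           x_um = x, y_um = y, gap_before = FALSE)
  }
  list(tracks = do.call(rbind, out),
       truth = list(model = model, D = D, speed_um_s = speed_um_s,
                    direction_deg = direction_deg, box_um = box_um,
                    frame_interval = frame_interval, loc_sigma = loc_sigma,
                    seed = seed))
}

#' Generate an IRM-like spreading movie
#'
#' A dark disk on a bright background whose area follows
#' `A(t) = A0 tanh(alpha (t - t_contact))`, with smooth angular boundary
#' roughness and Gaussian noise.
#'
#' @param A0_um2 Plateau area, um^2.
#' @param alpha Spreading rate, 1/s.
#' @param duration_s Movie duration, s.
#' @param frame_interval s/frame.
#' @param size_px Image edge, px.
#' @param pixel_size um/px.
#' @param t_contact Contact time, s.
#' @param bg,fg Background and footprint intensity levels.
#' @param roughness Relative amplitude of the boundary modulation.
#' @param noise_sd Gaussian noise s.d.
#' @param seed RNG seed.
#' @return List: `stack`, `truth` (`A0_um2`, `alpha`, `t_contact`,
#'   per-frame `areas_um2`).
#' @export
generate_spreading_movie <- function(A0_um2 = 300, alpha = 0.02,
                                     duration_s = 295, frame_interval = 5,
                                     size_px = 128L, pixel_size = 0.2,
                                     t_contact = 0, bg = 1, fg = 0.3,
                                     roughness = 0.03, noise_sd = 0.02,
                                     seed = 1L) {
  set.seed(seed)
  r_max <- sqrt(A0_um2 / pi) / pixel_size
  stopifnot(2 * r_max < size_px - 4)
  times <- seq(0, duration_s, by = frame_interval)
  areas <- A0_um2 * tanh(alpha * pmax(times - t_contact, 0))
  center <- (size_px - 1) / 2
  # fixed low-order angular modulation of the radius (same every frame)
  n_modes <- 4L
  mode_amp <- stats::rnorm(n_modes, 0, roughness)
  mode_phase <- stats::runif(n_modes, 0, 2 * pi)
  idx <- seq_len(size_px) - 1
  dr <- outer(idx - center, rep(1, size_px))
  dc <- outer(rep(1, size_px), idx - center)
  rad <- sqrt(dr^2 + dc^2)
  ang <- atan2(dr, dc)
  mod_factor <- 1 + Reduce(`+`, lapply(seq_len(n_modes), function(m)
    mode_amp[m] * cos(m * ang + mode_phase[m])))
  frames <- array(bg, dim = c(size_px, size_px, length(times)))
  for (f in seq_along(times)) {
    r_t <- sqrt(areas[f] / pi) / pixel_size
    if (r_t <= 0) next
    inside <- rad <= r_t * mod_factor
    frm <- matrix(bg, size_px, size_px)
    frm[inside] <- fg
    frames[, , f] <- frm
  }
  frames <- add_noise(frames, gaussian_sd = noise_sd)
  list(stack = image_stack(frames, pixel_size, frame_interval),
       truth = list(A0_um2 = A0_um2, alpha = alpha, t_contact = t_contact,
                    times = times, areas_um2 = areas, seed = seed))
}

#' Generate a single granule scene with known component layout
#'
#' Disk-shaped bright granules at prescribed radial positions and angles
#' inside a circular cell mask, on a dim in-cell background.
#'
#' @param cell_radius_px Cell mask radius, px.
#' @param granules Data frame with columns `radial_pos` (0-1), `angle_deg`,
#'   `radius_px`, `intensity`; defaults to 5 well-separated granules.
#' @param size_px Image edge, px.
#' @param pixel_size um/px.
#' @param bg_in In-cell background intensity.
#' @param noise_sd Gaussian noise s.d.
#' @param seed RNG seed.
#' @return List: `frame`, `mask` ([cell_mask()]), `truth` (granule table
#'   with expected radial bins and overlap flags).
#' @export
generate_granule_scene <- function(cell_radius_px = 50,
                                   granules = NULL, size_px = 128L,
                                   pixel_size = 0.16, bg_in = 0.1,
                                   noise_sd = 0, seed = 1L) {
  set.seed(seed)
  if (is.null(granules))
    granules <- data.frame(
      radial_pos = c(0.1, 0.3, 0.5, 0.7, 0.9),
      angle_deg = c(0, 72, 144, 216, 288),
      radius_px = 3, intensity = 1)
  center <- (size_px - 1) / 2
  idx <- seq_len(size_px) - 1
  dr <- outer(idx - center, rep(1, size_px))
  dc <- outer(rep(1, size_px), idx - center)
  rad <- sqrt(dr^2 + dc^2)
  mask <- rad <= cell_radius_px
  frame <- matrix(0, size_px, size_px)
  frame[mask] <- bg_in
  g_rows <- center + granules$radial_pos * cell_radius_px *
    sin(granules$angle_deg * pi / 180)
  g_cols <- center + granules$radial_pos * cell_radius_px *
    cos(granules$angle_deg * pi / 180)
  for (i in seq_len(nrow(granules))) {
    disk <- (dr - (g_rows[i] - center))^2 +
      (dc - (g_cols[i] - center))^2 <= granules$radius_px[i]^2
    frame[disk & mask] <- frame[disk & mask] + granules$intensity[i]
  }
  if (noise_sd > 0)
    frame <- pmax(frame + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                                 size_px, size_px), 0)
  # overlap flags: granules whose disks intersect are one clump
  n_g <- nrow(granules)
  overlap <- rep(FALSE, n_g)
  if (n_g > 1) for (i in 1:(n_g - 1)) for (j in (i + 1):n_g) {
    d <- sqrt((g_rows[i] - g_rows[j])^2 + (g_cols[i] - g_cols[j])^2)
    if (d <= granules$radius_px[i] + granules$radius_px[j])
      overlap[i] <- overlap[j] <- TRUE
  }
  truth <- granules
  truth$row_px <- g_rows; truth$col_px <- g_cols
  truth$expected_bin <- pmin(floor(truth$radial_pos / 0.2) + 1L, 5L)
  truth$clumped <- overlap
  list(frame = frame, mask = cell_mask(mask, pixel_size), truth = truth)
}

#' Generate a TFM bead-image pair from a balanced ring traction
#'
#' Ground-truth traction is a centripetal ring (zero net force, matching
#' the inversion's zero-frequency convention):
#' `T(r) = -A exp(-(r - r0)^2 / (2 w^2)) r_hat`. Surface displacement is
#' computed with [forward_displacement()] on the pixel grid, interpolated
#' bilinearly at the bead positions, and both states are rendered as
#' Gaussian spots.
#'
#' @param size_px Image edge, px.
#' @param pixel_size um/px.
#' @param gel A [gel_properties()].
#' @param amplitude_pa Peak ring traction, Pa.
#' @param ring_radius_um,ring_width_um Ring center radius and Gaussian
#'   width, um.
#' @param bead_density Beads per px^2.
#' @param bead_sigma_px Bead PSF s.d., px.
#' @param noise_sd Gaussian noise s.d.
#' @param max_disp_px Recoverability guard: generation fails if the peak
#'   bead displacement exceeds `max_disp_px - 2`.
#' @param seed RNG seed.
#' @return List: `reference`, `deformed` (matrices), `truth` (the
#'   [traction_field()], the forward [displacement_field()], peak bead
#'   displacement in px, integrated ground-truth force in nN).
#' @export
generate_tfm_scene <- function(size_px = 192L, pixel_size = 0.1067,
                               gel = gel_properties(1000),
                               amplitude_pa = 50, ring_radius_um = 5,
                               ring_width_um = 1.5, bead_density = 0.03,
                               bead_sigma_px = 1.5, noise_sd = 0.01,
                               max_disp_px = 16, seed = 1L) {
  set.seed(seed)
  center_um <- (size_px - 1) / 2 * pixel_size
  idx_um <- (seq_len(size_px) - 1) * pixel_size
  dy <- outer(idx_um - center_um, rep(1, size_px))
  dx <- outer(rep(1, size_px), idx_um - center_um)
  r <- sqrt(dx^2 + dy^2)
  mag <- amplitude_pa * exp(-(r - ring_radius_um)^2 / (2 * ring_width_um^2))
  rr <- pmax(r, 1e-9)
  tx <- -mag * dx / rr
  ty <- -mag * dy / rr
  truth_traction <- traction_field(tx, ty, pixel_size)
  disp <- forward_displacement(truth_traction, gel)
  peak_disp_px <- max(sqrt(disp$ux^2 + disp$uy^2)) / pixel_size
  if (peak_disp_px > max_disp_px - 2)
    stop("traction amplitude produces ", round(peak_disp_px, 1),
         " px displacement; unrecoverable for max_disp = ", max_disp_px)
  n_beads <- round(bead_density * size_px^2)
  bead_r <- stats::runif(n_beads, 0, size_px - 1)   # 0-based px
  bead_c <- stats::runif(n_beads, 0, size_px - 1)
  # bilinear interpolation of the displacement at the bead positions
  interp <- function(field_m, rp, cp) {
    r0 <- floor(rp); c0 <- floor(cp)
    fr <- rp - r0; fc <- cp - c0
    r0 <- pmin(pmax(r0, 0), size_px - 2); c0 <- pmin(pmax(c0, 0), size_px - 2)
    i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
    i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
    field_m[i00] * (1 - fr) * (1 - fc) + field_m[i10] * fr * (1 - fc) +
      field_m[i01] * (1 - fr) * fc + field_m[i11] * fr * fc
  }
  u_r <- interp(disp$uy, bead_r, bead_c) / pixel_size   # px
  u_c <- interp(disp$ux, bead_r, bead_c) / pixel_size
  reference <- render_spots(size_px, size_px, bead_r, bead_c, bead_sigma_px)
  deformed <- render_spots(size_px, size_px, bead_r + u_r, bead_c + u_c,
                           bead_sigma_px)
  if (noise_sd > 0) {
    reference <- pmax(reference +
                        matrix(stats::rnorm(size_px^2, 0, noise_sd),
                               size_px, size_px), 0)
    deformed <- pmax(deformed +
                       matrix(stats::rnorm(size_px^2, 0, noise_sd),
                              size_px, size_px), 0)
  }
  list(reference = reference, deformed = deformed,
       truth = list(traction = truth_traction, displacement = disp,
                    peak_disp_px = peak_disp_px,
                    force_nN = integrate_force(truth_traction),
                    seed = seed))
}

#' Write a ground-truth sidecar as structured text
#'
#' Flat key-value pairs go to a two-column CSV; data-frame entries are
#' written alongside as `<stem>_<name>.csv`.
#'
#' @param truth Named list of scalars and/or data frames.
#' @param stem Output path stem (without extension).
#' @return Paths written, invisibly.
#' @export
write_truth_sidecar <- function(truth, stem) {
  scalars <- truth[vapply(truth, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  paths <- character(0)
  if (length(scalars)) {
    p <- paste0(stem, "_truth.csv")
    utils::write.csv(data.frame(key = names(scalars),
                                value = unlist(lapply(scalars, format))),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  dfs <- truth[vapply(truth, is.data.frame, logical(1))]
  for (nm in names(dfs)) {
    p <- paste0(stem, "_", nm, ".csv")
    utils::write.csv(dfs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
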