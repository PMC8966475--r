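# Per-track time-averaged mean-squared displacement, anomalous-exponent
# fitting and motion classification.
#
# MSD(n dt) is the mean of |r(t + n dt) - r(t)|^2 over all pairs of
# observed frames n apart whose interval contains no closed gap. The first
# 25% of each curve is fit as MSD(t) = B t^alpha by ordinary least squares
# on log-log axes; fits with r^2 <= 0.8 are rejected. alpha > 1.2 is
# super-diffusive, alpha < 0.8 sub-diffusive, the closed interval
# [0.8, 1.2] normal diffusion.

#' Time-averaged MSD of one track
#'
#' @param track Data frame for one track (`frame`, `t_s`, `x_um`, `y_um`).
#' @param frame_interval Seconds per frame; inferred from `t_s`/`frame` if
#'   omitted.
#' @return An `msd_curve`: list with `lags` (s), `msd` (um^2), `n_pairs`.
#'   Lags whose every candidate pair spans a gap are dropped.
#' @export
compute_msd <- function(track, frame_interval = NULL) {
  if (nrow(track) < 3L) stop("track too short for MSD (need >= 3 points)")
  o <- order(track$frame)
  fr <- track$frame[o]; x <- track$x_um[o]; y <- track$y_um[o]
  if (is.null(frame_interval)) {
    dts <- diff(track$t_s[o]) / diff(fr)
    frame_interval <- stats::median(dts)
  }
  f0 <- fr - min(fr)                      # 0-based frame offsets
  span <- max(f0)
  present <- logical(span + 1L)
  present[f0 + 1L] <- TRUE
  px <- rep(NA_real_, span + 1L); py <- rep(NA_real_, span + 1L)
  px[f0 + 1L] <- x; py[f0 + 1L] <- y
  # a pair (i, i+n) is valid iff every frame in i..i+n was observed
  # (pairs spanning closed gaps are skipped)
  run_ok <- cumsum(!present)              # gap count up to each frame
  lags <- numeric(0); msd <- numeric(0); n_pairs <- integer(0)
  for (n in seq_len(span)) {
    i <- seq_len(span + 1L - n)
    valid <- present[i] & present[i + n] &
      (run_ok[i + n] - run_ok[i]) == 0L
    if (!any(valid)) next
    d2 <- (px[i + n] - px[i])^2 + (py[i + n] - py[i])^2
    lags <- c(lags, n * frame_interval)
    msd <- c(msd, mean(d2[valid]))
    n_pairs <- c(n_pairs, sum(valid))
  }
  if (length(lags) == 0L) stop("no valid displacement pairs in track")
  structure(list(lags = lags, msd = msd, n_pairs = n_pairs),
            class = "msd_curve")
}

#' Fit the anomalous-diffusion exponent of an MSD curve
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` over the first
#' `ceiling(fraction * n_lags)` lags; the slope is alpha, the intercept
#' `log(B)`. `r_squared` is computed on the fitted log-log points. Fits
#' with `r_squared <= min_r2` are flagged rejected, as are curves with a
#' zero MSD inside the fit window (log undefined).
#'
#' @param curve An [compute_msd()] result.
#' @param fraction Fraction of lags to fit (default 0.25).
#' @param min_r2 Acceptance threshold on r^2 (default 0.8).
#' @return An `msd_fit`: list with `B` (um^2/s^alpha), `alpha`,
#'   `r_squared`, `n_lags_fit`, `accepted`, `reject_reason`.
#' @export
fit_alpha <- function(curve, fraction = 0.25, min_r2 = 0.8) {
  stopifnot(inherits(curve, "msd_curve"))
  n_fit <- ceiling(fraction * length(curve$lags))
  if (n_fit < 3L)
    return(structure(list(B = NA_real_, alpha = NA_real_,
                          r_squared = NA_real_, n_lags_fit = n_fit,
                          accepted = FALSE,
                          reject_reason = "fewer than 3 lags in fit window"),
                     class = "msd_fit"))
  lag <- curve$lags[seq_len(n_fit)]
  m <- curve$msd[seq_len(n_fit)]
  if (any(m <= 0))
    return(structure(list(B = NA_real_, alpha = NA_real_,
                          r_squared = NA_real_, n_lags_fit = n_fit,
                          accepted = FALSE,
                          reject_reason = "zero MSD in fit window"),
                     class = "msd_fit"))
  lx <- log(lag); ly <- log(m)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  B <- exp(unname(fit$coefficients[1]))
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  accepted <- r2 > min_r2
  structure(list(B = B, alpha = alpha, r_squared = r2, n_lags_fit = n_fit,
                 accepted = accepted,
                 reject_reason = if (accepted) NA_character_
                                 else "r_squared below threshold"),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  if (is.na(x$alpha)) {
    cat("<msd_fit> rejected:", x$reject_reason, "\n")
  } else {
    cat(sprintf("<msd_fit> alpha = %.3f, B = %.4g, r^2 = %.3f (%s)\n",
                x$alpha, x$B, x$r_squared,
                if (x$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' Classify motion from the MSD exponent
#'
#' `alpha > 1.2` is super-diffusion, `alpha < 0.8` sub-diffusion, anything
#' in the closed interval `[0.8, 1.2]` (including the boundaries, which the
#' strict published inequalities leave open) normal diffusion.
#'
#' @param alpha Finite MSD exponent.
#' @return `"super"`, `"normal"` or `"sub"`.
#' @export
classify_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a single finite number")
  if (alpha > 1.2) "super" else if (alpha < 0.8) "sub" else "normal"
}

#' Ensemble MSD over a set of tracks
#'
#' At each lag, the mean of the per-track time-averaged MSD values over
#' the tracks long enough to contribute.
#'
#' @param tracks Track data frame (multiple `track_id`s) or a list of
#'   `msd_curve`s.
#' @param frame_interval Seconds per frame (for the track-table input).
#' @return An `msd_curve` whose `n_pairs` holds the number of contributing
#'   tracks per lag.
#' @export
ensemble_msd <- function(tracks, frame_interval = NULL) {
  curves <- if (is.data.frame(tracks)) {
    lapply(split_tracks(tracks), compute_msd, frame_interval = frame_interval)
  } else tracks
  if (length(curves) == 0L) stop("no tracks for ensemble MSD")
  stopifnot(all(vapply(curves, inherits, logical(1), "msd_curve")))
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lags"))))
  msd <- n_tracks <- numeric(length(all_lags))
  for (i in seq_along(all_lags)) {
    vals <- unlist(lapply(curves, function(cv) {
      j <- which(abs(cv$lags - all_lags[i]) < 1e-9)
      if (length(j) == 1L) cv$msd[j] else NULL
    }))
    msd[i] <- mean(vals)
    n_tracks[i] <- length(vals)
  }
  structure(list(lags = all_lags, msd = msd, n_pairs = as.integer(n_tracks)),
            class = "msd_curve")
}

#' Per-track MSD analysis table
#'
#' Convenience wrapper running [compute_msd()], [fit_alpha()] and
#' [classify_alpha()] over every track.
#'
#' @param tracks Track data frame.
#' @param frame_interval Seconds per frame.
#' @param fraction,min_r2 Passed to [fit_alpha()].
#' @return Data frame: `track_id`, `n_points`, `B`, `alpha`, `r_squared`,
#'   `accepted`, `motion_class`.
#' @export
msd_table <- function(tracks, frame_interval = NULL, fraction = 0.25,
                      min_r2 = 0.8) {
  per <- split_tracks(tracks)
  rows <- lapply(per, function(tr) {
    fit <- tryCatch(
      fit_alpha(compute_msd(tr, frame_interval), fraction, min_r2),
      error = function(e) NULL)
    data.frame(
      track_id = tr$track_id[1], n_points = nrow(tr),
      B = if (is.null(fit)) NA_real_ else fit$B,
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
      accepted = !is.null(fit) && isTRUE(fit$accepted),
      motion_class = if (!is.null(fit) && isTRUE(fit$accepted))
        classify_alpha(fit$alpha) else NA_character_)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
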