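# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# noisy dark disk on bright background (IRM-like single frame)
make_disk_frame <- function(radius_px, seed = 1, noise_sd = 0.02,
                            n = max(260, 2 * radius_px + 60),
                            center = NULL, fg = 0.3, bg = 1) {
  set.seed(seed)
  if (is.null(center)) center <- c((n - 1) / 2, (n - 1) / 2)
  ii <- seq_len(n) - 1
  rd <- sqrt(outer(ii - center[1], rep(1, n))^2 +
               outer(rep(1, n), ii - center[2])^2)
  fr <- matrix(bg, n, n)
  fr[rd <= radius_px] <- fg
  pmax(fr + matrix(stats::rnorm(n * n, 0, noise_sd), n, n), 0)
}

# direct O(T s^4) STICS correlation: the non-FFT double-loop oracle
direct_stics_oracle <- function(x, lag) {
  n_t <- dim(x)[3]; h <- dim(x)[1]; w <- dim(x)[2]
  mi <- apply(x, c(1, 2), mean)
  x <- sweep(x, c(1, 2), mi)
  acc <- matrix(0, h, w)
  for (t in seq_len(n_t - lag)) {
    a <- x[, , t]; b <- x[, , t + lag]
    cc <- matrix(0, h, w)
    for (dr in 0:(h - 1)) for (dc in 0:(w - 1)) {
      s <- 0
      for (r in seq_len(h)) for (c in seq_len(w)) {
        rr <- ((r - 1 + dr) %% h) + 1
        c2 <- ((c - 1 + dc) %% w) + 1
        s <- s + a[r, c] * b[rr, c2]
      }
      cc[dr + 1, dc + 1] <- s
    }
    acc <- acc + cc / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  synapseflow:::fftshift2(acc / (n_t - lag))
}

# O(n^2) double-loop MSD oracle (no gap handling; gap-free tracks only)
direct_msd_oracle <- function(track) {
  o <- order(track$frame)
  x <- track$x_um[o]; y <- track$y_um[o]; t <- track$t_s[o]
  n <- length(x)
  dt <- (t[n] - t[1]) / (n - 1)
  vapply(seq_len(n - 1), function(lag) {
    v <- numeric(0)
    for (i in seq_len(n - lag))
      v <- c(v, (x[i + lag] - x[i])^2 + (y[i + lag] - y[i])^2)
    mean(v)
  }, numeric(1))
}

# rotate a matrix by 90 degrees counter-clockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# render a point-emitter movie from a track table (one spot per track)
render_track_movie <- function(tracks, size_px, pixel_size, frame_interval,
                               psf_sigma_um = 1 / 2.355) {
  frames <- sort(unique(tracks$frame))
  arr <- array(0, dim = c(size_px, size_px, max(frames)))
  for (f in frames) {
    sel <- tracks$frame == f
    arr[, , f] <- synapseflow:::render_spots(
      size_px, size_px,
      tracks$y_um[sel] / pixel_size, tracks$x_um[sel] / pixel_size,
      psf_sigma_um / pixel_size)
  }
  image_stack(arr, pixel_size, frame_interval)
}
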