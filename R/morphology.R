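# Low-level raster operations shared by the segmentation, granule and
# tracking modules: FFT-based 2D convolution, binary morphology with a disk
# structuring element, hole filling and connected-component labelling
# (igraph does the graph traversal).

# "same"-sized 2D convolution of x with kernel k (odd-sized preferred),
# zero-padded boundaries, via FFT.
conv2_same <- function(x, k) {
  hx <- nrow(x); wx <- ncol(x)
  hk <- nrow(k); wk <- ncol(k)
  ph <- hx + hk - 1L; pw <- wx + wk - 1L
  xp <- matrix(0, ph, pw); xp[1:hx, 1:wx] <- x
  kp <- matrix(0, ph, pw); kp[1:hk, 1:wk] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (ph * pw)
  r0 <- (hk - 1L) %/% 2L
  c0 <- (wk - 1L) %/% 2L
  full[r0 + seq_len(hx), c0 + seq_len(wx)]
}

# Disk structuring element of integer radius r: (2r+1)^2 logical matrix.
disk_kernel <- function(r) {
  r <- as.integer(round(r))
  if (r < 0L) stop("disk radius must be >= 0")
  d <- 2L * r + 1L
  idx <- seq_len(d) - r - 1L
  outer(idx, idx, function(i, j) (i^2 + j^2) <= r^2 + 1e-9) * 1
}

binary_erode <- function(mask, kernel) {
  counts <- round(conv2_same(mask * 1, kernel))
  counts >= sum(kernel)
}

binary_dilate <- function(mask, kernel) {
  counts <- round(conv2_same(mask * 1, kernel))
  counts >= 1
}

binary_close <- function(mask, kernel) {
  # pad so dilation past the border is not clipped by the erosion step
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L * r, w + 2L * r)
  padded[r + seq_len(h), r + seq_len(w)] <- mask
  closed <- binary_erode(binary_dilate(padded, kernel), kernel)
  closed[r + seq_len(h), r + seq_len(w)]
}

# Close an edge curve into a filled region: dilate (sealing gaps up to
# ~2r), fill the enclosed holes, erode back. Bridges broken contours that
# plain closing cannot, because the hole fill happens while the curve is
# thick.
close_and_fill <- function(mask, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L * r, w + 2L * r)
  padded[r + seq_len(h), r + seq_len(w)] <- mask
  out <- binary_erode(fill_holes(binary_dilate(padded, kernel)), kernel)
  out[r + seq_len(h), r + seq_len(w)]
}

# Label connected components of a logical mask. connectivity 4 or 8.
# Returns an integer matrix, 0 = background, components numbered from 1
# in decreasing size order.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) return(labels)
  id <- integer(h * w)
  id[fg] <- seq_along(fg)

  offs <- list(c(1L, 0L), c(0L, 1L))              # down, right
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))  # diagonals
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nr <- rows + o[1]; nc <- cols + o[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    valid <- id[nidx] > 0L
    from <- c(from, id[fg[ok]][valid])
    to <- c(to, id[nidx][valid])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0L)
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  memb <- igraph::components(g)$membership
  # renumber by decreasing pixel count for a stable, size-ordered labelling
  sizes <- tabulate(memb)
  rank <- match(memb, order(sizes, decreasing = TRUE))
  labels[fg] <- rank
  labels
}

# Fill holes: background regions (4-connected) not touching the border
# become foreground.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  conv2_same(conv2_same(img, matrix(k, ncol = 1)), matrix(k, nrow = 1))
}

# Replicate image borders outward by p pixels (avoids the spurious
# gradients zero padding would create at the frame edge).
pad_replicate <- function(img, p) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1L, p), seq_len(h), rep(h, p))
  ci <- c(rep(1L, p), seq_len(w), rep(w, p))
  img[ri, ci]
}

# Otsu's threshold on a numeric vector (256-bin histogram): maximises the
# between-class variance. Adapts to any foreground fraction, unlike a
# fixed percentile.
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = 256L)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  mids[which.max(between)]
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression quantised to 4 directions, hysteresis by component labelling.
# The automatic high threshold is Otsu's on the gradient magnitude; the
# result carries the thresholds and the magnitude median as attributes so
# callers can judge edge contrast.
canny_edges <- function(img, low = NULL, high = NULL, sigma = 1.4,
                        low_fraction = 0.4) {
  pad <- max(1L, ceiling(3 * sigma)) + 1L
  padded <- pad_replicate(img, pad)
  sm <- gaussian_blur(padded, sigma)
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy <- conv2_same(sm, sob)         # gradient along rows
  gx <- conv2_same(sm, t(sob))      # gradient along columns
  core_r <- pad + seq_len(nrow(img))
  core_c <- pad + seq_len(ncol(img))
  gy <- gy[core_r, core_c]
  gx <- gx[core_r, core_c]
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  if (is.null(high)) high <- otsu_threshold(mag)
  if (is.null(low)) low <- low_fraction * high

  h <- nrow(img); w <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    okr <- rs >= 1 & rs <= h; okc <- cs >= 1 & cs <= w
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  # interpolated non-maximum suppression: compare against the gradient
  # magnitude bilinearly interpolated one step along +/- the true gradient
  # direction (quantised 4-sector NMS punches holes in contours near
  # 22.5-degree orientations)
  ax <- abs(gx); ay <- abs(gy)
  sx <- ifelse(gx >= 0, 1L, -1L)
  sy <- ifelse(gy >= 0, 1L, -1L)
  wdiag <- ifelse(ax >= ay, ifelse(ax > 0, ay / ax, 0),
                  ifelse(ay > 0, ax / ay, 0))
  m_fwd <- m_bwd <- matrix(0, h, w)
  for (sxi in c(-1L, 1L)) for (syi in c(-1L, 1L)) {
    diag_f <- shift(mag, syi, sxi)      # one step along (sy, sx)
    diag_b <- shift(mag, -syi, -sxi)
    for (xdom in c(TRUE, FALSE)) {
      sel <- sx == sxi & sy == syi & ((ax >= ay) == xdom)
      if (!any(sel)) next
      prin_f <- if (xdom) shift(mag, 0L, sxi) else shift(mag, syi, 0L)
      prin_b <- if (xdom) shift(mag, 0L, -sxi) else shift(mag, -syi, 0L)
      m_fwd[sel] <- (1 - wdiag[sel]) * prin_f[sel] + wdiag[sel] * diag_f[sel]
      m_bwd[sel] <- (1 - wdiag[sel]) * prin_b[sel] + wdiag[sel] * diag_b[sel]
    }
  }
  keep <- mag >= m_fwd & mag >= m_bwd
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) {
    out <- matrix(FALSE, h, w)
  } else {
    lab <- label_components(weak, connectivity = 8L)
    good <- unique(lab[strong])
    out <- lab > 0L & lab %in% good
  }
  attr(out, "high") <- high
  attr(out, "median_mag") <- stats::median(mag)
  out
}
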