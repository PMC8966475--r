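# Minimal baseline-TIFF I/O for grayscale scientific rasters.
#
# Scope: uncompressed, single-sample-per-pixel (grayscale) images, one or
# more pages, strip-organised. Bit depths: 8/16-bit unsigned integer,
# 32/64-bit IEEE float. Both byte orders are read; files are written
# little-endian with one strip per page. Tiled, compressed, palette and
# multi-channel TIFFs are rejected with an informative error. This is all
# the pipeline needs: quantitative microscopy stacks are grayscale.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

.read_tiff_values <- function(con, type, count, value_bytes, endian) {
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)
  total <- size * count
  if (total > 4L) {
    offset <- readBin(value_bytes, "integer", n = 1L, size = 4L, endian = endian)
    cur <- seek(con)
    seek(con, offset)
    raw_data <- readBin(con, "raw", n = total)
    seek(con, cur)
  } else {
    raw_data <- value_bytes[seq_len(total)]
  }
  switch(as.character(type),
    `1` = as.integer(raw_data),
    `3` = readBin(raw_data, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    `4` = readBin(raw_data, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(raw_data, "numeric", n = count, size = 4L, endian = endian),
    `12` = readBin(raw_data, "numeric", n = count, size = 8L, endian = endian),
    NULL)
}

.read_tiff_ifd <- function(con, offset, endian) {
  seek(con, offset)
  n_entries <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                       endian = endian)
  entries <- vector("list", n_entries)
  tags <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    tags[i] <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                       endian = endian)
    type <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                    endian = endian)
    count <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
    value_bytes <- readBin(con, "raw", n = 4L)
    entries[[i]] <- list(type = type, count = count, value_bytes = value_bytes)
  }
  next_ifd <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  list(tags = tags, entries = entries, next_ifd = next_ifd)
}

.tiff_tag <- function(con, ifd, tag, endian, default = NULL) {
  idx <- match(tag, ifd$tags)
  if (is.na(idx)) return(default)
  e <- ifd$entries[[idx]]
  .read_tiff_values(con, e$type, e$count, e$value_bytes, endian)
}

#' Read a grayscale TIFF file
#'
#' Reads an uncompressed single- or multi-page grayscale TIFF into a numeric
#' array. Supports 8/16-bit unsigned integer and 32/64-bit float samples in
#' either byte order. Pixel values are returned as doubles; the source bit
#' depth is attached as the `"bit_depth"` / `"sample_format"` attributes.
#'
#' @param path Path to the TIFF file.
#' @return A `H x W x T` numeric array (`T` = number of pages) with
#'   attributes `bit_depth` and `sample_format` (`"uint"` or `"float"`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  endian <- if (identical(rawToChar(magic), "II")) "little"
            else if (identical(rawToChar(magic), "MM")) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  forty_two <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                       endian = endian)
  if (forty_two != 42L) stop("not a TIFF file (bad magic number): ", path)
  ifd_offset <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)

  pages <- list()
  bit_depth <- NA_integer_
  fmt <- NA_character_
  while (ifd_offset != 0L) {
    ifd <- .read_tiff_ifd(con, ifd_offset, endian)
    if (!is.na(match(322L, ifd$tags)))
      stop("tiled TIFFs are not supported")
    width <- .tiff_tag(con, ifd, 256L, endian)
    height <- .tiff_tag(con, ifd, 257L, endian)
    bits <- .tiff_tag(con, ifd, 258L, endian, default = 1L)
    compression <- .tiff_tag(con, ifd, 259L, endian, default = 1L)
    photometric <- .tiff_tag(con, ifd, 262L, endian, default = 1L)
    strip_offsets <- .tiff_tag(con, ifd, 273L, endian)
    spp <- .tiff_tag(con, ifd, 277L, endian, default = 1L)
    rows_per_strip <- .tiff_tag(con, ifd, 278L, endian, default = height)
    strip_counts <- .tiff_tag(con, ifd, 279L, endian)
    sample_format <- .tiff_tag(con, ifd, 339L, endian, default = 1L)

    if (compression != 1L)
      stop("compressed TIFFs are not supported (compression tag = ",
           compression, ")")
    if (spp != 1L || photometric > 1L)
      stop("multi-channel / non-grayscale TIFF rejected ",
           "(SamplesPerPixel = ", spp, ", PhotometricInterpretation = ",
           photometric, ")")
    if (length(bits) != 1L) stop("unsupported BitsPerSample layout")
    what <- if (sample_format == 3L) "numeric" else "integer"
    if (sample_format == 3L && !bits %in% c(32L, 64L))
      stop("unsupported float bit depth: ", bits)
    if (sample_format != 3L && !bits %in% c(8L, 16L))
      stop("unsupported integer bit depth: ", bits)

    values <- numeric(0)
    for (s in seq_along(strip_offsets)) {
      seek(con, strip_offsets[s])
      n_px <- strip_counts[s] / (bits / 8L)
      v <- readBin(con, what, n = n_px, size = bits / 8L,
                   signed = FALSE || sample_format == 3L, endian = endian)
      values <- c(values, as.numeric(v))
    }
    if (length(values) != width * height)
      stop("corrupt TIFF page: expected ", width * height, " pixels, got ",
           length(values))
    # TIFF stores rows top-to-bottom, row-major
    pages[[length(pages) + 1L]] <- t(matrix(values, nrow = width,
                                            ncol = height))
    bit_depth <- bits
    fmt <- if (sample_format == 3L) "float" else "uint"
    ifd_offset <- ifd$next_ifd
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have non-uniform dimensions")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  attr(arr, "bit_depth") <- bit_depth
  attr(arr, "sample_format") <- fmt
  arr
}

.tiff_entry <- function(tag, type, count, value, endian = "little") {
  # returns 12 raw bytes for one IFD entry; `value` must fit inline
  out <- c(writeBin(as.integer(tag), raw(), size = 2L, endian = endian),
           writeBin(as.integer(type), raw(), size = 2L, endian = endian),
           writeBin(as.integer(count), raw(), size = 4L, endian = endian))
  size <- .tiff_type_size[as.character(type)]
  vb <- if (type %in% c(3L, 8L)) {
    writeBin(as.integer(value), raw(), size = 2L, endian = endian)
  } else {
    writeBin(as.integer(value), raw(), size = 4L, endian = endian)
  }
  vb <- c(vb, raw(4L - length(vb)))
  c(out, vb)
}

#' Write a grayscale (multi-page) TIFF file
#'
#' Writes a numeric matrix or `H x W x T` array as an uncompressed
#' little-endian grayscale TIFF, one page per slice, one strip per page.
#'
#' @param x Numeric matrix or 3-D array (`H x W x T`).
#' @param path Output path.
#' @param dtype One of `"float32"`, `"float64"`, `"uint16"`, `"uint8"`.
#'   `"float64"` round-trips doubles losslessly; `"float32"` halves the file
#'   size at ~1e-7 relative precision. Integer types truncate.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, dtype = c("float32", "float64", "uint16",
                                          "uint8")) {
  dtype <- match.arg(dtype)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  if (any(!is.finite(x))) stop("cannot write non-finite pixel values")
  h <- dim(x)[1]; w <- dim(x)[2]; n_pages <- dim(x)[3]
  bits <- switch(dtype, float32 = 32L, float64 = 64L, uint16 = 16L,
                 uint8 = 8L)
  fmt <- if (startsWith(dtype, "float")) 3L else 1L
  if (fmt == 1L) {
    maxv <- 2^bits - 1
    if (any(x < 0) || any(x > maxv))
      stop("pixel values out of range for ", dtype)
  }
  bytes_px <- bits / 8L
  strip_bytes <- h * w * bytes_px
  ifd_nbytes <- 2L + 10L * 12L + 4L   # 10 entries

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")   # first IFD at byte 8

  offset <- 8L
  for (p in seq_len(n_pages)) {
    strip_offset <- offset + ifd_nbytes
    next_ifd <- if (p < n_pages) strip_offset + strip_bytes else 0L
    entries <- c(
      .tiff_entry(256L, 4L, 1L, w),
      .tiff_entry(257L, 4L, 1L, h),
      .tiff_entry(258L, 3L, 1L, bits),
      .tiff_entry(259L, 3L, 1L, 1L),          # no compression
      .tiff_entry(262L, 3L, 1L, 1L),          # BlackIsZero
      .tiff_entry(273L, 4L, 1L, strip_offset),
      .tiff_entry(277L, 3L, 1L, 1L),          # one sample per pixel
      .tiff_entry(278L, 4L, 1L, h),
      .tiff_entry(279L, 4L, 1L, strip_bytes),
      .tiff_entry(339L, 3L, 1L, fmt))
    writeBin(10L, con, size = 2L, endian = "little")
    writeBin(entries, con)
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    vals <- as.numeric(t(x[, , p]))             # row-major
    if (fmt == 3L) {
      writeBin(vals, con, size = bytes_px, endian = "little")
    } else {
      writeBin(as.integer(round(vals)), con, size = bytes_px,
               endian = "little")
    }
    offset <- offset + ifd_nbytes + strip_bytes
  }
  invisible(path)
}
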