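# Minimal baseline TIFF 6.0 I/O for 8-bit greyscale multi-page stacks.
#
# No TIFF package is available in the target library set, so the subset of
# the format the pipeline needs is implemented here: little-endian,
# uncompressed, one 8-bit greyscale strip per page, one page per z-slice.
# The reader additionally tolerates multiple strips and SHORT/LONG/BYTE tag
# types, but rejects compressed, tiled, or non-greyscale files.

le_bytes <- function(x, width) {
  # little-endian unsigned integer -> raw vector of `width` bytes
  out <- raw(width * length(x))
  x <- as.numeric(x)
  for (b in seq_len(width)) {
    out[seq(b, by = width, length.out = length(x))] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (left-justified 4 bytes)
  width <- if (type == 3L) 2L else 4L
  val <- c(le_bytes(value, width), raw(4))[1:4]
  c(le_bytes(tag, 2), le_bytes(type, 2), le_bytes(count, 4), val)
}

#' Write a volume as a multi-page TIFF stack
#'
#' One 8-bit greyscale page per z-slice, uncompressed, little-endian. Voxel
#' sizes are not stored in the TIFF; writers of full datasets should pair the
#' stack with a JSON sidecar (see [write_ground_truth()]).
#'
#' @param vol an [intensity_volume()] or [binary_volume()] (binary data are
#'   written as 0/255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(vol, path) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  data <- as.integer(vol)
  if (inherits(vol, "binary_volume")) data <- data * 255L
  con <- file(path, "wb")
  on.exit(close(con))
  page_bytes <- nx * ny
  data_start <- 8
  ifd_start <- data_start + page_bytes * nz
  n_entries <- 9L
  ifd_size <- 2 + 12 * n_entries + 4
  # header: "II", magic 42, offset of first IFD
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)
  writeBin(le_bytes(42, 2), con)
  writeBin(le_bytes(ifd_start, 4), con)
  # pixel data: page-major, row-major within a page (row = y, col = x)
  for (z in seq_len(nz)) {
    # array [x, y] in column-major order already iterates x fastest, which is
    # exactly TIFF's row-major pixel order for row = y
    writeBin(as.raw(data[(z - 1) * page_bytes + seq_len(page_bytes)]), con)
  }
  for (z in seq_len(nz)) {
    strip_off <- data_start + (z - 1) * page_bytes
    next_ifd <- if (z < nz) ifd_start + z * ifd_size else 0
    entries <- c(
      ifd_entry(256, 4L, 1, nx),          # ImageWidth
      ifd_entry(257, 4L, 1, ny),          # ImageLength
      ifd_entry(258, 3L, 1, 8),           # BitsPerSample
      ifd_entry(259, 3L, 1, 1),           # Compression: none
      ifd_entry(262, 3L, 1, 1),           # Photometric: BlackIsZero
      ifd_entry(273, 4L, 1, strip_off),   # StripOffsets
      ifd_entry(277, 3L, 1, 1),           # SamplesPerPixel
      ifd_entry(278, 4L, 1, ny),          # RowsPerStrip
      ifd_entry(279, 4L, 1, page_bytes)   # StripByteCounts
    )
    writeBin(le_bytes(n_entries, 2), con)
    writeBin(entries, con)
    writeBin(le_bytes(next_ifd, 4), con)
  }
  invisible(path)
}

read_uint <- function(raw, offset, width) {
  # offset is 0-based; little-endian
  b <- as.integer(raw[offset + seq_len(width)])
  sum(b * 256^(seq_len(width) - 1))
}

#' Read a multi-page greyscale TIFF stack
#'
#' Supports the subset written by [write_tiff_volume()]: uncompressed 8-bit
#' greyscale, little-endian, strip-organised.
#'
#' @param path TIFF file.
#' @param voxel_lateral,voxel_axial voxel sizes to attach, micrometres.
#' @return an [intensity_volume()].
#' @export
read_tiff_volume <- function(path, voxel_lateral = 12, voxel_axial = 2.1) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  if (!(raw[1] == 0x49 && raw[2] == 0x49))
    stop("only little-endian ('II') TIFF is supported")
  if (read_uint(raw, 2, 2) != 42) stop("bad TIFF magic number")
  ifd_off <- read_uint(raw, 4, 4)
  pages <- list()
  nx <- ny <- NULL
  type_width <- c(1, 1, 2, 4)  # BYTE, ASCII, SHORT, LONG
  while (ifd_off != 0) {
    n <- read_uint(raw, ifd_off, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- read_uint(raw, e, 2)
      type <- read_uint(raw, e + 2, 2)
      count <- read_uint(raw, e + 4, 4)
      if (type > 4) { tags[[as.character(tag)]] <- NULL; next }
      w <- type_width[type]
      vals_off <- if (count * w <= 4) e + 8 else read_uint(raw, e + 8, 4)
      tags[[as.character(tag)]] <-
        vapply(seq_len(count), function(j) read_uint(raw, vals_off + (j - 1) * w, w), 0)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w_ <- g(256); h_ <- g(257)
    if (is.null(w_) || is.null(h_)) stop("TIFF page missing dimensions")
    if (any(g(258, 8) != 8) || g(277, 1) != 1)
      stop("only 8-bit single-sample greyscale TIFF is supported")
    if (g(259, 1) != 1) stop("compressed TIFF is not supported")
    offs <- g(273); cnts <- g(279, w_ * h_)
    page <- unlist(lapply(seq_along(offs), function(j)
      as.integer(raw[offs[j] + seq_len(cnts[j])])))
    if (length(page) != w_ * h_) stop("truncated TIFF strip data")
    if (is.null(nx)) { nx <- w_; ny <- h_ }
    else if (nx != w_ || ny != h_) stop("TIFF pages have differing dimensions")
    # stored row-major (x fastest within a row of constant y) -> [x, y]
    pages[[length(pages) + 1]] <- matrix(page, nrow = nx)
    ifd_off <- read_uint(raw, ifd_off + 2 + n * 12, 4)
  }
  arr <- array(0L, c(nx, ny, length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  intensity_volume(arr, voxel_lateral, voxel_axial)
}
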