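# Slice <-> 8-bit raster conversion and raster stack assembly.
#
# Slice matrices are indexed [x, y] to match scalar_volume sample order; on
# disk, image row r corresponds to y = r and image column c to x = c.

#' Convert one slice to an 8-bit grayscale raster
#'
#' With the default \code{"full"} window the slice's own \code{[min, max]}
#' range maps linearly onto 0..255 (a constant slice maps to all zeros).  An
#' explicit window \code{c(center, width)} maps
#' \code{[center - width/2, center + width/2]} onto 0..255 with clamping.
#' Either way the mapping is monotone non-decreasing in the input value.
#'
#' @param slice numeric matrix of sample values, indexed \code{[x, y]}.
#' @param window \code{"full"} or numeric \code{c(center, width)}, width > 0.
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
convert_slice_to_raster <- function(slice, window = "full") {
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("`slice` must be a numeric matrix")
  if (identical(window, "full") || identical(window, "full-range")) {
    lo <- min(slice); hi <- max(slice)
  } else {
    window <- as.numeric(window)
    if (length(window) != 2L || !all(is.finite(window)) || window[2] <= 0)
      stop("`window` must be \"full\" or c(center, width) with width > 0")
    lo <- window[1] - window[2] / 2
    hi <- window[1] + window[2] / 2
  }
  if (hi <= lo) {
    out <- matrix(0L, nrow(slice), ncol(slice))
  } else {
    scaled <- (slice - lo) / (hi - lo)
    scaled[scaled < 0] <- 0
    scaled[scaled > 1] <- 1
    out <- matrix(as.integer(round(255 * scaled)), nrow(slice), ncol(slice))
  }
  out
}

# ---- minimal 8-bit grayscale BMP codec --------------------------------------
# Uncompressed BI_RGB, 8 bits per pixel, 256-entry grayscale palette,
# bottom-up rows padded to 4 bytes.  Only the subset this package writes.

#' Write an 8-bit grayscale BMP
#'
#' @param raster integer matrix in 0..255, indexed \code{[x, y]}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gray_bmp <- function(raster, path) {
  stopifnot(is.matrix(raster))
  w <- nrow(raster); h <- ncol(raster)
  vals <- as.integer(raster)
  if (any(is.na(vals)) || any(vals < 0L) || any(vals > 255L))
    stop("raster values must be integers in 0..255")
  pad <- (4L - w %% 4L) %% 4L
  row_bytes <- w + pad
  data_size <- row_bytes * h
  offset <- 14L + 40L + 1024L
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(c(offset + data_size, 0L, offset), con, size = 4L,
           endian = "little")
  # BITMAPINFOHEADER
  writeBin(c(40L, w, h), con, size = 4L, endian = "little")
  writeBin(c(1L, 8L), con, size = 2L, endian = "little")
  writeBin(c(0L, data_size, 2835L, 2835L, 256L, 0L), con, size = 4L,
           endian = "little")
  pal <- as.raw(rep(0:255, each = 4L) * c(1L, 1L, 1L, 0L))
  writeBin(pal, con)
  img <- matrix(vals, nrow = w, ncol = h)
  for (r in h:1) {  # bottom-up
    writeBin(as.raw(c(img[, r], rep(0L, pad))), con)
  }
  invisible(path)
}

#' Read an 8-bit grayscale BMP written by [write_gray_bmp()]
#'
#' Accepts any uncompressed 8-bit palettized BMP; palette entries are
#' collapsed to gray via their red channel.
#'
#' @param path input file.
#' @return Integer matrix in 0..255, indexed \code{[x, y]}.
#' @export
read_gray_bmp <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "BM")) stop("not a BMP file: ", path)
  readBin(con, "integer", 2L, size = 4L, endian = "little")  # size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  w <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  h <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (bpp != 8L || compression != 0L)
    stop("unsupported BMP variant (need uncompressed 8-bit): ", path)
  readBin(con, "integer", 5L, size = 4L, endian = "little")
  n_colors <- 256L
  skip <- hdr_size - 40L
  if (skip > 0L) readBin(con, "raw", skip)
  pal <- readBin(con, "raw", n_colors * 4L)
  gray <- as.integer(pal[seq(3L, length(pal), by = 4L)])  # red channel (BGR0)
  flip <- h > 0L
  h <- abs(h)
  pad <- (4L - w %% 4L) %% 4L
  seek(con, offset)
  img <- matrix(0L, nrow = w, ncol = h)
  rows <- if (flip) h:1 else 1:h
  for (r in rows) {
    img[, r] <- gray[as.integer(readBin(con, "raw", w)) + 1L]
    if (pad > 0L) readBin(con, "raw", pad)
  }
  img
}

# ---- PNG (via the png package) ----------------------------------------------

#' Write an 8-bit grayscale PNG
#' @inheritParams write_gray_bmp
#' @export
write_gray_png <- function(raster, path) {
  stopifnot(is.matrix(raster))
  png::writePNG(t(raster) / 255, target = path)
  invisible(path)
}

#' Read a grayscale PNG as 0..255 integers
#' @param path input file.
#' @return Integer matrix in 0..255, indexed \code{[x, y]}.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of gray+alpha
  matrix(as.integer(round(t(img) * 255)), nrow = dim(img)[2], ncol = dim(img)[1])
}

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bmp = read_gray_bmp(path),
         png = read_gray_png(path),
         stop("unsupported raster format: .", ext, " (", path, ")"))
}

#' Load a stack of grayscale rasters as a volume
#'
#' @param paths a directory (slices taken in lexicographic order) or an
#'   explicit character vector of files in slice order; PNG or BMP.
#' @param spacing physical \code{c(dx, dy, dz)}; \code{dz} is the slice
#'   spacing.
#' @param origin physical coordinate of the first pixel of the first slice.
#' @return A \code{scalar_volume} whose samples are the raw pixel
#'   intensities.
#' @export
load_raster_stack <- function(paths, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(png|bmp)$",
                             ignore.case = TRUE, full.names = TRUE))
  if (length(paths) < 2L)
    stop("insufficient data: need at least 2 slices")
  slices <- lapply(paths, .read_raster)
  dims2 <- vapply(slices, dim, integer(2L))
  if (any(dims2[1, ] != dims2[1, 1]) || any(dims2[2, ] != dims2[2, 1]))
    stop("dimension mismatch: slices differ in size (",
         paste(basename(paths[1]), collapse = ""), " is ",
         dims2[1, 1], "x", dims2[2, 1], ")")
  vol <- array(0, dim = c(dims2[1, 1], dims2[2, 1], length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- slices[[k]]
  scalar_volume(vol, spacing = spacing, origin = origin)
}

#' Write a volume as a stack of 8-bit rasters
#'
#' The window is applied globally (one mapping for the whole volume, by
#' default its full range), so the z-profile of the data survives
#' quantization; reloading with [load_raster_stack()] reproduces the 8-bit
#' quantized volume exactly.
#'
#' @param volume a \code{scalar_volume}.
#' @param dir output directory (created if missing).
#' @param format \code{"png"} or \code{"bmp"}.
#' @param window \code{"full"} (volume-wide range) or \code{c(center, width)}.
#' @param prefix file-name prefix; slices are numbered \code{prefix0001...}.
#' @return Character vector of the written paths, invisibly.
#' @export
write_raster_stack <- function(volume, dir, format = c("png", "bmp"),
                               window = "full", prefix = "slice") {
  stopifnot(inherits(volume, "scalar_volume"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (identical(window, "full") || identical(window, "full-range")) {
    rng <- range(volume$samples)
    window <- c(mean(rng), diff(rng))
    if (window[2] <= 0) window <- "full"  # constant volume: per-slice rule
  }
  nz <- dim(volume$samples)[3]
  writer <- if (format == "png") write_gray_png else write_gray_bmp
  paths <- file.path(dir, sprintf("%s%04d.%s", prefix, seq_len(nz), format))
  for (k in seq_len(nz)) {
    writer(convert_slice_to_raster(volume$samples[, , k], window), paths[k])
  }
  invisible(paths)
}
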