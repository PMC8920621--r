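# Minimal DICOM support: explicit-VR little-endian, single-frame grayscale.
#
# The reader extracts only what volume assembly needs (pixel grid, rescale
# slope/intercept, geometry, ordering keys) and discards everything else, so
# patient-identifying metadata never reaches the returned objects.  The
# matching writer exists to build synthetic series for tests and pipeline
# shakedowns.

.dcm_tag <- function(group, element) bitwShiftL(group, 16L) + element

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one explicit-VR element; returns list(tag, vr, value raw) or NULL at EOF
.dcm_read_element <- function(con) {
  gr <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                endian = "little")
  if (length(gr) == 0L) return(NULL)
  el <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2L))
  if (vr %in% .dcm_long_vrs) {
    readBin(con, "raw", 2L)  # reserved
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    len <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                   endian = "little")
  }
  if (len < 0L) stop("unsupported DICOM element length")
  value <- readBin(con, "raw", len)
  list(tag = .dcm_tag(gr, el), vr = vr, value = value)
}

.dcm_str <- function(raw) {
  while (length(raw) && raw[length(raw)] %in% as.raw(c(0L, 32L)))
    raw <- raw[-length(raw)]
  rawToChar(raw)
}
.dcm_ds <- function(raw) as.numeric(strsplit(.dcm_str(raw), "\\\\")[[1]])
.dcm_us <- function(raw) readBin(raw, "integer", 1L, size = 2L,
                                 signed = FALSE, endian = "little")

#' Read one DICOM slice (minimal explicit-VR little-endian subset)
#'
#' Parses a single-frame grayscale slice and keeps only the pixel grid and
#' the handful of numeric attributes needed to assemble a volume.  All other
#' elements -- names, IDs, dates, free text -- are read past and dropped.
#'
#' @param path file to read.
#' @return A list with \code{pixels} (integer matrix \code{[x, y]}, raw
#'   stored values), \code{rescale_slope}, \code{rescale_intercept},
#'   \code{instance_number}, \code{position_z}, \code{pixel_spacing}
#'   (\code{c(dx, dy)}), \code{slice_thickness}.
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("I/O error reading DICOM slice: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 128L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "DICM"))
    stop("I/O error: not a DICOM file (missing DICM marker): ", path)
  out <- list(pixels = NULL, rescale_slope = 1, rescale_intercept = 0,
              instance_number = NA_integer_, position_z = NA_real_,
              pixel_spacing = c(1, 1), slice_thickness = NA_real_)
  rows <- cols <- NULL
  bits <- 16L
  signed_px <- FALSE
  repeat {
    elt <- tryCatch(.dcm_read_element(con), error = function(e)
      stop("I/O error reading DICOM slice ", path, ": ", conditionMessage(e)))
    if (is.null(elt)) break
    tag <- elt$tag
    if (tag == .dcm_tag(0x0018L, 0x0050L)) {
      out$slice_thickness <- .dcm_ds(elt$value)[1]
    } else if (tag == .dcm_tag(0x0020L, 0x0013L)) {
      out$instance_number <- as.integer(.dcm_str(elt$value))
    } else if (tag == .dcm_tag(0x0020L, 0x0032L)) {
      pos <- .dcm_ds(elt$value)
      if (length(pos) >= 3L) out$position_z <- pos[3]
    } else if (tag == .dcm_tag(0x0028L, 0x0010L)) {
      rows <- .dcm_us(elt$value)
    } else if (tag == .dcm_tag(0x0028L, 0x0011L)) {
      cols <- .dcm_us(elt$value)
    } else if (tag == .dcm_tag(0x0028L, 0x0030L)) {
      sp <- .dcm_ds(elt$value)  # row spacing (y), column spacing (x)
      out$pixel_spacing <- c(sp[2], sp[1])
    } else if (tag == .dcm_tag(0x0028L, 0x0100L)) {
      bits <- .dcm_us(elt$value)
    } else if (tag == .dcm_tag(0x0028L, 0x0103L)) {
      signed_px <- .dcm_us(elt$value) == 1L
    } else if (tag == .dcm_tag(0x0028L, 0x1052L)) {
      out$rescale_intercept <- .dcm_ds(elt$value)[1]
    } else if (tag == .dcm_tag(0x0028L, 0x1053L)) {
      out$rescale_slope <- .dcm_ds(elt$value)[1]
    } else if (tag == .dcm_tag(0x7FE0L, 0x0010L)) {
      if (is.null(rows) || is.null(cols))
        stop("I/O error: pixel data before Rows/Columns in ", path)
      if (!bits %in% c(8L, 16L))
        stop("unsupported DICOM: bits allocated must be 8 or 16 in ", path)
      n <- rows * cols
      px <- readBin(elt$value, "integer", n, size = bits %/% 8L,
                    signed = if (bits == 8L) FALSE else signed_px,
                    endian = "little")
      if (bits == 16L && !signed_px) px[px < 0L] <- px[px < 0L] + 65536L
      if (length(px) != n)
        stop("I/O error: truncated pixel data in ", path)
      # pixel order is row-major: x varies fastest within an image row
      out$pixels <- matrix(px, nrow = cols, ncol = rows)
    }
    # every other element (patient name, IDs, dates, ...) is discarded here
  }
  if (is.null(out$pixels))
    stop("I/O error: no pixel data found in ", path)
  out
}

#' Write one DICOM slice (minimal explicit-VR little-endian subset)
#'
#' Produces a small single-frame grayscale file that [read_dicom_slice()] and
#' mainstream DICOM readers can parse.  Intended for building synthetic test
#' series; it deliberately includes a patient-name element so that metadata
#' stripping is observable downstream.
#'
#' @param pixels integer matrix \code{[x, y]} of stored values (0..65535).
#' @param path output file.
#' @param instance_number slice index used as an ordering fallback.
#' @param position_z slice position along the stack normal.
#' @param pixel_spacing in-plane \code{c(dx, dy)}.
#' @param slice_thickness nominal slice thickness.
#' @param rescale_slope,rescale_intercept value rescale: real value =
#'   slope * stored + intercept.
#' @param patient_name planted identifying metadata (stripped on load).
#' @return \code{path}, invisibly.
#' @export
write_dicom_slice <- function(pixels, path, instance_number = 1L,
                              position_z = 0,
                              pixel_spacing = c(1, 1),
                              slice_thickness = 1,
                              rescale_slope = 1, rescale_intercept = 0,
                              patient_name = "Synthetic^Phantom") {
  stopifnot(is.matrix(pixels))
  vals <- as.integer(round(pixels))
  if (any(vals < 0L) || any(vals > 65535L))
    stop("pixel values must be in 0..65535")
  w <- nrow(pixels); h <- ncol(pixels)
  con <- file(path, "wb"); on.exit(close(con))

  pad_even <- function(s) if (nchar(s) %% 2L == 1L) paste0(s, " ") else s
  put_short <- function(group, element, vr, value_raw) {
    writeBin(as.integer(c(group, element)), con, size = 2L, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(length(value_raw), con, size = 2L, endian = "little")
    writeBin(value_raw, con)
  }
  put_long <- function(group, element, vr, value_raw) {
    writeBin(as.integer(c(group, element)), con, size = 2L, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(as.raw(c(0L, 0L)), con)
    writeBin(length(value_raw), con, size = 4L, endian = "little")
    writeBin(value_raw, con)
  }
  str_raw <- function(s) charToRaw(pad_even(s))
  us_raw <- function(x) {
    as.raw(c(bitwAnd(x, 0xFFL), bitwShiftR(x, 8L)))
  }
  num_str <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                               collapse = "\\")

  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  put_short(0x0002L, 0x0010L, "UI", str_raw("1.2.840.10008.1.2.1"))
  put_short(0x0008L, 0x0020L, "DA", str_raw("20220307"))
  put_short(0x0008L, 0x0060L, "CS", str_raw("OT"))
  put_short(0x0010L, 0x0010L, "PN", str_raw(patient_name))
  put_short(0x0010L, 0x0020L, "LO", str_raw("SYN-000"))
  put_short(0x0018L, 0x0050L, "DS", str_raw(num_str(slice_thickness)))
  put_short(0x0020L, 0x0013L, "IS", str_raw(as.character(instance_number)))
  put_short(0x0020L, 0x0032L, "DS",
            str_raw(num_str(c(0, 0, position_z))))
  put_short(0x0028L, 0x0002L, "US", us_raw(1L))
  put_short(0x0028L, 0x0010L, "US", us_raw(h))  # Rows (y)
  put_short(0x0028L, 0x0011L, "US", us_raw(w))  # Columns (x)
  put_short(0x0028L, 0x0030L, "DS",
            str_raw(num_str(c(pixel_spacing[2], pixel_spacing[1]))))
  put_short(0x0028L, 0x0100L, "US", us_raw(16L))
  put_short(0x0028L, 0x0101L, "US", us_raw(16L))
  put_short(0x0028L, 0x0102L, "US", us_raw(15L))
  put_short(0x0028L, 0x0103L, "US", us_raw(0L))
  put_short(0x0028L, 0x1052L, "DS", str_raw(num_str(rescale_intercept)))
  put_short(0x0028L, 0x1053L, "DS", str_raw(num_str(rescale_slope)))
  px <- raw(2L * w * h)
  v <- as.vector(matrix(vals, nrow = w, ncol = h))  # x fastest = row-major image
  px[seq(1L, length(px), by = 2L)] <- as.raw(bitwAnd(v, 0xFFL))
  px[seq(2L, length(px), by = 2L)] <- as.raw(bitwShiftR(v, 8L))
  put_long(0x7FE0L, 0x0010L, "OW", px)
  invisible(path)
}

#' Assemble a DICOM series into a scalar volume
#'
#' Slices are ordered by their position along the stack normal when present,
#' falling back to instance number, then to file order.  The rescale
#' transform (value = slope * stored + intercept) is applied, and only
#' samples/spacing/origin survive into the result: no patient-identifying
#' metadata is reachable from the returned object.
#'
#' @param paths a directory or an explicit vector of DICOM files.
#' @param slice_spacing optional explicit z spacing; by default inferred from
#'   slice positions, then slice thickness, then 1.
#' @return A \code{scalar_volume}.
#' @export
load_dicom_series <- function(paths, slice_spacing = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.dcm$", ignore.case = TRUE,
                             full.names = TRUE))
  if (length(paths) < 2L)
    stop("insufficient data: a series needs at least 2 slices")
  slices <- lapply(paths, read_dicom_slice)

  dims2 <- vapply(slices, function(s) dim(s$pixels), integer(2L))
  if (any(dims2[1, ] != dims2[1, 1]) || any(dims2[2, ] != dims2[2, 1]))
    stop("dimension mismatch: DICOM slices differ in size")

  pos <- vapply(slices, `[[`, numeric(1L), "position_z")
  inst <- vapply(slices, `[[`, numeric(1L), "instance_number")
  ord <- if (all(is.finite(pos)) && !anyDuplicated(pos)) {
    order(pos)
  } else if (all(is.finite(inst)) && !anyDuplicated(inst)) {
    order(inst)
  } else {
    seq_along(slices)  # tie-break: file order
  }
  slices <- slices[ord]
  pos <- pos[ord]

  if (is.null(slice_spacing)) {
    dz <- if (all(is.finite(pos)) && length(pos) > 1L)
      stats::median(diff(pos)) else NA_real_
    if (!is.finite(dz) || dz <= 0) dz <- slices[[1]]$slice_thickness
    if (!is.finite(dz) || dz <= 0) dz <- 1
    slice_spacing <- dz
  }

  nz <- length(slices)
  vol <- array(0, dim = c(dims2[1, 1], dims2[2, 1], nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    vol[, , k] <- s$rescale_slope * s$pixels + s$rescale_intercept
  }
  z0 <- if (all(is.finite(pos))) min(pos) else 0
  scalar_volume(vol,
                spacing = c(slices[[1]]$pixel_spacing, slice_spacing),
                origin = c(0, 0, z0))
}
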