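# Scalar volumes: the 3D sampled field f(X, Y, Z) that marching cubes walks.

#' Construct a scalar volume
#'
#' A scalar volume is a dense 3D grid of finite scalar samples together with
#' the physical step per axis and the physical coordinate of the first sample.
#' Grid coordinates are 0-based: grid index \code{(x, y, z)} (each starting at
#' 0) sits at physical position \code{origin + c(x, y, z) * spacing}.  The
#' samples array is indexed \code{samples[x + 1, y + 1, z + 1]} in R.
#'
#' @param samples numeric 3D array, at least 2 samples per axis, all finite.
#' @param spacing numeric length-3, physical units per grid step, all > 0.
#' @param origin numeric length-3, physical coordinate of grid index (0,0,0).
#' @return An object of class \code{scalar_volume} with fields
#'   \code{samples}, \code{spacing}, \code{origin}.
#' @examples
#' v <- scalar_volume(array(rnorm(8 * 8 * 4), dim = c(8, 8, 4)),
#'                    spacing = c(1, 1, 2.5))
#' dim(v)
#' @export
scalar_volume <- function(samples, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(samples) || length(dim(samples)) != 3L)
    stop("`samples` must be a 3D array")
  if (any(dim(samples) < 2L))
    stop("insufficient data: each axis needs at least 2 samples")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("volume data error: non-finite sample values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(samples = samples, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
dim.scalar_volume <- function(x) dim(x$samples)

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("scalar_volume: %d x %d x %d samples\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %g x %g x %g, origin: (%g, %g, %g)\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range: [%g, %g]\n", min(x$samples), max(x$samples)))
  invisible(x)
}

#' Physical coordinates of grid indices
#'
#' @param volume a \code{scalar_volume}.
#' @param index integer matrix (n x 3) or length-3 vector of 0-based grid
#'   indices.
#' @return n x 3 matrix of physical coordinates.
#' @export
grid_to_physical <- function(volume, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3L)
  sweep(sweep(index, 2L, volume$spacing, `*`), 2L, volume$origin, `+`)
}

#' Describe an analytic test field
#'
#' Field specifications drive [generate_volume()], which stands in for
#' acquired slice stacks in tests and benchmarks.  Supported kinds:
#' \describe{
#'   \item{sphere}{signed distance \code{radius - |p - center|}, positive
#'     inside the sphere.}
#'   \item{two_spheres}{union (pointwise max) of two sphere fields.}
#'   \item{torus}{signed distance to a z-axis torus:
#'     \code{tube_radius - sqrt((sqrt(x^2 + y^2) - major_radius)^2 + z^2)},
#'     coordinates relative to \code{center}.}
#'   \item{smooth_noise}{seeded Gaussian white noise smoothed by repeated
#'     box blurs; exactly reproducible from \code{seed}.}
#'   \item{linear_ramp}{\code{a*X + b*Y + c*Z + d} with
#'     \code{coef = c(a, b, c, d)} in physical coordinates.}
#' }
#'
#' @param kind one of \code{"sphere"}, \code{"two_spheres"}, \code{"torus"},
#'   \code{"smooth_noise"}, \code{"linear_ramp"}.
#' @param center,radius sphere/torus parameters (radius > 0).
#' @param centers,radii 2 x 3 matrix and length-2 vector for
#'   \code{two_spheres}.
#' @param major_radius,tube_radius torus radii (both > 0).
#' @param coef length-4 coefficients for \code{linear_ramp}.
#' @param seed integer; required for \code{smooth_noise}, fixes it exactly.
#' @param smooth_passes box-blur passes per axis for \code{smooth_noise}.
#' @return A \code{field_spec} object.
#' @export
field_spec <- function(kind = c("sphere", "two_spheres", "torus",
                                "smooth_noise", "linear_ramp"),
                       center = c(0, 0, 0), radius = 1,
                       centers = NULL, radii = NULL,
                       major_radius = 1, tube_radius = 0.4,
                       coef = c(1, 0, 0, 0), seed = NULL,
                       smooth_passes = 3L) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, center = as.numeric(center),
               radius = as.numeric(radius), centers = centers, radii = radii,
               major_radius = as.numeric(major_radius),
               tube_radius = as.numeric(tube_radius),
               coef = as.numeric(coef), seed = seed,
               smooth_passes = as.integer(smooth_passes))
  switch(kind,
    sphere = if (spec$radius <= 0) stop("sphere radius must be > 0"),
    two_spheres = {
      if (is.null(centers) || is.null(radii))
        stop("two_spheres needs `centers` (2 x 3) and `radii` (length 2)")
      spec$centers <- matrix(as.numeric(centers), ncol = 3L)
      spec$radii <- as.numeric(radii)
      if (nrow(spec$centers) != 2L || length(spec$radii) != 2L ||
          any(spec$radii <= 0))
        stop("two_spheres: need 2 centers and 2 positive radii")
    },
    torus = if (spec$major_radius <= 0 || spec$tube_radius <= 0)
      stop("torus radii must be > 0"),
    smooth_noise = if (is.null(seed) || !is.finite(seed))
      stop("smooth_noise requires an integer `seed`"),
    linear_ramp = if (length(spec$coef) != 4L)
      stop("linear_ramp needs coef = c(a, b, c, d)"))
  class(spec) <- "field_spec"
  spec
}

# one box-blur pass along each axis, edge-clamped
.box_blur3 <- function(a) {
  d <- dim(a)
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n))
  sx <- ix(d[1]); sy <- ix(d[2]); sz <- ix(d[3])
  a <- (a[sx$lo, , , drop = FALSE] + a + a[sx$hi, , , drop = FALSE]) / 3
  a <- (a[, sy$lo, , drop = FALSE] + a + a[, sy$hi, , drop = FALSE]) / 3
  (a[, , sz$lo, drop = FALSE] + a + a[, , sz$hi, drop = FALSE]) / 3
}

#' Generate a synthetic scalar volume
#'
#' Evaluates an analytic field at every grid point's physical coordinate.
#' These volumes exercise the reconstruction pipeline in place of acquired
#' skin-CT slice stacks.
#'
#' @param spec a [field_spec()].
#' @param dims integer length-3 grid size, each >= 2.
#' @param spacing,origin passed to [scalar_volume()].
#' @return A \code{scalar_volume}.
#' @examples
#' v <- generate_volume(field_spec("sphere", radius = 1),
#'                      dims = c(17, 17, 17),
#'                      spacing = c(0.2, 0.2, 0.2), origin = c(-1.6, -1.6, -1.6))
#' @export
generate_volume <- function(spec, dims, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "field_spec"))
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(dims) != 3L || any(dims < 2L))
    stop("`dims` must give at least 2 samples per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)

  X <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  Y <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  Z <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  gx <- array(X, dim = dims)
  gy <- array(rep(Y, each = dims[1]), dim = dims)
  gz <- array(rep(Z, each = dims[1] * dims[2]), dim = dims)

  sphere_field <- function(center, radius)
    radius - sqrt((gx - center[1])^2 + (gy - center[2])^2 + (gz - center[3])^2)

  samples <- switch(spec$kind,
    sphere = sphere_field(spec$center, spec$radius),
    two_spheres = pmax(sphere_field(spec$centers[1, ], spec$radii[1]),
                       sphere_field(spec$centers[2, ], spec$radii[2])),
    torus = {
      rx <- gx - spec$center[1]; ry <- gy - spec$center[2]
      rz <- gz - spec$center[3]
      spec$tube_radius -
        sqrt((sqrt(rx^2 + ry^2) - spec$major_radius)^2 + rz^2)
    },
    smooth_noise = withr::with_seed(as.integer(spec$seed), {
      a <- array(stats::rnorm(prod(dims)), dim = dims)
      for (i in seq_len(spec$smooth_passes)) a <- .box_blur3(a)
      a
    }),
    linear_ramp = spec$coef[1] * gx + spec$coef[2] * gy +
      spec$coef[3] * gz + spec$coef[4])

  scalar_volume(samples, spacing = spacing, origin = origin)
}

# ---- raw binary grid with JSON sidecar --------------------------------------

.raw_dtypes <- list(
  float64 = list(size = 8L, what = "double", signed = TRUE),
  float32 = list(size = 4L, what = "double", signed = TRUE),
  uint8   = list(size = 1L, what = "integer", signed = FALSE),
  uint16  = list(size = 2L, what = "integer", signed = FALSE),
  int16   = list(size = 2L, what = "integer", signed = TRUE))

#' Write a volume as a raw little-endian grid plus JSON sidecar
#'
#' The sidecar (\code{<path>.json}) records dims, dtype, spacing and origin so
#' the grid is self-describing; sample order is x-fastest (R array order).
#'
#' @param volume a \code{scalar_volume}.
#' @param path output path for the binary grid; sidecar written next to it.
#' @param dtype one of \code{"float64"}, \code{"float32"}, \code{"uint8"},
#'   \code{"uint16"}, \code{"int16"}.  Integer dtypes round.
#' @return \code{path}, invisibly.
#' @export
write_raw_volume <- function(volume, path, dtype = "float64") {
  stopifnot(inherits(volume, "scalar_volume"))
  dt <- .raw_dtypes[[dtype]]
  if (is.null(dt)) stop("unknown dtype: ", dtype)
  v <- as.vector(volume$samples)
  if (dt$what == "integer") v <- as.integer(round(v))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(v, con, size = dt$size, endian = "little")
  meta <- list(dims = dim(volume$samples), dtype = dtype,
               spacing = volume$spacing, origin = volume$origin,
               byte_order = "little", order = "x-fastest")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw binary grid written by [write_raw_volume()]
#'
#' @param path path to the binary grid; \code{<path>.json} must exist.
#' @return A \code{scalar_volume}.
#' @export
read_raw_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("I/O error: no such volume file: ", path)
  if (!file.exists(sidecar)) stop("I/O error: missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- .raw_dtypes[[meta$dtype]]
  if (is.null(dt)) stop("unknown dtype in sidecar: ", meta$dtype)
  n <- prod(meta$dims)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, what = dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = "little")
  if (length(v) != n) stop("I/O error: truncated volume file: ", path)
  scalar_volume(array(as.double(v), dim = meta$dims),
                spacing = meta$spacing, origin = meta$origin)
}
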