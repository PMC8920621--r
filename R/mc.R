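# Marching cubes: cell classification, edge intersection (linear or
# midpoint), central-difference gradient normals, and the full extraction
# sweep.  Geometry is computed in 0-based grid coordinates and scaled to
# physical coordinates (origin + index * spacing) at emission.

#' Build one marching-cubes cell
#'
#' A cell is one voxel: 8 corner samples in the package's fixed corner order
#' (see \code{R/tables-mc.R}: corner 0 at the cell base, corners 0-3 around
#' the bottom face counter-clockwise, 4-7 above them).
#'
#' @param values numeric length-8 corner samples D0..D7.
#' @param base integer length-3, 0-based grid index of corner 0.
#' @return An \code{mc_cell}.
#' @export
mc_cell <- function(values, base = c(0L, 0L, 0L)) {
  values <- as.numeric(values)
  if (length(values) != 8L || any(!is.finite(values)))
    stop("a cell needs exactly 8 finite corner samples")
  structure(list(values = values, base = as.numeric(base)), class = "mc_cell")
}

#' Extract one cell of a volume
#'
#' @param volume a \code{scalar_volume}.
#' @param base 0-based grid index of the cell's corner 0; every component
#'   must be at most \code{dim - 2}.
#' @return An \code{mc_cell}.
#' @export
volume_cell <- function(volume, base) {
  stopifnot(inherits(volume, "scalar_volume"))
  base <- as.integer(base)
  d <- dim(volume$samples)
  if (any(base < 0L) || any(base > d - 2L))
    stop("cell base index out of range")
  idx <- sweep(.mc_corner_offsets, 2L, base, `+`) + 1L
  mc_cell(volume$samples[idx], base = base)
}

#' Isosurface extraction settings
#'
#' @param isovalue finite scalar Q; the surface is \code{f = Q}.
#' @param mode \code{"linear"} places edge intersections by linear
#'   interpolation of the endpoint samples; \code{"midpoint"} (alias
#'   \code{"median"}) places them at the geometric middle of the crossed
#'   grid edge, independent of the sample values.
#' @param inside \code{">="} (default; ties count as inside) or \code{">"}.
#' @return An \code{isosurface_spec}.
#' @export
isosurface_spec <- function(isovalue, mode = c("linear", "midpoint", "median"),
                            inside = c(">=", ">")) {
  mode <- match.arg(mode)
  if (mode == "median") mode <- "midpoint"
  inside <- match.arg(inside)
  if (!is.finite(isovalue)) stop("isovalue must be finite")
  structure(list(isovalue = as.numeric(isovalue), mode = mode,
                 inside = inside),
            class = "isosurface_spec")
}

.inside_fun <- function(inside) {
  if (inside == ">=") function(v, q) v >= q else function(v, q) v > q
}

#' Trilinear sample inside a cell
#'
#' Blends the 8 corner samples with the standard trilinear weights: the
#' weight of each corner is the product, per axis, of the point's fractional
#' distance to the opposite cell face.  Equivalent to evaluating the cell's
#' trilinear polynomial (see [trilinear_coefficients()]).
#'
#' @param cell an \code{mc_cell}.
#' @param point length-3 grid coordinates; must lie within the cell's unit
#'   box \code{[base, base + 1]}.
#' @return The interpolated scalar.
#' @export
trilinear_sample <- function(cell, point) {
  stopifnot(inherits(cell, "mc_cell"))
  u <- as.numeric(point) - cell$base
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("point outside the cell")
  u <- pmin(pmax(u, 0), 1)
  off <- .mc_corner_offsets
  w <- (u[1]^off[, 1] * (1 - u[1])^(1L - off[, 1])) *
       (u[2]^off[, 2] * (1 - u[2])^(1L - off[, 2])) *
       (u[3]^off[, 3] * (1 - u[3])^(1L - off[, 3]))
  sum(w * cell$values)
}

#' Coefficients of a cell's trilinear expansion
#'
#' The in-cell field is the polynomial
#' \code{C(u,v,w) = b0 + b1 u + b2 v + b3 w + b4 uv + b5 vw + b6 wu + b7 uvw}
#' in local coordinates \code{u,v,w} in \code{[0,1]}; evaluating it at the 8
#' corners reproduces D0..D7 exactly.
#'
#' @param cell an \code{mc_cell}.
#' @return Named numeric vector \code{b0..b7}.
#' @export
trilinear_coefficients <- function(cell) {
  stopifnot(inherits(cell, "mc_cell"))
  d <- cell$values
  b0 <- d[1]
  b1 <- d[2] - d[1]
  b2 <- d[4] - d[1]
  b3 <- d[5] - d[1]
  b4 <- d[3] - d[2] - d[4] + d[1]
  b5 <- d[8] - d[4] - d[5] + d[1]
  b6 <- d[6] - d[2] - d[5] + d[1]
  b7 <- d[7] - d[3] - d[6] - d[8] + d[2] + d[4] + d[5] - d[1]
  stats::setNames(c(b0, b1, b2, b3, b4, b5, b6, b7), paste0("b", 0:7))
}

#' Evaluate a trilinear expansion
#' @param coef coefficients from [trilinear_coefficients()].
#' @param point length-3 local coordinates in \code{[0,1]^3}.
#' @return Scalar value of the polynomial.
#' @export
trilinear_evaluate <- function(coef, point) {
  u <- point[1]; v <- point[2]; w <- point[3]
  coef[["b0"]] + coef[["b1"]] * u + coef[["b2"]] * v + coef[["b3"]] * w +
    coef[["b4"]] * u * v + coef[["b5"]] * v * w + coef[["b6"]] * w * u +
    coef[["b7"]] * u * v * w
}

#' Marching-cubes case index of a cell
#'
#' Bit k (k = 0..7) is set iff corner k is inside per the spec's inside rule.
#' Index 0 (all outside) and 255 (all inside) mean the cell does not
#' intersect the isosurface.
#'
#' @param cell an \code{mc_cell}.
#' @param spec an [isosurface_spec()] (or a bare isovalue).
#' @return Integer in 0..255.
#' @export
cell_case_index <- function(cell, spec) {
  stopifnot(inherits(cell, "mc_cell"))
  if (!inherits(spec, "isosurface_spec")) spec <- isosurface_spec(spec)
  ins <- .inside_fun(spec$inside)(cell$values, spec$isovalue)
  as.integer(sum(2L^(0:7) * ins))
}

#' Triangles of a single cell
#'
#' Looks the cell's case up in the 256-entry table and returns the local edge
#' indices (0..11) of each triangle's vertices.
#'
#' @inheritParams cell_case_index
#' @return Integer matrix (n_triangles x 3) of edge indices.
#' @export
cell_triangle_edges <- function(cell, spec) {
  ci <- cell_case_index(cell, spec)
  row <- .mc_tri_table_ccw[ci + 1L, ]
  row <- row[row >= 0L]
  matrix(row, ncol = 3L, byrow = TRUE)
}

#' Linear edge intersection
#'
#' Standard marching-cubes vertex placement: the point where the linear
#' interpolant of the endpoint samples reaches the isovalue,
#' \code{p = p_a + t (p_b - p_a)} with \code{t = (Q - v_a) / (v_b - v_a)},
#' clamped to the edge.  If both endpoints equal Q the midpoint is returned.
#'
#' @param p_a,p_b endpoint coordinates (length-3).
#' @param v_a,v_b endpoint sample values; the edge must be crossed
#'   (\code{v_a - Q} and \code{v_b - Q} of opposite sign, or one zero).
#' @param isovalue the isovalue Q.
#' @return Length-3 intersection coordinates.
#' @export
edge_intersection_linear <- function(p_a, p_b, v_a, v_b, isovalue) {
  da <- v_a - isovalue; db <- v_b - isovalue
  if (da * db > 0)
    stop("contract violation: edge is not crossed by the isosurface")
  t <- if (v_b == v_a) 0.5 else (isovalue - v_a) / (v_b - v_a)
  t <- min(max(t, 0), 1)
  as.numeric(p_a) + t * (as.numeric(p_b) - as.numeric(p_a))
}

#' Midpoint ("median") edge intersection
#'
#' The accelerated vertex placement: the intersection is taken at the
#' geometric middle of the crossed grid edge, so an x-edge based at grid
#' point \code{(x, y, z)} yields \code{(x + 1/2, y, z)}, and likewise for y-
#' and z-edges.  The result does not depend on the sample values and needs
#' no division per vertex.
#'
#' @param p_a,p_b endpoints of an axis-aligned edge between adjacent grid
#'   vertices (integer coordinates differing by 1 on exactly one axis).
#' @return Length-3 midpoint coordinates.
#' @export
edge_intersection_midpoint <- function(p_a, p_b) {
  p_a <- as.numeric(p_a); p_b <- as.numeric(p_b)
  d <- p_b - p_a
  axis_moves <- abs(d) > 0
  if (any(p_a != round(p_a)) || any(p_b != round(p_b)) ||
      sum(axis_moves) != 1L || abs(d[axis_moves]) != 1)
    stop("contract violation: edge must join adjacent grid vertices along one axis")
  p_a + d / 2
}

#' Central-difference gradient at a grid index
#'
#' Interior indices use the symmetric difference
#' \code{(f(i+1) - f(i-1)) / (2 * spacing)} per axis; boundary indices fall
#' back to the one-sided difference (the symmetric form is undefined there).
#'
#' @param volume a \code{scalar_volume}.
#' @param index 0-based grid index (length-3 vector or n x 3 matrix).
#' @return Gradient components \code{c(qX, qY, qZ)} (or an n x 3 matrix), in
#'   sample units per physical unit.
#' @export
gradient_central_difference <- function(volume, index) {
  stopifnot(inherits(volume, "scalar_volume"))
  single <- is.null(dim(index))
  if (single) index <- matrix(index, ncol = 3L)
  g <- .volume_gradient(volume)
  i <- index + 1L
  out <- cbind(g$x[i], g$y[i], g$z[i])
  colnames(out) <- c("qX", "qY", "qZ")
  if (single) out[1L, ] else out
}

# full-grid gradient arrays (central differences, one-sided at the boundary)
.volume_gradient <- function(volume) {
  f <- volume$samples
  d <- dim(f)
  sp <- volume$spacing
  diff_axis <- function(axis) {
    n <- d[axis]
    hi <- c(seq_len(n - 1L) + 1L, n)     # i+1, clamped
    lo <- c(1L, seq_len(n - 1L))         # i-1, clamped
    denom <- rep(2, n); denom[1L] <- 1; denom[n] <- 1  # one-sided at ends
    take <- function(i) switch(axis,
      f[i, , , drop = FALSE], f[, i, , drop = FALSE], f[, , i, drop = FALSE])
    g <- (take(hi) - take(lo))
    scale <- array(0, dim = d)
    scale[] <- switch(axis,
      rep(denom, times = d[2] * d[3]),
      rep(rep(denom, each = d[1]), times = d[3]),
      rep(denom, each = d[1] * d[2]))
    g / (scale * sp[axis])
  }
  list(x = diff_axis(1L), y = diff_axis(2L), z = diff_axis(3L))
}

#' Extract a triangulated isosurface
#'
#' Marches every cell of the volume, classifies its corners against the
#' isovalue, emits triangles from the classic 256-configuration table, and
#' places each triangle vertex on its crossed grid edge either by linear
#' interpolation or at the edge midpoint, per \code{spec$mode}.  Per-vertex
#' normals interpolate the central-difference gradients of the edge's
#' endpoints at the vertex position and are oriented toward decreasing field
#' values; triangle winding is made counter-clockwise as seen from the
#' normal side.  Triangles that collapse to a segment or point (possible
#' when an isovalue hits grid samples exactly) are dropped and counted.
#'
#' @param volume a \code{scalar_volume} (no NaNs).
#' @param spec an [isosurface_spec()], or a bare isovalue (linear mode).
#' @return A \code{triangle_soup}: list with \code{vertices} and
#'   \code{normals} (3T x 3 matrices, consecutive triples form triangles, in
#'   physical coordinates), \code{n_triangles}, \code{n_crossed_edges},
#'   \code{degenerate_dropped}, \code{division_count} (per-vertex divisions
#'   performed by the interpolator: 0 in midpoint mode), \code{mode},
#'   \code{isovalue}.
#' @export
extract_isosurface <- function(volume, spec) {
  stopifnot(inherits(volume, "scalar_volume"))
  if (!inherits(spec, "isosurface_spec")) spec <- isosurface_spec(spec)
  f <- volume$samples
  if (anyNA(f)) stop("volume data error: NaN samples")
  d <- dim(f)
  q <- spec$isovalue

  inside <- .inside_fun(spec$inside)(f, q)
  cx <- seq_len(d[1] - 1L); cy <- seq_len(d[2] - 1L); cz <- seq_len(d[3] - 1L)
  corner <- function(k) {
    o <- .mc_corner_offsets[k, ]
    inside[cx + o[1], cy + o[2], cz + o[3]]
  }
  case_idx <- array(0L, dim = d - 1L)
  for (k in 1:8) case_idx <- case_idx + as.integer(2L^(k - 1L)) * corner(k)

  active <- which(case_idx > 0L & case_idx < 255L)
  empty <- function() structure(
    list(vertices = matrix(numeric(0), ncol = 3L),
         normals = matrix(numeric(0), ncol = 3L),
         n_triangles = 0L, n_crossed_edges = 0L, degenerate_dropped = 0L,
         division_count = 0L, mode = spec$mode, isovalue = q),
    class = "triangle_soup")
  if (length(active) == 0L) return(empty())

  ci <- case_idx[active]
  cell_base <- arrayInd(active, dim(case_idx)) - 1L  # 0-based

  # flatten the per-cell triangle lists, keeping per-cell entry order
  tt <- .mc_tri_table_ccw[ci + 1L, , drop = FALSE]
  ttT <- t(tt)
  keep <- ttT >= 0L
  edge_local <- ttT[keep]                       # local edge id per vertex slot
  cell_of <- rep(seq_along(active), each = 16L)[as.vector(keep)]

  base <- cell_base[cell_of, , drop = FALSE] +
    .mc_edge_base[edge_local + 1L, , drop = FALSE]
  axis <- .mc_edge_axis[edge_local + 1L]

  # one geometry computation per unique grid edge
  key <- ((base[, 3] * d[2] + base[, 2]) * d[1] + base[, 1]) * 3 + (axis - 1)
  ukey <- unique(key)
  uid <- match(key, ukey)
  first <- match(ukey, key)
  ub <- base[first, , drop = FALSE]
  ua <- axis[first]
  n_edges <- length(ukey)

  ia <- ub + 1L
  ib <- ia
  ib[cbind(seq_len(n_edges), ua)] <- ib[cbind(seq_len(n_edges), ua)] + 1L
  va <- f[ia]; vb <- f[ib]

  divisions <- 0L
  if (spec$mode == "linear") {
    t_par <- (q - va) / (vb - va)
    divisions <- n_edges
    t_par[!is.finite(t_par)] <- 0.5
    t_par <- pmin(pmax(t_par, 0), 1)
  } else {
    t_par <- rep(0.5, n_edges)
  }

  coord <- ub
  coord[cbind(seq_len(n_edges), ua)] <-
    coord[cbind(seq_len(n_edges), ua)] + t_par

  g <- .volume_gradient(volume)
  grad_at <- function(idx) cbind(g$x[idx], g$y[idx], g$z[idx])
  gv <- (1 - t_par) * grad_at(ia) + t_par * grad_at(ib)
  nrm <- -gv
  len <- sqrt(rowSums(nrm^2))
  ok <- len > 0
  nrm[ok, ] <- nrm[ok, , drop = FALSE] / len[ok]
  nrm[!ok, ] <- 0

  phys <- sweep(sweep(coord, 2L, volume$spacing, `*`), 2L,
                volume$origin, `+`)

  verts <- phys[uid, , drop = FALSE]
  norms <- nrm[uid, , drop = FALSE]

  # drop triangles with coincident vertices
  n_tri <- nrow(verts) %/% 3L
  i1 <- 3L * seq_len(n_tri) - 2L
  same <- function(a, b) rowSums((verts[a, , drop = FALSE] -
                                  verts[b, , drop = FALSE])^2) == 0
  degen <- same(i1, i1 + 1L) | same(i1, i1 + 2L) | same(i1 + 1L, i1 + 2L)
  if (any(degen)) {
    keep_rows <- rep(!degen, each = 3L)
    verts <- verts[keep_rows, , drop = FALSE]
    norms <- norms[keep_rows, , drop = FALSE]
    n_tri <- n_tri - sum(degen)
  }

  # vertices with a vanishing gradient inherit their triangle's geometric
  # normal (the emission table's winding is counter-clockwise from the
  # normal side, so the cross product already points the right way)
  zero_n <- rowSums(norms^2) == 0
  if (n_tri > 0L && any(zero_n)) {
    i1 <- 3L * seq_len(n_tri) - 2L
    e1 <- verts[i1 + 1L, , drop = FALSE] - verts[i1, , drop = FALSE]
    e2 <- verts[i1 + 2L, , drop = FALSE] - verts[i1, , drop = FALSE]
    gn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    glen <- sqrt(rowSums(gn^2))
    gunit <- gn
    gunit[glen > 0, ] <- gn[glen > 0, , drop = FALSE] / glen[glen > 0]
    tri_of_row <- rep(seq_len(n_tri), each = 3L)
    norms[zero_n, ] <- gunit[tri_of_row[zero_n], , drop = FALSE]
  }

  structure(
    list(vertices = verts, normals = norms, n_triangles = n_tri,
         n_crossed_edges = n_edges,
         degenerate_dropped = as.integer(sum(degen)),
         division_count = as.integer(divisions),
         mode = spec$mode, isovalue = q),
    class = "triangle_soup")
}

#' @export
print.triangle_soup <- function(x, ...) {
  cat(sprintf(
    "triangle_soup: %d triangles (%s mode, isovalue %g)\n",
    x$n_triangles, x$mode, x$isovalue))
  cat(sprintf("  crossed edges: %d, degenerate dropped: %d, divisions: %d\n",
              x$n_crossed_edges, x$degenerate_dropped, x$division_count))
  invisible(x)
}
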