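# Linear vs midpoint extraction comparison: the two modes share case
# classification and connectivity, so counts must agree; vertex placement
# (and hence smoothness/accuracy) and arithmetic cost differ.

#' Compare linear and midpoint extraction on one volume
#'
#' Runs both modes at the same isovalue and reports triangle/vertex counts
#' (identical by construction of the shared case table), wall-clock seconds
#' (informational only -- hardware-dependent), per-vertex interpolation
#' division counts, and the displacement statistics between matched
#' vertices.  Matched vertices are the two placements of the same crossed
#' grid edge, so each displacement is at most half that edge's length.
#'
#' @param volume a \code{scalar_volume}.
#' @param isovalue the isovalue Q.
#' @param inside inside rule, \code{">="} or \code{">"}.
#' @return An \code{mc_benchmark} list.
#' @export
benchmark_modes <- function(volume, isovalue, inside = ">=") {
  run <- function(mode) {
    spec <- isosurface_spec(isovalue, mode = mode, inside = inside)
    tm <- system.time(soup <- extract_isosurface(volume, spec))
    mesh <- deduplicate(soup)
    list(soup = soup, mesh = mesh, seconds = unname(tm["elapsed"]))
  }
  lin <- run("linear")
  mid <- run("midpoint")

  disp <- numeric(0)
  if (nrow(lin$soup$vertices) == nrow(mid$soup$vertices) &&
      nrow(lin$soup$vertices) > 0L) {
    # same connectivity => soup rows correspond edge-for-edge
    disp <- sqrt(rowSums((lin$soup$vertices - mid$soup$vertices)^2))
  }
  structure(list(
    isovalue = isovalue,
    triangle_count = c(linear = lin$soup$n_triangles,
                       midpoint = mid$soup$n_triangles),
    vertex_count = c(linear = nrow(lin$mesh$vertices),
                     midpoint = nrow(mid$mesh$vertices)),
    counts_equal = lin$soup$n_triangles == mid$soup$n_triangles &&
      nrow(lin$mesh$vertices) == nrow(mid$mesh$vertices),
    seconds = c(linear = lin$seconds, midpoint = mid$seconds),
    division_count = c(linear = lin$soup$division_count,
                       midpoint = mid$soup$division_count),
    max_displacement = if (length(disp)) max(disp) else 0,
    mean_displacement = if (length(disp)) mean(disp) else 0),
    class = "mc_benchmark")
}

#' @export
print.mc_benchmark <- function(x, ...) {
  cat(sprintf("mc_benchmark at isovalue %g\n", x$isovalue))
  cat(sprintf("  triangles: linear %d, midpoint %d; vertices: %d / %d\n",
              x$triangle_count["linear"], x$triangle_count["midpoint"],
              x$vertex_count["linear"], x$vertex_count["midpoint"]))
  cat(sprintf("  seconds (informational): linear %.4f, midpoint %.4f\n",
              x$seconds["linear"], x$seconds["midpoint"]))
  cat(sprintf("  interpolation divisions: linear %d, midpoint %d\n",
              x$division_count["linear"], x$division_count["midpoint"]))
  cat(sprintf("  vertex displacement: max %.6g, mean %.6g\n",
              x$max_displacement, x$mean_displacement))
  invisible(x)
}
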