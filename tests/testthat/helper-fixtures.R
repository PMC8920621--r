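# Shared fixtures.  Analytic fields use slightly offset centers so that no
# grid sample lands exactly on the isosurface: tie hits collapse linear-mode
# vertices onto grid corners (degenerate triangles, dropped), which is a
# separate, separately-tested code path.

# index-space sphere: dims 17^3, unit spacing, generic center
fix_sphere_index <- function() {
  generate_volume(field_spec("sphere", center = c(8.5, 8.3, 8.1),
                             radius = 4.7),
                  dims = c(17, 17, 17))
}

# physical-space sphere of radius 1 on an anisotropic-free 0.23 grid
fix_sphere_physical <- function(h = 0.23) {
  generate_volume(field_spec("sphere", center = c(0.013, 0.011, 0.007),
                             radius = 1),
                  dims = c(15, 15, 15), spacing = rep(h, 3L),
                  origin = rep(-7 * h, 3L))
}

fix_torus <- function() {
  generate_volume(field_spec("torus", center = c(0.0131, 0.0087, -0.0053),
                             major_radius = 1, tube_radius = 0.4),
                  dims = c(41, 41, 17), spacing = rep(0.075, 3L),
                  origin = c(-1.5, -1.5, -0.6))
}

fix_noise <- function(seed = 42L) {
  generate_volume(field_spec("smooth_noise", seed = seed),
                  dims = c(24, 24, 24))
}

# a random cell with reproducible values
random_cell <- function(seed) {
  withr::with_seed(seed, mc_cell(stats::rnorm(8), base = c(0, 0, 0)))
}

# a 2x2x2 volume realizing one corner sign pattern (inside = 1, outside = 0)
pattern_volume <- function(case_index) {
  a <- array(0, dim = c(2, 2, 2))
  off <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                  0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                ncol = 3L, byrow = TRUE)
  for (k in 0:7)
    if (bitwAnd(bitwShiftR(case_index, k), 1L) == 1L)
      a[off[k + 1L, 1] + 1L, off[k + 1L, 2] + 1L, off[k + 1L, 3] + 1L] <- 1
  scalar_volume(a)
}

# write a synthetic DICOM series; slice_values[[k]] is the [x, y] matrix of
# stored pixel values for slice k
write_dicom_series <- function(dir, slice_values, positions = NULL,
                               instance_numbers = NULL,
                               pixel_spacing = c(1, 1), slice_thickness = 1,
                               rescale_slope = 1, rescale_intercept = 0,
                               names_ = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(slice_values)
  if (is.null(positions)) positions <- (seq_len(n) - 1) * slice_thickness
  if (is.null(instance_numbers)) instance_numbers <- seq_len(n)
  if (is.null(names_)) names_ <- sprintf("slice%03d.dcm", seq_len(n))
  paths <- file.path(dir, names_)
  for (k in seq_len(n)) {
    write_dicom_slice(slice_values[[k]], paths[k],
                      instance_number = instance_numbers[k],
                      position_z = positions[k],
                      pixel_spacing = pixel_spacing,
                      slice_thickness = slice_thickness,
                      rescale_slope = rescale_slope,
                      rescale_intercept = rescale_intercept,
                      patient_name = "Doe^Jane")
  }
  paths
}

# expand an indexed mesh back into a soup (for dedup idempotence checks)
mesh_to_soup <- function(mesh) {
  idx <- as.vector(t(mesh$faces))
  structure(list(vertices = mesh$vertices[idx, , drop = FALSE],
                 normals = mesh$normals[idx, , drop = FALSE],
                 n_triangles = nrow(mesh$faces),
                 n_crossed_edges = NA_integer_,
                 degenerate_dropped = 0L, division_count = 0L,
                 mode = "expanded", isovalue = NA_real_),
            class = "triangle_soup")
}

# triangle area sum of a soup, computed independently of mesh_report
soup_area <- function(soup) {
  v <- soup$vertices
  n <- nrow(v) / 3L
  if (n == 0L) return(0)
  i1 <- 3L * seq_len(n) - 2L
  e1 <- v[i1 + 1L, , drop = FALSE] - v[i1, , drop = FALSE]
  e2 <- v[i1 + 2L, , drop = FALSE] - v[i1, , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# corner offsets in the package's documented order, restated independently
# for oracle computations in tests
test_corner_offsets <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                                0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                              ncol = 3L, byrow = TRUE)

test_edge_corners <- matrix(c(0, 1, 1, 2, 2, 3, 3, 0,
                              4, 5, 5, 6, 6, 7, 7, 4,
                              0, 4, 1, 5, 2, 6, 3, 7) + 1L,
                            ncol = 2L, byrow = TRUE)
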