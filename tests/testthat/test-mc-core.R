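test_that("trilinear sampling reproduces corners and blends exactly", {
  cell <- mc_cell(1:8)
  for (k in 1:8)
    expect_equal(trilinear_sample(cell, test_corner_offsets[k, ]), k)
  expect_equal(trilinear_sample(mc_cell(rep(5, 8)), c(0.5, 0.5, 0.5)), 5)
  expect_error(trilinear_sample(cell, c(1.5, 0, 0)), "outside")
})

test_that("trilinear sample equals the independent 8-term corner sum", {
  # oracle: weight of corner k is the product over axes of u or (1 - u)
  oracle <- function(values, p) {
    w <- apply(test_corner_offsets, 1L, function(o)
      prod(ifelse(o == 1, p, 1 - p)))
    sum(w * values)
  }
  withr::with_seed(101, {
    for (rep in 1:50) {
      cell <- mc_cell(stats::rnorm(8))
      p <- stats::runif(3)
      expect_equal(trilinear_sample(cell, p), oracle(cell$values, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("the trilinear polynomial expansion matches direct blending", {
  withr::with_seed(202, {
    for (rep in 1:50) {
      cell <- mc_cell(stats::rnorm(8))
      coef <- trilinear_coefficients(cell)
      # corners reproduce D0..D7 exactly
      for (k in 1:8)
        expect_equal(trilinear_evaluate(coef, test_corner_offsets[k, ]),
                     cell$values[k], tolerance = 1e-12)
      p <- stats::runif(3)
      expect_equal(trilinear_evaluate(coef, p), trilinear_sample(cell, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("case index sets one bit per inside corner", {
  expect_equal(cell_case_index(mc_cell(rep(-1, 8)), isosurface_spec(0)), 0L)
  expect_equal(cell_case_index(mc_cell(rep(1, 8)), isosurface_spec(0)), 255L)
  for (k in 0:7) {
    vals <- rep(-1, 8); vals[k + 1] <- 1
    idx <- cell_case_index(mc_cell(vals), isosurface_spec(0))
    expect_equal(idx, as.integer(2^k))
    expect_equal(nrow(cell_triangle_edges(mc_cell(vals), isosurface_spec(0))),
                 1L)  # single-bit cases emit exactly one triangle
  }
  # tie handling: >= counts the tied corner as inside, > does not
  tied <- mc_cell(c(0, rep(-1, 7)))
  expect_equal(cell_case_index(tied, isosurface_spec(0, inside = ">=")), 1L)
  expect_equal(cell_case_index(tied, isosurface_spec(0, inside = ">")), 0L)
})

test_that("case table emits triangles only on crossed edges", {
  spec <- isosurface_spec(0.5)
  n_tri <- integer(256L)
  for (ci in 0:255) {
    inside <- bitwAnd(bitwShiftR(ci, 0:7), 1L) == 1L
    cell <- mc_cell(ifelse(inside, 1, 0))
    expect_equal(cell_case_index(cell, spec), ci)
    tri <- cell_triangle_edges(cell, spec)
    n_tri[ci + 1L] <- nrow(tri)
    crossed <- which(inside[test_edge_corners[, 1]] !=
                       inside[test_edge_corners[, 2]]) - 1L
    expect_setequal(as.vector(tri), crossed)
  }
  expect_equal(n_tri[1], 0L)
  expect_equal(n_tri[256], 0L)
})

test_that("linear edge intersection follows its closed form", {
  expect_equal(edge_intersection_linear(c(0, 0, 0), c(1, 0, 0), 0, 10, 5),
               c(0.5, 0, 0))
  expect_equal(edge_intersection_linear(c(0, 0, 0), c(1, 0, 0), 0, 10, 2.5),
               c(0.25, 0, 0))
  # both endpoints at the isovalue: midpoint convention
  expect_equal(edge_intersection_linear(c(2, 0, 0), c(3, 0, 0), 5, 5, 5),
               c(2.5, 0, 0))
  expect_error(edge_intersection_linear(c(0, 0, 0), c(1, 0, 0), 1, 2, 5),
               "not crossed")
})

test_that("midpoint intersection is the exact edge middle on each axis", {
  expect_equal(edge_intersection_midpoint(c(1, 2, 3), c(2, 2, 3)),
               c(1.5, 2, 3))
  expect_equal(edge_intersection_midpoint(c(4, 1, 0), c(4, 2, 0)),
               c(4, 1.5, 0))
  expect_equal(edge_intersection_midpoint(c(0, 0, 0), c(0, 0, 1)),
               c(0, 0, 0.5))
  # orientation of the edge does not matter
  expect_equal(edge_intersection_midpoint(c(2, 2, 3), c(1, 2, 3)),
               c(1.5, 2, 3))
  expect_error(edge_intersection_midpoint(c(0, 0, 0), c(1, 1, 0)),
               "contract violation")
  expect_error(edge_intersection_midpoint(c(0, 0, 0), c(2, 0, 0)),
               "contract violation")
  # when Q is the endpoint mean, linear and midpoint placements coincide
  expect_equal(edge_intersection_linear(c(1, 2, 3), c(2, 2, 3), 2, 8, 5),
               edge_intersection_midpoint(c(1, 2, 3), c(2, 2, 3)))
})

test_that("central differences are exact on linear and quadratic fields", {
  v <- generate_volume(field_spec("linear_ramp", coef = c(2, -3, 0.5, 1)),
                       dims = c(6, 6, 6), spacing = c(0.5, 1, 2))
  idx <- as.matrix(expand.grid(0:5, 0:5, 0:5))
  g <- gradient_central_difference(v, idx)
  # one-sided boundary differences are also exact for linear fields
  expect_equal(unname(g),
               matrix(rep(c(2, -3, 0.5), each = nrow(idx)), ncol = 3L),
               tolerance = 1e-12)

  const <- scalar_volume(array(3, dim = c(4, 4, 4)))
  expect_equal(unname(gradient_central_difference(const, c(2, 2, 2))),
               c(0, 0, 0))

  # f = X^2: symmetric difference gives exactly 2x at interior indices
  quad <- scalar_volume(array(rep((0:5)^2, 36), dim = c(6, 6, 6)))
  for (x in 1:4)
    expect_equal(gradient_central_difference(quad, c(x, 2, 2))[["qX"]],
                 2 * x)
})

test_that("gradient respects anisotropic spacing", {
  v <- generate_volume(field_spec("linear_ramp", coef = c(1, 1, 1, 0)),
                       dims = c(5, 5, 5), spacing = c(1, 2, 4))
  g <- gradient_central_difference(v, c(2, 2, 2))
  expect_equal(unname(g), c(1, 1, 1), tolerance = 1e-12)
})

test_that("extraction handles empty and single-cell volumes", {
  const <- scalar_volume(array(1, dim = c(4, 4, 4)))
  empty <- extract_isosurface(const, isosurface_spec(5))
  expect_equal(empty$n_triangles, 0L)
  expect_equal(nrow(empty$vertices), 0L)

  # single cell, only corner 0 inside: 1 triangle on the 3 edges at corner 0
  vol <- pattern_volume(1L)
  soup <- extract_isosurface(vol, isosurface_spec(0.5))
  expect_equal(soup$n_triangles, 1L)
  expect_equal(soup$n_crossed_edges, 3L)
  expected <- rbind(c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5))
  got <- soup$vertices[order(soup$vertices[, 1]), ]
  expect_equal(got, expected[order(expected[, 1]), ])
})

test_that("both modes share topology; midpoint shifts vertices along edges", {
  for (vol in list(fix_sphere_index(), fix_torus(), fix_noise())) {
    q <- if (identical(dim(vol), c(24L, 24L, 24L))) 0.02 else 0
    lin <- extract_isosurface(vol, isosurface_spec(q, mode = "linear"))
    mid <- extract_isosurface(vol, isosurface_spec(q, mode = "midpoint"))
    expect_identical(lin$n_triangles, mid$n_triangles)
    expect_identical(lin$n_crossed_edges, mid$n_crossed_edges)
    ml <- deduplicate(lin); mm <- deduplicate(mid)
    expect_identical(nrow(ml$vertices), nrow(mm$vertices))
    expect_identical(ml$faces, mm$faces)  # connectivity is mode-independent
    # placements differ by at most half an edge along the crossed edge
    disp <- sqrt(rowSums((ml$vertices - mm$vertices)^2))
    expect_lte(max(disp), max(vol$spacing) / 2 + 1e-12)
  }
})

test_that("reconstruction counts match the frozen reference values", {
  # frozen from an independent classic marching-cubes implementation on the
  # same fields (re-derived live in the acceptance suite)
  ms <- mesh_report(deduplicate(extract_isosurface(fix_sphere_index(),
                                                   isosurface_spec(0))))
  expect_equal(ms$n_triangles, 828L)
  expect_equal(ms$n_vertices, 416L)
  mt <- mesh_report(deduplicate(extract_isosurface(fix_torus(),
                                                   isosurface_spec(0))))
  expect_equal(mt$n_triangles, 8272L)
  expect_equal(mt$n_vertices, 4136L)
})

test_that("closed surfaces come out watertight with the right topology", {
  ms <- mesh_report(deduplicate(extract_isosurface(fix_sphere_index(),
                                                   isosurface_spec(0))))
  expect_true(ms$watertight)
  expect_equal(ms$euler_characteristic, 2L)   # genus 0
  mt <- mesh_report(deduplicate(extract_isosurface(fix_torus(),
                                                   isosurface_spec(0))))
  expect_true(mt$watertight)
  expect_equal(mt$euler_characteristic, 0L)   # genus 1
})

test_that("sphere vertices lie within sqrt(3) h of the true surface", {
  h <- 0.23
  vol <- fix_sphere_physical(h)
  center <- c(0.013, 0.011, 0.007)
  for (mode in c("linear", "midpoint")) {
    m <- deduplicate(extract_isosurface(vol, isosurface_spec(0, mode = mode)))
    r <- sqrt(rowSums(sweep(m$vertices, 2L, center, `-`)^2))
    expect_lte(max(abs(r - 1)), sqrt(3) * h)
  }
  # linear placement is strictly more accurate on average at this resolution
  ml <- deduplicate(extract_isosurface(vol, isosurface_spec(0)))
  mm <- deduplicate(extract_isosurface(vol,
                                       isosurface_spec(0, mode = "midpoint")))
  err <- function(m) mean(abs(sqrt(rowSums(
    sweep(m$vertices, 2L, center, `-`)^2)) - 1))
  expect_lt(err(ml), err(mm))
})

test_that("normals point outward on a positive-inside sphere", {
  vol <- fix_sphere_physical()
  center <- c(0.013, 0.011, 0.007)
  for (mode in c("linear", "midpoint")) {
    m <- deduplicate(extract_isosurface(vol, isosurface_spec(0, mode = mode)))
    radial <- sweep(m$vertices, 2L, center, `-`)
    radial <- radial / sqrt(rowSums(radial^2))
    expect_true(all(rowSums(m$normals * radial) > 0))
    expect_equal(sqrt(rowSums(m$normals^2)), rep(1, nrow(m$normals)),
                 tolerance = 1e-9)
  }
})

test_that("triangle winding is counter-clockwise seen from the normal side", {
  m <- deduplicate(extract_isosurface(fix_sphere_physical(),
                                      isosurface_spec(0)))
  v <- m$vertices; f <- m$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  gn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  navg <- (m$normals[f[, 1], ] + m$normals[f[, 2], ] + m$normals[f[, 3], ])
  expect_true(all(rowSums(gn * navg) > 0))
})

test_that("isovalues that hit samples exactly drop collapsed triangles", {
  # grid-aligned sphere: samples sit exactly on the surface, so linear
  # placement lands on corners and some triangles collapse
  vol <- generate_volume(field_spec("sphere", center = c(8, 8, 8),
                                    radius = 5), dims = c(17, 17, 17))
  soup <- extract_isosurface(vol, isosurface_spec(0))
  expect_gt(soup$degenerate_dropped, 0L)
  m <- mesh_report(deduplicate(soup))
  expect_equal(m$boundary_edges, 0L)  # still a closed surface
})
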