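# Indexed triangle meshes: soup deduplication, topology/metric reports, and
# STL/OBJ/PLY round-trips.

#' Construct an indexed triangle mesh
#'
#' @param vertices V x 3 numeric matrix of physical coordinates; no
#'   duplicate rows up to the dedup tolerance used to build it.
#' @param faces F x 3 integer matrix of 1-based vertex indices; no face may
#'   repeat a vertex.
#' @param normals optional V x 3 matrix of unit (or zero) vertex normals.
#' @param degenerate_dropped count of degenerate triangles dropped on the way
#'   to this mesh.
#' @return A \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL,
                          degenerate_dropped = 0L) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("faces must not repeat a vertex index")
  }
  if (is.null(normals)) normals <- matrix(0, nrow(vertices), 3L)
  normals <- matrix(as.numeric(normals), ncol = 3L)
  if (nrow(normals) != nrow(vertices))
    stop("need one normal per vertex")
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 degenerate_dropped = as.integer(degenerate_dropped)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Merge coincident soup vertices into an indexed mesh
#'
#' Vertices within \code{tolerance} of each other (grid hash with the
#' first-seen point as representative) become one mesh vertex; their normals
#' are averaged and renormalized, and face winding is preserved.  Faces that
#' collapse onto fewer than 3 distinct vertices are dropped and counted.
#'
#' @param soup a \code{triangle_soup} from [extract_isosurface()].
#' @param tolerance merge radius; default \code{1e-9 *} the bounding-box
#'   diagonal (soup vertices from shared edges are bit-identical by
#'   construction, the tolerance only guards float noise).  Use 0 for exact
#'   matching.
#' @return A \code{triangle_mesh}.
#' @export
deduplicate <- function(soup, tolerance = NULL) {
  stopifnot(inherits(soup, "triangle_soup"))
  v <- soup$vertices
  if (nrow(v) == 0L)
    return(triangle_mesh(matrix(numeric(0), ncol = 3L),
                         matrix(integer(0), ncol = 3L),
                         degenerate_dropped = soup$degenerate_dropped))
  if (is.null(tolerance)) {
    bbox <- apply(v, 2L, range)
    tolerance <- 1e-9 * sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  key <- if (tolerance > 0) {
    g <- round(sweep(v, 2L, tolerance, `/`))
    paste(g[, 1], g[, 2], g[, 3], sep = "|")
  } else {
    paste(v[, 1], v[, 2], v[, 3], sep = "|")
  }
  ukey <- unique(key)
  id <- match(key, ukey)
  first <- match(ukey, key)

  verts <- v[first, , drop = FALSE]
  nsum <- rowsum(soup$normals, id, reorder = TRUE)
  len <- sqrt(rowSums(nsum^2))
  norms <- nsum
  norms[len > 0, ] <- nsum[len > 0, , drop = FALSE] / len[len > 0]

  faces <- matrix(id, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  dropped <- soup$degenerate_dropped + sum(degen)
  faces <- faces[!degen, , drop = FALSE]
  triangle_mesh(verts, faces, norms, degenerate_dropped = dropped)
}

# undirected edge keys of all faces (3F entries)
.mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  (as.numeric(lo) - 1) * nrow(mesh$vertices) + hi
}

#' Topology and size report for a mesh
#'
#' Reports the metrics used to compare reconstructions: triangle and vertex
#' counts, total surface area, unique undirected edge count, boundary-edge
#' count (edges on exactly one face), Euler characteristic V - E + F, and
#' whether the surface is watertight (no boundary edges; a closed genus-0
#' surface has V - E + F = 2).
#'
#' @param mesh a \code{triangle_mesh}.
#' @return A \code{mesh_report} list.
#' @export
mesh_report <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  area <- 0
  if (nrow(f) > 0L) {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- sum(sqrt(rowSums(cr^2))) / 2
  }
  keys <- .mesh_edge_keys(mesh)
  tab <- table(keys)
  n_edges <- length(tab)
  boundary <- sum(tab == 1L)
  structure(list(
    n_triangles = nrow(f),
    n_vertices = nrow(v),
    surface_area = area,
    n_edges = n_edges,
    boundary_edges = as.integer(boundary),
    euler_characteristic = nrow(v) - n_edges + nrow(f),
    watertight = boundary == 0L,
    degenerate_dropped = mesh$degenerate_dropped), class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf(
    paste0("mesh_report: V=%d E=%d F=%d (chi=%d)\n",
           "  area %.6g, boundary edges %d, watertight %s, ",
           "degenerate dropped %d\n"),
    x$n_vertices, x$n_edges, x$n_triangles, x$euler_characteristic,
    x$surface_area, x$boundary_edges, x$watertight, x$degenerate_dropped))
  invisible(x)
}

# ---- mesh file formats ------------------------------------------------------

.mesh_format_of <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "obj", "ply"))
    stop("unknown mesh format: .", ext)
  ext
}

#' Write a mesh to STL (binary), OBJ or PLY (ascii)
#'
#' @param mesh a \code{triangle_mesh}.
#' @param path output file; with \code{format = "auto"} the extension picks
#'   the format.
#' @param format \code{"auto"}, \code{"stl"}, \code{"obj"} or \code{"ply"}.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "obj", "ply")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- .mesh_format_of(path, match.arg(format))
  switch(format,
         stl = .write_stl(mesh, path),
         obj = .write_obj(mesh, path),
         ply = .write_ply(mesh, path))
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' STL stores a triangle soup, so reading deduplicates exactly-equal
#' vertices to recover connectivity; OBJ and PLY round-trip the indexed mesh
#' directly.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension) or explicit.
#' @return A \code{triangle_mesh}.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj", "ply")) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  format <- .mesh_format_of(path, match.arg(format))
  switch(format,
         stl = .read_stl(path),
         obj = .read_obj(path),
         ply = .read_ply(path))
}

.face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(matrix(numeric(0), ncol = 3L))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  cr[len > 0, ] <- cr[len > 0, , drop = FALSE] / len[len > 0]
  cr
}

.write_stl <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  header <- raw(80L)
  txt <- charToRaw("binary STL")
  header[seq_along(txt)] <- txt
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(nf, con, size = 4L, endian = "little")
  if (nf == 0L) return(invisible(path))
  fn <- .face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 float32 per facet: normal, v1, v2, v3; then attribute short
  block <- matrix(0, nrow = 12L, ncol = nf)
  block[1:3, ] <- t(fn)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  for (i in seq_len(nf)) {
    writeBin(block[, i], con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(nf) == 0L || nf == 0L)
    return(triangle_mesh(matrix(numeric(0), ncol = 3L),
                         matrix(integer(0), ncol = 3L)))
  verts <- matrix(0, nrow = 3L * nf, ncol = 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stop("I/O error: truncated STL: ", path)
    verts[3L * i - 2L, ] <- rec[4:6]
    verts[3L * i - 1L, ] <- rec[7:9]
    verts[3L * i, ] <- rec[10:12]
    readBin(con, "integer", 1L, size = 2L, endian = "little")
  }
  soup <- structure(list(vertices = verts,
                         normals = matrix(0, nrow(verts), 3L),
                         n_triangles = nf, n_crossed_edges = NA_integer_,
                         degenerate_dropped = 0L, division_count = 0L,
                         mode = "file", isovalue = NA_real_),
                    class = "triangle_soup")
  deduplicate(soup, tolerance = 0)
}

.fmt_num <- function(x) sprintf("%.17g", x)

.write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces; n <- mesh$normals
  has_n <- any(n != 0)
  lines <- character(0)
  if (nrow(v) > 0L)
    lines <- c(lines, sprintf("v %s %s %s", .fmt_num(v[, 1]),
                              .fmt_num(v[, 2]), .fmt_num(v[, 3])))
  if (has_n)
    lines <- c(lines, sprintf("vn %s %s %s", .fmt_num(n[, 1]),
                              .fmt_num(n[, 2]), .fmt_num(n[, 3])))
  if (nrow(f) > 0L) {
    lines <- c(lines, if (has_n)
      sprintf("f %d//%d %d//%d %d//%d", f[, 1], f[, 1], f[, 2], f[, 2],
              f[, 3], f[, 3])
      else sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  }
  writeLines(lines, path)
}

.read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  nl <- grep("^vn ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  parse3 <- function(x, skip) {
    if (length(x) == 0L) return(matrix(numeric(0), ncol = 3L))
    t(vapply(strsplit(sub(skip, "", x), "[ \t]+"),
             function(p) as.numeric(p[1:3]), numeric(3L)))
  }
  v <- parse3(vl, "^v +")
  n <- parse3(nl, "^vn +")
  f <- if (length(fl) == 0L) matrix(integer(0), ncol = 3L) else
    t(vapply(strsplit(sub("^f +", "", fl), "[ \t]+"), function(p)
      as.integer(sub("/.*$", "", p[1:3])), integer(3L)))
  triangle_mesh(v, f, if (nrow(n) == nrow(v)) n else NULL)
}

.write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces; n <- mesh$normals
  header <- c("ply", "format ascii 1.0",
              "comment dermamesh ascii PLY",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              "property double nx", "property double ny", "property double nz",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  body_v <- if (nrow(v) > 0L)
    sprintf("%s %s %s %s %s %s", .fmt_num(v[, 1]), .fmt_num(v[, 2]),
            .fmt_num(v[, 3]), .fmt_num(n[, 1]), .fmt_num(n[, 2]),
            .fmt_num(n[, 3])) else character(0)
  body_f <- if (nrow(f) > 0L)
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    else character(0)
  writeLines(c(header, body_v, body_f), path)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("I/O error: malformed PLY (no end_header): ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  vlines <- lines[end + seq_len(nv)]
  flines <- lines[end + nv + seq_len(nf)]
  vmat <- if (nv > 0L)
    t(vapply(strsplit(vlines, " "), function(p) as.numeric(p[1:6]),
             numeric(6L))) else matrix(numeric(0), ncol = 6L)
  fmat <- if (nf > 0L)
    t(vapply(strsplit(flines, " "), function(p) as.integer(p[2:4]) + 1L,
             integer(3L))) else matrix(integer(0), ncol = 3L)
  triangle_mesh(vmat[, 1:3, drop = FALSE], fmat,
                if (nv > 0L) vmat[, 4:6, drop = FALSE] else NULL)
}
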