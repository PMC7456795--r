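# Triangle-mesh container, procedural sphere/ellipsoid meshes used by the
# phantom and the tests, and STL/PLY file I/O (ASCII and binary read, binary
# write). Vertices are world millimetres; faces are 1-based inside R and
# 0-based on disk, following the file-format conventions.

#' Triangle mesh in world millimetres
#'
#' Validates indices and removes degenerate (zero-area) faces at construction.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `trimesh` with fields `vertices` and `faces`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- .as_points_matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  # drop zero-area faces (repeated vertices or collinear corners)
  a <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  area2 <- rowSums(.cross_rows(a, b)^2)
  keep <- area2 > 1e-20
  if (!any(keep)) stop("mesh must have at least one non-degenerate face")
  structure(list(vertices = vertices, faces = faces[keep, , drop = FALSE]),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Unit icosphere mesh
#'
#' Icosahedron refined by `subdivisions` rounds of edge bisection, vertices
#' projected back to the unit sphere (so vertices are exact, faces are chords).
#'
#' @param subdivisions nonnegative integer; face count is `20 * 4^subdivisions`.
#' @param radius sphere radius in mm.
#' @param center numeric length-3 center (mm).
#' @return A [trimesh()].
#' @export
icosphere <- function(subdivisions = 4L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    vlist <- vector("list", nrow(f) * 3L)
    vn <- 0L
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      vn <<- vn + 1L
      vlist[[vn]] <<- m
      idx <- nv + vn
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      i1 <- f[k, 1L]; i2 <- f[k, 2L]; i3 <- f[k, 3L]
      a <- midpoint(i1, i2); b <- midpoint(i2, i3); cc <- midpoint(i3, i1)
      newf[(k - 1L) * 4L + 1L, ] <- c(i1, a, cc)
      newf[(k - 1L) * 4L + 2L, ] <- c(i2, b, a)
      newf[(k - 1L) * 4L + 3L, ] <- c(i3, cc, b)
      newf[(k - 1L) * 4L + 4L, ] <- c(a, b, cc)
    }
    v <- rbind(v, do.call(rbind, vlist[seq_len(vn)]))
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2L, .as_point(center, "center"), "+")
  trimesh(v, f)
}

#' Ellipsoid mesh
#'
#' Axis-aligned ellipsoid obtained by anisotropic scaling of a unit icosphere.
#'
#' @param semi_axes numeric length-3 semi-axes (mm).
#' @param subdivisions icosphere refinement level.
#' @param center numeric length-3 center (mm).
#' @return A [trimesh()].
#' @export
ellipsoid_mesh <- function(semi_axes, subdivisions = 4L, center = c(0, 0, 0)) {
  semi_axes <- .as_point(semi_axes, "semi_axes")
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  m <- icosphere(subdivisions)
  v <- sweep(m$vertices, 2L, semi_axes, "*")
  v <- sweep(v, 2L, .as_point(center, "center"), "+")
  trimesh(v, m$faces)
}

# ---- STL ----------------------------------------------------------------

# STL stores one vertex triple per facet; weld identical float32 vertices back
# into a shared-vertex mesh on read.
.weld_vertices <- function(tri_vertices, tol = 0) {
  key <- paste(tri_vertices[, 1L], tri_vertices[, 2L], tri_vertices[, 3L])
  idx <- match(key, unique(key))
  verts <- tri_vertices[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Read a triangle mesh from STL or PLY
#'
#' Format is chosen from the file extension. Both ASCII and binary variants
#' are accepted; STL facet soup is welded into shared vertices.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return A [trimesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .read_stl(path),
         ply = .read_ply(path),
         stop("unsupported mesh format: ", ext, " (expected stl or ply)"))
}

#' Write a triangle mesh to STL or PLY (binary)
#'
#' @param mesh a [trimesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .write_stl(mesh, path),
         ply = .write_ply(mesh, path),
         stop("unsupported mesh format: ", ext, " (expected stl or ply)"))
  invisible(path)
}

.read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("STL file truncated or unreadable: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    if (length(raw) < 50L * ntri) stop("binary STL truncated: ", path)
    m <- matrix(raw, nrow = 50L)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                    n = 12L * ntri, endian = "little")
    vm <- matrix(vals, ncol = 12L, byrow = TRUE) # normal + 3 vertices per facet
    tri <- matrix(t(vm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
    w <- .weld_vertices(tri)
    return(trimesh(w$vertices, w$faces))
  }
  # ASCII
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
    if (length(p) != 4L) stop("malformed ASCII STL vertex line: ", path)
    as.numeric(p[2:4])
  }))
  if (any(!is.finite(nums))) stop("malformed ASCII STL (non-numeric vertex): ", path)
  w <- .weld_vertices(nums)
  trimesh(w$vertices, w$faces)
}

.write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  ntri <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "seegaccuracy binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  nrm <- .cross_rows(a, b)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-30)
  block <- cbind(nrm, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE])
  zero <- as.raw(c(0, 0))
  for (i in seq_len(ntri)) {
    writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
    writeBin(zero, con)
  }
  invisible(path)
}

# ---- PLY ----------------------------------------------------------------

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines terminated by \n
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("malformed PLY (unterminated header): ", path)
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (read_hline() != "ply") stop("malformed PLY (missing magic): ", path)
  fmt <- NULL; nvert <- NA_integer_; nface <- NA_integer_
  vprops <- character(0); in_vertex <- FALSE
  repeat {
    ln <- read_hline()
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element") {
      in_vertex <- identical(tok[2L], "vertex")
      if (tok[2L] == "vertex") nvert <- as.integer(tok[3L])
      if (tok[2L] == "face") nface <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex && tok[2L] != "list") {
      vprops <- c(vprops, tok[3L])
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt) || is.na(nvert) || is.na(nface))
    stop("malformed PLY header: ", path)
  ixyz <- match(c("x", "y", "z"), vprops)
  if (any(is.na(ixyz))) stop("malformed PLY (missing x/y/z properties): ", path)
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nvert + nface) stop("PLY truncated: ", path)
    vt <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nvert)]), "\\s+"),
                                function(p) as.numeric(p[ixyz])))
    fl <- strsplit(trimws(txt[nvert + seq_len(nface)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(p) {
      cnt <- as.integer(p[1L])
      if (is.na(cnt) || cnt != 3L) stop("PLY faces must be triangles: ", path)
      as.integer(p[2:4]) + 1L
    }))
    return(trimesh(vt, faces))
  }
  if (fmt != "binary_little_endian")
    stop("unsupported PLY format: ", fmt)
  if (length(vprops) != 3L || !identical(vprops, c("x", "y", "z")))
    stop("binary PLY reader supports exactly x,y,z float vertex properties")
  vals <- readBin(con, "numeric", n = 3L * nvert, size = 4L, endian = "little")
  if (length(vals) < 3L * nvert) stop("PLY truncated: ", path)
  vt <- matrix(vals, ncol = 3L, byrow = TRUE)
  faces <- matrix(0L, nface, 3L)
  for (i in seq_len(nface)) {
    cnt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
    if (length(cnt) == 0L) stop("PLY truncated: ", path)
    if (cnt != 3L) stop("PLY faces must be triangles: ", path)
    idx <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    if (length(idx) < 3L) stop("PLY truncated: ", path)
    faces[i, ] <- idx + 1L
  }
  trimesh(vt, faces)
}

.write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment seegaccuracy mesh",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
  }
  invisible(path)
}
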