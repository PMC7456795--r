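# Core exact 3D geometry: distances, angles, total-least-squares line fits and
# line/mesh intersection. Everything downstream (entry/target errors, angles,
# pairing) reduces to these primitives. All coordinates are world millimetres.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (!is.finite(n) || n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# row-wise cross product of two n x 3 matrices
.cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stop(sprintf("%s must be 3 finite coordinates (mm)", what))
  p
}

.as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.matrix(points)) {
    storage.mode(points) <- "double"
    if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  } else {
    points <- matrix(as.numeric(points), ncol = 3L, byrow = TRUE)
  }
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

#' Construct a 3D line (origin + unit direction)
#'
#' @param origin numeric length-3, a point on the line (world mm).
#' @param direction numeric length-3; normalized internally, must be nonzero.
#' @return An object of class `line3` with fields `origin` and `direction`
#'   (unit norm).
#' @examples
#' line3(c(0, 0, 0), c(0, 0, 2))
#' @export
line3 <- function(origin, direction) {
  origin <- .as_point(origin, "origin")
  direction <- .as_point(direction, "direction")
  structure(list(origin = origin, direction = .unit(direction)),
            class = "line3")
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> origin (%.3f, %.3f, %.3f) mm, direction (%.6f, %.6f, %.6f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Euclidean distance between two points
#'
#' The straight-line distance between two 3D points in millimetres; the
#' "Euclidean error" between corresponding planned and implanted points.
#'
#' @param p,q numeric length-3 points (world mm).
#' @return Nonnegative distance in mm.
#' @examples
#' euclidean_distance(c(1, 2, 2), c(0, 0, 0)) # 3
#' @export
euclidean_distance <- function(p, q) {
  .vnorm(.as_point(p, "p") - .as_point(q, "q"))
}

#' Lateral shift: shortest distance from a point to a line
#'
#' The perpendicular (lateral) deviation of a point from an infinite 3D line,
#' the standard "lateral shift" accuracy metric for entry and target points.
#'
#' @param p numeric length-3 point (world mm).
#' @param line a [line3()].
#' @return Nonnegative perpendicular distance in mm; 0 iff `p` lies on the line.
#' @examples
#' lateral_shift(c(3, 4, 0), line3(c(0, 0, 0), c(0, 0, 1))) # 5
#' @export
lateral_shift <- function(p, line) {
  stopifnot(inherits(line, "line3"))
  d <- .as_point(p, "p") - line$origin
  .vnorm(d - sum(d * line$direction) * line$direction)
}

#' Angle between two directions, in degrees
#'
#' Oriented angle in `[0, 180]` degrees: directions are not folded to
#' `[0, 90]`. Trajectory directions are fixed proximal-to-distal (entry toward
#' target) throughout the package, so angles between planned and implanted
#' trajectories are small by construction.
#'
#' @param u,v numeric length-3 direction vectors (normalized internally).
#' @return Angle in degrees in `[0, 180]`.
#' @examples
#' angle_between(c(0, 0, 1), c(0, 1, 1)) # 45
#' @export
angle_between <- function(u, v) {
  u <- .unit(.as_point(u, "u"))
  v <- .unit(.as_point(v, "v"))
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Signed axial coordinate of a point along a line
#'
#' Scalar projection of `p - origin` onto the line direction: positive in the
#' direction of travel. Differences of axial coordinates along a planned
#' trajectory give the signed insertion-depth error.
#'
#' @param p numeric length-3 point (world mm).
#' @param line a [line3()].
#' @return Signed distance in mm.
#' @export
axial_coordinate <- function(p, line) {
  stopifnot(inherits(line, "line3"))
  sum((.as_point(p, "p") - line$origin) * line$direction)
}

#' Total-least-squares 3D line fit
#'
#' Fits the line through the centroid of the points whose direction minimizes
#' the sum of squared perpendicular distances (orthogonal regression via the
#' principal axis of the centered cloud). The direction is oriented so that it
#' has a nonnegative dot product with (last point - first point), i.e. it
#' points from the first listed point toward the last.
#'
#' @param points n x 3 matrix (or coercible) of points, n >= `min_points`.
#' @param min_points minimum number of points required (default 2).
#' @return A [line3()] through the centroid.
#' @details Errors with `"degenerate fit"` when fewer than `min_points` points
#'   are supplied or all points coincide, and with `"ambiguous direction"` when
#'   the two largest singular values of the centered cloud differ by less than
#'   1e-9 relative (isotropic cloud, no principal axis).
#' @examples
#' fit_line_tls(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)))
#' @export
fit_line_tls <- function(points, min_points = 2L) {
  points <- .as_points_matrix(points)
  n <- nrow(points)
  if (n < max(2L, min_points)) stop("degenerate fit: fewer than min_points points")
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  s <- svd(x, nu = 0L)
  scale <- max(abs(x))
  if (s$d[1L] <= 1e-12 * max(1, scale)) stop("degenerate fit: all points coincident")
  if ((s$d[1L] - s$d[2L]) / s$d[1L] < 1e-9)
    stop("ambiguous direction: tied principal directions")
  dir <- s$v[, 1L]
  span <- points[n, ] - points[1L, ]
  if (sum(dir * span) < 0) dir <- -dir
  line3(ctr, dir)
}

#' Intersections of an infinite line with a triangle mesh
#'
#' Vectorized Moller-Trumbore ray-triangle tests applied to every face, with
#' the parameter unconstrained (the full infinite line, not a half ray). Hits
#' on shared edges/vertices are deduplicated within 1e-6 mm.
#'
#' @param line a [line3()].
#' @param mesh a [trimesh()].
#' @param bary_eps tolerance on barycentric bounds (default 1e-9).
#' @param dedup_tol merge distance for duplicate hits in mm (default 1e-6).
#' @return A list with `points` (k x 3 matrix) and `axial` (length-k numeric,
#'   signed axial coordinates), sorted by axial coordinate ascending. `k = 0`
#'   (empty matrix) when the line misses the mesh.
#' @export
line_mesh_intersections <- function(line, mesh, bary_eps = 1e-9,
                                    dedup_tol = 1e-6) {
  stopifnot(inherits(line, "line3"), inherits(mesh, "trimesh"))
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - v0
  e2 <- v[f[, 3L], , drop = FALSE] - v0
  nf <- nrow(f)
  dirm <- matrix(line$direction, nf, 3L, byrow = TRUE)
  h <- .cross_rows(dirm, e2)
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  t_hit <- numeric(0)
  if (any(ok)) {
    fa <- 1 / a[ok]
    sm <- -sweep(v0[ok, , drop = FALSE], 2L, line$origin, "-") # origin - v0
    u <- fa * rowSums(sm * h[ok, , drop = FALSE])
    q <- .cross_rows(sm, e1[ok, , drop = FALSE])
    vv <- fa * rowSums(dirm[ok, , drop = FALSE] * q)
    hit <- u >= -bary_eps & vv >= -bary_eps & (u + vv) <= 1 + bary_eps
    tt <- fa * rowSums(e2[ok, , drop = FALSE] * q)
    t_hit <- sort(tt[hit])
  }
  if (length(t_hit) == 0L)
    return(list(points = matrix(numeric(0), 0L, 3L), axial = numeric(0)))
  keep <- c(TRUE, diff(t_hit) > dedup_tol)
  t_hit <- t_hit[keep]
  pts <- matrix(line$origin, length(t_hit), 3L, byrow = TRUE) +
    outer(t_hit, line$direction)
  # axial coordinate equals the line parameter because direction is unit-norm
  list(points = pts, axial = t_hit)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (normalized) `axis`.
#'
#' @param axis numeric length-3, rotation axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- .unit(.as_point(axis, "axis"))
  th <- angle_deg * pi / 180
  kx <- rbind(c(0, -k[3L], k[2L]),
              c(k[3L], 0, -k[1L]),
              c(-k[2L], k[1L], 0))
  diag(3L) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Apply a rigid transform to points, lines or meshes
#'
#' `x_world = R x + t`. Used for expressing whole scenes in a different world
#' frame; all accuracy metrics are invariant under a common rigid transform of
#' every input.
#'
#' @param x an n x 3 matrix of points, a numeric length-3 point, a [line3()]
#'   or a [trimesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric length-3 (mm).
#' @return The transformed object, same class as `x`.
#' @export
rigid_transform <- function(x, rotation = diag(3L), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- .as_point(translation, "translation")
  if (inherits(x, "line3")) {
    return(line3(drop(rotation %*% x$origin) + translation,
                 drop(rotation %*% x$direction)))
  }
  if (inherits(x, "trimesh")) {
    v <- x$vertices %*% t(rotation)
    v <- sweep(v, 2L, translation, "+")
    return(trimesh(v, x$faces))
  }
  if (is.matrix(x)) {
    return(sweep(x %*% t(rotation), 2L, translation, "+"))
  }
  drop(rotation %*% .as_point(x)) + translation
}
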