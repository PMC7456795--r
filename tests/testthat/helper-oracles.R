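# Independent oracles used to validate the package's geometry and statistics
# by a second route. These deliberately avoid the package's own algorithms:
# distances are minimized numerically, line fits are found by grid search over
# the unit sphere, sphere intersections come from the quadratic closed form.

# shortest point-line distance by 1D numerical minimization along the line
oracle_lateral_shift <- function(p, origin, direction, span = 500) {
  direction <- direction / sqrt(sum(direction^2))
  f <- function(t) sqrt(sum((origin + t * direction - p)^2))
  stats::optimize(f, c(-span, span), tol = 1e-10)$objective
}

# dense-sampling variant: brute-force minimum over regularly spaced samples
# bracketing the projection (slow; used on a few instances)
oracle_lateral_shift_dense <- function(p, origin, direction, n = 1e6) {
  direction <- direction / sqrt(sum(direction^2))
  tproj <- sum((p - origin) * direction)
  ts <- seq(tproj - 2, tproj + 2, length.out = n)
  pts <- outer(ts, direction)
  pts <- sweep(pts, 2L, origin, "+")
  sqrt(min(rowSums(sweep(pts, 2L, p)^2)))
}

# total-least-squares direction by grid search over the unit hemisphere
# followed by Nelder-Mead refinement in spherical coordinates
oracle_tls_direction <- function(points, coarse_deg = 10) {
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  rss <- function(ang) {
    d <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    sum(x^2) - sum((x %*% d)^2)
  }
  th <- seq(0, pi, by = coarse_deg * pi / 180)
  ph <- seq(0, 2 * pi, by = coarse_deg * pi / 180)
  grid <- as.matrix(expand.grid(th, ph))
  vals <- apply(grid, 1L, rss)
  best <- grid[which.min(vals), ]
  opt <- stats::optim(best, rss, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  ang <- opt$par
  d <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
  d / sqrt(sum(d^2))
}

# analytic line-sphere intersection parameters (centered sphere)
oracle_sphere_hits <- function(origin, direction, radius) {
  direction <- direction / sqrt(sum(direction^2))
  b <- 2 * sum(origin * direction)
  cc <- sum(origin^2) - radius^2
  disc <- b^2 - 4 * cc
  if (disc < 0) return(numeric(0))
  sort(c((-b - sqrt(disc)) / 2, (-b + sqrt(disc)) / 2))
}

# random rigid transform (rotation + translation), deterministic in the seed
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  r <- rotation_about_axis(ax, runif(1, 0, 360))
  list(rotation = r, translation = rnorm(3, 0, 50))
}

# minimum distance of points (n x 3) to a 3D segment, for masking the bolt
# entry sites when checking scalp-surface accuracy
.dist_to_segment <- function(p, p0, p1) {
  v <- p1 - p0
  t <- pmin(1, pmax(0, ((p - matrix(p0, nrow(p), 3, byrow = TRUE)) %*% v) /
                      sum(v^2)))
  sqrt(rowSums((p - (matrix(p0, nrow(p), 3, byrow = TRUE) + t %*% t(v)))^2))
}

# a straight phantom-free electrode along a known axis, for unit tests:
# bolt head at `head`, pivot `bolt_len` along `dir`, contacts from the deepest
# point spaced back toward the pivot
make_straight_electrode <- function(id = "e1", head = c(0, 0, 100),
                                    dir = c(0, 0, -1), bolt_len = 10,
                                    first_contact_depth = 60, n = 8,
                                    spacing = 5) {
  dir <- dir / sqrt(sum(dir^2))
  pivot <- head + bolt_len * dir
  deepest <- head + first_contact_depth * dir
  contacts <- t(vapply(seq_len(n) - 1L,
                       function(j) deepest - j * spacing * dir,
                       numeric(3)))
  implanted_electrode(id, head, pivot, contacts)
}
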