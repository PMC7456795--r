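# Synthetic implantation phantom: cohorts of planned/implanted electrodes
# with controlled, ground-truthed deviations, ellipsoidal scalp/skull meshes
# and optional rasterized CT volumes. This module is the package's entire
# test substrate; no clinical data are shipped or required.
#
# The head is an axis-aligned ellipsoid (scalp), with an outer-skull surface
# a fixed offset beneath it and an inner-skull surface a (sector-dependent)
# bone thickness beneath that. A designated lateral "temporal" sector has
# thinner bone and labels the electrodes implanted through it, so stratified
# summaries are exercisable synthetically.

#' Phantom cohort specification
#'
#' Defaults describe a plausible adult-head implantation: ellipsoidal scalp
#' with semi-axes 95/80/70 mm, outer skull 5 mm beneath the scalp, 8.5 mm
#' nominal bone thickness thinned by `temporal_thin_factor` in the temporal
#' sector, 10-contact electrodes at 5 mm spacing behind 25 mm guide bolts,
#' and deviation magnitudes of the order reported for frameless SEEG
#' implantations (entry shift ~1.3 mm, tilt ~2.2 degrees, depth error ~2 mm,
#' contact segmentation noise ~0.38 mm, no bending).
#'
#' When `vary_magnitudes` is `TRUE` each electrode draws its own deviation
#' magnitude uniformly in `[0.25, 1.75]` times the stated value (mean equal to
#' the stated value), giving a spread of true deviations for recovery
#' regressions; when `FALSE` every electrode receives exactly the stated
#' magnitude (random direction), for per-electrode injection/recovery checks.
#'
#' @param seed integer random seed; the cohort is a pure function of the spec.
#' @param n_cases number of synthetic patients.
#' @param electrodes_per_case electrodes implanted per case.
#' @param scalp_semi_axes numeric length-3 ellipsoid semi-axes (mm).
#' @param skull_offset scalp-to-outer-skull depth (mm).
#' @param skull_thickness nominal outer-to-inner skull bone span (mm).
#' @param temporal_thin_factor multiplier on `skull_thickness` inside the
#'   temporal sector (0..1).
#' @param contact_spacing center-to-center contact spacing (mm).
#' @param n_contacts contacts per electrode.
#' @param bolt_length pivot-to-bolt-head length (mm).
#' @param entry_shift_mm tangential planned-to-implanted entry shift (mm).
#' @param tilt_deg tilt of the implanted axis about the entry point (degrees).
#' @param depth_mm signed insertion-depth error along the implanted axis (mm).
#' @param bend_deg_per_10mm quadratic bending beyond the pivot (degrees of
#'   direction change per 10 mm of insertion; 0 = rigid).
#' @param contact_noise_mm isotropic Gaussian noise SD on each contact
#'   centroid (mm).
#' @param vary_magnitudes see Details above.
#' @param planned_depth_range min/max planned entry-to-target depth (mm).
#' @param mesh_subdivisions icosphere refinement of the head meshes.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, n_cases = 15L, electrodes_per_case = 10L,
                         scalp_semi_axes = c(95, 80, 70), skull_offset = 5,
                         skull_thickness = 8.5, temporal_thin_factor = 0.45,
                         contact_spacing = 5, n_contacts = 10L,
                         bolt_length = 25, entry_shift_mm = 1.3,
                         tilt_deg = 2.2, depth_mm = 2, bend_deg_per_10mm = 0,
                         contact_noise_mm = 0.38, vary_magnitudes = TRUE,
                         planned_depth_range = c(30, 45),
                         mesh_subdivisions = 4L) {
  spec <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
               electrodes_per_case = as.integer(electrodes_per_case),
               scalp_semi_axes = as.numeric(scalp_semi_axes),
               skull_offset = skull_offset,
               skull_thickness = skull_thickness,
               temporal_thin_factor = temporal_thin_factor,
               contact_spacing = contact_spacing,
               n_contacts = as.integer(n_contacts),
               bolt_length = bolt_length,
               entry_shift_mm = entry_shift_mm, tilt_deg = tilt_deg,
               depth_mm = depth_mm, bend_deg_per_10mm = bend_deg_per_10mm,
               contact_noise_mm = contact_noise_mm,
               vary_magnitudes = isTRUE(vary_magnitudes),
               planned_depth_range = as.numeric(planned_depth_range),
               mesh_subdivisions = as.integer(mesh_subdivisions))
  stopifnot(length(spec$scalp_semi_axes) == 3L, all(spec$scalp_semi_axes > 0),
            spec$skull_offset > 0, spec$skull_thickness > 0,
            spec$temporal_thin_factor > 0, spec$temporal_thin_factor <= 1,
            spec$n_contacts >= 2L, spec$contact_spacing > 0,
            spec$bolt_length > 0,
            spec$entry_shift_mm >= 0, spec$tilt_deg >= 0,
            spec$bend_deg_per_10mm >= 0, spec$contact_noise_mm >= 0,
            spec$n_cases >= 1L, spec$electrodes_per_case >= 1L)
  class(spec) <- "phantom_spec"
  spec
}

# temporal sector: a lateral band on both sides of the head. `u` is the unit
# sphere parameter of an ellipsoid surface point (p = semi_axes * u).
.is_temporal <- function(u) abs(u[3L]) < 0.30 && abs(u[1L]) > 0.65

.smoothstep <- function(x, a, b) {
  t <- pmin(1, pmax(0, (x - a) / (b - a)))
  t * t * (3 - 2 * t)
}

# smooth sector weight in [0,1]; 1 deep inside the temporal sector
.temporal_weight <- function(u) {
  .smoothstep(abs(u[, 1L, drop = TRUE]), 0.55, 0.70) *
    (1 - .smoothstep(abs(u[, 3L, drop = TRUE]), 0.25, 0.40))
}

# local bone thickness (mm) for unit-sphere parameters u (n x 3)
.bone_thickness <- function(spec, u) {
  w <- .temporal_weight(u)
  spec$skull_thickness * (1 - (1 - spec$temporal_thin_factor) * w)
}

.phantom_meshes <- function(spec) {
  a <- spec$scalp_semi_axes
  b <- a - spec$skull_offset
  if (any(b <= spec$skull_thickness))
    stop("scalp semi-axes too small for the skull offset and thickness")
  scalp <- ellipsoid_mesh(a, spec$mesh_subdivisions)
  outer <- ellipsoid_mesh(b, spec$mesh_subdivisions)
  # inner skull: outer surface pushed inward radially by the local thickness
  unit <- icosphere(spec$mesh_subdivisions)
  t_mm <- .bone_thickness(spec, unit$vertices)
  vo <- outer$vertices
  rhat <- vo / sqrt(rowSums(vo^2))
  inner <- trimesh(vo - rhat * t_mm, outer$faces)
  list(scalp = entry_surface(scalp, "scalp", "phantom"),
       outer_skull = entry_surface(outer, "outer_skull", "phantom"),
       inner_skull = entry_surface(inner, "inner_skull", "phantom"))
}

# first intersection of the ray p + t*dir (t > 0) with the ellipsoid
# |diag(1/axes) x| = 1, or NA when it misses
.ellipsoid_entry_t <- function(p, dir, axes) {
  ps <- p / axes; ds <- dir / axes
  a <- sum(ds^2); b <- 2 * sum(ps * ds); cc <- sum(ps^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(NA_real_)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  if (t1 > 0) t1 else if (t2 > 0) t2 else NA_real_
}

# a unit vector perpendicular to v, at uniform random azimuth
.random_perp <- function(v) {
  v <- .unit(v)
  ref <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross(v, ref))
  e2 <- .cross(v, e1)
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * e1 + sin(phi) * e2
}

.draw_magnitude <- function(value, vary) {
  if (value == 0) return(0)
  if (vary) value * stats::runif(1, 0.25, 1.75) else value
}

#' Generate a synthetic implantation cohort with ground truth
#'
#' Planned entry points are sampled on the scalp ellipsoid with minimum
#' pairwise spacing `4 * max(entry_shift_mm, 2)` mm within each case; planned
#' targets lie interior along inward-pointing directions. Each implanted
#' electrode is derived from its plan by applying, in order: a tangential
#' entry shift (the whole trajectory is translated), a tilt about the shifted
#' entry point, a signed depth error along the tilted axis, optional quadratic
#' bending beyond the pivot, then placing the pivot at the outer-skull
#' crossing, the bolt head `bolt_length` proximal of it, and the contacts at
#' `contact_spacing` with isotropic noise. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `phantom_cohort`: `spec`, `plans` (named list of
#'   [planned_trajectory()]), `implants` (named list of
#'   [implanted_electrode()]), `meshes` (list of [entry_surface()]: `scalp`,
#'   `outer_skull`, `inner_skull`), `truth` (data frame of per-electrode
#'   ground truth), `case_of` (named character vector electrode -> case).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  meshes <- .phantom_meshes(spec)
  a <- spec$scalp_semi_axes
  b <- a - spec$skull_offset
  min_spacing <- 4 * max(spec$entry_shift_mm, 2)
  plans <- list(); implants <- list(); truth <- list()
  case_of <- character(0)
  for (ci in seq_len(spec$n_cases)) {
    case_id <- sprintf("C%02d", ci)
    eps_case <- matrix(numeric(0), 0L, 3L)
    us_case <- matrix(numeric(0), 0L, 3L)
    tries <- 0L
    while (nrow(eps_case) < spec$electrodes_per_case) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("infeasible spacing: cannot place ", spec$electrodes_per_case,
             " entry points at ", min_spacing, " mm minimum spacing")
      u <- .unit(stats::rnorm(3L))
      if (u[3L] < -0.4) next # keep entries off the skull base
      ep <- a * u
      if (nrow(eps_case) > 0L &&
          min(sqrt(rowSums(sweep(eps_case, 2L, ep)^2))) < min_spacing) next
      eps_case <- rbind(eps_case, ep)
      us_case <- rbind(us_case, u)
    }
    for (ei in seq_len(spec$electrodes_per_case)) {
      eid <- sprintf("%sE%02d", case_id, ei)
      ep <- eps_case[ei, ]
      u <- us_case[ei, ]
      # planned trajectory: inward, roughly toward a jittered deep target
      aim <- stats::rnorm(3L, 0, 8)
      dir <- .unit(aim - ep)
      depth <- stats::runif(1, spec$planned_depth_range[1L],
                            spec$planned_depth_range[2L])
      tp <- ep + depth * dir
      grp <- if (.is_temporal(u)) "temporal" else "non-temporal"
      plan <- planned_trajectory(eid, ep, tp, grp)

      # 1) tangential entry shift: translate the whole trajectory
      shift_mag <- .draw_magnitude(spec$entry_shift_mm, spec$vary_magnitudes)
      normal <- .unit(2 * ep / a^2) # ellipsoid outward normal at ep
      tangent <- .unit(.random_perp(normal))
      shift <- shift_mag * tangent
      ep_i <- ep + shift
      tp_i <- tp + shift
      # 2) tilt about the (shifted) entry point
      tilt <- .draw_magnitude(spec$tilt_deg, spec$vary_magnitudes)
      dir_i <- dir
      if (tilt > 0) {
        axis <- .random_perp(dir)
        rot <- rotation_about_axis(axis, tilt)
        dir_i <- .unit(drop(rot %*% dir))
        tp_i <- ep_i + drop(rot %*% (tp_i - ep_i))
      }
      # 3) signed depth error along the tilted axis
      dmag <- .draw_magnitude(abs(spec$depth_mm), spec$vary_magnitudes)
      depth_err <- if (spec$depth_mm == 0) 0 else if (spec$vary_magnitudes)
        sample(c(-1, 1), 1L) * dmag else sign(spec$depth_mm) * dmag
      tp_i <- tp_i + depth_err * dir_i

      # bolt geometry on the implanted axis
      t_piv <- .ellipsoid_entry_t(ep_i - 60 * dir_i, dir_i, b)
      if (is.na(t_piv))
        stop("implanted trajectory misses the outer skull (electrode ", eid, ")")
      pivot <- (ep_i - 60 * dir_i) + t_piv * dir_i
      bolt_head <- pivot - spec$bolt_length * dir_i

      # contacts, deepest first, with optional bending beyond the pivot
      idx <- seq_len(spec$n_contacts) - 1L
      centers <- matrix(tp_i, spec$n_contacts, 3L, byrow = TRUE) -
        outer(idx * spec$contact_spacing, dir_i)
      bent <- spec$bend_deg_per_10mm > 0
      if (bent) {
        cbend <- tan(spec$bend_deg_per_10mm * pi / 180) / 20
        wdir <- .random_perp(dir_i)
        s <- as.vector((centers - matrix(pivot, spec$n_contacts, 3L,
                                         byrow = TRUE)) %*% dir_i)
        lat <- cbend * pmax(s, 0)^2
        centers <- centers + outer(lat, wdir)
      }
      tp_final <- centers[1L, ]
      if (spec$contact_noise_mm > 0)
        centers <- centers + matrix(stats::rnorm(3L * spec$n_contacts, 0,
                                                 spec$contact_noise_mm),
                                    ncol = 3L)
      elec <- implanted_electrode(eid, bolt_head, pivot, centers)

      pl <- planned_line(plan)
      truth[[eid]] <- data.frame(
        electrode_id = eid, case = case_id, group_label = grp,
        true_angle_deg = tilt,
        true_entry_offset_mm = shift_mag,
        true_target_offset_mm = lateral_shift(tp_final, pl),
        true_depth_error_mm = axial_coordinate(tp_final, pl) -
          axial_coordinate(tp, pl),
        true_depth_injected_mm = depth_err,
        true_bent = bent,
        stringsAsFactors = FALSE)
      plans[[eid]] <- plan
      implants[[eid]] <- elec
      case_of[eid] <- case_id
    }
  }
  structure(list(spec = spec, plans = plans, implants = implants,
                 meshes = meshes,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 case_of = case_of),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases x %d electrodes (seed %d)\n",
              x$spec$n_cases, x$spec$electrodes_per_case, x$spec$seed))
  invisible(x)
}

#' Analytic ground-truth accuracy metrics of a phantom cohort
#'
#' Metrics computed directly from the generative construction — final
#' implanted target point and axis versus the planned line — with no meshes
#' and no line fitting. Used as the recovery oracle for the full pipeline.
#'
#' @param cohort a [generate_cohort()] result.
#' @return Data frame with `electrode_id`, `LT`, `ET`, `depth_error`, `angle`,
#'   `entry_offset`, `group_label`.
#' @export
true_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  tr <- cohort$truth
  data.frame(electrode_id = tr$electrode_id,
             LT = tr$true_target_offset_mm,
             ET = sqrt(tr$true_target_offset_mm^2 + tr$true_depth_error_mm^2),
             depth_error = tr$true_depth_error_mm,
             angle = tr$true_angle_deg,
             entry_offset = tr$true_entry_offset_mm,
             group_label = tr$group_label,
             stringsAsFactors = FALSE)
}

# documented intensity bands of the rasterized phantom CT; contacts are the
# brightest band and painted last so that thresholding above the bolt band
# isolates exactly the contact spheres (contacts proximal of the pivot lie
# inside the bolt lumen)
.ct_bands <- c(background = 0, brain = 20, scalp = 100, skull = 400,
               bolt = 2000, contact = 3000)

#' Intensity bands of the rasterized phantom CT
#'
#' @return Named numeric vector: `background`, `brain`, `scalp`, `skull`,
#'   `contact`, `bolt` intensities.
#' @export
ct_intensity_bands <- function() .ct_bands

#' Rasterize a phantom cohort into a CT-like volume
#'
#' Paints the head shells (scalp between the scalp and outer-skull
#' ellipsoids, bone between the outer skull and the sector-thinned inner
#' skull, a soft-tissue interior), bolt cylinders (radius 1.5 mm) and contact
#' spheres (radius 1 mm) with the distinct intensity bands of
#' [ct_intensity_bands()]. The affine maps voxel centers to world mm. A cohort
#' with zero electrodes yields a background-only volume of the same field of
#' view.
#'
#' @param cohort a [generate_cohort()] result.
#' @param voxel_mm isotropic voxel size (default 0.75).
#' @param margin_mm padding around the scene bounding box (default 12).
#' @return A [ctvolume()].
#' @export
rasterize_ct <- function(cohort, voxel_mm = 0.75, margin_mm = 12) {
  stopifnot(inherits(cohort, "phantom_cohort"), voxel_mm > 0)
  spec <- cohort$spec
  a <- spec$scalp_semi_axes
  pts <- rbind(cbind(c(-a[1], a[1]), c(-a[2], a[2]), c(-a[3], a[3])))
  for (e in cohort$implants) pts <- rbind(pts, e$bolt_head, e$pivot)
  lo <- apply(pts, 2L, min) - margin_mm
  hi <- apply(pts, 2L, max) + margin_mm
  d <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_mm)) + 1L)
  affine <- diag(c(rep(voxel_mm, 3L), 1))
  affine[1:3, 4L] <- lo
  vol <- array(.ct_bands[["background"]], d)
  if (length(cohort$implants) == 0L)
    return(ctvolume(vol, affine))

  xs <- lo[1L] + (seq_len(d[1L]) - 1) * voxel_mm
  ys <- lo[2L] + (seq_len(d[2L]) - 1) * voxel_mm
  zs <- lo[3L] + (seq_len(d[3L]) - 1) * voxel_mm
  b <- a - spec$skull_offset
  # normalized ellipsoid coordinates via separable outer sums
  sq_outer <- function(axes) {
    qx <- (xs / axes[1L])^2; qy <- (ys / axes[2L])^2; qz <- (zs / axes[3L])^2
    outer(outer(qx, qy, "+"), qz, "+")
  }
  qs <- sq_outer(a)
  qo <- sq_outer(b)
  vol[qs <= 1] <- .ct_bands[["scalp"]]
  inside_outer <- qo <= 1
  # radial depth below the outer skull: r * (1/sqrt(qo) - 1)
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  idx <- which(inside_outer)
  if (length(idx) > 0L) {
    rr <- sqrt(r2[idx])
    depth_in <- rr * (1 / sqrt(qo[idx]) - 1)
    ijk <- arrayInd(idx, d)
    p <- cbind(xs[ijk[, 1L]], ys[ijk[, 2L]], zs[ijk[, 3L]])
    pn <- p / pmax(rr, 1e-9)
    t_mm <- .bone_thickness(spec, pn)
    vol[idx] <- ifelse(depth_in <= t_mm, .ct_bands[["skull"]],
                       .ct_bands[["brain"]])
  }
  rm(qs, qo, r2)

  paint_ball <- function(center, radius, value) {
    loi <- floor((center - radius - lo) / voxel_mm) + 1
    hii <- ceiling((center + radius - lo) / voxel_mm) + 1
    if (any(loi < 1) || any(hii > d))
      stop("electrode geometry extends outside the rasterized field of view")
    ii <- loi[1L]:hii[1L]; jj <- loi[2L]:hii[2L]; kk <- loi[3L]:hii[3L]
    dx2 <- (xs[ii] - center[1L])^2
    dy2 <- (ys[jj] - center[2L])^2
    dz2 <- (zs[kk] - center[3L])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    sub <- vol[ii, jj, kk, drop = FALSE]
    sub[m] <- value
    vol[ii, jj, kk] <<- sub
  }
  paint_cylinder <- function(p0, p1, radius, value) {
    lo3 <- pmin(p0, p1) - radius; hi3 <- pmax(p0, p1) + radius
    loi <- floor((lo3 - lo) / voxel_mm) + 1
    hii <- ceiling((hi3 - lo) / voxel_mm) + 1
    if (any(loi < 1) || any(hii > d))
      stop("electrode geometry extends outside the rasterized field of view")
    ii <- loi[1L]:hii[1L]; jj <- loi[2L]:hii[2L]; kk <- loi[3L]:hii[3L]
    g <- expand.grid(x = xs[ii], y = ys[jj], z = zs[kk])
    p <- as.matrix(g)
    v <- p1 - p0
    len2 <- sum(v^2)
    tpar <- pmin(1, pmax(0, (sweep(p, 2L, p0) %*% v) / len2))
    near <- matrix(p0, nrow(p), 3L, byrow = TRUE) + tpar %*% t(v)
    m <- array(rowSums((p - near)^2) <= radius^2,
               c(length(ii), length(jj), length(kk)))
    sub <- vol[ii, jj, kk, drop = FALSE]
    sub[m] <- value
    vol[ii, jj, kk] <- sub
    vol
  }
  for (e in cohort$implants) {
    vol <- paint_cylinder(e$bolt_head, e$pivot, 1.5, .ct_bands[["bolt"]])
    for (ri in seq_len(nrow(e$contacts)))
      paint_ball(e$contacts[ri, ], 1, .ct_bands[["contact"]])
  }
  ctvolume(vol, affine)
}
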