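test_that("zero-perturbation cohorts are exact and deterministic", {
  sp <- phantom_spec(seed = 101, n_cases = 2, electrodes_per_case = 5,
                     entry_shift_mm = 0, tilt_deg = 0, depth_mm = 0,
                     contact_noise_mm = 0)
  co <- generate_cohort(sp)
  expect_identical(length(co$plans), 10L)
  tm <- true_metrics(co)
  expect_true(all(abs(tm$LT) < 1e-9))
  expect_true(all(abs(tm$depth_error) < 1e-9))
  expect_true(all(tm$angle == 0))
  # implanted lines coincide with plans
  for (id in names(co$plans)) {
    pl <- planned_line(co$plans[[id]])
    e <- co$implants[[id]]
    expect_lt(lateral_shift(e$pivot, pl), 1e-9)
    expect_lt(lateral_shift(e$bolt_head, pl), 1e-9)
    expect_lt(max(apply(e$contacts, 1, lateral_shift, line = pl)), 1e-9)
  }
  co2 <- generate_cohort(sp)
  expect_identical(co, co2)
})

test_that("fixed-magnitude perturbations are injected exactly", {
  # tilt only
  sp <- phantom_spec(seed = 5, n_cases = 1, electrodes_per_case = 8,
                     entry_shift_mm = 0, tilt_deg = 2, depth_mm = 0,
                     contact_noise_mm = 0, vary_magnitudes = FALSE)
  co <- generate_cohort(sp)
  for (id in names(co$plans)) {
    pl <- planned_line(co$plans[[id]])
    a1 <- bolt_axis_trajectory(co$implants[[id]])
    expect_equal(angle_between(pl$direction, a1$line$direction), 2,
                 tolerance = 1e-9)
  }
  # depth only: +3 mm along the (untilted) axis
  spd <- phantom_spec(seed = 6, n_cases = 1, electrodes_per_case = 8,
                      entry_shift_mm = 0, tilt_deg = 0, depth_mm = 3,
                      contact_noise_mm = 0, vary_magnitudes = FALSE)
  cod <- generate_cohort(spd)
  tmd <- true_metrics(cod)
  expect_equal(tmd$depth_error, rep(3, 8), tolerance = 1e-9)
  expect_true(all(abs(tmd$LT) < 1e-9))
  # tangential shift only: LT equals the perpendicular component of the shift
  sps <- phantom_spec(seed = 7, n_cases = 1, electrodes_per_case = 8,
                      entry_shift_mm = 2, tilt_deg = 0, depth_mm = 0,
                      contact_noise_mm = 0, vary_magnitudes = FALSE)
  cos_ <- generate_cohort(sps)
  tms <- true_metrics(cos_)
  expect_true(all(tms$LT <= 2 + 1e-9))
  expect_true(all(tms$LT > 0.5)) # tangent is near-perpendicular to the axis
  expect_equal(tms$entry_offset, rep(2, 8))
})

test_that("the temporal sector thins the skull and labels electrodes", {
  sp <- phantom_spec(seed = 42, n_cases = 6, electrodes_per_case = 8,
                     entry_shift_mm = 0, tilt_deg = 0, depth_mm = 0,
                     contact_noise_mm = 0)
  co <- generate_cohort(sp)
  expect_true(all(co$truth$group_label %in% c("temporal", "non-temporal")))
  expect_gt(sum(co$truth$group_label == "temporal"), 0)
  pr <- pair_electrodes(co$plans, co$implants, surface = co$meshes$scalp)
  rec <- cohort_accuracy(pr, co$plans, co$implants, methods = "A1",
                         surfaces = co$meshes$scalp,
                         outer_skull = co$meshes$outer_skull,
                         inner_skull = co$meshes$inner_skull)
  st <- tapply(rec$skull_thickness, rec$group_label, mean)
  expect_lt(st[["temporal"]], st[["non-temporal"]])
  expect_lt(st[["temporal"]], 6.5)
  expect_gt(st[["non-temporal"]], 6.5)
})

test_that("electrode geometry respects spacing, bolt length and contact count", {
  sp <- phantom_spec(seed = 9, n_cases = 1, electrodes_per_case = 6,
                     contact_noise_mm = 0)
  co <- generate_cohort(sp)
  for (e in co$implants) {
    expect_identical(nrow(e$contacts), 10L)
    expect_equal(euclidean_distance(e$bolt_head, e$pivot), 25,
                 tolerance = 1e-9)
    gaps <- sqrt(rowSums(diff(e$contacts)^2))
    expect_equal(gaps, rep(5, 9), tolerance = 1e-9)
    # pivot lies on the outer-skull ellipsoid
    b <- sp$scalp_semi_axes - sp$skull_offset
    expect_equal(sum((e$pivot / b)^2), 1, tolerance = 1e-9)
  }
  # minimum planned entry spacing is honored within each case
  eps <- t(vapply(co$plans, function(p) p$planned_ep, numeric(3)))
  dmin <- min(dist(eps))
  expect_gte(dmin, 4 * max(sp$entry_shift_mm, 2) - 1e-9)
})

test_that("bending displaces deep contacts laterally and is flagged", {
  sp <- phantom_spec(seed = 10, n_cases = 1, electrodes_per_case = 4,
                     entry_shift_mm = 0, tilt_deg = 0, depth_mm = 0,
                     contact_noise_mm = 0, bend_deg_per_10mm = 3)
  co <- generate_cohort(sp)
  expect_true(all(co$truth$true_bent))
  for (id in names(co$plans)) {
    e <- co$implants[[id]]
    a1 <- bolt_axis_trajectory(e)
    # deepest contact deviates more from the bolt axis than the shallowest
    expect_gt(lateral_shift(e$contacts[1, ], a1$line),
              lateral_shift(e$contacts[10, ], a1$line))
  }
  # with bending on, the A4-vs-A1 angle is nonzero
  pr <- pair_electrodes(co$plans, co$implants, surface = co$meshes$scalp)
  rec <- cohort_accuracy(pr, co$plans, co$implants, methods = c("A1", "A4"),
                         surfaces = co$meshes$scalp)
  expect_gt(mean(rec$angle[rec$method == "A4"]),
            mean(rec$angle[rec$method == "A1"]))
})

test_that("rasterized CT supports contact centroid and scalp surface recovery", {
  sp <- phantom_spec(seed = 77, n_cases = 1, electrodes_per_case = 3,
                     contact_noise_mm = 0)
  co <- generate_cohort(sp)
  bands <- ct_intensity_bands()
  # contact recovery at the native voxel size; contacts are the brightest
  # band, so thresholding above the bolt band isolates the contact spheres
  vox <- 0.75
  vol <- rasterize_ct(co, voxel_mm = vox)
  blobs <- threshold_components(vol,
                                (bands[["contact"]] + bands[["bolt"]]) / 2)
  truth_contacts <- do.call(rbind, lapply(co$implants, function(e) e$contacts))
  expect_identical(nrow(blobs), nrow(truth_contacts))
  got <- as.matrix(blobs[, c("cx_mm", "cy_mm", "cz_mm")])
  errs <- vapply(seq_len(nrow(truth_contacts)), function(i)
    min(sqrt(rowSums(sweep(got, 2, truth_contacts[i, ])^2))), numeric(1))
  expect_lt(max(errs), vox / 2)
  # scalp isosurface on a coarser raster: radial error below one voxel
  # diagonal everywhere away from the bolt shafts piercing the scalp
  vox2 <- 1.5
  vol2 <- rasterize_ct(co, voxel_mm = vox2)
  m <- extract_isosurface(vol2, bands[["scalp"]] / 2)
  dmin <- Reduce(pmin, lapply(co$implants, function(e)
    .dist_to_segment(m$vertices, e$bolt_head, e$pivot)))
  keep <- dmin > 4
  expect_gt(mean(keep), 0.95)
  q <- sqrt(rowSums(sweep(m$vertices, 2, sp$scalp_semi_axes, "/")^2))
  rr <- sqrt(rowSums(m$vertices^2))
  err_mm <- abs(q - 1) * rr / q # normalized radial error in mm
  expect_lt(max(err_mm[keep]), vox2 * sqrt(3))
  # closed surface: radial lines cross it an even number of times
  h <- line_mesh_intersections(line3(c(1, 2, 0), c(0.2, 0.1, 1)), m)
  expect_identical(length(h$axial) %% 2L, 0L)
  # empty cohort rasterizes to background only
  co0 <- co; co0$implants <- list()
  vol0 <- rasterize_ct(co0, voxel_mm = 2.5)
  expect_identical(unique(as.vector(vol0$data)), bands[["background"]])
})
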