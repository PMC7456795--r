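# pairing and per-electrode accuracy records

make_two_electrode_scene <- function() {
  scalp <- entry_surface(icosphere(3, 92), "scalp", "phantom")
  plans <- list(
    planned_trajectory("L", c(0, 0, 92), c(0, 0, 50)),
    planned_trajectory("R", c(40, 0, 82.8), c(30, 0, 45)))
  names(plans) <- c("L", "R")
  elecs <- list(
    L = make_straight_electrode("L", head = c(1, 0, 105), dir = c(0, 0, -1)),
    R = make_straight_electrode("R", head = c(46, 1, 101),
                                dir = c(30, 0, 45) - c(40, 0, 82.8)))
  list(scalp = scalp, plans = plans, elecs = elecs)
}

test_that("pairing recovers correspondence regardless of list order", {
  sc <- make_two_electrode_scene()
  pr <- pair_electrodes(sc$plans, sc$elecs, surface = sc$scalp)
  expect_identical(pr$pairs$planned_id, pr$pairs$implanted_id)
  pr2 <- pair_electrodes(rev(sc$plans), rev(sc$elecs), surface = sc$scalp)
  expect_identical(pr$pairs, pr2$pairs)
  expect_length(pr$unmatched_planned, 0)
})

test_that("angle breaks distance ties in pairing", {
  # two implanted candidates equidistant from one planned entry point,
  # angles 1 and 8 degrees: the 1-degree candidate must win
  plan <- list(P = planned_trajectory("P", c(0, 0, 100), c(0, 0, 50)))
  mk <- function(id, angle, offset) {
    d <- drop(rotation_about_axis(c(1, 0, 0), angle) %*% c(0, 0, -1))
    head <- c(offset, 0, 110)
    pivot <- head + 15 * d
    contacts <- t(vapply(0:3, function(j) head + (55 - 5 * j) * d, numeric(3)))
    implanted_electrode(id, head, pivot, contacts)
  }
  elecs <- list(good = mk("good", 1, 0.3), bad = mk("bad", 8, -0.3))
  pr <- pair_electrodes(plan, elecs, max_ep_distance = 15,
                        distance_tie_tol = 1)
  expect_identical(pr$pairs$implanted_id, "good")
  expect_identical(pr$unmatched_implanted, "bad")
})

test_that("unmatched electrodes are reported, not fatal", {
  sc <- make_two_electrode_scene()
  plans3 <- c(sc$plans,
              list(X = planned_trajectory("X", c(-40, 0, 82.8), c(-30, 0, 45))))
  pr <- pair_electrodes(plans3, sc$elecs, surface = sc$scalp)
  expect_identical(nrow(pr$pairs), 2L)
  expect_identical(pr$unmatched_planned, "X")
  expect_length(pr$unmatched_implanted, 0)
})

test_that("an identically implanted electrode has all-zero metrics", {
  scalp <- entry_surface(icosphere(4, 92), "scalp", "phantom")
  plan <- planned_trajectory("P", c(0, 0, 92), c(0, 0, 50))
  e <- make_straight_electrode("P", head = c(0, 0, 110),
                               first_contact_depth = 60)
  # deepest contact at z = 50 equals the planned target
  rec <- compute_accuracy(plan, e, "A1", scalp)
  for (m in c("LE", "EE", "LT", "ET", "depth_error", "angle"))
    expect_lt(abs(rec[[m]]), 1e-6)
})

test_that("a pure translation shows up as lateral shift, a pure depth offset as depth error", {
  scalp <- entry_surface(icosphere(4, 92), "scalp", "phantom")
  plan <- planned_trajectory("P", c(0, 0, 92), c(0, 0, 50))
  # translated 2 mm perpendicular to a near-radial trajectory
  et <- make_straight_electrode("P", head = c(2, 0, 110),
                                first_contact_depth = 60)
  rec <- compute_accuracy(plan, et, "A1", scalp)
  expect_equal(rec$LT, 2, tolerance = 1e-9)
  expect_equal(rec$ET^2, rec$LT^2 + rec$depth_error^2, tolerance = 1e-6)
  expect_equal(rec$angle, 0, tolerance = 1e-9)
  # implanted 3 mm deeper along the planned line
  ed <- make_straight_electrode("P", head = c(0, 0, 110),
                                first_contact_depth = 63)
  rec2 <- compute_accuracy(plan, ed, "A1", scalp)
  expect_equal(rec2$LT, 0, tolerance = 1e-9)
  expect_equal(rec2$depth_error, 3, tolerance = 1e-9)
  expect_equal(rec2$ET, 3, tolerance = 1e-9)
  # shallower insertion gives a negative depth error
  es <- make_straight_electrode("P", head = c(0, 0, 110),
                                first_contact_depth = 57)
  expect_equal(compute_accuracy(plan, es, "A1", scalp)$depth_error, -3,
               tolerance = 1e-9)
})

test_that("record invariants hold on a perturbed phantom cohort", {
  sp <- phantom_spec(seed = 21, n_cases = 2, electrodes_per_case = 6)
  co <- generate_cohort(sp)
  pr <- pair_electrodes(co$plans, co$implants, surface = co$meshes$scalp)
  rec <- cohort_accuracy(pr, co$plans, co$implants, methods = c("A1", "A4"),
                         surfaces = co$meshes$scalp)
  expect_true(all(rec$LE <= rec$EE + 1e-9))
  expect_true(all(rec$LT <= rec$ET + 1e-9))
  expect_equal(rec$ET^2, rec$LT^2 + rec$depth_error^2, tolerance = 1e-6)
  # A1 and A4 share the target point, so all target metrics coincide
  a1 <- rec[rec$method == "A1", ]; a4 <- rec[rec$method == "A4", ]
  expect_equal(a1$LT, a4$LT[match(a1$electrode_id, a4$electrode_id)])
  expect_equal(a1$ET, a4$ET[match(a1$electrode_id, a4$electrode_id)])
})

test_that("accuracy records are invariant under a common rigid transform", {
  scalp_mesh <- icosphere(3, 92)
  plan <- planned_trajectory("P", c(0, 0, 92), c(5, -3, 50), "g")
  e <- make_straight_electrode("P", head = c(1.5, 0.5, 108),
                               dir = c(4, -3, -55))
  rec <- compute_accuracy(plan, e, "A4",
                          entry_surface(scalp_mesh, "scalp", "t"))
  tr <- random_rigid(77)
  tplan <- planned_trajectory("P",
                              rigid_transform(plan$planned_ep, tr$rotation,
                                              tr$translation),
                              rigid_transform(plan$planned_tp, tr$rotation,
                                              tr$translation), "g")
  te <- implanted_electrode("P",
                            rigid_transform(e$bolt_head, tr$rotation,
                                            tr$translation),
                            rigid_transform(e$pivot, tr$rotation,
                                            tr$translation),
                            rigid_transform(e$contacts, tr$rotation,
                                            tr$translation))
  trec <- compute_accuracy(tplan, te, "A4",
                           entry_surface(rigid_transform(scalp_mesh,
                                                         tr$rotation,
                                                         tr$translation),
                                         "scalp", "t"))
  for (m in c("LE", "EE", "LT", "ET", "depth_error", "angle", "length",
              "max_contact_displacement"))
    expect_equal(trec[[m]], rec[[m]], tolerance = 1e-6)
})

test_that("cohort summaries aggregate per case and stratify by group", {
  rec <- data.frame(
    electrode_id = c("a", "b", "c", "d"), method = "A1",
    surface_kind = "scalp", source_tag = "t",
    LE = c(1, 2, 3, 5), EE = c(1, 2, 3, 5), LT = c(2, 2, 4, 4),
    ET = c(2, 2, 4, 4), depth_error = 0, angle = c(1, 3, 1, 3),
    length = c(30, 40, 35, 45), max_contact_displacement = c(.5, .7, .6, .8),
    skull_thickness = c(4, 8, 5, 7),
    group_label = c("temporal", "non-temporal", "temporal", "non-temporal"))
  case_ids <- c(a = "C1", b = "C1", c = "C2", d = "C2")
  s <- summarize_cohort(rec, case_ids)
  expect_equal(s$per_case$LE_mean, c(1.5, 4))
  expect_equal(s$per_case$LE_sd, c(sd(c(1, 2)), sd(c(3, 5))))
  expect_equal(s$total$LE_mean, mean(rec$LE))
  expect_equal(s$total$n, 4L)
  expect_identical(sum(s$total_by_group$n), s$total$n)
  expect_equal(s$total_by_group$LE_mean[s$total_by_group$group == "temporal"],
               2)
  # single-record summary equals the record
  s1 <- summarize_cohort(rec[1, , drop = FALSE])
  expect_equal(s1$total$angle_mean, 1)
})

test_that("surface comparison tabulates per-electrode LE differences", {
  rec <- data.frame(electrode_id = c("a", "b", "c"), method = "A4",
                    LE = c(1, 1.5, 2))
  skull <- rec; skull$LE <- skull$LE - 0.16
  cmp <- compare_surfaces(rec, skull)
  expect_equal(cmp$diff, rep(0.16, 3))
  expect_equal(attr(cmp, "mean_diff"), 0.16)
  same <- compare_surfaces(rec, rec)
  expect_true(all(same$diff == 0))
  other <- rec; other$electrode_id <- c("x", "y", "z")
  expect_error(compare_surfaces(rec, other), "share")
})
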