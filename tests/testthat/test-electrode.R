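test_that("bolt axis trajectory points into the head with zero displacement for straight electrodes", {
  e <- make_straight_electrode()
  a1 <- bolt_axis_trajectory(e)
  expect_equal(a1$line$direction, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(a1$line$origin, c(0, 0, 90), tolerance = 1e-12)
  expect_identical(a1$method, "A1")
  expect_identical(a1$contacts_used, integer(0))
  expect_equal(a1$max_contact_displacement, 0, tolerance = 1e-12)
  expect_error(implanted_electrode("x", c(0, 0, 1), c(0, 0, 1),
                                   rbind(c(0, 0, 0), c(0, 0, -5))),
               "distinct")
})

test_that("a perpendicular displaced contact sets the maximum contact displacement", {
  e <- make_straight_electrode()
  contacts <- e$contacts
  contacts[3, 1] <- contacts[3, 1] + 1.5
  e2 <- implanted_electrode("e2", e$bolt_head, e$pivot, contacts)
  expect_equal(bolt_axis_trajectory(e2)$max_contact_displacement, 1.5,
               tolerance = 1e-12)
})

test_that("A4 window selection follows the anchor-plus-20mm rule", {
  # contacts at axial offsets (-2,2,6,10,14,18,22,26) mm beyond the pivot:
  # anchor is the offset-2 contact; 20 mm inclusive reaches offset 22, not 26
  offsets <- c(26, 22, 18, 14, 10, 6, 2, -2) # deepest-first listing
  e <- implanted_electrode("e", c(0, 0, 30), c(0, 0, 20),
                           cbind(0, 0, 20 - offsets))
  sel <- select_a4_contacts(e, window = 20, outside_margin = 1.2)
  expect_identical(sort(offsets[sel]), c(2, 6, 10, 14, 18, 22))
  # all contacts within the bolt margin: no anchor
  e2 <- implanted_electrode("e", c(0, 0, 30), c(0, 0, 20),
                            cbind(0, 0, 20 - c(1.0, 0.5)))
  expect_error(select_a4_contacts(e2), "no anchor contact")
  expect_error(select_a4_contacts(e, window = 0), "window")
})

test_that("A4 selection is idempotent and windows are inclusive at the boundary", {
  offsets <- c(26, 22, 18, 14, 10, 6, 2, -2)
  e <- implanted_electrode("e", c(0, 0, 30), c(0, 0, 20),
                           cbind(0, 0, 20 - offsets))
  s1 <- select_a4_contacts(e)
  expect_identical(select_a4_contacts(e), s1)
})

test_that("line-of-best-fit estimators coincide with the bolt axis for straight electrodes", {
  e <- make_straight_electrode(n = 10)
  a1 <- bolt_axis_trajectory(e)
  for (m in c("A2", "A3", "A4")) {
    est <- lbf_trajectory(e, m)
    expect_identical(est$method, m)
    expect_lt(angle_between(est$line$direction, a1$line$direction), 1e-9)
    expect_equal(est$max_contact_displacement, 0, tolerance = 1e-10)
  }
  expect_identical(length(lbf_trajectory(e, "A2")$contacts_used), 2L)
  expect_identical(length(lbf_trajectory(e, "A3")$contacts_used), 3L)
  expect_error(lbf_trajectory(
    implanted_electrode("e", c(0, 0, 30), c(0, 0, 20),
                        rbind(c(0, 0, 5), c(0, 0, 10), c(0, 0, 10) + 1e-13)),
    "A2"), "degenerate")
})

test_that("a bend at the pivot is seen by contact-based estimators but not the bolt axis", {
  # plan along -z; bolt on the plan; electrode bent 2 degrees at the pivot
  plan_dir <- c(0, 0, -1)
  pivot <- c(0, 0, 90)
  bent_dir <- drop(rotation_about_axis(c(1, 0, 0), 2) %*% plan_dir)
  deepest <- pivot + 50 * bent_dir
  contacts <- t(vapply(0:7, function(j) deepest - j * 5 * bent_dir, numeric(3)))
  e <- implanted_electrode("bent", pivot - 10 * plan_dir, pivot, contacts)
  a1 <- bolt_axis_trajectory(e)
  a4 <- lbf_trajectory(e, "A4")
  expect_lt(angle_between(a1$line$direction, plan_dir), 1e-9)
  expect_equal(angle_between(a4$line$direction, plan_dir), 2, tolerance = 1e-6)
})

test_that("the implanted target point is the most distal contact", {
  e <- make_straight_electrode()
  expect_equal(implanted_target_point(e), e$contacts[1, ])
  # loaders reject proximal-first contact ordering rather than reordering
  expect_error(implanted_electrode("e", c(0, 0, 100), c(0, 0, 90),
                                   cbind(0, 0, c(60, 50, 40))),
               "deepest-first")
})

test_that("surface entry points pick the intersection nearest the reference", {
  scalp <- entry_surface(icosphere(4, 92), "scalp", "phantom")
  ln <- line3(c(0, 0, 120), c(0, 0, -1))
  ep <- surface_entry_point(ln, c(0, 0, 120), scalp)
  expect_lt(euclidean_distance(ep, c(0, 0, 92)), 0.2)
  # the same line referenced from below picks the antipodal sheet
  ep2 <- surface_entry_point(ln, c(0, 0, -120), scalp)
  expect_lt(euclidean_distance(ep2, c(0, 0, -92)), 0.2)
  expect_error(surface_entry_point(line3(c(200, 0, 0), c(0, 0, 1)),
                                   c(0, 0, 0), scalp),
               "misses")
})

test_that("electrode length and skull thickness are measured along the trajectory", {
  e <- make_straight_electrode(first_contact_depth = 60)
  expect_equal(electrode_length(e, c(0, 0, 80)), 40)
  expect_equal(electrode_length(e, implanted_target_point(e)), 0)
  a1 <- bolt_axis_trajectory(e)
  outer <- icosphere(4, 85); inner <- icosphere(4, 80)
  expect_equal(skull_thickness(a1$line, outer, inner, e$bolt_head), 5,
               tolerance = 0.3)
  expect_lt(skull_thickness(a1$line, outer, outer, e$bolt_head), 1e-9)
  # a line missing the inner sphere errors
  graze <- line3(c(82, 0, 200), c(0, 0, -1))
  expect_error(skull_thickness(graze, outer, inner, c(82, 0, 200)), "misses")
})

test_that("plan and electrode files round-trip through CSV and JSON with validation", {
  plans <- list(
    planned_trajectory("P01", c(10, 20, 80), c(5, 10, 40), "temporal"),
    planned_trajectory("P02", c(-10, 25, 78), c(-4, 12, 42), "non-temporal"))
  names(plans) <- c("P01", "P02")
  elecs <- list(P01 = make_straight_electrode("P01"),
                P02 = make_straight_electrode("P02", head = c(50, 0, 90),
                                              dir = c(-0.4, 0, -1)))
  td <- withr::local_tempdir()
  pcsv <- file.path(td, "plans.csv"); ecsv <- file.path(td, "electrodes.csv")
  write_plans(plans, pcsv, header_comment = "seed: 99")
  write_electrodes(elecs, ecsv, header_comment = "seed: 99")
  expect_identical(readLines(pcsv, n = 1), "# seed: 99")
  p2 <- read_plans(pcsv)
  expect_identical(names(p2), c("P01", "P02"))
  expect_equal(p2$P01$planned_ep, plans$P01$planned_ep)
  expect_identical(p2$P02$group_label, "non-temporal")
  e2 <- read_electrodes(ecsv)
  expect_equal(e2$P01$contacts, elecs$P01$contacts, ignore_attr = TRUE)
  expect_equal(e2$P02$bolt_head, elecs$P02$bolt_head, tolerance = 1e-12)
  # JSON form with identical field names
  pj <- file.path(td, "plans.json")
  df <- utils::read.csv(pcsv, comment.char = "#")
  jsonlite::write_json(df, pj, dataframe = "rows", digits = NA)
  p3 <- read_plans(pj)
  expect_equal(p3$P01$planned_tp, plans$P01$planned_tp)
  # schema violations name the file and electrode
  bad <- utils::read.csv(ecsv, comment.char = "#")
  bad <- bad[bad$role != "pivot" | bad$electrode_id != "P01", ]
  bcsv <- file.path(td, "bad.csv")
  utils::write.csv(bad, bcsv, row.names = FALSE)
  expect_error(read_electrodes(bcsv), "P01.*pivot")
  # a proximal-first listing is rejected at load time
  rev_ct <- utils::read.csv(ecsv, comment.char = "#")
  sel <- rev_ct$electrode_id == "P01" & rev_ct$role == "contact"
  rev_ct$index[sel] <- rev(rev_ct$index[sel])
  rcsv <- file.path(td, "rev.csv")
  utils::write.csv(rev_ct, rcsv, row.names = FALSE)
  expect_error(read_electrodes(rcsv), "deepest-first")
})
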