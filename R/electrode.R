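# Electrode-level estimation: planned/implanted containers with load-time
# validation, the four implanted-trajectory estimators (A1 bolt axis; A2/A3
# two/three most proximal contacts; A4 windowed line of best fit), entry and
# target points, and per-electrode descriptors (length, skull thickness,
# maximum contact displacement).
#
# Conventions used throughout:
#   * contacts are ordered deepest-first: index 1 (R) is the most distal
#     contact and defines the implanted target point;
#   * trajectory directions point proximal -> distal (entry toward target);
#   * estimator tags A1..A4 follow the usual shorthand: A1 = bolt axis,
#     A2/A3 = fit of the 2/3 most proximal contacts, A4 = fit of the contacts
#     from the first contact fully outside the bolt through all contacts
#     within a 20 mm window of it.

#' Planned trajectory for one electrode
#'
#' @param electrode_id character id, unique within a plan.
#' @param planned_ep,planned_tp numeric length-3 planned entry and target
#'   points (world mm); must be more than 1 mm apart.
#' @param group_label optional free-text stratification label (e.g.
#'   `"temporal"` / `"non-temporal"`).
#' @return Object of class `planned_trajectory`.
#' @export
planned_trajectory <- function(electrode_id, planned_ep, planned_tp,
                               group_label = NA_character_) {
  planned_ep <- .as_point(planned_ep, "planned_ep")
  planned_tp <- .as_point(planned_tp, "planned_tp")
  if (euclidean_distance(planned_ep, planned_tp) <= 1)
    stop("planned entry and target points must be separated by more than 1 mm")
  structure(list(electrode_id = as.character(electrode_id),
                 planned_ep = planned_ep, planned_tp = planned_tp,
                 group_label = as.character(group_label)),
            class = "planned_trajectory")
}

#' Line through a planned trajectory
#'
#' @param plan a [planned_trajectory()].
#' @return A [line3()] from entry toward target (proximal to distal).
#' @export
planned_line <- function(plan) {
  stopifnot(inherits(plan, "planned_trajectory"))
  line3(plan$planned_ep, plan$planned_tp - plan$planned_ep)
}

#' Implanted electrode segmentation result
#'
#' Container for the segmented bolt head, pivot point (distal end of the bolt
#' at the skull) and ordered contact centroids. Contact order is validated at
#' construction: axial coordinates along the bolt axis must be strictly
#' decreasing from index 1 (deepest, most distal) to the last (most proximal);
#' a proximal-first listing is rejected rather than silently reordered.
#'
#' @param electrode_id character id.
#' @param bolt_head,pivot numeric length-3 points (world mm); must differ.
#' @param contacts n x 3 matrix of contact centroids, deepest first, n >= 2.
#' @return Object of class `implanted_electrode`.
#' @export
implanted_electrode <- function(electrode_id, bolt_head, pivot, contacts) {
  bolt_head <- .as_point(bolt_head, "bolt_head")
  pivot <- .as_point(pivot, "pivot")
  if (euclidean_distance(bolt_head, pivot) < 1e-9)
    stop("bolt_head and pivot must be distinct points")
  contacts <- .as_points_matrix(contacts)
  if (nrow(contacts) < 2L) stop("an electrode needs at least 2 contacts")
  axis <- line3(pivot, pivot - bolt_head)
  ax <- apply(contacts, 1L, axial_coordinate, line = axis)
  if (any(diff(ax) >= 0))
    stop("contacts must be ordered deepest-first: axial coordinates along ",
         "the bolt axis must be strictly decreasing")
  structure(list(electrode_id = as.character(electrode_id),
                 bolt_head = bolt_head, pivot = pivot, contacts = contacts),
            class = "implanted_electrode")
}

#' Reference head surface used for entry points
#'
#' @param mesh a [trimesh()] in the common world space.
#' @param surface_kind one of `"scalp"`, `"outer_skull"`, `"inner_skull"`.
#' @param source_tag free string naming the source image (e.g. `"T1"`,
#'   `"navCT"`, `"icCT"`, `"phantom"`).
#' @return Object of class `entry_surface`.
#' @export
entry_surface <- function(mesh, surface_kind = c("scalp", "outer_skull",
                                                 "inner_skull"),
                          source_tag = "unspecified") {
  stopifnot(inherits(mesh, "trimesh"))
  surface_kind <- match.arg(surface_kind)
  structure(list(mesh = mesh, surface_kind = surface_kind,
                 source_tag = as.character(source_tag)),
            class = "entry_surface")
}

.surface_mesh <- function(surface) {
  if (inherits(surface, "entry_surface")) surface$mesh
  else if (inherits(surface, "trimesh")) surface
  else stop("expected an entry_surface or trimesh")
}

.new_estimate <- function(line, method, contacts_used, max_disp) {
  structure(list(line = line, method = method,
                 contacts_used = as.integer(contacts_used),
                 max_contact_displacement = max_disp),
            class = "trajectory_estimate")
}

#' Bolt-axis (A1) implanted trajectory
#'
#' Line through the pivot point directed from bolt head toward pivot, i.e.
#' into the head. The maximum contact displacement is the largest lateral
#' shift of any contact from this axis — a measure of electrode bending.
#'
#' @param e an [implanted_electrode()].
#' @return A `trajectory_estimate` with `method = "A1"` and empty
#'   `contacts_used`.
#' @export
bolt_axis_trajectory <- function(e) {
  stopifnot(inherits(e, "implanted_electrode"))
  ln <- line3(e$pivot, e$pivot - e$bolt_head)
  disp <- apply(e$contacts, 1L, lateral_shift, line = ln)
  .new_estimate(ln, "A1", integer(0), max(disp))
}

#' Select the contacts for the windowed (A4) line of best fit
#'
#' The anchor is the most proximal contact "fully outside" the bolt: the one
#' with the smallest axial coordinate (relative to the pivot, positive distal)
#' still exceeding `outside_margin`. The selection is the anchor plus every
#' contact within `window` mm (Euclidean, inclusive) of it, returned
#' deepest-first.
#'
#' @param e an [implanted_electrode()].
#' @param window window size in mm (default 20, inclusive).
#' @param outside_margin axial clearance beyond the pivot for a contact to
#'   count as outside the bolt (default 1.2 mm, about half a contact length).
#' @return Integer vector of contact row indices (1-based, deepest first).
#' @export
select_a4_contacts <- function(e, window = 20, outside_margin = 1.2) {
  stopifnot(inherits(e, "implanted_electrode"))
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  axis <- line3(e$pivot, e$pivot - e$bolt_head)
  ax <- apply(e$contacts, 1L, axial_coordinate, line = axis)
  outside <- which(ax > outside_margin)
  if (length(outside) == 0L)
    stop("no anchor contact: all contacts lie within the bolt margin")
  anchor <- outside[which.min(ax[outside])] # most proximal outside contact
  d <- apply(e$contacts, 1L, euclidean_distance,
             q = e$contacts[anchor, ])
  sel <- which(d <= window + 1e-12 & ax > outside_margin)
  sel <- sort(sel) # deepest first by the ordering invariant
  if (length(sel) < 2L)
    stop("insufficient contacts for fit: fewer than 2 contacts in window")
  sel
}

#' Line-of-best-fit implanted trajectory (A2, A3, A4)
#'
#' A2/A3 fit the two/three most proximal contacts (largest indices in the
#' deepest-first ordering); A4 fits the [select_a4_contacts()] window. The
#' fitted line is a total-least-squares fit of the selected contact centroids,
#' oriented proximal to distal.
#'
#' @param e an [implanted_electrode()].
#' @param method `"A2"`, `"A3"` or `"A4"`.
#' @param window,outside_margin A4 selection parameters, see
#'   [select_a4_contacts()].
#' @return A `trajectory_estimate`; `max_contact_displacement` is the largest
#'   lateral shift of the *selected* contacts from the fitted line.
#' @export
lbf_trajectory <- function(e, method = c("A4", "A2", "A3"), window = 20,
                           outside_margin = 1.2) {
  stopifnot(inherits(e, "implanted_electrode"))
  method <- match.arg(method)
  n <- nrow(e$contacts)
  sel <- switch(method,
                A2 = {
                  if (n < 2L) stop("A2 needs at least 2 contacts")
                  (n - 1L):n
                },
                A3 = {
                  if (n < 3L) stop("A3 needs at least 3 contacts")
                  (n - 2L):n
                },
                A4 = select_a4_contacts(e, window, outside_margin))
  sel <- sort(sel)
  pts <- e$contacts[sel, , drop = FALSE]
  ln <- fit_line_tls(pts)
  # orient proximal -> distal: nonnegative dot with pivot -> deepest contact
  into_head <- e$contacts[1L, ] - e$pivot
  if (sum(ln$direction * into_head) < 0)
    ln <- line3(ln$origin, -ln$direction)
  disp <- apply(pts, 1L, lateral_shift, line = ln)
  .new_estimate(ln, method, sel, max(disp))
}

#' Estimate an implanted trajectory by method tag
#'
#' Dispatcher over [bolt_axis_trajectory()] (A1) and [lbf_trajectory()]
#' (A2/A3/A4).
#'
#' @param e an [implanted_electrode()].
#' @param method one of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @param window,outside_margin A4 parameters.
#' @return A `trajectory_estimate`.
#' @export
estimate_trajectory <- function(e, method = c("A1", "A2", "A3", "A4"),
                                window = 20, outside_margin = 1.2) {
  method <- match.arg(method)
  if (method == "A1") bolt_axis_trajectory(e)
  else lbf_trajectory(e, method, window, outside_margin)
}

#' Implanted target point
#'
#' The implanted target point is the most distal contact (index 1 in the
#' deepest-first ordering), for every trajectory estimator.
#'
#' @param e an [implanted_electrode()].
#' @return Numeric length-3 point (mm).
#' @export
implanted_target_point <- function(e) {
  stopifnot(inherits(e, "implanted_electrode"))
  if (nrow(e$contacts) < 1L) stop("electrode has no contacts")
  e$contacts[1L, ]
}

#' Entry point of a trajectory on a head surface
#'
#' Intersects the (infinite) trajectory line with the surface mesh and returns
#' the intersection closest to `reference`, which disambiguates multi-sheet
#' intersections (ears, contralateral scalp). For an implanted trajectory the
#' natural reference is the bolt head; for a planned trajectory, the planned
#' entry point.
#'
#' @param line a [line3()].
#' @param reference numeric length-3 point (mm).
#' @param surface an [entry_surface()] or bare [trimesh()].
#' @return Numeric length-3 entry point on the surface (mm).
#' @export
surface_entry_point <- function(line, reference, surface) {
  reference <- .as_point(reference, "reference")
  hits <- line_mesh_intersections(line, .surface_mesh(surface))
  if (length(hits$axial) == 0L)
    stop("trajectory misses surface")
  d <- sqrt(rowSums(sweep(hits$points, 2L, reference)^2))
  hits$points[which.min(d), ]
}

#' Implanted electrode length
#'
#' Distance from the surface entry point to the deepest contact.
#'
#' @param e an [implanted_electrode()].
#' @param entry numeric length-3 entry point (mm).
#' @return Length in mm.
#' @export
electrode_length <- function(e, entry) {
  euclidean_distance(.as_point(entry, "entry"), implanted_target_point(e))
}

#' Skull thickness along a trajectory
#'
#' Distance along the trajectory between its intersection with the outer skull
#' surface nearest `reference` and the inner-skull intersection nearest that
#' outer point: the bone span the drill traverses, measured along the
#' implanted axis rather than the surface normal.
#'
#' @param traj a [line3()] (typically the A1 bolt axis).
#' @param outer,inner [entry_surface()] or [trimesh()] outer/inner skull.
#' @param reference numeric length-3 point used to pick the near-side
#'   crossing (typically the bolt head).
#' @return Thickness in mm.
#' @export
skull_thickness <- function(traj, outer, inner, reference) {
  reference <- .as_point(reference, "reference")
  ho <- line_mesh_intersections(traj, .surface_mesh(outer))
  if (length(ho$axial) == 0L) stop("trajectory misses outer skull surface")
  d <- sqrt(rowSums(sweep(ho$points, 2L, reference)^2))
  i <- which.min(d)
  p_out <- ho$points[i, ]
  hi <- line_mesh_intersections(traj, .surface_mesh(inner))
  if (length(hi$axial) == 0L) stop("trajectory misses inner skull surface")
  d2 <- sqrt(rowSums(sweep(hi$points, 2L, p_out)^2))
  abs(hi$axial[which.min(d2)] - ho$axial[i])
}

# ---- plan / electrode file I/O -------------------------------------------
# Plan CSV: electrode_id,ep_x_mm,ep_y_mm,ep_z_mm,tp_x_mm,tp_y_mm,tp_z_mm,group_label
# Electrode CSV (one row per point): electrode_id,role,index,x_mm,y_mm,z_mm
#   role in {bolt_head,pivot,contact}; contacts indexed 0..n-1 deepest-first.
# A JSON array of objects with the same field names is accepted for either.
# Lines starting with '#' are treated as comments (run headers echo the seed).

.read_table_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- jsonlite::fromJSON(path)
    if (!is.data.frame(df)) df <- as.data.frame(df)
    df
  } else {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")))
}

#' Read planned trajectories from CSV or JSON
#'
#' @param path plan file; see package README for the schema.
#' @return Named list of [planned_trajectory()] objects.
#' @export
read_plans <- function(path) {
  df <- .read_table_auto(path)
  .require_cols(df, c("electrode_id", "ep_x_mm", "ep_y_mm", "ep_z_mm",
                      "tp_x_mm", "tp_y_mm", "tp_z_mm"), path)
  if (anyDuplicated(df$electrode_id))
    stop(path, ": duplicated electrode_id in plan")
  if (!("group_label" %in% names(df))) df$group_label <- NA_character_
  plans <- lapply(seq_len(nrow(df)), function(i) {
    planned_trajectory(df$electrode_id[i],
                       c(df$ep_x_mm[i], df$ep_y_mm[i], df$ep_z_mm[i]),
                       c(df$tp_x_mm[i], df$tp_y_mm[i], df$tp_z_mm[i]),
                       df$group_label[i])
  })
  names(plans) <- df$electrode_id
  plans
}

#' Read implanted electrodes from CSV or JSON
#'
#' Validates per electrode: exactly one bolt head and one pivot, at least two
#' contacts with contiguous indices from 0, and deepest-first contact ordering
#' (strictly decreasing axial coordinate along the bolt axis). Violations are
#' reported with the file name and electrode id.
#'
#' @param path electrode file; see package README for the schema.
#' @return Named list of [implanted_electrode()] objects.
#' @export
read_electrodes <- function(path) {
  df <- .read_table_auto(path)
  .require_cols(df, c("electrode_id", "role", "index", "x_mm", "y_mm", "z_mm"),
                path)
  out <- lapply(split(df, df$electrode_id), function(g) {
    id <- g$electrode_id[1L]
    ctx <- function(msg) stop(sprintf("%s (electrode %s): %s", path, id, msg))
    bh <- g[g$role == "bolt_head", , drop = FALSE]
    pv <- g[g$role == "pivot", , drop = FALSE]
    ct <- g[g$role == "contact", , drop = FALSE]
    if (nrow(bh) != 1L) ctx("expected exactly one bolt_head row")
    if (nrow(pv) != 1L) ctx("expected exactly one pivot row")
    if (nrow(ct) < 2L) ctx("expected at least two contact rows")
    ct <- ct[order(ct$index), , drop = FALSE]
    if (!identical(as.integer(ct$index), seq_len(nrow(ct)) - 1L))
      ctx("contact indices must be contiguous from 0")
    tryCatch(
      implanted_electrode(id,
                          c(bh$x_mm, bh$y_mm, bh$z_mm),
                          c(pv$x_mm, pv$y_mm, pv$z_mm),
                          as.matrix(ct[, c("x_mm", "y_mm", "z_mm")])),
      error = function(e) ctx(conditionMessage(e)))
  })
  out[order(names(out))]
}

#' Write planned trajectories to CSV
#'
#' @param plans list of [planned_trajectory()].
#' @param path output CSV path.
#' @param header_comment optional character vector written as leading
#'   `#`-comment lines (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_plans <- function(plans, path, header_comment = NULL) {
  df <- do.call(rbind, lapply(plans, function(p) {
    data.frame(electrode_id = p$electrode_id,
               ep_x_mm = p$planned_ep[1], ep_y_mm = p$planned_ep[2],
               ep_z_mm = p$planned_ep[3],
               tp_x_mm = p$planned_tp[1], tp_y_mm = p$planned_tp[2],
               tp_z_mm = p$planned_tp[3],
               group_label = p$group_label)
  }))
  .write_csv_commented(df, path, header_comment)
}

#' Write implanted electrodes to CSV
#'
#' @param electrodes list of [implanted_electrode()].
#' @param path output CSV path.
#' @param header_comment optional `#`-comment header lines.
#' @return `path`, invisibly.
#' @export
write_electrodes <- function(electrodes, path, header_comment = NULL) {
  df <- do.call(rbind, lapply(electrodes, function(e) {
    n <- nrow(e$contacts)
    data.frame(electrode_id = e$electrode_id,
               role = c("bolt_head", "pivot", rep("contact", n)),
               index = c(NA_integer_, NA_integer_, seq_len(n) - 1L),
               x_mm = c(e$bolt_head[1], e$pivot[1], e$contacts[, 1]),
               y_mm = c(e$bolt_head[2], e$pivot[2], e$contacts[, 2]),
               z_mm = c(e$bolt_head[3], e$pivot[3], e$contacts[, 3]))
  }))
  .write_csv_commented(df, path, header_comment)
}

.write_csv_commented <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
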