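# Cohort-level analysis: automatic pairing of planned with implanted
# electrodes, per-electrode accuracy records under chosen (estimator, surface)
# settings, per-case summaries and scalp-vs-skull paired comparisons.

#' Pair planned with implanted electrodes
#'
#' Greedy one-to-one matching that encodes the two ordered criteria used for
#' automatic pairing: (1) closest distance between entry points, then
#' (2) lowest angle between trajectories. Candidate pairs are sorted
#' lexicographically by (entry distance quantized to `distance_tie_tol`,
#' angle) and accepted greedily; a candidate whose entry distance exceeds
#' `max_ep_distance` is never matched. Deterministic given its inputs, and
#' invariant to permutations of either list.
#'
#' The implanted entry proxy is the bolt head when no `surface` is given;
#' with a surface, both planned and implanted (A1 bolt-axis) trajectories are
#' re-projected onto it via [surface_entry_point()]. Angles compare the
#' planned direction with the A1 bolt-axis direction.
#'
#' @param planned list of [planned_trajectory()].
#' @param implanted list of [implanted_electrode()].
#' @param surface optional [entry_surface()] for on-surface entry points.
#' @param max_ep_distance reject matches farther apart than this (mm).
#' @param distance_tie_tol distances within this quantum are considered tied
#'   and the angle criterion decides (mm).
#' @return List with `pairs` (data frame: `planned_id`, `implanted_id`,
#'   `pairing_distance`, `pairing_angle`), `unmatched_planned`,
#'   `unmatched_implanted` (character ids).
#' @export
pair_electrodes <- function(planned, implanted, surface = NULL,
                            max_ep_distance = 15, distance_tie_tol = 0.5) {
  stopifnot(length(planned) > 0L, length(implanted) > 0L)
  pid <- vapply(planned, function(p) p$electrode_id, character(1))
  iid <- vapply(implanted, function(e) e$electrode_id, character(1))
  # deterministic candidate order regardless of input list order
  pord <- order(pid); iord <- order(iid)
  planned <- planned[pord]; pid <- pid[pord]
  implanted <- implanted[iord]; iid <- iid[iord]

  pdirs <- lapply(planned, function(p) planned_line(p)$direction)
  peps <- lapply(planned, function(p) {
    if (is.null(surface)) p$planned_ep
    else surface_entry_point(planned_line(p), p$planned_ep, surface)
  })
  itraj <- lapply(implanted, bolt_axis_trajectory)
  ieps <- lapply(seq_along(implanted), function(i) {
    if (is.null(surface)) implanted[[i]]$bolt_head
    else surface_entry_point(itraj[[i]]$line, implanted[[i]]$bolt_head,
                             surface)
  })

  np <- length(planned); ni <- length(implanted)
  cand <- expand.grid(p = seq_len(np), i = seq_len(ni))
  cand$dist <- mapply(function(p, i) euclidean_distance(peps[[p]], ieps[[i]]),
                      cand$p, cand$i)
  cand$angle <- mapply(function(p, i) angle_between(pdirs[[p]],
                                                    itraj[[i]]$line$direction),
                       cand$p, cand$i)
  cand <- cand[cand$dist <= max_ep_distance, , drop = FALSE]
  qd <- round(cand$dist / distance_tie_tol)
  cand <- cand[order(qd, cand$angle, cand$dist, cand$p, cand$i), , drop = FALSE]

  used_p <- logical(np); used_i <- logical(ni)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    p <- cand$p[k]; i <- cand$i[k]
    if (used_p[p] || used_i[i]) next
    used_p[p] <- TRUE; used_i[i] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      planned_id = pid[p], implanted_id = iid[i],
      pairing_distance = cand$dist[k], pairing_angle = cand$angle[k],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(planned_id = character(0), implanted_id = character(0),
               pairing_distance = numeric(0), pairing_angle = numeric(0))
  pairs <- pairs[order(pairs$planned_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_planned = unname(pid[!used_p]),
       unmatched_implanted = unname(iid[!used_i]))
}

#' Accuracy record for one planned/implanted electrode pair
#'
#' Computes the full deviation profile of an implanted electrode against its
#' plan under one (estimator, surface) choice:
#' \describe{
#'   \item{LE}{lateral shift of the implanted on-surface entry point from the
#'     planned trajectory line (mm).}
#'   \item{EE}{Euclidean distance between the planned and implanted entry
#'     points, both re-projected onto the surface (mm).}
#'   \item{LT}{lateral shift of the implanted target point (deepest contact)
#'     from the planned line (mm).}
#'   \item{ET}{Euclidean distance between planned and implanted target points
#'     (mm).}
#'   \item{depth_error}{signed along-axis component of the target
#'     displacement; positive = implanted deeper than planned (mm). By
#'     construction `ET^2 = LT^2 + depth_error^2`.}
#'   \item{angle}{angle between planned and implanted directions (degrees).}
#' }
#' plus the electrode length (entry to deepest contact), the maximum contact
#' displacement of the estimator, and optionally the skull thickness along
#' the bolt axis.
#'
#' @param plan a [planned_trajectory()].
#' @param electrode an [implanted_electrode()].
#' @param method trajectory estimator, `"A1"`, `"A2"`, `"A3"` or `"A4"`.
#' @param surface an [entry_surface()] (or [trimesh()]) defining entry points.
#' @param outer_skull,inner_skull optional skull surfaces; when both given the
#'   record carries `skull_thickness` along the A1 bolt axis.
#' @param window,outside_margin A4 parameters, see [select_a4_contacts()].
#' @return One-row data frame (an `AccuracyRecord`).
#' @export
compute_accuracy <- function(plan, electrode, method = "A1", surface,
                             outer_skull = NULL, inner_skull = NULL,
                             window = 20, outside_margin = 1.2) {
  stopifnot(inherits(plan, "planned_trajectory"),
            inherits(electrode, "implanted_electrode"))
  pline <- planned_line(plan)
  est <- estimate_trajectory(electrode, method, window, outside_margin)
  iline <- est$line
  p_ep <- surface_entry_point(pline, plan$planned_ep, surface)
  i_ep <- surface_entry_point(iline, electrode$bolt_head, surface)
  i_tp <- implanted_target_point(electrode)
  le <- lateral_shift(i_ep, pline)
  ee <- euclidean_distance(p_ep, i_ep)
  lt <- lateral_shift(i_tp, pline)
  et <- euclidean_distance(plan$planned_tp, i_tp)
  depth <- axial_coordinate(i_tp, pline) - axial_coordinate(plan$planned_tp,
                                                            pline)
  ang <- angle_between(pline$direction, iline$direction)
  st <- NA_real_
  if (!is.null(outer_skull) && !is.null(inner_skull)) {
    a1 <- bolt_axis_trajectory(electrode)
    st <- skull_thickness(a1$line, outer_skull, inner_skull,
                          electrode$bolt_head)
  }
  sk <- if (inherits(surface, "entry_surface")) surface$surface_kind else "scalp"
  tag <- if (inherits(surface, "entry_surface")) surface$source_tag else
    "unspecified"
  data.frame(electrode_id = plan$electrode_id, method = method,
             surface_kind = sk, source_tag = tag,
             LE = le, EE = ee, LT = lt, ET = et, depth_error = depth,
             angle = ang,
             length = electrode_length(electrode, i_ep),
             max_contact_displacement = est$max_contact_displacement,
             skull_thickness = st,
             group_label = plan$group_label,
             stringsAsFactors = FALSE)
}

#' Accuracy records for a whole paired cohort
#'
#' Applies [compute_accuracy()] to every pair for every requested method and
#' surface. A record-level failure (surface miss, degenerate fit) does not
#' abort the run: the failure is collected and reported in the `failures`
#' attribute.
#'
#' @param pairing result of [pair_electrodes()].
#' @param planned,implanted the same lists given to [pair_electrodes()].
#' @param methods character vector within `c("A1","A2","A3","A4")`.
#' @param surfaces list of [entry_surface()] objects.
#' @param outer_skull,inner_skull optional skull surfaces for thickness.
#' @param window,outside_margin A4 parameters.
#' @return Data frame of accuracy records (one row per pair x method x
#'   surface) with a `failures` attribute (data frame of electrode_id, method,
#'   surface, message).
#' @export
cohort_accuracy <- function(pairing, planned, implanted, methods = "A1",
                            surfaces, outer_skull = NULL, inner_skull = NULL,
                            window = 20, outside_margin = 1.2) {
  stopifnot(all(methods %in% c("A1", "A2", "A3", "A4")))
  if (inherits(surfaces, "entry_surface")) surfaces <- list(surfaces)
  pmap <- stats::setNames(planned,
                          vapply(planned, `[[`, character(1), "electrode_id"))
  imap <- stats::setNames(implanted,
                          vapply(implanted, `[[`, character(1), "electrode_id"))
  recs <- list(); fails <- list()
  for (k in seq_len(nrow(pairing$pairs))) {
    plan <- pmap[[pairing$pairs$planned_id[k]]]
    elec <- imap[[pairing$pairs$implanted_id[k]]]
    for (m in methods) for (s in surfaces) {
      r <- tryCatch(
        compute_accuracy(plan, elec, m, s, outer_skull, inner_skull,
                         window, outside_margin),
        error = function(e) e)
      if (inherits(r, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          electrode_id = plan$electrode_id, method = m,
          surface_kind = if (inherits(s, "entry_surface")) s$surface_kind
                         else "scalp",
          message = conditionMessage(r), stringsAsFactors = FALSE)
      } else {
        recs[[length(recs) + 1L]] <- r
      }
    }
  }
  out <- if (length(recs) > 0L) do.call(rbind, recs) else
    stop("no accuracy records could be computed")
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails) > 0L) do.call(rbind, fails) else
    data.frame(electrode_id = character(0), method = character(0),
               surface_kind = character(0), message = character(0))
  out
}

.summ_stats <- function(df, by) {
  metrics <- c("length", "skull_thickness", "max_contact_displacement",
               "LE", "LT", "angle")
  agg <- function(fun, suffix) {
    out <- stats::aggregate(df[metrics], by = by, FUN = fun)
    names(out)[names(out) %in% metrics] <- paste0(metrics, suffix)
    out
  }
  mean_na <- function(x) mean(x, na.rm = TRUE)
  sd_na <- function(x) stats::sd(x, na.rm = TRUE)
  m <- agg(mean_na, "_mean")
  s <- agg(sd_na, "_sd")
  n <- stats::aggregate(list(n = df$LE), by = by, FUN = length)
  out <- merge(merge(m, s, by = names(by)), n, by = names(by))
  out[do.call(order, out[names(by)]), , drop = FALSE]
}

#' Summarize a cohort of accuracy records
#'
#' Per-case mean/SD of length, skull thickness, maximum contact displacement,
#' LE, LT and angle — overall and stratified by `group_label` — plus grand
#' totals, in the layout used for per-patient accuracy reporting.
#'
#' @param records data frame from [cohort_accuracy()] (a single method and
#'   surface, or filter beforehand).
#' @param case_ids named character vector mapping `electrode_id` to a case
#'   (patient) id; electrodes missing from the map fall into case `"all"`.
#' @return Object of class `cohort_summary`: list with `per_case`,
#'   `per_case_by_group`, `total`, `total_by_group` data frames.
#' @export
summarize_cohort <- function(records, case_ids = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  case <- if (is.null(case_ids)) rep("all", nrow(records)) else {
    cs <- unname(case_ids[records$electrode_id])
    cs[is.na(cs)] <- "all"
    cs
  }
  df <- records
  df$case <- case
  grp <- if ("group_label" %in% names(df)) df$group_label else
    rep(NA_character_, nrow(df))
  grp[is.na(grp)] <- "unlabelled"
  df$group <- grp
  out <- list(
    per_case = .summ_stats(df, list(case = df$case)),
    per_case_by_group = .summ_stats(df, list(case = df$case,
                                             group = df$group)),
    total = .summ_stats(df, list(all = rep("total", nrow(df)))),
    total_by_group = .summ_stats(df, list(group = df$group)))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("Cohort accuracy summary\n\nPer case:\n")
  print(format(x$per_case, digits = digits), row.names = FALSE)
  cat("\nTotal:\n")
  print(format(x$total, digits = digits), row.names = FALSE)
  cat("\nTotal by group:\n")
  print(format(x$total_by_group, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Paired scalp-vs-skull comparison of entry-point lateral shift
#'
#' Pairs records by `electrode_id` and `method` and tabulates per-electrode
#' LE differences (scalp minus skull), ready for agreement testing
#' ([bland_altman()], [wilcoxon_signed_rank()]).
#'
#' @param records_scalp,records_skull accuracy-record data frames computed on
#'   a scalp and a skull surface respectively.
#' @return Data frame with `electrode_id`, `method`, `LE_scalp`, `LE_skull`,
#'   `diff` plus attributes `mean_diff` and `sd_diff`.
#' @export
compare_surfaces <- function(records_scalp, records_skull) {
  key <- c("electrode_id", "method")
  a <- records_scalp[, c(key, "LE")]
  b <- records_skull[, c(key, "LE")]
  names(a)[3L] <- "LE_scalp"; names(b)[3L] <- "LE_skull"
  m <- merge(a, b, by = key)
  if (nrow(m) == 0L) stop("no records share electrode_id and method")
  m$diff <- m$LE_scalp - m$LE_skull
  m <- m[order(m$electrode_id, m$method), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "mean_diff") <- mean(m$diff)
  attr(m, "sd_diff") <- stats::sd(m$diff)
  m
}
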