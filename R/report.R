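# Run orchestration: phantom dataset emission, end-to-end accuracy
# computation from files, and agreement tables. Every run directory carries a
# machine-readable echo of the resolved configuration and a log file; all
# units are mm and degrees, never rescaled.

.log_line <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "", file = log, append = TRUE)
  invisible(msg)
}

#' Emit a phantom dataset to disk
#'
#' Writes the full synthetic dataset produced by [generate_cohort()] in the
#' exact file schemas consumed by [run_compute()]: `plans.csv`,
#' `electrodes.csv`, STL meshes (`scalp.stl`, `outer_skull.stl`,
#' `inner_skull.stl`), `ground_truth.csv`, `cases.csv` and a `spec.json` echo.
#' Every CSV carries the generator seed in a leading `#` comment header.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param volume also rasterize and write `ct.nii.gz` (default `FALSE`).
#' @param voxel_mm voxel size for the optional volume.
#' @return The cohort, invisibly; files under `out_dir`.
#' @export
run_phantom <- function(spec, out_dir, volume = FALSE, voxel_mm = 0.75) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  hdr <- sprintf("seed: %d", spec$seed)
  write_plans(cohort$plans, file.path(out_dir, "plans.csv"), hdr)
  write_electrodes(cohort$implants, file.path(out_dir, "electrodes.csv"), hdr)
  for (nm in names(cohort$meshes))
    write_mesh(cohort$meshes[[nm]]$mesh, file.path(out_dir,
                                                   paste0(nm, ".stl")))
  .write_csv_commented(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                       hdr)
  .write_csv_commented(
    data.frame(electrode_id = names(cohort$case_of),
               case = unname(cohort$case_of)),
    file.path(out_dir, "cases.csv"), hdr)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  if (volume)
    write_volume(rasterize_ct(cohort, voxel_mm),
                 file.path(out_dir, "ct.nii.gz"))
  invisible(cohort)
}

#' Resolve a compute-run configuration
#'
#' @param plans path to the plan CSV/JSON.
#' @param electrodes path to the electrode CSV/JSON.
#' @param scalp_mesh path to the scalp mesh (STL/PLY).
#' @param outer_skull_mesh,inner_skull_mesh optional skull mesh paths.
#' @param methods trajectory estimators to run, subset of A1..A4.
#' @param a4_window,a4_margin A4 selection parameters (mm).
#' @param max_ep_distance,distance_tie_tol pairing thresholds (mm).
#' @param cases optional path to a CSV mapping `electrode_id` to `case`.
#' @param source_tag free label for the mesh source image.
#' @return A `run_config` list (validated paths).
#' @export
run_config <- function(plans, electrodes, scalp_mesh,
                       outer_skull_mesh = NULL, inner_skull_mesh = NULL,
                       methods = c("A1", "A4"), a4_window = 20,
                       a4_margin = 1.2, max_ep_distance = 15,
                       distance_tie_tol = 0.5, cases = NULL,
                       source_tag = "unspecified") {
  methods <- match.arg(methods, c("A1", "A2", "A3", "A4"), several.ok = TRUE)
  cfg <- list(plans = plans, electrodes = electrodes, scalp_mesh = scalp_mesh,
              outer_skull_mesh = outer_skull_mesh,
              inner_skull_mesh = inner_skull_mesh, methods = methods,
              a4_window = a4_window, a4_margin = a4_margin,
              max_ep_distance = max_ep_distance,
              distance_tie_tol = distance_tie_tol, cases = cases,
              source_tag = source_tag)
  for (p in c(cfg$plans, cfg$electrodes, cfg$scalp_mesh,
              cfg$outer_skull_mesh, cfg$inner_skull_mesh, cfg$cases))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if (length(cfg$methods) == 0L) stop("method list must be nonempty")
  class(cfg) <- "run_config"
  cfg
}

#' Run the accuracy pipeline from files
#'
#' Loads plans, electrodes and meshes, pairs electrodes on the scalp surface,
#' computes accuracy records for every requested estimator, and writes under
#' `out_dir`: `records.csv` (one row per electrode x method), `summary.json`
#' (cohort summary), `pairing.csv`, `agreement.csv` (pairwise-method
#' Bland-Altman and Wilcoxon tables on LE, LT and angle, plus Mann-Whitney
#' group comparisons), `config.json` (resolved configuration echo) and
#' `run.log`. Purely deterministic: re-running identical inputs reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if missing).
#' @return List with `records`, `summary`, `pairing`, `agreement`, invisibly.
#' @export
run_compute <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "run.log")
  cat("", file = log)
  .log_line(log, "loading plans: %s", config$plans)
  plans <- read_plans(config$plans)
  .log_line(log, "loading electrodes: %s", config$electrodes)
  implants <- read_electrodes(config$electrodes)
  scalp <- entry_surface(read_mesh(config$scalp_mesh), "scalp",
                         config$source_tag)
  outer <- if (!is.null(config$outer_skull_mesh))
    entry_surface(read_mesh(config$outer_skull_mesh), "outer_skull",
                  config$source_tag)
  inner <- if (!is.null(config$inner_skull_mesh))
    entry_surface(read_mesh(config$inner_skull_mesh), "inner_skull",
                  config$source_tag)
  .log_line(log, "pairing %d planned with %d implanted electrodes",
            length(plans), length(implants))
  pairing <- pair_electrodes(plans, implants, surface = scalp,
                             max_ep_distance = config$max_ep_distance,
                             distance_tie_tol = config$distance_tie_tol)
  .log_line(log, "paired %d; unmatched planned: %d, unmatched implanted: %d",
            nrow(pairing$pairs), length(pairing$unmatched_planned),
            length(pairing$unmatched_implanted))
  records <- cohort_accuracy(pairing, plans, implants,
                             methods = config$methods, surfaces = scalp,
                             outer_skull = outer, inner_skull = inner,
                             window = config$a4_window,
                             outside_margin = config$a4_margin)
  fails <- attr(records, "failures")
  if (nrow(fails) > 0L)
    for (i in seq_len(nrow(fails)))
      .log_line(log, "record failure: %s %s (%s): %s", fails$electrode_id[i],
                fails$method[i], fails$surface_kind[i], fails$message[i])
  case_ids <- NULL
  if (!is.null(config$cases)) {
    cs <- utils::read.csv(config$cases, comment.char = "#",
                          stringsAsFactors = FALSE)
    case_ids <- stats::setNames(cs$case, cs$electrode_id)
  }
  summ <- summarize_cohort(records, case_ids)
  agreement <- method_agreement_tables(records)

  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(pairing$pairs, file.path(out_dir, "pairing.csv"),
                   row.names = FALSE)
  utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(unclass(summ), as.data.frame),
                       file.path(out_dir, "summary.json"), digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  .log_line(log, "wrote %d records for %d methods", nrow(records),
            length(config$methods))
  invisible(list(records = records, summary = summ, pairing = pairing,
                 agreement = agreement))
}

#' Pairwise-method agreement and group-comparison tables
#'
#' For every pair of estimators present in `records`, Bland-Altman bias/limits
#' and a Wilcoxon signed-rank test on each of LE, LT and angle (paired by
#' electrode). For every metric, a Mann-Whitney U comparison between the
#' groups in `group_label` (when exactly two groups are present). The table
#' notes the total number of tests performed; p-values are reported raw, with
#' no multiple-testing correction.
#'
#' @param records accuracy-record data frame (single surface).
#' @return Data frame with one row per (comparison, metric).
#' @export
method_agreement_tables <- function(records) {
  metrics <- c("LE", "LT", "angle")
  methods <- sort(unique(records$method))
  rows <- list()
  if (length(methods) >= 2L) {
    cmb <- utils::combn(methods, 2L)
    for (k in seq_len(ncol(cmb))) {
      m1 <- cmb[1L, k]; m2 <- cmb[2L, k]
      a <- records[records$method == m1, c("electrode_id", metrics)]
      b <- records[records$method == m2, c("electrode_id", metrics)]
      m <- merge(a, b, by = "electrode_id", suffixes = c("_1", "_2"))
      if (nrow(m) < 3L) next
      for (met in metrics) {
        x <- m[[paste0(met, "_1")]]; y <- m[[paste0(met, "_2")]]
        ba <- bland_altman(x, y)
        wt <- if (all(x == y)) NULL else wilcoxon_signed_rank(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste(m1, "vs", m2), metric = met, n = ba$n,
          bias = ba$bias, sd = ba$sd,
          loa_low = ba$loa_low, loa_high = ba$loa_high,
          test = "Wilcoxon signed-rank W",
          statistic = if (is.null(wt)) NA_real_ else wt$statistic,
          p_value = if (is.null(wt)) NA_real_ else wt$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  grps <- unique(records$group_label)
  grps <- grps[!is.na(grps)]
  if (length(grps) == 2L) {
    for (m1 in methods) for (met in metrics) {
      sel <- records$method == m1
      x <- records[sel & records$group_label == grps[1L], met]
      y <- records[sel & records$group_label == grps[2L], met]
      if (length(x) == 0L || length(y) == 0L) next
      mw <- mann_whitney_u(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s: %s vs %s", m1, grps[1L], grps[2L]),
        metric = met, n = mw$n_x + mw$n_y,
        bias = mean(x) - mean(y), sd = NA_real_,
        loa_low = NA_real_, loa_high = NA_real_,
        test = "Mann-Whitney U", statistic = mw$statistic,
        p_value = mw$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(comparison = character(0), metric = character(0),
               n = integer(0), bias = numeric(0), sd = numeric(0),
               loa_low = numeric(0), loa_high = numeric(0),
               test = character(0), statistic = numeric(0),
               p_value = numeric(0))
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}
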