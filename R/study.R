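#' Simulate a study grid and extract the KPI table
#'
#' Runs every (setting, twin, arm) combination of the grid over the
#' matching cohort and extracts per-cycle KPI records. Pure and
#' deterministic: rerunning with the same cohorts and grid reproduces the
#' table exactly.
#'
#' @param grid Study grid ([enumerate_study()] or a subset).
#' @param hdac_cohort,idac_cohort The two dose cohorts.
#' @param arms Arms to simulate.
#' @param config Model configuration.
#' @param n_cycles Cycles per course.
#' @param progress Print a line per setting.
#' @return Data frame: KPI records joined with the grid columns.
#' @export
run_kpi_table <- function(grid, hdac_cohort, idac_cohort,
                          arms = c("AC123", "AC135"),
                          config = default_config(), n_cycles = 3,
                          progress = FALSE) {
  cohorts <- list(HDAC = hdac_cohort, IDAC = idac_cohort)
  out <- vector("list", nrow(grid) * length(arms))
  n <- 0
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    twins <- cohorts[[row$cohort]]$twins
    for (arm in arms) {
      plan <- plan_from_grid_row(row, arm, n_cycles)
      recs <- lapply(twins, function(tw) {
        traj <- simulate_course(tw, plan, config,
                                schedule_id = row$schedule_id)
        kpi_records(traj, threshold = config$threshold)
      })
      n <- n + 1
      out[[n]] <- do.call(rbind, recs)
    }
    if (progress)
      message("setting ", row$schedule_id, " (", i, "/", nrow(grid), ")")
  }
  kpi <- do.call(rbind, out[seq_len(n)])
  merge(kpi, grid, by = "schedule_id", sort = FALSE)
}

#' Median-KPI heat grid over the lenograstim schedules
#'
#' For each (offset, duration) cell and each cohort/arm, the median of the
#' chosen KPI over the cohort's twins in the chosen cycle (the published
#' grids use the first cycle). Cells with no defined value carry `NA`
#' plus an explicit count of undefined twins.
#'
#' @param kpi KPI table from [run_kpi_table()].
#' @param var `"kpiL"`, `"kpiB"`, `"nadir"` or `"leukopenia_d"`.
#' @param cycle Cycle index to summarise.
#' @return Data frame: `cohort`, `arm`, `offset`, `duration`, `median`,
#'   `n`, `n_undefined`.
#' @export
kpi_heat_grid <- function(kpi, var = "kpiL", cycle = 1) {
  k <- kpi[kpi$cycle == cycle, , drop = FALSE]
  k$offset[is.na(k$offset)] <- 0L  # no-G-CSF sentinel cell
  agg <- aggregate(k[[var]],
                   by = list(cohort = k$cohort, arm = k$arm,
                             offset = k$offset, duration = k$duration),
                   FUN = function(v) c(median = median(v, na.rm = TRUE),
                                       n = sum(!is.na(v)),
                                       n_undefined = sum(is.na(v))))
  data.frame(agg[, 1:4], median = agg$x[, "median"], n = agg$x[, "n"],
             n_undefined = agg$x[, "n_undefined"])
}

#' Median-KPI curves over cycle lengths
#'
#' The cycle-length sweep: median KPI per (cohort, arm, G-CSF setting,
#' cycle length).
#'
#' @inheritParams kpi_heat_grid
#' @return Data frame: `cohort`, `arm`, `gcsf`, `cycle_length`, `median`, `n`.
#' @export
kpi_cycle_length_curves <- function(kpi, var = "kpiL", cycle = 1) {
  k <- kpi[kpi$cycle == cycle, , drop = FALSE]
  k$gcsf <- ifelse(k$duration > 0, "gcsf", "none")
  agg <- aggregate(k[[var]],
                   by = list(cohort = k$cohort, arm = k$arm, gcsf = k$gcsf,
                             cycle_length = k$cycle_length),
                   FUN = function(v) c(median = median(v, na.rm = TRUE),
                                       n = sum(!is.na(v))))
  data.frame(agg[, 1:4], median = agg$x[, "median"], n = agg$x[, "n"])
}

#' Run the study end to end
#'
#' Orchestrates the full pipeline: builds (or loads) the cohorts,
#' enumerates the treatment grid, simulates every (setting, twin, arm)
#' run, extracts KPIs, and computes the result surfaces: the
#' lenograstim heat grids (median kpiL and kpiB), the cycle-length
#' curves, the paired AC-123 versus AC-135 comparison, and the
#' Wei--Lin--Weissfeld fit. Optionally writes all tables to `out_dir`
#' as tab-separated text plus a JSON run-metadata file.
#'
#' @param cohorts List with `hdac` and `idac` cohorts (e.g. from
#'   [make_virtual_trial()]); `NULL` generates synthetic cohorts from
#'   `seed`.
#' @param grid Study grid; default the full [enumerate_study()]. Use
#'   `enumerate_study(gcsf = reduced_gcsf_grid(), cycle_lengths =
#'   integer(0))` for a desk-scale run.
#' @param arms Arms to simulate.
#' @param config Model configuration.
#' @param seed Seed for synthetic cohorts.
#' @param out_dir Optional output directory.
#' @param progress Print progress.
#' @return List with `kpi`, `grid_kpiL`, `grid_kpiB`, `cycle_curves_kpiL`,
#'   `cycle_curves_kpiB`, `paired_kpiL`, `paired_kpiB`, `wlw`, `manifest`,
#'   `meta`.
#' @export
run_study <- function(cohorts = NULL, grid = enumerate_study(),
                      arms = c("AC123", "AC135"),
                      config = default_config(), seed = 1L,
                      out_dir = NULL, progress = FALSE) {
  validate_config(config)
  if (is.null(cohorts)) cohorts <- make_virtual_trial(seed = seed)
  kpi <- run_kpi_table(grid, cohorts$hdac, cohorts$idac, arms = arms,
                       config = config, progress = progress)
  k123 <- kpi[kpi$arm == "AC123", , drop = FALSE]
  k135 <- kpi[kpi$arm == "AC135", , drop = FALSE]
  paired_L <- paired_fraction_reduced(k123, k135, var = "kpiL")
  paired_B <- paired_fraction_reduced(k123, k135, var = "kpiB")
  recs <- wlw_records_from_kpi(kpi, list(cohorts$hdac, cohorts$idac))
  wlw <- fit_wlw(recs)
  res <- list(
    kpi = kpi,
    grid_kpiL = kpi_heat_grid(kpi, "kpiL"),
    grid_kpiB = kpi_heat_grid(kpi, "kpiB"),
    cycle_curves_kpiL = kpi_cycle_length_curves(kpi, "kpiL"),
    cycle_curves_kpiB = kpi_cycle_length_curves(kpi, "kpiB"),
    paired_kpiL = paired_L, paired_kpiB = paired_B,
    wlw = wlw,
    manifest = study_manifest(grid, cohorts$hdac, cohorts$idac, arms),
    meta = list(seed = seed, n_settings = nrow(grid),
                arms = arms, solver = config$solver,
                threshold = config$threshold,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(res$kpi, "kpi_table.tsv")
    wt(res$grid_kpiL, "grid_kpiL.tsv")
    wt(res$grid_kpiB, "grid_kpiB.tsv")
    wt(res$cycle_curves_kpiL, "cycle_curves_kpiL.tsv")
    wt(res$cycle_curves_kpiB, "cycle_curves_kpiB.tsv")
    wt(as.data.frame(res$wlw), "wlw_result.tsv")
    wt(res$manifest, "manifest.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        c(res$meta, list(paired_kpiL = paired_L, paired_kpiB = paired_B)),
        file.path(out_dir, "run_meta.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
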