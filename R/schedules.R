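#' Construct a treatment plan
#'
#' A plan covers `n_cycles` consecutive consolidation cycles with identical
#' settings: the Ara-C arm (AC-123 = administration days 1,2,3; AC-135 =
#' days 1,3,5), the Ara-C dose per square metre, the lenograstim schedule
#' (start offset after the last Ara-C day, and duration in consecutive
#' days; offset `NA`/duration 0 means no G-CSF), and the cycle length.
#' Cycle day 1 of cycle k+1 is the day after day `cycle_length` of cycle k.
#'
#' @param arm `"AC123"` or `"AC135"`.
#' @param dose_g_per_m2 Ara-C dose in g/m^2 (3 for HDAC, 1 for IDAC).
#' @param gcsf_offset Days between the last Ara-C day and the first
#'   lenograstim day (>= 1), or `NA` for no G-CSF.
#' @param gcsf_duration Consecutive lenograstim days (0 for none).
#' @param cycle_length Cycle length in days (28--56 in the study).
#' @param n_cycles Number of consecutive cycles (3 in the study).
#' @param gcsf_daily_dose_ug Lenograstim daily dose (263 ug).
#' @return Object of class `ct_plan`.
#' @export
treatment_plan <- function(arm = c("AC123", "AC135"), dose_g_per_m2 = 3,
                           gcsf_offset = NA, gcsf_duration = 0,
                           cycle_length = 42, n_cycles = 3,
                           gcsf_daily_dose_ug = 263) {
  arm <- match.arg(arm)
  if (gcsf_duration == 0 && !is.na(gcsf_offset))
    stop("duration 0 requires no G-CSF offset (use NA)", call. = FALSE)
  if (gcsf_duration > 0 && (is.na(gcsf_offset) || gcsf_offset < 1))
    stop("G-CSF offset must be >= 1 day after the last Ara-C day",
         call. = FALSE)
  if (cycle_length < 7) stop("cycle_length too short", call. = FALSE)
  if (dose_g_per_m2 < 0) stop("dose must be >= 0", call. = FALSE)
  structure(list(arm = arm,
                 ara_days = if (arm == "AC123") c(1, 2, 3) else c(1, 3, 5),
                 dose_g_per_m2 = dose_g_per_m2,
                 gcsf_offset = gcsf_offset, gcsf_duration = gcsf_duration,
                 cycle_length = cycle_length, n_cycles = n_cycles,
                 gcsf_daily_dose_ug = gcsf_daily_dose_ug),
            class = "ct_plan")
}

cycle_starts <- function(plan) (seq_len(plan$n_cycles) - 1) * plan$cycle_length

#' Absolute lenograstim administration days within a cycle
#'
#' The start offset counts from the last Ara-C day of the arm, so offset 3
#' means cycle day 6 for AC-123 (last Ara-C day 3) and cycle day 8 for
#' AC-135 (last Ara-C day 5); the block runs for `duration` consecutive
#' days.
#'
#' @param offset Start offset in days after the last Ara-C day (>= 1).
#' @param duration Consecutive administration days (>= 1).
#' @param arm `"AC123"` or `"AC135"`.
#' @param cycle_length Cycle length, for bounds checking.
#' @return Integer vector of 1-based cycle-day numbers.
#' @export
absolute_gcsf_days <- function(offset, duration, arm = c("AC123", "AC135"),
                               cycle_length = 42) {
  arm <- match.arg(arm)
  if (is.na(offset) || duration < 1)
    stop("no G-CSF schedule: offset/duration undefined", call. = FALSE)
  first <- (if (arm == "AC123") 3 else 5) + offset
  days <- seq.int(first, first + duration - 1)
  if (max(days) > cycle_length)
    stop("G-CSF days exceed the cycle length", call. = FALSE)
  days
}

gcsf_days_in_cycle <- function(plan) {
  if (plan$gcsf_duration == 0) return(integer(0))
  absolute_gcsf_days(plan$gcsf_offset, plan$gcsf_duration, plan$arm,
                     plan$cycle_length)
}

#' The lenograstim schedule grid
#'
#' All combinations of start offsets 1--10 (days after the last Ara-C day)
#' with durations 1, 3, ..., 21 days, plus the no-G-CSF schedule:
#' 10 x 11 + 1 = 111 schedules.
#'
#' @return Data frame with columns `offset` and `duration` (the no-G-CSF
#'   row has `offset = NA`, `duration = 0`).
#' @export
gcsf_grid <- function() {
  g <- expand.grid(offset = 1:10, duration = seq(1, 21, by = 2))
  rbind(data.frame(offset = NA_integer_, duration = 0L),
        g[order(g$offset, g$duration), ])
}

#' A reduced, deterministic subset of the lenograstim grid
#'
#' Twenty schedules used for desk-scale directional analyses: the
#' no-G-CSF schedule, the clinically referenced start-5/duration-5 block,
#' and offsets \{2, 6, 10\} crossed with durations \{1, 5, 9, 13, 17, 21\}.
#'
#' @return Data frame with columns `offset`, `duration` (20 rows).
#' @export
reduced_gcsf_grid <- function() {
  g <- expand.grid(offset = c(2L, 6L, 10L),
                   duration = c(1L, 5L, 9L, 13L, 17L, 21L))
  g <- g[order(g$offset, g$duration), ]
  out <- rbind(data.frame(offset = NA_integer_, duration = 0L),
               data.frame(offset = 5L, duration = 5L), g)
  rownames(out) <- NULL
  out
}

#' Enumerate the full study grid
#'
#' Part 1: every lenograstim schedule of [gcsf_grid()] at a fixed 42-day
#' cycle length, instantiated for both the HDAC (3 g/m^2) and IDAC
#' (1 g/m^2) cohorts. Part 2: cycle lengths 28--56 excluding 42, crossed
#' with two G-CSF settings (start 5 / duration 5, and none), for both
#' cohorts. Total 111 x 2 + 28 x 2 x 2 = 334 settings; each setting is
#' simulated for both arms (AC-123 and AC-135) for every twin of its
#' cohort.
#'
#' @param gcsf Data frame of G-CSF schedules for part 1 (default the full
#'   [gcsf_grid()]).
#' @param cycle_lengths Integer vector for part 2 (default 28--56 without
#'   42); use `integer(0)` to drop part 2.
#' @param cohorts Character vector of dose cohorts to instantiate.
#' @return Data frame (the study grid) with columns `schedule_id`, `part`,
#'   `cohort`, `dose_g_per_m2`, `offset`, `duration`, `cycle_length`.
#' @export
enumerate_study <- function(gcsf = gcsf_grid(),
                            cycle_lengths = setdiff(28:56, 42),
                            cohorts = c("HDAC", "IDAC")) {
  dose <- c(HDAC = 3, IDAC = 1)
  part1 <- if (nrow(gcsf)) do.call(rbind, lapply(cohorts, function(co)
    data.frame(part = 1L, cohort = co, dose_g_per_m2 = dose[[co]],
               offset = gcsf$offset, duration = gcsf$duration,
               cycle_length = 42L))) else NULL
  part2 <- if (length(cycle_lengths)) do.call(rbind, lapply(cohorts, function(co)
    do.call(rbind, lapply(c("g55", "none"), function(gs)
      data.frame(part = 2L, cohort = co, dose_g_per_m2 = dose[[co]],
                 offset = if (gs == "g55") 5L else NA_integer_,
                 duration = if (gs == "g55") 5L else 0L,
                 cycle_length = as.integer(cycle_lengths)))))) else NULL
  grid <- rbind(part1, part2)
  o <- order(grid$part, grid$offset, grid$duration, grid$cycle_length,
             grid$cohort, na.last = FALSE)
  grid <- grid[o, , drop = FALSE]
  grid$schedule_id <- sprintf("S%03d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid[, c("schedule_id", "part", "cohort", "dose_g_per_m2", "offset",
           "duration", "cycle_length")]
}

#' Run manifest: one row per (setting, twin, arm)
#'
#' Expands a study grid over the twins of the matching cohorts; with the
#' study's grid and 65 twins this lists 32,565 consolidation cycles per
#' arm (settings x twins x 3 cycles).
#'
#' @param grid A study grid from [enumerate_study()].
#' @param hdac_cohort,idac_cohort Cohorts ([make_virtual_trial()] or
#'   [load_cohort()]).
#' @param arms Arms to include.
#' @return Data frame with one row per simulation run.
#' @export
study_manifest <- function(grid, hdac_cohort, idac_cohort,
                           arms = c("AC123", "AC135")) {
  ids <- list(HDAC = vapply(hdac_cohort$twins, `[[`, "", "twin_id"),
              IDAC = vapply(idac_cohort$twins, `[[`, "", "twin_id"))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tw <- ids[[grid$cohort[i]]]
    expand.grid(schedule_id = grid$schedule_id[i], twin_id = tw, arm = arms,
                stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  merge(man, grid, by = "schedule_id", sort = FALSE)
}

plan_from_grid_row <- function(row, arm, n_cycles = 3) {
  treatment_plan(arm = arm, dose_g_per_m2 = row$dose_g_per_m2,
                 gcsf_offset = if (row$duration == 0) NA else row$offset,
                 gcsf_duration = row$duration,
                 cycle_length = row$cycle_length, n_cycles = n_cycles)
}
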