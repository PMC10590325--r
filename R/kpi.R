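daily_samples <- function(traj, cycle_index) {
  cb <- traj$cycle_bounds
  if (cycle_index < 1 || cycle_index > length(cb) - 1)
    stop("cycle index out of range", call. = FALSE)
  s0 <- cb[cycle_index]; s1 <- cb[cycle_index + 1]
  len <- round(s1 - s0)
  # sample for cycle day d is the state at the start of day d
  tt <- s0 + (seq_len(len) - 1)
  idx <- vapply(tt, function(t) which.min(abs(traj$time - t)), integer(1))
  if (any(abs(traj$time[idx] - tt) > 1e-6))
    stop("trajectory grid does not contain the daily samples", call. = FALSE)
  list(day = seq_len(len), wbc = traj$wbc[idx])
}

#' WBC recovery time (kpiL) for one cycle
#'
#' Days from cycle day 1 to the first daily sample at which the WBC is
#' back at or above the threshold after having been below it. `NA` (with a
#' message-free flag) when the WBC never drops below the threshold within
#' the cycle -- such cycles are excluded from kpiL summaries, not coded 0.
#'
#' @param traj A `ct_trajectory`.
#' @param cycle_index Cycle number (1-based).
#' @param threshold Leukopenia threshold in 10^9 WBC/L (default 1.0).
#' @return Recovery day (numeric) or `NA` if no sub-threshold episode.
#' @export
recovery_time <- function(traj, cycle_index, threshold = 1.0) {
  s <- daily_samples(traj, cycle_index)
  below <- s$wbc < threshold
  if (!any(below)) return(NA_real_)
  first_below <- which(below)[1]
  rec <- which(!below & seq_along(below) > first_below)
  if (!length(rec)) return(NA_real_)  # not recovered within the cycle
  as.numeric(s$day[rec[1]])
}

#' Leukopenia duration for one cycle
#'
#' Days from the first sub-threshold daily sample to the recovery sample;
#' `NA` when there is no sub-threshold episode (or no recovery within the
#' cycle).
#'
#' @inheritParams recovery_time
#' @return Duration in days, or `NA`.
#' @export
leukopenia_duration <- function(traj, cycle_index, threshold = 1.0) {
  s <- daily_samples(traj, cycle_index)
  below <- s$wbc < threshold
  if (!any(below)) return(NA_real_)
  first_below <- s$day[which(below)[1]]
  rec <- recovery_time(traj, cycle_index, threshold)
  if (is.na(rec)) return(NA_real_)
  as.numeric(rec - first_below)
}

#' WBC nadir for one cycle
#'
#' Minimum circulating WBC within the cycle, taken on the dense (0.1-day)
#' output grid.
#'
#' @inheritParams recovery_time
#' @return Nadir in 10^9 WBC/L.
#' @export
wbc_nadir <- function(traj, cycle_index) {
  cb <- traj$cycle_bounds
  if (cycle_index < 1 || cycle_index > length(cb) - 1)
    stop("cycle index out of range", call. = FALSE)
  sel <- traj$time >= cb[cycle_index] - 1e-9 &
    traj$time <= cb[cycle_index + 1] + 1e-9
  min(traj$wbc[sel])
}

#' Blast ratio (kpiB) for one cycle
#'
#' Total leukemic blast burden (proliferating + post-mitotic) at the end
#' of the cycle divided by the burden at the start of consolidation
#' therapy (t = 0, not the start of the cycle). Values below 1 indicate a
#' net reduction of blasts relative to therapy start.
#'
#' @inheritParams recovery_time
#' @return Positive ratio.
#' @export
blast_ratio <- function(traj, cycle_index) {
  cb <- traj$cycle_bounds
  if (cycle_index < 1 || cycle_index > length(cb) - 1)
    stop("cycle index out of range", call. = FALSE)
  tot <- traj$state[, "l_prol"] + traj$state[, "l_mat"]
  i0 <- which.min(abs(traj$time - 0))
  i1 <- which.min(abs(traj$time - cb[cycle_index + 1]))
  if (tot[i0] <= 0) stop("zero initial blast burden", call. = FALSE)
  tot[i1] / tot[i0]
}

#' Eligibility of a simulated course
#'
#' A course qualifies for the recovery-time comparisons when all three
#' cycles show a defined sub-threshold episode (WBC < threshold at some
#' daily sample, with recovery), mirroring the clinical inclusion rule of
#' identical treatment over three cycles with leukopenia in each.
#'
#' @param kpil Numeric vector of per-cycle recovery times (length 3, `NA`
#'   for cycles with no episode).
#' @return Logical flag.
#' @export
eligible_course <- function(kpil) {
  if (!length(kpil)) stop("empty record set", call. = FALSE)
  all(!is.na(kpil))
}

#' Extract all KPI records from one simulated course
#'
#' @param traj A `ct_trajectory`.
#' @param threshold Leukopenia threshold (10^9/L).
#' @return Data frame with one row per cycle: `twin_id`, `schedule_id`,
#'   `arm`, `cycle`, `kpiL`, `leukopenia_d`, `nadir`, `kpiB`, `eligible`.
#' @export
kpi_records <- function(traj, threshold = 1.0) {
  n_cyc <- length(traj$cycle_bounds) - 1
  kpil <- vapply(seq_len(n_cyc), function(k)
    recovery_time(traj, k, threshold), numeric(1))
  rec <- data.frame(
    twin_id = traj$twin_id, schedule_id = traj$schedule_id, arm = traj$arm,
    cycle = seq_len(n_cyc),
    kpiL = kpil,
    leukopenia_d = vapply(seq_len(n_cyc), function(k)
      leukopenia_duration(traj, k, threshold), numeric(1)),
    nadir = vapply(seq_len(n_cyc), function(k) wbc_nadir(traj, k), numeric(1)),
    kpiB = vapply(seq_len(n_cyc), function(k) blast_ratio(traj, k), numeric(1)))
  rec$eligible <- eligible_course(kpil) && all(!is.na(rec$kpiL))
  rec
}
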