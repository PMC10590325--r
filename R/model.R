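#' @useDynLib cytotwin
#' @importFrom stats approx median rnorm runif rbinom setNames aggregate
#' @importFrom utils head tail read.delim write.table
NULL

# order of the parameter vector handed to the compiled rhs
.parm_names <- c("n_tr", "B", "gamma", "k_tr", "slope_w", "p_l", "a_l", "d_l",
                 "k_s", "e_cap", "ke_ara", "v_ara", "ka_g", "ke_g", "kw_g",
                 "g_scale", "beta1", "beta2", "blast_fb_w", "blast_sens",
                 "ara_rate")

#' Construct and validate a set of individual model parameters
#'
#' The six per-twin parameters of the digital-twin model: WBC baseline `B`
#' (10^9/L), feedback exponent `gamma`, transit rate `k_tr` (1/day), Ara-C
#' effect slope `slope_w` (per mg/L), blast proliferation rate `p_l`
#' (1/day), and initial blast burden `l0` (10^9 cells, arbitrary scale).
#'
#' @param B,gamma,k_tr,slope_w,p_l,l0 Scalar parameter values.
#' @return A named list of class `ct_theta`.
#' @export
individual_parameters <- function(B, gamma, k_tr, slope_w, p_l, l0 = 1.0) {
  theta <- list(B = B, gamma = gamma, k_tr = k_tr,
                slope_w = slope_w, p_l = p_l, l0 = l0)
  vals <- unlist(theta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("individual parameters must be finite and strictly positive",
         call. = FALSE)
  if (gamma > 5) stop("gamma must lie in (0, 5]", call. = FALSE)
  if (B <= 0.5 || B >= 20) stop("B must lie in (0.5, 20)", call. = FALSE)
  structure(theta, class = "ct_theta")
}

state_names <- function(n_tr) {
  c("x_prol", paste0("x_tr", seq_len(n_tr)), "x_wbc",
    "a_ara", "g_depot", "g_circ", "l_prol", "l_mat")
}

model_parms <- function(theta, config, ara_rate = 0) {
  pp <- config$population_parameters
  setNames(c(config$n_transit, theta$B, theta$gamma, theta$k_tr,
             theta$slope_w, theta$p_l, pp$a_l, pp$d_l, pp$k_s, pp$e_cap,
             pp$ke_ara, pp$v_ara, pp$ka_g, pp$ke_g, pp$kw_g, pp$g_scale,
             pp$beta1, pp$beta2, pp$blast_fb_w, pp$blast_sens, ara_rate),
           .parm_names)
}

#' Pre-treatment homeostatic state
#'
#' Initial condition at the start of consolidation: the healthy lineage at
#' its feedback equilibrium (all hematopoietic compartments equal the
#' baseline `B`, so their derivatives vanish), no drug on board, and the
#' leukemic blast pools at the configured initial burden. Blasts are not
#' required to be at equilibrium -- the proliferative pool is set to `l0`
#' and the post-mitotic pool to its conditional flux balance given `l0`.
#'
#' @param theta Individual parameters ([individual_parameters()]).
#' @param config Model configuration ([default_config()]).
#' @return Named state vector.
#' @export
homeostatic_state <- function(theta, config = default_config()) {
  if (!inherits(theta, "ct_theta")) theta <- do.call(individual_parameters, theta)
  pp <- config$population_parameters
  n_tr <- config$n_transit
  y <- setNames(numeric(n_tr + 7), state_names(n_tr))
  y[1:(n_tr + 2)] <- theta$B      # progenitors, transit chain, circulating WBC
  y["l_prol"] <- theta$l0
  # post-mitotic blasts at flux balance given l_prol = l0 (fixed point in s
  # when blasts enter the feedback signal)
  lm <- 0
  for (i in 1:50) {
    s <- 1 / (1 + pp$k_s * (theta$B + pp$blast_fb_w * (theta$l0 + lm)))
    lm_new <- 2 * theta$p_l * theta$l0 * (1 - pp$a_l * s) / pp$d_l
    if (abs(lm_new - lm) < 1e-12) { lm <- lm_new; break }
    lm <- lm_new
  }
  y["l_mat"] <- lm
  y
}

#' Model right-hand side (reference R implementation)
#'
#' Derivative of the full state at time `t`. This is the readable reference
#' implementation; [simulate_course()] integrates an identical compiled
#' version for speed, and the two are cross-checked in the test suite.
#'
#' @param t Time (days; the autonomous system ignores it).
#' @param y Named state vector as from [homeostatic_state()].
#' @param theta Individual parameters.
#' @param config Model configuration.
#' @param inputs List with `ara_rate` (mg/day of ongoing Ara-C infusion).
#' @return Named derivative vector.
#' @export
rhs <- function(t, y, theta, config = default_config(),
                inputs = list(ara_rate = 0)) {
  if (any(y < 0 & abs(y) > 1e-6))
    stop("negative state components beyond solver floor", call. = FALSE)
  pp <- config$population_parameters
  n_tr <- config$n_transit
  iw <- n_tr + 2; ia <- n_tr + 3; idp <- n_tr + 4; ig <- n_tr + 5
  il <- n_tr + 6; im <- n_tr + 7
  xw <- max(y[[iw]], 1e-8)
  g  <- max(y[[ig]], 0)
  conc <- max(y[[ia]], 0) / pp$v_ara
  E <- min(theta$slope_w * conc, pp$e_cap)
  gf1 <- (1 + g)^pp$beta1
  gf2 <- (1 + g)^pp$beta2
  fb  <- (theta$B / xw)^theta$gamma
  d <- numeric(length(y))
  d[1] <- theta$k_tr * y[[1]] * (fb * gf1 * (1 - E) - gf2)
  for (j in 2:(n_tr + 1)) d[j] <- theta$k_tr * gf2 * (y[[j - 1]] - y[[j]])
  d[iw] <- theta$k_tr * gf2 * y[[n_tr + 1]] - theta$k_tr * y[[iw]]
  d[ia] <- inputs$ara_rate - pp$ke_ara * y[[ia]]
  d[idp] <- -pp$ka_g * y[[idp]]
  d[ig] <- pp$ka_g * y[[idp]] / pp$g_scale - (pp$ke_g + pp$kw_g * xw) * y[[ig]]
  lp <- max(y[[il]], 0); lm <- max(y[[im]], 0)
  s <- 1 / (1 + pp$k_s * (xw + pp$blast_fb_w * (lp + lm)))
  El <- min(pp$blast_sens * theta$slope_w * conc, pp$e_cap)
  d[il] <- theta$p_l * y[[il]] * (2 * pp$a_l * s * (1 - El) - 1)
  d[im] <- 2 * theta$p_l * lp * (1 - pp$a_l * s) * (1 - El) - pp$d_l * y[[im]]
  setNames(d, names(y))
}

#' Expand a treatment plan into dosing events
#'
#' Ara-C administrations become constant-rate infusions of the configured
#' duration (3 h) delivering `dose_per_m2 x BSA` per administration;
#' G-CSF administrations become instantaneous subcutaneous depot additions
#' of the daily dose at the start of each administration day. Every
#' integration breakpoint (infusion start/stop, injection, cycle boundary)
#' is listed.
#'
#' @param plan A [treatment_plan()].
#' @param twin A [digital_twin()] (supplies the body surface area).
#' @param config Model configuration.
#' @return A data frame with columns `time` (days from consolidation
#'   start), `type` (`"ara_start"`, `"ara_stop"`, `"gcsf"`), `amount`
#'   (mg per infusion for Ara-C, ug for G-CSF) and `rate` (mg/day while
#'   the infusion runs), sorted by time.
#' @export
dosing_events <- function(plan, twin, config = default_config()) {
  stopifnot(inherits(plan, "ct_plan"))
  inf_d <- config$infusion_h / 24
  ipd <- config$infusions_per_day
  dose_mg <- plan$dose_g_per_m2 * twin$bsa * 1000
  rate <- dose_mg / inf_d
  ev <- list()
  starts <- cycle_starts(plan)
  for (k in seq_len(plan$n_cycles)) {
    s0 <- starts[k]
    for (d in if (dose_mg > 0) plan$ara_days else numeric(0)) {
      if (d > plan$cycle_length)
        stop("Ara-C day ", d, " outside cycle of length ",
             plan$cycle_length, call. = FALSE)
      for (i in seq_len(ipd) - 1) {
        t0 <- s0 + d - 1 + i * 0.5
        ev[[length(ev) + 1]] <- data.frame(
          time = c(t0, t0 + inf_d), type = c("ara_start", "ara_stop"),
          amount = c(dose_mg, 0), rate = c(rate, 0))
      }
    }
    gd <- gcsf_days_in_cycle(plan)
    if (length(gd)) {
      if (max(gd) > plan$cycle_length)
        stop("G-CSF day ", max(gd), " outside cycle of length ",
             plan$cycle_length, call. = FALSE)
      ev[[length(ev) + 1]] <- data.frame(
        time = s0 + gd - 1, type = "gcsf",
        amount = plan$gcsf_daily_dose_ug, rate = 0)
    }
  }
  if (!length(ev))
    return(data.frame(time = numeric(0), type = character(0),
                      amount = numeric(0), rate = numeric(0)))
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Simulate a full consolidation course
#'
#' Integrates the coupled model over the plan's consecutive cycles,
#' splitting the integration at every dosing breakpoint so the solver
#' never steps across a discontinuity. Output is dense (0.1-day grid by
#' default) and includes every integer day, which the KPI extractors use
#' as the daily sampling grid.
#'
#' @param twin A [digital_twin()].
#' @param plan A [treatment_plan()].
#' @param config Model configuration.
#' @param rtol,atol Solver tolerances (defaults from the configuration).
#' @param schedule_id Optional identifier carried into the trajectory.
#' @return An object of class `ct_trajectory`: list with `time`, `state`
#'   (matrix, one named column per state, clamped at 0), `wbc`,
#'   `cycle_bounds`, `events`, `twin_id`, `schedule_id`, `arm`.
#' @export
simulate_course <- function(twin, plan, config = default_config(),
                            rtol = config$solver$rtol,
                            atol = config$solver$atol,
                            schedule_id = NA_character_) {
  theta <- twin$theta
  ev <- dosing_events(plan, twin, config)
  starts <- cycle_starts(plan)
  t_end <- starts[plan$n_cycles] + plan$cycle_length
  step <- config$solver$grid_step
  grid <- round(seq(0, t_end, by = step), 6)
  bp <- sort(unique(round(c(0, ev$time, starts, t_end), 6)))
  bp <- bp[bp >= 0 & bp <= t_end]
  parms <- model_parms(theta, config, ara_rate = 0)
  y <- homeostatic_state(theta, config)
  out_t <- numeric(0)
  out_y <- NULL
  for (k in seq_len(length(bp) - 1)) {
    t0 <- bp[k]; t1 <- bp[k + 1]
    # G-CSF depot bolus at segment start
    gix <- ev$type == "gcsf" & abs(ev$time - t0) < 1e-8
    if (any(gix)) y["g_depot"] <- y["g_depot"] + sum(ev$amount[gix])
    # infusion rate on [t0, t1): sum over infusions whose window covers it
    st <- ev[ev$type == "ara_start", , drop = FALSE]
    en <- ev[ev$type == "ara_stop", , drop = FALSE]
    covered <- st$time <= t0 + 1e-8 & en$time >= t1 - 1e-8
    parms["ara_rate"] <- sum(st$rate[covered])
    times <- sort(unique(c(t0, grid[grid > t0 + 1e-9 & grid < t1 - 1e-9], t1)))
    sol <- deSolve::lsoda(y = y, times = times, func = "cytotwin_derivs",
                          parms = parms, dllname = "cytotwin",
                          initfunc = "cytotwin_initmod",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure for twin ", twin$twin_id, " schedule ",
           schedule_id, call. = FALSE)
    y <- sol[nrow(sol), -1]
    keep <- if (k == 1) seq_len(nrow(sol)) else -1
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
  }
  out_y[out_y < 0] <- 0
  colnames(out_y) <- state_names(config$n_transit)
  structure(list(time = out_t, state = out_y, wbc = out_y[, "x_wbc"],
                 cycle_bounds = c(starts, t_end), events = ev,
                 twin_id = twin$twin_id, schedule_id = schedule_id,
                 arm = plan$arm, plan = plan),
            class = "ct_trajectory")
}

#' Observed (measurable) WBC along a trajectory
#'
#' The blood count seen in a CBC: healthy circulating WBC plus the small
#' circulating fraction of post-mitotic leukemic blasts
#' (`blast_obs_frac x l_mat`). This observation function is shared by the
#' synthetic observation generator and the per-twin fitter.
#'
#' @param traj A `ct_trajectory`.
#' @param config Model configuration.
#' @return Numeric vector along `traj$time`.
#' @export
observed_wbc <- function(traj, config = default_config()) {
  traj$state[, "x_wbc"] +
    config$population_parameters$blast_obs_frac * traj$state[, "l_mat"]
}

#' Export a trajectory as a data frame
#'
#' @param x A `ct_trajectory`.
#' @param ... Unused.
#' @return Data frame with `time_d`, one column per state, and the
#'   `twin_id`, `schedule_id`, `arm` metadata.
#' @export
as.data.frame.ct_trajectory <- function(x, ...) {
  data.frame(time_d = x$time, x$state, twin_id = x$twin_id,
             schedule_id = x$schedule_id, arm = x$arm,
             check.names = FALSE)
}
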