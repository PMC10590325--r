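# shared fixtures: the population-median twin and common plans

median_theta <- function() {
  p <- population_prior()$params
  do.call(individual_parameters, as.list(setNames(p$median, p$name)))
}

median_twin <- function(cohort = "HDAC") {
  digital_twin("TW1", cohort, age = 58.5, bsa = 1.9, theta = median_theta())
}

plan_hdac123 <- function(...) treatment_plan("AC123", 3, ...)
plan_hdac135 <- function(...) treatment_plan("AC135", 3, ...)

# a hand-built trajectory carrying a prescribed daily WBC series (one cycle)
fake_trajectory <- function(daily_wbc, cycle_length = length(daily_wbc),
                            l_traj = NULL) {
  tt <- seq(0, cycle_length, by = 0.5)
  wbc <- approx(seq_along(daily_wbc) - 1, daily_wbc, xout = tt, rule = 2)$y
  st <- cbind(x_wbc = wbc,
              l_prol = if (is.null(l_traj)) rep(1, length(tt)) else
                approx(seq_along(l_traj) - 1, l_traj, xout = tt, rule = 2)$y,
              l_mat = 0)
  structure(list(time = tt, state = st, wbc = wbc,
                 cycle_bounds = c(0, cycle_length),
                 twin_id = "F1", schedule_id = "S", arm = "AC123"),
            class = "ct_trajectory")
}
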