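#' Default population prior for virtual cohorts
#'
#' Log-normal laws (median + coefficient of variation) for the six
#' individual model parameters, plus truncated-normal laws for age and
#' body surface area. Medians are the repo-default population values; all
#' CVs are kept below 0.37, matching the dispersion reported for the
#' externally estimated parameters.
#'
#' @return A list with `params` (data frame: `name`, `median`, `cv`),
#'   `age` (median, sd, lower, upper) and `bsa` (median, sd, lower, upper).
#' @export
population_prior <- function() {
  list(
    params = data.frame(
      name   = c("B", "gamma", "k_tr", "slope_w", "p_l", "l0"),
      median = c(7.0,  0.15,   1.00,   1.5,      0.35,  1.0),
      cv     = c(0.25, 0.30,   0.20,   0.30,     0.35,  0.30)),
    age = list(median = 58.5, sd = 10, lower = 18, upper = 80),
    bsa = list(median = 1.9, sd = 0.18, lower = 1.25, upper = 2.55)
  )
}

rlnorm_cv <- function(n, median, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  median * exp(rnorm(n, 0, sdlog))
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

sample_twin <- function(id, cohort, prior) {
  p <- prior$params
  vals <- setNames(rlnorm_cv(nrow(p), p$median, p$cv), p$name)
  # keep draws inside the hard parameter bounds
  vals["B"] <- min(max(vals["B"], 0.6), 19.9)
  vals["gamma"] <- min(vals["gamma"], 4.9)
  age <- rtruncnorm1(1, prior$age$median, prior$age$sd,
                     prior$age$lower, prior$age$upper)
  bsa <- rtruncnorm1(1, prior$bsa$median, prior$bsa$sd,
                     prior$bsa$lower, prior$bsa$upper)
  digital_twin(id, cohort, age, bsa, do.call(individual_parameters,
                                             as.list(vals)))
}

#' Generate the virtual trial cohorts
#'
#' Draws the two dose cohorts of digital twins emulated throughout the
#' study: 30 high-dose (HDAC, 3 g/m^2) and 35 intermediate-dose (IDAC,
#' 1 g/m^2) twins, with log-normal individual parameters and ages centred
#' on a median of 58.5 years. Deterministic given the seed.
#'
#' @param prior A [population_prior()].
#' @param seed Integer seed.
#' @param n_hdac,n_idac Cohort sizes.
#' @return List with `hdac` and `idac` (each a `ct_cohort` with
#'   provenance `"synthetic"`).
#' @export
make_virtual_trial <- function(prior = population_prior(), seed = 1L,
                               n_hdac = 30, n_idac = 35) {
  set.seed(seed)
  hd <- lapply(seq_len(n_hdac), function(i)
    sample_twin(sprintf("H%02d", i), "HDAC", prior))
  id <- lapply(seq_len(n_idac), function(i)
    sample_twin(sprintf("I%02d", i), "IDAC", prior))
  list(hdac = new_cohort(hd, "synthetic"), idac = new_cohort(id, "synthetic"))
}

#' Generate a noisy WBC observation series for one twin
#'
#' Simulates the twin under the plan and samples the observable WBC
#' (healthy WBC plus circulating blast contribution) on a clinical
#' cadence: `n_per_cycle` draws at 2--3-day gaps from the cycle start
#' (covering the leukopenic weeks in which CBCs are frequent), giving
#' about 24 observations over a 3-cycle course. Observations carry
#' multiplicative log-normal noise of the configured coefficient of
#' variation. Deterministic given the seed.
#'
#' @param twin A [digital_twin()].
#' @param plan A [treatment_plan()].
#' @param seed Integer seed.
#' @param noise_cv Observation coefficient of variation (default 0.15).
#' @param n_per_cycle Observations per cycle (default 8, i.e. ~24 per
#'   3-cycle course).
#' @param config Model configuration.
#' @return Data frame with `time` (days from consolidation start) and
#'   `wbc` (10^9/L).
#' @export
generate_observations <- function(twin, plan, seed = 1L, noise_cv = 0.15,
                                  n_per_cycle = 8,
                                  config = default_config()) {
  traj <- simulate_course(twin, plan, config)
  set.seed(seed)
  times <- numeric(0)
  for (k in seq_len(plan$n_cycles)) {
    s0 <- (k - 1) * plan$cycle_length
    gaps <- sample(2:3, n_per_cycle, replace = TRUE)
    times <- c(times, s0 + cumsum(gaps))
  }
  mod <- approx(traj$time, observed_wbc(traj, config), xout = times)$y
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- if (noise_cv > 0) exp(rnorm(length(times), 0, sdlog)) else 1
  data.frame(time = times, wbc = mod * noise)
}

#' Generate a pseudo-clinical recovery-time table
#'
#' Emulates a tabulated clinical WBC-recovery dataset (subject, cycle,
#' recovery days, arm, G-CSF flag, age) so the `simulated` covariate of
#' the combined marginal Cox analysis can be exercised end to end. This
#' is a synthetic stand-in, not a re-creation of any trial's data.
#'
#' Recovery days are drawn from a discrete-time proportional-hazards law:
#' a geometric-type baseline hazard from day `day_min` on, with arm,
#' G-CSF and age effects injected on the log-hazard scale.
#'
#' @param n_subjects Number of subjects.
#' @param n_cycles Cycles per subject.
#' @param beta Named numeric: log-hazard effects `arm123`, `gcsf`,
#'   `age_decades`.
#' @param p_arm123,p_gcsf Assignment probabilities.
#' @param base_hazard Daily baseline recovery hazard.
#' @param day_min First possible recovery day.
#' @param age_median,age_sd Age law (years).
#' @param seed Integer seed.
#' @return Data frame of recovery records: `subject_id`, `cycle`, `time`,
#'   `event`, `arm123`, `gcsf`, `age_decades`, `simulated` (all 0).
#' @export
make_pseudo_clinical_table <- function(n_subjects = 100, n_cycles = 3,
                                       beta = c(arm123 = log(2),
                                                gcsf = log(2),
                                                age_decades = -0.2),
                                       p_arm123 = 0.5, p_gcsf = 0.5,
                                       base_hazard = 0.05, day_min = 10,
                                       age_median = 50, age_sd = 8,
                                       seed = 1L) {
  set.seed(seed)
  arm <- rbinom(n_subjects, 1, p_arm123)
  gcsf <- rbinom(n_subjects, 1, p_gcsf)
  age10 <- rnorm(n_subjects, age_median, age_sd) / 10
  rows <- lapply(seq_len(n_subjects), function(i) {
    h <- min(0.95, base_hazard *
               exp(beta[["arm123"]] * arm[i] + beta[["gcsf"]] * gcsf[i] +
                   beta[["age_decades"]] * age10[i]))
    day <- day_min + rgeom_safe(n_cycles, h)
    data.frame(subject_id = sprintf("C%03d", i), cycle = seq_len(n_cycles),
               time = day, event = 1L, arm123 = arm[i], gcsf = gcsf[i],
               age_decades = age10[i], simulated = 0L)
  })
  do.call(rbind, rows)
}

rgeom_safe <- function(n, p) stats::rgeom(n, p)
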