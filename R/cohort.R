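#' Construct a digital twin
#'
#' The shared mechanistic model instantiated with one patient's individual
#' parameters plus demographics. The dose cohort determines the simulated
#' Ara-C dose: HDAC twins receive 3 g/m^2, IDAC twins 1 g/m^2.
#'
#' @param twin_id Identifier.
#' @param cohort `"HDAC"` or `"IDAC"`.
#' @param age Age in years.
#' @param bsa Body surface area in m^2 (1.2--2.6).
#' @param theta Individual parameters ([individual_parameters()]).
#' @return Object of class `ct_twin`.
#' @export
digital_twin <- function(twin_id, cohort = c("HDAC", "IDAC"), age, bsa, theta) {
  cohort <- match.arg(cohort)
  if (!is.numeric(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  if (!is.numeric(bsa) || bsa <= 1.2 || bsa >= 2.6)
    stop("bsa must lie in (1.2, 2.6)", call. = FALSE)
  if (!inherits(theta, "ct_theta")) theta <- do.call(individual_parameters, theta)
  structure(list(twin_id = as.character(twin_id), cohort = cohort,
                 age = age, bsa = bsa, theta = theta,
                 dose_g_per_m2 = if (cohort == "HDAC") 3 else 1),
            class = "ct_twin")
}

new_cohort <- function(twins, provenance) {
  ids <- vapply(twins, `[[`, "", "twin_id")
  if (anyDuplicated(ids)) stop("twin ids must be unique", call. = FALSE)
  structure(list(twins = twins, provenance = provenance), class = "ct_cohort")
}

#' @export
length.ct_cohort <- function(x) length(x$twins)

#' Write a cohort parameter table
#'
#' Delimited text in the per-twin parameter-table layout: one row per
#' twin with `twin_id`, `cohort`, `age_y`, `bsa_m2` and the six individual
#' parameters.
#'
#' @param cohort A `ct_cohort`.
#' @param path Output path (tab-separated).
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort$twins, function(tw)
    data.frame(twin_id = tw$twin_id, cohort = tw$cohort, age_y = tw$age,
               bsa_m2 = tw$bsa, B = tw$theta$B, gamma = tw$theta$gamma,
               k_tr = tw$theta$k_tr, slope_w = tw$theta$slope_w,
               p_l = tw$theta$p_l, l0 = tw$theta$l0))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load a cohort from a per-twin parameter table
#'
#' Reads a delimited table with columns `twin_id`, `cohort`, `age_y`,
#' `bsa_m2` and the six individual parameters. Column names can be
#' remapped via `col_map` to absorb external table layouts.
#'
#' @param path Path to a tab- or comma-separated table.
#' @param col_map Optional named character vector mapping the canonical
#'   names (names of the vector) to the file's column names.
#' @return A `ct_cohort` with provenance `"loaded"`.
#' @export
load_cohort <- function(path, col_map = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("twin_id", "cohort", "age_y", "bsa_m2",
            "B", "gamma", "k_tr", "slope_w", "p_l", "l0")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(tab))
        stop("mapped column '", col_map[[nm]], "' not in table", call. = FALSE)
      names(tab)[names(tab) == col_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  twins <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    for (p in c("B", "gamma", "k_tr", "slope_w", "p_l", "l0"))
      if (!is.finite(row[[p]]) || row[[p]] <= 0)
        stop("non-positive parameter '", p, "' in row ", i, call. = FALSE)
    digital_twin(row$twin_id, row$cohort, row$age_y, row$bsa_m2,
                 individual_parameters(row$B, row$gamma, row$k_tr,
                                       row$slope_w, row$p_l, row$l0))
  })
  new_cohort(twins, provenance = "loaded")
}

#' Split a cohort by dose group
#'
#' @param cohort A `ct_cohort`.
#' @return List with elements `HDAC` and `IDAC` (each a `ct_cohort`).
#' @export
split_cohort <- function(cohort) {
  lab <- vapply(cohort$twins, `[[`, "", "cohort")
  lapply(split(cohort$twins, factor(lab, levels = c("HDAC", "IDAC"))),
         new_cohort, provenance = cohort$provenance)
}

# sum of squared log-residuals of a parameter proposal against observations
fit_objective <- function(par_log, obs, twin, plan, config, l0) {
  theta <- tryCatch(
    individual_parameters(B = exp(par_log[1]), gamma = exp(par_log[2]),
                          k_tr = exp(par_log[3]), slope_w = exp(par_log[4]),
                          p_l = exp(par_log[5]), l0 = l0),
    error = function(e) NULL)
  if (is.null(theta)) return(rep(1e3, length(obs$time)))
  tw <- twin; tw$theta <- theta
  traj <- tryCatch(simulate_course(tw, plan, config),
                   error = function(e) NULL)
  if (is.null(traj)) return(rep(1e3, length(obs$time)))
  pred <- approx(traj$time, observed_wbc(traj, config), xout = obs$time)$y
  pred <- pmax(pred, 1e-6)
  log(obs$wbc) - log(pred)
}

#' Fit individual parameters to one twin's WBC series
#'
#' Multi-start Levenberg--Marquardt least squares on log WBC
#' (multiplicative error model): the five observable parameters `B`,
#' `gamma`, `k_tr`, `slope_w`, `p_l` are estimated on the log scale; the
#' initial blast burden `l0` is not identifiable from WBC series and is
#' held at its configured value. Starts are the supplied initial values
#' plus log-uniform perturbations, drawn from a fixed per-call seed stream
#' so the fit is deterministic.
#'
#' @param obs Data frame or list with `time` (days) and `wbc` (10^9/L);
#'   at least 10 observations.
#' @param plan The [treatment_plan()] under which the series was observed.
#' @param twin A [digital_twin()] supplying demographics (its `theta` is
#'   ignored except for `l0`).
#' @param init Initial [individual_parameters()] (e.g. population medians).
#' @param n_starts Number of local optimizations.
#' @param config Model configuration.
#' @param seed Seed for the start stream.
#' @return List with `theta` (fitted `ct_theta`), `residual` (sum of
#'   squared log residuals), `converged`, and `starts` (per-start residuals).
#' @export
fit_individual <- function(obs, plan, twin, init, n_starts = 3,
                           config = default_config(), seed = 1L) {
  if (length(obs$time) < 10)
    stop("at least 10 observations are required", call. = FALSE)
  l0 <- twin$theta$l0
  p0 <- log(unlist(init[c("B", "gamma", "k_tr", "slope_w", "p_l")]))
  starts <- list(p0)
  if (n_starts > 1) {
    rs <- local({ set.seed(seed); lapply(seq_len(n_starts - 1), function(i)
      p0 + runif(5, log(1 / 3), log(3))) })
    starts <- c(starts, rs)
  }
  best <- NULL
  trace <- numeric(0)
  for (p in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p, fn = fit_objective, obs = obs, twin = twin,
                         plan = plan, config = config, l0 = l0,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) { trace <- c(trace, NA_real_); next }
    rss <- sum(fit$fvec^2)
    trace <- c(trace, rss)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best))
    stop("all fit starts failed; residual trace: ",
         paste(signif(trace, 3), collapse = ", "), call. = FALSE)
  bp <- unname(exp(best$par))
  theta <- individual_parameters(B = bp[1], gamma = bp[2], k_tr = bp[3],
                                 slope_w = bp[4], p_l = bp[5], l0 = l0)
  list(theta = theta, residual = best$rss,
       converged = best$info %in% 1:4, starts = trace)
}
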