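# independent oracle: stratified Cox partial log-likelihood with Efron ties,
# written directly from the definition (risk sums per stratum), evaluated on
# a beta grid -- no survival-package code involved
efron_loglik <- function(beta, data, covar = "x") {
  ll <- 0
  for (st in unique(data$cycle)) {
    d <- data[data$cycle == st, ]
    r <- exp(beta * d[[covar]])
    for (t in sort(unique(d$time[d$event == 1]))) {
      D <- which(d$time == t & d$event == 1)
      R <- which(d$time >= t)
      sR <- sum(r[R]); sD <- sum(r[D]); m <- length(D)
      ll <- ll + sum(beta * d[[covar]][D])
      for (l in seq_len(m) - 1) ll <- ll - log(sR - (l / m) * sD)
    }
  }
  ll
}

grid_max <- function(data, covar = "x", lo = -4, hi = 4) {
  b <- seq(lo, hi, by = 0.001)
  ll <- vapply(b, efron_loglik, numeric(1), data = data, covar = covar)
  b0 <- b[which.max(ll)]
  b <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  ll <- vapply(b, efron_loglik, numeric(1), data = data, covar = covar)
  b[which.max(ll)]
}

test_that("toy-data coefficient matches the grid-search partial likelihood", {
  toy <- data.frame(
    subject_id = c("a", "b", "c", "a", "b", "c"),
    cycle = c(1, 1, 1, 2, 2, 2),
    time = c(12, 15, 15, 14, 18, 22),
    event = 1L,
    x = c(1, 0, 1, 1, 0, 0))
  oracle <- grid_max(toy)
  fit <- fit_wlw(toy, covariates = "x")
  expect_equal(fit$coef[fit$factor == "x"], oracle, tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(fit$ci_lo < fit$hr & fit$hr < fit$ci_hi)
})

test_that("label-randomized null data give an arm HR near 1 with covering CI", {
  set.seed(21)
  n <- 200
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = sprintf("s%03d", i), cycle = 1:3,
               time = 10 + rgeom(3, 0.12), event = 1L,
               arm123 = rbinom(1, 1, 0.5))
  }))
  fit <- fit_wlw(recs, covariates = "arm123")
  hr <- fit$hr[fit$factor == "arm123"]
  expect_gt(hr, 0.8); expect_lt(hr, 1.25)
  expect_true(fit$ci_lo[1] < 1 && fit$ci_hi[1] > 1)
})

test_that("a true hazard ratio of 2 is recovered at n = 500", {
  set.seed(33)
  n <- 500
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- rbinom(1, 1, 0.5)
    data.frame(subject_id = sprintf("s%03d", i), cycle = 1:3,
               time = rexp(3, rate = 0.05 * 2^x), event = 1L, arm123 = x)
  }))
  fit <- fit_wlw(recs, covariates = "arm123")
  hr <- fit$hr[fit$factor == "arm123"]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})

test_that("coefficients are invariant under uniform time rescaling", {
  set.seed(5)
  recs <- make_pseudo_clinical_table(n_subjects = 120, seed = 5)
  f1 <- fit_wlw(recs)
  recs2 <- recs; recs2$time <- recs2$time * 3.7
  f2 <- fit_wlw(recs2)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("with one record per subject the clustered and unclustered robust
           variances agree", {
  recs <- make_pseudo_clinical_table(n_subjects = 150, n_cycles = 1, seed = 9)
  fit <- fit_wlw(recs)
  plain <- survival::coxph(
    survival::Surv(time, event) ~ arm123 + gcsf + age_decades +
      survival::strata(cycle),
    data = recs, ties = "efron", robust = TRUE)
  expect_equal(fit$robust_se,
               unname(summary(plain)$coefficients[, "robust se"]),
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  one_time <- data.frame(subject_id = c("a", "b"), cycle = 1,
                         time = c(5, 5), event = 1L, x = c(0, 1))
  expect_error(fit_wlw(one_time, covariates = "x"), "distinct event times")
  col <- make_pseudo_clinical_table(n_subjects = 30, seed = 2)
  col$dup <- col$arm123
  expect_error(fit_wlw(col, covariates = c("arm123", "dup")), "collinear")
})

test_that("paired comparison counts strict reductions and is antisymmetric", {
  base <- expand.grid(twin_id = c("t1", "t2"), schedule_id = "S1", cycle = 1:3,
                      stringsAsFactors = FALSE)
  k1 <- base; k1$kpiL <- c(18, 20, 17, 21, 19, 22)
  k2 <- base; k2$kpiL <- k1$kpiL + 2
  r <- paired_fraction_reduced(k1, k2)
  expect_equal(r$fraction_reduced, 1.0)
  expect_equal(r$median_reduction, 2.0)
  same <- paired_fraction_reduced(k1, k1)
  expect_equal(same$fraction_reduced, 0.0)
  expect_equal(same$median_reduction, 0.0)
  # mixed signs: exhaustive hand count over 5 pairs
  b5 <- data.frame(twin_id = paste0("t", 1:5), schedule_id = "S", cycle = 1,
                   stringsAsFactors = FALSE)
  a <- b5; a$kpiL <- c(10, 15, 12, 20, 11)
  b <- b5; b$kpiL <- c(12, 14, 12, 24, 13)
  # diffs b - a: 2, -1, 0, 4, 2 -> strict reductions 3/5, median 2
  r5 <- paired_fraction_reduced(a, b)
  expect_equal(r5$fraction_reduced, 3 / 5)
  expect_equal(r5$median_reduction, 2)
  swap <- paired_fraction_reduced(b, a)
  expect_equal(swap$fraction_reduced, 1 / 5)  # strict increases of the original
  expect_equal(swap$median_reduction, -2)
  # undefined pairs are dropped and counted; orphans are an error
  a2 <- a; a2$kpiL[2] <- NA
  r4 <- paired_fraction_reduced(a2, b)
  expect_equal(r4$n_pairs, 4); expect_equal(r4$n_dropped, 1)
  expect_error(paired_fraction_reduced(a[-1, ], b), "unpaired")
})

test_that("pseudo-clinical effect injection is recovered by the fitter", {
  null_tab <- make_pseudo_clinical_table(
    n_subjects = 200, beta = c(arm123 = 0, gcsf = 0, age_decades = 0),
    seed = 11)
  f0 <- fit_wlw(null_tab)
  expect_true(f0$ci_lo[f0$factor == "arm123"] < 1 &&
              f0$ci_hi[f0$factor == "arm123"] > 1)
  eff <- make_pseudo_clinical_table(
    n_subjects = 500, beta = c(arm123 = log(2), gcsf = 0.3,
                               age_decades = -0.2), seed = 12)
  f1 <- fit_wlw(eff)
  hr <- f1$hr[f1$factor == "arm123"]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})
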