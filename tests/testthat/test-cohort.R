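test_that("cohort tables round-trip through write and load", {
  coh <- make_virtual_trial(seed = 1, n_hdac = 4, n_idac = 3)
  all65 <- cytotwin:::new_cohort(c(coh$hdac$twins, coh$idac$twins), "synthetic")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(all65, path)
  back <- load_cohort(path)
  expect_equal(length(back), 7)
  expect_equal(back$provenance, "loaded")
  for (i in seq_along(all65$twins)) {
    expect_equal(back$twins[[i]]$twin_id, all65$twins[[i]]$twin_id)
    expect_equal(unlist(back$twins[[i]]$theta), unlist(all65$twins[[i]]$theta),
                 tolerance = 1e-12)
  }
})

test_that("schema violations are reported with the offending column or row", {
  coh <- make_virtual_trial(seed = 2, n_hdac = 3, n_idac = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh$hdac, path)
  tab <- read.delim(path)
  tab$gamma <- NULL
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(path2), "gamma")
  tab2 <- read.delim(path)
  tab2$k_tr[2] <- -1
  write.table(tab2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(path2), "row 2")
  # column remapping absorbs external layouts
  tab3 <- read.delim(path)
  names(tab3)[names(tab3) == "k_tr"] <- "ktr_est"
  write.table(tab3, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  remap <- load_cohort(path2, col_map = c(k_tr = "ktr_est"))
  expect_equal(length(remap), 3)
})

test_that("a 65-row table with 30/35 labels splits into the two dose cohorts", {
  coh <- make_virtual_trial(seed = 3)
  all65 <- cytotwin:::new_cohort(c(coh$hdac$twins, coh$idac$twins), "synthetic")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(all65, path)
  sp <- split_cohort(load_cohort(path))
  expect_equal(length(sp$HDAC), 30)
  expect_equal(length(sp$IDAC), 35)
  expect_equal(sp$HDAC$twins[[1]]$dose_g_per_m2, 3)
  expect_equal(sp$IDAC$twins[[1]]$dose_g_per_m2, 1)
})

test_that("noiseless series are refit to the generating parameters", {
  plan <- treatment_plan("AC123", 3, 5, 5, 42)
  coh <- make_virtual_trial(seed = 5)
  tw <- coh$hdac$twins[[2]]
  obs <- generate_observations(tw, plan, seed = 7, noise_cv = 0)
  init <- median_theta()
  fit <- fit_individual(obs, plan, tw, init, n_starts = 1, seed = 1)
  tr <- unlist(tw$theta)[c("B", "gamma", "k_tr")]
  es <- unlist(fit$theta)[c("B", "gamma", "k_tr")]
  expect_true(all(abs(es - tr) / tr < 0.01))
  expect_true(fit$converged)
})

test_that("starting at the truth is at least as good as perturbed starts", {
  plan <- treatment_plan("AC123", 3, 5, 5, 42)
  coh <- make_virtual_trial(seed = 8)
  tw <- coh$hdac$twins[[1]]
  obs <- generate_observations(tw, plan, seed = 2, noise_cv = 0.1)
  fit_truth <- fit_individual(obs, plan, tw, init = tw$theta,
                              n_starts = 1, seed = 1)
  fit_pop <- fit_individual(obs, plan, tw, init = median_theta(),
                            n_starts = 1, seed = 1)
  # both starts land in the same basin; allow optimizer-tolerance slack
  expect_lte(fit_truth$residual, fit_pop$residual * (1 + 1e-3) + 1e-4)
})

test_that("the noiseless residual surface has its minimum at the truth", {
  # identifiability guard: +/-50% perturbations of each parameter raise the
  # sum of squared log residuals above its value at the generating values
  plan <- treatment_plan("AC123", 3, 5, 5, 42)
  cfg <- default_config()
  coh <- make_virtual_trial(seed = 9)
  tw <- coh$hdac$twins[[3]]
  obs <- generate_observations(tw, plan, seed = 4, noise_cv = 0)
  rss <- function(theta) {
    par_log <- log(unlist(theta[c("B", "gamma", "k_tr", "slope_w", "p_l")]))
    sum(cytotwin:::fit_objective(par_log, obs, tw, plan, cfg, tw$theta$l0)^2)
  }
  at_truth <- rss(tw$theta)
  expect_lt(at_truth, 1e-12)
  for (p in c("B", "gamma", "k_tr", "slope_w", "p_l")) {
    for (f in c(0.5, 1.5)) {
      th <- tw$theta; th[[p]] <- th[[p]] * f
      expect_gt(rss(th), at_truth + 1e-8)
    }
  }
})

test_that("fits require a minimally informative series", {
  plan <- treatment_plan("AC123", 3, 5, 5, 42)
  tw <- median_twin()
  expect_error(fit_individual(list(time = 1:5, wbc = rep(5, 5)), plan, tw,
                              median_theta()), "at least 10")
})
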