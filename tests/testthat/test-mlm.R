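test_that("noiseless quadratic data identify the fixed effects exactly", {
  g <- growth_params(B0 = 2, B1 = -0.08, B2 = 0.004,
                     var_u0 = 0, var_u1 = 0, var_resid = 0)
  cfg <- sim_config(n_individuals = 60, prop_women = 1, domains = "Gf",
                    retention = 1,
                    growth = list(women = list(Gf = g), men = list(Gf = g)),
                    hazard = list(women = hazard_params(),
                                  men = hazard_params()), seed = 5)
  sim <- simulate_cohort(cfg)
  fit <- fit_mlm(sim$panel, sim$cohort,
                 model_spec("quadratic", stratum = "women", domain = "Gf"),
                 light_mcmc(), seed = 2)
  pm <- stats::setNames(fit$summary$mean, fit$summary$param)
  expect_equal(unname(pm[c("B0", "B1", "B2")]), c(2, -0.08, 0.004),
               tolerance = 1e-3)
  expect_lt(pm[["var_resid"]], 1e-3)
  expect_lt(pm[["var_u1"]], 1e-2)
})

test_that("fixed effects are recovered without bias under ignorable dropout", {
  tr <- recovery_truth()
  tr$hazard$alpha1 <- 0
  tr$hazard$alpha2 <- 0
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  est <- t(vapply(1:6, function(r) {
    sim <- simulate_cohort(recovery_config(800, seed = 600 + r, truth = tr))
    f <- fit_mlm(sim$panel, sim$cohort, spec,
                 mcmc_control(chains = 2, iter = 700, burnin = 400),
                 seed = r)
    stats::setNames(f$summary$mean[match(c("B0", "B1", "B2"),
                                         f$summary$param)],
                    c("B0", "B1", "B2"))
  }, c(B0 = 0, B1 = 0, B2 = 0)))
  truth <- tr$values[c("B0", "B1", "B2")]
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-8))
})

test_that("restricting to decedents lowers the estimated intercept under MNAR", {
  tr <- recovery_truth()
  tr$hazard$alpha1 <- -0.03  # strong intercept-driven mortality
  sim <- simulate_cohort(recovery_config(2000, seed = 77, truth = tr))
  spec_all <- model_spec("quadratic", subset = "all", stratum = "women",
                         domain = "Gf")
  spec_dec <- model_spec("quadratic", subset = "decedents",
                         stratum = "women", domain = "Gf")
  f_all <- fit_mlm(sim$panel, sim$cohort, spec_all, light_mcmc(), seed = 1)
  f_dec <- fit_mlm(sim$panel, sim$cohort, spec_dec, light_mcmc(), seed = 1)
  b0 <- function(f) f$summary$mean[match("B0", f$summary$param)]
  expect_lt(b0(f_dec), b0(f_all))
})

test_that("empty subsets and unknown strata are errors", {
  sim <- small_sim()
  cohort <- sim$cohort
  cohort$event <- 0
  expect_error(fit_mlm(sim$panel, cohort,
                       model_spec(subset = "decedents")), "empty subset")
})

test_that("scores of single-observation persons shrink toward zero", {
  sim <- simulate_cohort(recovery_config(600, seed = 55))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  fit <- fit_mlm(sim$panel, sim$cohort, spec, light_mcmc(), seed = 9)
  occ <- table(sim$panel$person_id)
  one_obs <- as.integer(names(occ)[occ == 1])
  sc <- ranef_scores(fit)
  pm <- stats::setNames(fit$summary$mean, fit$summary$param)
  sd1 <- sqrt(pm[["var_u1"]])
  s1 <- sc[sc$person_id %in% one_obs, ]
  expect_gt(nrow(s1), 5)
  # posterior mean near prior mean, posterior SD near prior SD
  expect_lt(mean(abs(s1$u1_hat)), 0.35 * sd1)
  expect_gt(mean(s1$u1_sd), 0.8 * sd1)
  # latent truth correlates with the estimated scores overall
  lat <- sim$latent[match(sc$person_id, sim$latent$person_id), ]
  expect_gt(stats::cor(lat$u0, sc$u0_hat), 0.8)
})

test_that("pseudo-R2 is the proportional reduction in residual variance", {
  mk <- function(vr, tag) {
    structure(list(summary = posterior_summary(list(
      matrix(vr, 10, 1, dimnames = list(NULL, "var_resid")),
      matrix(vr, 10, 1, dimnames = list(NULL, "var_resid")))),
      nobs = 50, data = list(y = rep(1, 50))), class = "mlm_fit")
  }
  expect_equal(pseudo_r2(mk(0.5), mk(1.0)), 0.5)
  expect_equal(pseudo_r2(mk(0.7), mk(0.7)), 0)
  bad <- mk(0.5); bad$nobs <- 51
  expect_error(pseudo_r2(bad, mk(1)), "same data")
})

test_that("age signal strength orders pseudo-R2 across domains", {
  # Gf-like truth has strong age-related change; Gc-like truth is flat
  sim <- small_sim(600, seed = 12)
  r2 <- vapply(c("Gc", "Gf"), function(d) {
    spec_q <- model_spec("quadratic", stratum = "women", domain = d)
    spec_0 <- model_spec("intercept_only", stratum = "women", domain = d)
    f <- fit_mlm(sim$panel, sim$cohort, spec_q, light_mcmc(), seed = 4)
    f0 <- fit_mlm(sim$panel, sim$cohort, spec_0, light_mcmc(), seed = 4)
    pseudo_r2(f, f0)
  }, 0)
  expect_gt(r2[["Gf"]], r2[["Gc"]])
})

test_that("trajectory prediction respects centering and flatness", {
  set.seed(1)
  dm <- cbind(B0 = rnorm(400, 1.7, 0.05), B1 = 0, B2 = 0)
  fit <- fake_mlm_fit(dm)
  tr <- predict_trajectory(fit, ages = c(55, 65, 80))
  expect_equal(diff(tr$mean), c(0, 0), tolerance = 1e-12)
  expect_equal(tr$mean[tr$age == 65],
               mean(dm[, "B0"]), tolerance = 1e-12)
  expect_warning(predict_trajectory(fit, ages = c(40)), "support")
})

test_that("credible band widens toward the sparse age extremes", {
  sim <- small_sim(500, seed = 19)
  fit <- fit_mlm(sim$panel, sim$cohort,
                 model_spec("quadratic", stratum = "women", domain = "Gf"),
                 light_mcmc(), seed = 6)
  tr <- suppressWarnings(predict_trajectory(fit, ages = c(66, 87)))
  w <- tr$hi - tr$lo
  expect_gt(w[2], w[1])
})

test_that("model comparison orders nested fits and applies the BIC formula", {
  sim <- small_sim(500, seed = 19)
  specs <- lapply(c("intercept_only", "linear", "quadratic"), model_spec,
                  stratum = "women", domain = "Gf")
  fits <- lapply(specs, function(s)
    fit_mlm(sim$panel, sim$cohort, s, light_mcmc(), seed = 8))
  cmp <- compare_fits(fits, chisq = TRUE)
  # Gf truth is quadratic: richer models must win on BIC
  expect_lt(cmp$bic[3], cmp$bic[1])
  expect_equal(cmp$bic, cmp$deviance + cmp$k * log(fits[[1]]$nobs))
  expect_equal(cmp$k, c(1 + 1 + 1, 2 + 3 + 1, 3 + 3 + 1))
  # duplicate fit: identical deviance
  cmp2 <- compare_fits(list(fits[[3]], fits[[3]]))
  expect_equal(cmp2$deviance[1], cmp2$deviance[2])
  # chi-square comparison of non-nested (out-of-order) fits is an error
  expect_error(compare_fits(rev(fits), chisq = TRUE), "nested")
  # different data is an error
  sim2 <- small_sim(400, seed = 20)
  f_other <- fit_mlm(sim2$panel, sim2$cohort, specs[[1]], light_mcmc(),
                     seed = 8)
  expect_error(compare_fits(list(fits[[1]], f_other)), "identical data")
})

test_that("convergence diagnostics are attached rather than silently passed", {
  sim <- small_sim(200, seed = 23)
  fit <- fit_mlm(sim$panel, sim$cohort,
                 model_spec("quadratic", stratum = "women", domain = "Gf"),
                 mcmc_control(chains = 2, iter = 2000, burnin = 800),
                 seed = 2)
  expect_named(fit$converged)
  expect_true(all(fit$summary$lo <= fit$summary$mean &
                    fit$summary$mean <= fit$summary$hi))
})
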