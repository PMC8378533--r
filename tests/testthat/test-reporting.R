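test_that("scaled hazard ratio arithmetic and monotonicity", {
  expect_equal(scaled_hazard_ratio(0, 3.7), 1)
  expect_equal(scaled_hazard_ratio(-2, 0), 1)
  expect_equal(scaled_hazard_ratio(log(2), 1), 2)
  expect_error(scaled_hazard_ratio(1, -0.1), "non-negative")
  coefs <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(scaled_hazard_ratio(coefs, 0.8)) > 0))
  expect_true(all(scaled_hazard_ratio(coefs, 0.8) > 0))
})

test_that("scaled HR tables report model-based and empirical conventions", {
  sim <- small_sim(300, seed = 42)
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  jf <- fit_joint(sim$panel, sim$cohort, spec, light_mcmc(), seed = 3)
  tab <- scaled_hr_table(jf)
  expect_setequal(tab$param, c("alpha1", "alpha2"))
  pm <- stats::setNames(jf$summary$mean, jf$summary$param)
  i <- match("alpha2", tab$param)
  expect_equal(tab$hr_model[i],
               exp(tab$coef[i] * sqrt(pm[["var_u1"]])), tolerance = 1e-12)
  # shrunken empirical SD is below the model-based SD
  ts <- run_two_stage(sim$panel, sim$cohort, spec, light_mcmc(), seed = 3)
  tab2 <- scaled_hr_table(ts)
  expect_lt(tab2$sd_empirical[tab2$param == "alpha2"],
            tab2$sd_model[tab2$param == "alpha2"])
})

test_that("CI width contrasts are exact ratios and recomputable from draws", {
  sim <- small_sim(300, seed = 42)
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  f <- fit_mlm(sim$panel, sim$cohort, spec, light_mcmc(), seed = 3)
  r <- ci_width_contrast(f, f, c("B0", "B1", "var_resid"))
  expect_equal(unname(r), c(1, 1, 1))
  expect_error(ci_width_contrast(f, f, "nonexistent"), "missing")
  draws <- do.call(rbind, attr(f$summary, "draws"))
  w_draws <- diff(unname(stats::quantile(draws[, "B1"], c(0.025, 0.975))))
  i <- match("B1", f$summary$param)
  expect_equal(f$summary$hi[i] - f$summary$lo[i], w_draws,
               tolerance = 1e-10)
})

test_that("standardized change per decade follows the stated conventions", {
  set.seed(2)
  flat <- fake_mlm_fit(cbind(B0 = rnorm(200, 1, 0.01), B1 = 0, B2 = 0,
                             var_u0 = 1, var_resid = 1))
  expect_equal(as.numeric(delta_z_per_decade(flat, sd_ref = 1)), 0,
               tolerance = 1e-9)
  lin <- fake_mlm_fit(cbind(B0 = rnorm(200, 0, 0.01), B1 = -0.05, B2 = 0,
                            var_u0 = 1, var_resid = 1))
  expect_equal(as.numeric(delta_z_per_decade(lin, sd_ref = 1)), -0.5,
               tolerance = 1e-9)
  # two windows reported side by side from the same posterior
  quad <- fake_mlm_fit(cbind(B0 = rnorm(200, 0, 0.01), B1 = -0.02,
                             B2 = -0.002, var_u0 = 4, var_resid = 1))
  d1 <- delta_z_per_decade(quad, window = c(65, 75))
  d2 <- delta_z_per_decade(quad, window = c(70, 80))
  expect_equal(attr(d1, "window"), c(65, 75))
  expect_equal(attr(d2, "window"), c(70, 80))
  expect_lt(d2, d1)  # steeper later under negative curvature
  expect_warning(delta_z_per_decade(quad, window = c(85, 95)), "window")
})

test_that("occasion summaries match hand computation on a tiny panel", {
  cohort <- data.frame(person_id = 1:3, sex = c("women", "women", "men"),
                       start_age_c = c(0, 2, -1), smoker = 0, srh = 3,
                       event = c(1, 0, 1), time = c(5, 20, 2.5))
  panel <- data.frame(
    person_id = c(1, 1, 2, 2, 3),
    occasion = c(1, 2, 1, 2, 1),
    age_c = c(0, 4, 2, 6, -1),
    domain = "Gf",
    score = c(1, 2, 3, 4, 5))
  s <- summarize_panel(panel, cohort)
  w1 <- s[s$stratum == "women" & s$occasion == 1, ]
  expect_equal(w1$n, 2)
  expect_equal(w1$cum_deaths, 0)
  expect_equal(w1$median_age, 66)  # ages 65 and 67
  expect_equal(w1$mean_Gf, 2)
  w2 <- s[s$stratum == "women" & s$occasion == 2, ]
  expect_equal(w2$n, 2)
  expect_equal(w2$median_age, 70)
  m1 <- s[s$stratum == "men" & s$occasion == 1, ]
  expect_equal(m1$n, 1)
  # men have no occasion 2: the row is omitted
  expect_equal(nrow(s[s$stratum == "men", ]), 1)
  expect_error(summarize_panel(transform(panel, person_id = person_id + 10),
                               cohort), "absent")
})

test_that("occasion counts decrease and cumulative deaths increase by design", {
  sim <- small_sim(800, seed = 71)
  s <- summarize_panel(sim$panel, sim$cohort)
  for (st in unique(s$stratum)) {
    ss <- s[s$stratum == st, ]
    ss <- ss[order(ss$occasion), ]
    expect_true(all(diff(ss$n) < 0))
    expect_true(all(diff(ss$cum_deaths) >= 0))
  }
})

test_that("diagnostics quantify autocorrelation, chain agreement and short chains", {
  set.seed(8)
  wn <- matrix(rnorm(4000), 2000, 2,
               dimnames = list(NULL, c("a", "b")))
  d <- mcmc_diagnostics(list(wn, wn + 0))
  expect_true(all(abs(d$autocorr["a", ]) < 4 / sqrt(2000)))
  # duplicated chains: convergence statistic ~ 1
  expect_true(all(abs(d$table$rhat - 1) < 0.01))
  expect_true(all(d$table$flag == ""))
  # a strongly autocorrelated short chain is flagged
  rw <- cbind(a = cumsum(rnorm(300)), b = rnorm(300))
  rw2 <- cbind(a = cumsum(rnorm(300)), b = rnorm(300))
  d2 <- mcmc_diagnostics(list(rw, rw2))
  expect_true(d2$table$flag[d2$table$param == "a"] != "")
  # draws stripped from a summary: error advising retention
  s <- posterior_summary(list(wn))
  attr(s, "draws") <- NULL
  expect_error(mcmc_diagnostics(s), "retention|re-run")
  # plot export writes one file per parameter
  pd <- file.path(tempdir(), "diagplots")
  unlink(pd, recursive = TRUE)
  mcmc_diagnostics(list(wn, wn), plot_dir = pd)
  expect_length(list.files(pd, pattern = "\\.png$"), 2)
})

test_that("report tables regenerate identically from stored fit artifacts", {
  sim <- small_sim(300, seed = 42)
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  jf <- fit_joint(sim$panel, sim$cohort, spec, light_mcmc(), seed = 3)
  expect_identical(scaled_hr_table(jf), scaled_hr_table(jf))
  expect_identical(suppressWarnings(extract_shared_association(jf)),
                   suppressWarnings(extract_shared_association(jf)))
})
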