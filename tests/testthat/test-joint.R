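test_that("joint log-posterior matches the brute-force oracle on toy data", {
  sim <- simulate_cohort(recovery_config(10, seed = 13))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  set.seed(2)
  n <- length(unique(sim$panel$person_id))
  pars <- toy_params()
  pars$u <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 0.25))
  lp <- joint_log_posterior(pars, sim$panel, sim$cohort, spec)
  oracle <- brute_joint_lp(pars, sim$panel, sim$cohort, spec,
                           prior_control())
  expect_equal(lp, oracle, tolerance = 1e-8)
})

test_that("with zero shared parameters the joint posterior separates", {
  sim <- simulate_cohort(recovery_config(25, seed = 14))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  set.seed(3)
  n <- length(unique(sim$panel$person_id))
  pars <- toy_params(alpha = c(0, 0))
  pars$u <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 0.25))
  lp_joint <- joint_log_posterior(pars, sim$panel, sim$cohort, spec)
  lp_mlm <- mlm_log_posterior(
    list(B = pars$growth$B, sigma2 = pars$growth$sigma2,
         Sigma = pars$growth$Sigma, u = pars$u),
    sim$panel, sim$cohort, spec)
  ch <- sim$cohort[sim$cohort$sex == "women", ]
  ch <- ch[order(ch$person_id), ]
  d <- data.frame(time = ch$time, event = ch$event, u0 = pars$u[, 1],
                  u1 = pars$u[, 2])
  lp_ph <- ph_log_posterior(
    list(baseline = pars$hazard$baseline, coef = c(u0 = 0, u1 = 0)), d)
  expect_equal(lp_joint, lp_mlm + lp_ph, tolerance = 1e-10)
})

test_that("doubling the residual SD changes the posterior by the Gaussian amount", {
  sim <- simulate_cohort(recovery_config(15, seed = 16))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  set.seed(5)
  n <- length(unique(sim$panel$person_id))
  pars <- toy_params()
  pars$u <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 0.25))
  lp1 <- joint_log_posterior(pars, sim$panel, sim$cohort, spec)
  pars2 <- pars
  pars2$growth$sigma2 <- 4 * pars$growth$sigma2
  lp2 <- joint_log_posterior(pars2, sim$panel, sim$cohort, spec)
  # analytic: Gaussian term per observation plus the sigma2 prior change
  pn <- sim$panel
  md_a <- pn$age_c
  pid <- match(pn$person_id, sort(unique(pn$person_id)))
  mu <- 0.3 + 0.05 * md_a - 0.015 * md_a^2 + pars$u[pid, 1] +
    pars$u[pid, 2] * md_a
  SS <- sum((pn$score - mu)^2)
  nobs <- nrow(pn)
  s2 <- pars$growth$sigma2
  pr <- prior_control()
  dlong <- -nobs * log(2) - SS / (2 * 4 * s2) + SS / (2 * s2)
  dprior <- (dgamma(1 / (4 * s2), pr$resid_a, rate = pr$resid_b, log = TRUE) -
               2 * log(4 * s2)) -
    (dgamma(1 / s2, pr$resid_a, rate = pr$resid_b, log = TRUE) -
       2 * log(s2))
  expect_equal(lp2 - lp1, dlong + dprior, tolerance = 1e-8)
})

test_that("non-finite contributions are reported with person ids", {
  sim <- simulate_cohort(recovery_config(5, seed = 18))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  pars <- toy_params()
  n <- length(unique(sim$panel$person_id))
  pars$u <- matrix(0, n, 2)
  pars$u[2, 1] <- Inf
  expect_error(joint_log_posterior(pars, sim$panel, sim$cohort, spec),
               "person id")
})

test_that("standalone initialization is consumed and mismatches are named", {
  sim <- small_sim(250, seed = 44)
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  mlm <- fit_mlm(sim$panel, sim$cohort, spec, light_mcmc(), seed = 1)
  jf <- fit_joint(sim$panel, sim$cohort, spec, light_mcmc(),
                  init = list(mlm = mlm), seed = 2)
  expect_s3_class(jf, "joint_fit")
  # an intercept-only standalone fit cannot initialize a quadratic joint fit
  mlm0 <- fit_mlm(sim$panel, sim$cohort,
                  model_spec("intercept_only", stratum = "women",
                             domain = "Gf"), light_mcmc(), seed = 1)
  expect_error(fit_joint(sim$panel, sim$cohort, spec, light_mcmc(),
                         init = list(mlm = mlm0), seed = 2),
               "dimension mismatch")
  expect_error(fit_joint(sim$panel, sim$cohort, spec, light_mcmc(),
                         init = list(alpha = c(1, 2, 3)), seed = 2),
               "alpha")
})

test_that("shared-association extraction agrees with a raw-draw quantile oracle", {
  sim <- simulate_cohort(recovery_config(400, seed = 47))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  fit <- fit_joint(sim$panel, sim$cohort, spec,
                   mcmc_control(chains = 2, iter = 700, burnin = 400),
                   seed = 6)
  assoc <- suppressWarnings(extract_shared_association(fit))
  expect_setequal(assoc$param, c("alpha1", "alpha2"))
  draws <- do.call(rbind, attr(fit$summary, "draws"))
  for (p in assoc$param) {
    qs <- unname(stats::quantile(draws[, p], c(0.025, 0.975)))
    i <- match(p, assoc$param)
    expect_equal(assoc$lo[i], qs[1], tolerance = 1e-12)
    expect_equal(assoc$hi[i], qs[2], tolerance = 1e-12)
    expect_equal(assoc$significant[i], qs[1] > 0 || qs[2] < 0)
  }
  # a CI straddling zero is not flagged (construct directly)
  fake <- fit
  fake$summary$lo[fake$summary$param == "alpha1"] <- -1
  fake$summary$hi[fake$summary$param == "alpha1"] <- 1
  out <- suppressWarnings(extract_shared_association(fake))
  expect_false(out$significant[out$param == "alpha1"])
})

test_that("flipping the sign of all scores flips the growth and association signs", {
  tr <- recovery_truth()
  sim <- simulate_cohort(recovery_config(600, seed = 49, truth = tr))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  mc <- mcmc_control(chains = 2, iter = 700, burnin = 400)
  f1 <- fit_joint(sim$panel, sim$cohort, spec, mc, seed = 8)
  panel_flip <- sim$panel
  panel_flip$score <- -panel_flip$score
  f2 <- fit_joint(panel_flip, sim$cohort, spec, mc, seed = 8)
  get <- function(f, p) f$summary$mean[match(p, f$summary$param)]
  sdp <- function(f, p) {
    i <- match(p, f$summary$param)
    (f$summary$hi[i] - f$summary$lo[i]) / 3.92
  }
  for (p in c("B1", "B2", "alpha2")) {
    tol <- 4 * sqrt(sdp(f1, p)^2 + sdp(f2, p)^2) + 1e-6
    expect_lt(abs(get(f2, p) + get(f1, p)), tol)
  }
  # variance components are sign-invariant
  expect_equal(get(f2, "var_u1"), get(f1, "var_u1"),
               tolerance = 0.2 * get(f1, "var_u1") + 1e-6)
})
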