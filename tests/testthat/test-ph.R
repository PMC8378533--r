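test_that("log-likelihood reduces to closed forms in degenerate cases", {
  # one person, event at t = 1 under unit constant hazard: log h - H = -1
  d <- data.frame(time = 1, event = 1)
  expect_equal(
    log_likelihood_ph(list(baseline = constant_hazard(1),
                           coef = numeric(0)), d), -1)
  # with all coefficients zero the likelihood is the exponential-model form
  set.seed(4)
  d2 <- data.frame(time = rexp(40, 0.2), event = rbinom(40, 1, 0.7),
                   x = rnorm(40))
  lam <- 0.31
  ll <- log_likelihood_ph(list(baseline = constant_hazard(lam),
                               coef = c(x = 0)), d2)
  expect_equal(ll, sum(d2$event) * log(lam) - lam * sum(d2$time),
               tolerance = 1e-12)
})

test_that("piecewise likelihood matches a numerical-integration oracle", {
  set.seed(11)
  n <- 25
  d <- data.frame(time = rexp(n, 0.15) + 0.05, event = rbinom(n, 1, 0.6),
                  x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  bl <- piecewise_hazard(c(2, 5, 9), c(0.05, 0.12, 0.2, 0.35))
  coef <- c(x1 = 0.4, x2 = -0.7)
  ll <- log_likelihood_ph(list(baseline = bl, coef = coef), d)
  lin <- 0.4 * d$x1 - 0.7 * d$x2
  oracle <- 0
  for (i in seq_len(n)) {
    H <- stats::integrate(function(s) hazard_rate(bl, s), 0, d$time[i],
                          subdivisions = 2000L, rel.tol = 1e-12)$value
    oracle <- oracle +
      d$event[i] * (log(hazard_rate(bl, d$time[i])) + lin[i]) -
      H * exp(lin[i])
  }
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("degenerate survival inputs raise the documented errors", {
  d <- data.frame(time = c(2, 3), event = c(0, 0), x = c(1, 2))
  expect_error(fit_ph(d, "x"), "censored")
  d2 <- data.frame(time = rexp(50) + 0.1, event = 1,
                   x = rnorm(50))
  d2$x2 <- d2$x  # duplicated covariate column
  expect_warning(fit_ph(d2, c("x", "x2"), mcmc = light_mcmc()),
                 "collinear")
})

test_that("smoking-like exposure recovers a positive mortality coefficient", {
  set.seed(21)
  n <- 2000
  smoker <- rbinom(n, 1, 0.25)
  u <- runif(n)
  t <- sample_survival_time(u, 0.3 * smoker, constant_hazard(0.05))
  d <- data.frame(time = pmin(t, 30), event = as.integer(t <= 30),
                  smoker = smoker)
  fit <- fit_ph(d, "smoker", mcmc = mcmc_control(chains = 2, iter = 800,
                                                 burnin = 400), seed = 5)
  s <- fit$summary[fit$summary$param == "smoker", ]
  expect_gt(s$mean, 0)
  expect_gt(s$lo, 0)  # CI excludes 0 at this n
  expect_lt(abs(s$mean - 0.3), 0.15)
})

test_that("simulated hazard coefficients are covered by 95% CIs", {
  # recovery across replicates: gamma and alpha-style coefficients
  truth <- c(x = 0.4, z = -0.8)
  hits <- 0; total <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    n <- 1000
    x <- rnorm(n); z <- rnorm(n, 0, 0.5)
    t <- sample_survival_time(runif(n), 0.4 * x - 0.8 * z,
                              piecewise_hazard(c(4, 10), c(0.03, 0.07, 0.15)))
    d <- data.frame(time = pmin(t, 25), event = as.integer(t <= 25),
                    x = x, z = z)
    fit <- fit_ph(d, c("x", "z"),
                  mcmc = mcmc_control(chains = 2, iter = 600, burnin = 300),
                  seed = r)
    for (p in names(truth)) {
      s <- fit$summary[fit$summary$param == p, ]
      hits <- hits + (s$lo <= truth[p] && truth[p] <= s$hi)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("sampled parameters always imply a valid survival function", {
  sim <- small_sim(300, seed = 42)
  ch <- sim$cohort[sim$cohort$sex == "women", ]
  fit <- fit_ph(data.frame(time = ch$time, event = ch$event,
                           x = ch$start_age_c),
                "x", mcmc = light_mcmc(), seed = 2)
  draws <- do.call(rbind, attr(fit$summary, "draws"))
  lam_cols <- grep("^lambda", colnames(draws))
  expect_true(all(draws[, lam_cols] > 0))
  # survival implied by any draw is monotone non-increasing with S(0) = 1
  bl <- piecewise_hazard(fit$cuts, draws[7, lam_cols])
  tt <- seq(0, 40, by = 0.5)
  S <- exp(-cum_hazard(bl, tt))
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 0))
})

test_that("latent-truth scores recover alpha while shrunken scores attenuate", {
  tr <- recovery_truth()
  sim <- simulate_cohort(recovery_config(1500, seed = 91, truth = tr))
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  mlm <- fit_mlm(sim$panel, sim$cohort, spec, light_mcmc(), seed = 3)
  lat <- sim$latent[match(mlm$scores$person_id, sim$latent$person_id), ]
  ch <- sim$cohort[match(mlm$scores$person_id, sim$cohort$person_id), ]
  mc <- mcmc_control(chains = 2, iter = 800, burnin = 400)
  d_true <- data.frame(time = ch$time, event = ch$event,
                       u0 = lat$u0, u1 = lat$u1)
  f_true <- fit_ph(d_true, c("u0", "u1"), mcmc = mc, seed = 4)
  d_hat <- data.frame(time = ch$time, event = ch$event,
                      u0 = mlm$scores$u0_hat, u1 = mlm$scores$u1_hat)
  f_hat <- fit_ph(d_hat, c("u0", "u1"), mcmc = mc, seed = 4)
  a2_true <- f_true$summary[f_true$summary$param == "u1", ]
  a2_hat <- f_hat$summary[f_hat$summary$param == "u1", ]
  # truth-based fit covers alpha2 = -1; shrunken-score fit attenuates
  expect_true(a2_true$lo <= -1 && -1 <= a2_true$hi)
  expect_lt(abs(a2_hat$mean), abs(a2_true$mean))
})
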