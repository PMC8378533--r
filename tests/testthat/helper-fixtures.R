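# Shared fixtures: small generative configurations and fabricated fits.
# Everything is built in code; heavy shared computations are memoized in
# `.fixture_env` so several test files can reuse one run.

.fixture_env <- new.env(parent = emptyenv())

# Gf-like single-stratum truth used by the recovery/attenuation harness:
# quadratic growth, slope variance 0.09, shared parameters alpha1 = -0.005,
# alpha2 = -1, ~60-65% deaths by census under the sparse default schedule.
recovery_truth <- function() {
  list(growth = growth_params(B0 = 0.1, B1 = 0.04, B2 = -0.02,
                              var_u0 = 71.75, var_u1 = 0.09,
                              corr_u0u1 = -0.07, var_resid = 0.95),
       hazard = hazard_params(
         baseline = piecewise_hazard(c(5, 10, 15, 20, 25),
                                     0.012 * 1.45^(0:5)),
         alpha1 = -0.005, alpha2 = -1.0),
       values = c(B0 = 0.1, B1 = 0.04, B2 = -0.02, var_u0 = 71.75,
                  var_u1 = 0.09, corr_u0u1 = -0.07, var_resid = 0.95,
                  alpha1 = -0.005, alpha2 = -1.0))
}

recovery_config <- function(n, seed, truth = recovery_truth(),
                            retention = NULL) {
  args <- list(n_individuals = n, prop_women = 1, domains = "Gf",
               growth = list(women = list(Gf = truth$growth),
                             men = list(Gf = truth$growth)),
               hazard = list(women = truth$hazard, men = truth$hazard),
               seed = seed)
  if (!is.null(retention)) args$retention <- retention
  do.call(sim_config, args)
}

# Twenty MNAR replicates at n = 1000, each fitted by the joint model and by
# the two-stage procedure with the desk-scale sampler settings
# (2 chains x 2000 kept draws). Computed once and reused by the
# recovery-coverage and attenuation checks.
recovery_replicates <- function(n_rep = 20, n = 1000) {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  spec <- model_spec("quadratic", stratum = "women", domain = "Gf")
  mc <- mcmc_control()
  out <- lapply(seq_len(n_rep), function(r) {
    sim <- simulate_cohort(recovery_config(n, seed = 5000 + r))
    list(joint = fit_joint(sim$panel, sim$cohort, spec, mc, seed = 40 + r),
         two_stage = run_two_stage(sim$panel, sim$cohort, spec, mc,
                                   seed = 70 + r))
  })
  .fixture_env$recovery <- out
  out
}

# A small two-domain mixed-sex cohort for smoke tests.
small_sim <- function(n = 300, seed = 42) {
  key <- paste0("small_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <-
      simulate_cohort(sim_config(n_individuals = n, seed = seed))
  .fixture_env[[key]]
}

light_mcmc <- function() mcmc_control(chains = 2, iter = 400, burnin = 250)

# Fabricate an `mlm_fit`-shaped object from explicit draws, for operations
# that are pure functions of the posterior sample (trajectories, scaled
# change, pseudo-R2 arithmetic).
fake_mlm_fit <- function(draws_mat, ages_obs = seq(-15, 22, by = 1),
                         nobs = 100) {
  draws <- list(draws_mat[seq_len(nrow(draws_mat) / 2), , drop = FALSE],
                draws_mat[-seq_len(nrow(draws_mat) / 2), , drop = FALSE])
  summ <- posterior_summary(draws)
  Xcols <- intersect(c("B0", "B1", "B2", "B3", "B4", "B5", "B6"),
                     colnames(draws_mat))
  X <- matrix(0, 1, length(Xcols), dimnames = list(NULL, Xcols))
  structure(list(summary = summ, nobs = nobs, n = 50,
                 spec = model_spec("quadratic"),
                 data = list(a = ages_obs, X = X, y = rep(0, nobs))),
            class = "mlm_fit")
}
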