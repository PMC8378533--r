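#' Specify a growth model to fit
#'
#' Describes which longitudinal model is fitted: the polynomial form of the
#' age trajectory (`intercept_only`, `linear`, or `quadratic`; random effects
#' are always limited to the intercept and linear change, with the quadratic
#' term a fixed effect only), whether baseline covariates (entry age, entry
#' age by linear change, smoking, self-rated health) are included, the person
#' subset, the sex stratum, and the cognitive domain.
#'
#' @param form One of `"intercept_only"`, `"linear"`, `"quadratic"`.
#' @param adjusted Include the covariate fixed effects (B3-B6)?
#' @param subset `"all"` or `"decedents"` (persons with an observed death).
#' @param stratum `"women"` or `"men"` (models are always sex-stratified).
#' @param domain `"Gc"` or `"Gf"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(form = c("quadratic", "linear", "intercept_only"),
                       adjusted = FALSE,
                       subset = c("all", "decedents"),
                       stratum = c("women", "men"),
                       domain = c("Gc", "Gf")) {
  form <- match.arg(form)
  subset <- match.arg(subset)
  stratum <- match.arg(stratum)
  domain <- match.arg(domain)
  structure(list(form = form, adjusted = isTRUE(adjusted), subset = subset,
                 stratum = stratum, domain = domain),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Growth model spec: %s%s, %s, %s, %s\n", x$form,
              if (x$adjusted) " + covariates" else "", x$subset, x$stratum,
              x$domain))
  invisible(x)
}

#' MCMC sampler settings
#'
#' Defaults are scaled for desk use (2 chains, 1,000 burn-in + 2,000 kept
#' draws per chain); `full_scale = TRUE` restores the original published
#' protocol of 20,000 iterations per chain with a 3,000-iteration burn-in.
#'
#' @param chains Number of chains (2 or more enables split-chain
#'   convergence checks).
#' @param iter Kept draws per chain after burn-in.
#' @param burnin Burn-in iterations per chain (discarded; adaptation of
#'   Metropolis step sizes happens here).
#' @param thin Thinning interval for stored draws.
#' @param full_scale If `TRUE`, overrides `iter`/`burnin` with 17,000 kept
#'   draws and 3,000 burn-in.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, iter = 2000, burnin = 1000, thin = 1,
                         full_scale = FALSE) {
  if (full_scale) { iter <- 17000; burnin <- 3000 }
  stopifnot(chains >= 1, iter >= 10, burnin >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "mcmc_control")
}

#' Prior settings for all Bayesian models
#'
#' Weakly-informative conjugate-style priors: independent normals on fixed
#' effects and on log-hazard coefficients (including the shared parameters),
#' inverse-gamma on the residual variance, inverse-Wishart on the
#' random-effects covariance (inverse-gamma when only a random intercept is
#' present), and independent gammas on the piecewise-constant baseline
#' hazard levels.
#'
#' @param beta_sd Prior SD of fixed effects (normal, mean 0).
#' @param coef_sd Prior SD of hazard coefficients gamma and alpha.
#' @param resid_a,resid_b Inverse-gamma shape/rate for the residual variance.
#' @param wishart_df Inverse-Wishart degrees of freedom (>= q + 1).
#' @param wishart_scale Inverse-Wishart scale matrix diagonal (length 2,
#'   intercept and linear-change scales).
#' @param hazard_a,hazard_b Gamma shape/rate for baseline hazard levels.
#' @return An object of class `prior_control`.
#' @export
prior_control <- function(beta_sd = 100, coef_sd = 10,
                          resid_a = 0.01, resid_b = 0.01,
                          wishart_df = 3, wishart_scale = c(0.01, 0.001),
                          hazard_a = 0.01, hazard_b = 0.01) {
  structure(list(beta_sd = beta_sd, coef_sd = coef_sd,
                 resid_a = resid_a, resid_b = resid_b,
                 wishart_df = wishart_df, wishart_scale = wishart_scale,
                 hazard_a = hazard_a, hazard_b = hazard_b),
            class = "prior_control")
}
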