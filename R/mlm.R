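#' Fit the Bayesian quadratic-growth multilevel model
#'
#' Fits the growth model for a cognitive factor score by MCMC: fixed effects
#' for intercept, linear and quadratic change in age (centered at 65 years),
#' optionally adjusted for entry age, entry age x linear change, smoking and
#' self-rated health; random effects for intercept and linear change (the
#' quadratic component is a fixed effect only); Gaussian occasion-level
#' residual. The sampler is a fully conjugate Gibbs scheme (normal fixed
#' effects, inverse-gamma residual variance, inverse-Wishart random-effects
#' covariance, exact normal draws of the person-level effects).
#'
#' @param panel Long panel (`person_id`, `occasion`, `age_c`, `domain`,
#'   `score`); every included person needs at least one observation.
#' @param cohort Cohort table (`person_id`, `sex`, `start_age_c`, `smoker`,
#'   `srh`, `event`, `time`).
#' @param spec A [model_spec()].
#' @param mcmc A [mcmc_control()].
#' @param priors A [prior_control()].
#' @param seed Integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @return An object of class `mlm_fit` with components `summary`
#'   (a [posterior_summary()]), `scores` (posterior means and SDs of the
#'   person-level random effects), `deviance`, `bic`, `k`, `converged`, and
#'   the data/spec used. Non-convergence is flagged in `converged`, never
#'   silently ignored.
#' @seealso [fit_joint()], [pseudo_r2()], [predict_trajectory()],
#'   [compare_fits()]
#' @export
fit_mlm <- function(panel, cohort, spec = model_spec(),
                    mcmc = mcmc_control(), priors = prior_control(),
                    seed = 1L) {
  md <- assemble_model_data(panel, cohort, spec)
  res <- run_sampler(md, mcmc, priors, joint = FALSE, seed = seed)
  summ <- posterior_summary(res$draws, settings = mcmc, seed = seed)
  scores <- data.frame(person_id = md$person_id,
                       u0_hat = res$u_mean[, 1],
                       u0_sd = res$u_sd[, 1])
  if (md$q == 2) {
    scores$u1_hat <- res$u_mean[, 2]
    scores$u1_sd <- res$u_sd[, 2]
  }
  pm <- stats::setNames(summ$mean, summ$param)
  dev <- -2 * mlm_marginal_loglik(md, pm)
  k <- ncol(md$X) + (if (md$q == 2) 3 else 1) + 1
  bic <- dev + k * log(md$nobs)
  structure(list(summary = summ, scores = scores, spec = spec,
                 deviance = dev, bic = bic, k = k,
                 nobs = md$nobs, n = md$n, data = md,
                 converged = converged(summ), mcmc = mcmc, priors = priors,
                 seed = seed),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("Bayesian growth MLM (%s%s), %s %s, %s persons: n = %d, obs = %d\n",
              x$spec$form, if (x$spec$adjusted) " + covariates" else "",
              x$spec$stratum, x$spec$domain, x$spec$subset, x$n, x$nobs))
  cat(sprintf("Deviance (at posterior means) %.1f, BIC %.1f, k = %d\n",
              x$deviance, x$bic, x$k))
  if (!all(x$converged))
    cat("NOT CONVERGED:", paste(names(x$converged)[!x$converged],
                                collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

# marginal log-likelihood integrating the random effects, at given
# parameter values (used for deviance/BIC model screening)
#' @keywords internal
mlm_marginal_loglik <- function(md, pm) {
  B <- pm[colnames(md$X)]
  s2 <- pm["var_resid"]
  if (md$q == 2) {
    sd0 <- sqrt(pm["var_u0"]); sd1 <- sqrt(pm["var_u1"])
    Sg <- matrix(c(pm["var_u0"], pm["corr_u0u1"] * sd0 * sd1,
                   pm["corr_u0u1"] * sd0 * sd1, pm["var_u1"]), 2, 2)
  } else Sg <- matrix(pm["var_u0"], 1, 1)
  r <- md$y - as.numeric(md$X %*% B)
  ll <- 0
  for (i in seq_len(md$n)) {
    sel <- md$pid == i
    Zi <- if (md$q == 2) cbind(1, md$a[sel]) else
      matrix(1, sum(sel), 1)
    Vi <- Zi %*% Sg %*% t(Zi) + diag(s2, nrow(Zi))
    Rch <- chol(Vi)
    z <- backsolve(Rch, r[sel], transpose = TRUE)
    ll <- ll - 0.5 * (nrow(Zi) * log(2 * pi) + 2 * sum(log(diag(Rch))) +
                        sum(z^2))
  }
  ll
}

#' Extract person-level random-effect scores
#'
#' Posterior means (and SDs) of the random intercept and random linear
#' change, one row per person with at least one observation. These are the
#' "stage-1" scores used as survival predictors in the two-stage procedure;
#' persons with a single observation shrink toward zero.
#'
#' @param fit An `mlm_fit` or `joint_fit`.
#' @return Data frame with `person_id`, `u0_hat`, `u0_sd` (and `u1_hat`,
#'   `u1_sd` when a random linear change is in the model).
#' @export
ranef_scores <- function(fit) {
  stopifnot(inherits(fit, c("mlm_fit", "joint_fit")))
  fit$scores
}

#' Proportional reduction in residual variance (pseudo-R-squared)
#'
#' `1 - var_resid(fit) / var_resid(null_fit)`, where the null fit is the
#' unconditional means model (fixed and random intercepts only) on the same
#' data. Reported to two decimals by convention.
#'
#' @param fit,null_fit `mlm_fit` objects on identical data.
#' @return Fraction of residual variance explained.
#' @export
pseudo_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "mlm_fit"), inherits(null_fit, "mlm_fit"))
  if (fit$nobs != null_fit$nobs ||
      abs(sum(fit$data$y) - sum(null_fit$data$y)) > 1e-8)
    stop("pseudo_r2 requires fits on the same data", call. = FALSE)
  vr <- function(f) f$summary$mean[match("var_resid", f$summary$param)]
  1 - vr(fit) / vr(null_fit)
}

#' Posterior mean trajectory with credible band
#'
#' Evaluates the fixed-effect age trajectory at a grid of ages for a given
#' covariate profile, across the stored posterior draws, and returns the
#' pointwise posterior mean and 95% credible band. Band width grows toward
#' the sparse age extremes.
#'
#' @param fit An `mlm_fit` or `joint_fit`.
#' @param ages Grid of ages in years (the study design covers 50-87).
#' @param profile Named list of covariate values for adjusted fits:
#'   `start_age_c` (default 0), `smoker` (default 0), `srh` (default 3).
#' @return Data frame with `age`, `mean`, `lo`, `hi`.
#' @export
predict_trajectory <- function(fit, ages = seq(50, 87, by = 1),
                               profile = list()) {
  stopifnot(inherits(fit, c("mlm_fit", "joint_fit")))
  md <- fit$data
  obs_rng <- range(md$a) + 65
  if (any(ages < obs_rng[1] - 1e-9) || any(ages > obs_rng[2] + 1e-9))
    warning("some ages lie outside the observed age support [",
            round(obs_rng[1], 1), ", ", round(obs_rng[2], 1), "]")
  prof <- utils::modifyList(list(start_age_c = 0, smoker = 0, srh = 3),
                            profile)
  a <- ages - 65
  pooled <- do.call(rbind, attr(fit$summary, "draws"))
  cols <- colnames(md$X)
  G <- matrix(0, length(a), length(cols), dimnames = list(NULL, cols))
  G[, "B0"] <- 1
  if ("B1" %in% cols) G[, "B1"] <- a
  if ("B2" %in% cols) G[, "B2"] <- a^2
  if ("B3" %in% cols) G[, "B3"] <- prof$start_age_c
  if ("B4" %in% cols) G[, "B4"] <- prof$start_age_c * a
  if ("B5" %in% cols) G[, "B5"] <- prof$smoker
  if ("B6" %in% cols) G[, "B6"] <- prof$srh - 3
  curves <- G %*% t(pooled[, cols, drop = FALSE])
  data.frame(age = ages,
             mean = rowMeans(curves),
             lo = apply(curves, 1, stats::quantile, 0.025, names = FALSE),
             hi = apply(curves, 1, stats::quantile, 0.975, names = FALSE))
}

#' Compare growth-model fits by deviance and BIC
#'
#' Deviance is `-2 x` the marginal log-likelihood (random effects
#' integrated out) evaluated at the posterior means; `BIC = deviance +
#' k log(N_obs)` with `k` counting all free parameters including variance
#' components. Optionally performs chi-square tests of the change in
#' deviance between successive *nested* fits (intercept-only within linear
#' within quadratic, same covariates), the screening step used before MCMC
#' re-estimation.
#'
#' @param fits List of `mlm_fit` objects on identical data.
#' @param chisq If `TRUE`, fits must be ordered and nested; likelihood-ratio
#'   chi-square tests between successive fits are added. Requesting the test
#'   for non-nested fits is an error.
#' @return Data frame with `model`, `k`, `deviance`, `bic` (and `lr_chisq`,
#'   `lr_df`, `lr_p` when `chisq = TRUE`).
#' @export
compare_fits <- function(fits, chisq = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "mlm_fit")))
  nobs <- vapply(fits, `[[`, 0, "nobs")
  ys <- vapply(fits, function(f) sum(f$data$y), 0)
  if (length(unique(nobs)) != 1 || max(abs(ys - ys[1])) > 1e-8)
    stop("compare_fits requires fits on identical data", call. = FALSE)
  lab <- vapply(fits, function(f)
    paste0(f$spec$form, if (f$spec$adjusted) "+cov" else ""), "")
  out <- data.frame(model = lab,
                    k = vapply(fits, `[[`, 0, "k"),
                    deviance = vapply(fits, `[[`, 0, "deviance"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  if (chisq && length(fits) > 1) {
    rank_of <- c(intercept_only = 1, linear = 2, quadratic = 3)
    forms <- vapply(fits, function(f) f$spec$form, "")
    adj <- vapply(fits, function(f) f$spec$adjusted, TRUE)
    if (any(diff(rank_of[forms]) <= 0) || length(unique(adj)) != 1)
      stop("chi-square comparison requires nested fits in increasing order ",
           "(same covariates)", call. = FALSE)
    dchi <- c(NA, -diff(out$deviance))
    ddf <- c(NA, diff(out$k))
    out$lr_chisq <- dchi
    out$lr_df <- ddf
    out$lr_p <- ifelse(is.na(dchi), NA,
                       stats::pchisq(pmax(dchi, 0), ddf, lower.tail = FALSE))
  }
  out
}

#' Log-posterior of the standalone growth model
#'
#' Evaluates the (unnormalized) log-posterior of the longitudinal model at
#' fixed parameter values, treating the person-level random effects as
#' parameters: Gaussian observation density, bivariate-normal density of the
#' random effects, and the priors on fixed effects, residual variance and
#' random-effects covariance. Used for separability and oracle checks of the
#' joint model.
#'
#' @param params List with `B` (named by design columns), `sigma2`, `Sigma`
#'   (`q x q`), `u` (matrix, persons in `person_id` order).
#' @param panel,cohort Data as in [fit_mlm()].
#' @param spec A [model_spec()].
#' @param priors A [prior_control()].
#' @return Scalar log-posterior.
#' @export
mlm_log_posterior <- function(params, panel, cohort, spec = model_spec(),
                              priors = prior_control()) {
  md <- assemble_model_data(panel, cohort, spec)
  B <- params$B[colnames(md$X)]
  if (any(is.na(B)))
    stop("params$B must be named for design columns: ",
         paste(colnames(md$X), collapse = ", "), call. = FALSE)
  U <- as.matrix(params$u)
  s2 <- params$sigma2
  Sg <- as.matrix(params$Sigma)
  mu <- as.numeric(md$X %*% B) + U[md$pid, 1] +
    (if (md$q == 2) U[md$pid, 2] * md$a else 0)
  ll <- sum(stats::dnorm(md$y, mu, sqrt(s2), log = TRUE))
  lu <- sum(dmvnorm_log(U, Sg))
  lp <- sum(stats::dnorm(B, 0, priors$beta_sd, log = TRUE)) +
    dinvgamma_log(s2, priors$resid_a, priors$resid_b) +
    (if (md$q == 2)
      as.numeric(dinvwishart_log(Sg, priors$wishart_df,
                                 diag(priors$wishart_scale[1:2])))
     else dinvgamma_log(Sg[1, 1], priors$resid_a,
                        priors$wishart_scale[1] / 2))
  ll + lu + lp
}

#' @keywords internal
dmvnorm_log <- function(U, Sigma) {
  q <- ncol(Sigma)
  Rch <- chol(Sigma)
  z <- backsolve(Rch, t(U), transpose = TRUE)
  -0.5 * q * log(2 * pi) - sum(log(diag(Rch))) - 0.5 * colSums(z^2)
}

#' @keywords internal
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' @keywords internal
dinvwishart_log <- function(S, df, Scale) {
  p <- ncol(S)
  lgamma_p <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma((df + 1 - seq_len(p)) / 2))
  (df / 2) * determinant(Scale, logarithm = TRUE)$modulus -
    (df * p / 2) * log(2) - lgamma_p -
    ((df + p + 1) / 2) * determinant(S, logarithm = TRUE)$modulus -
    0.5 * sum(diag(Scale %*% chol2inv(chol(S))))
}
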