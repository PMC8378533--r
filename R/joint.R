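#' Log-posterior of the shared-random-effects joint model
#'
#' Evaluates the joint longitudinal-survival log-posterior at fixed
#' parameter values. Per person, the contribution is the Gaussian log-density
#' of the observed scores given the latent effects, plus the
#' proportional-hazards log-likelihood term with log-hazard offset
#' `alpha1 * u0 + alpha2 * u1`, plus the bivariate-normal log-density of the
#' latent effects; priors are added once. Because the association acts
#' through the shared random effects (not the current value of the
#' trajectory), the person-level cumulative hazard is
#' \eqn{H_0(t_i) e^{\gamma w_i + \alpha u_i}} in closed form — no time
#' quadrature is needed.
#'
#' @param params List with components `growth` (list `B` named by design
#'   columns, `sigma2`, `Sigma`), `hazard` (list `baseline`, `gamma` named
#'   vector over `start_age`/`smoker`/`srh` — may be empty — and `alpha`,
#'   length `q`), and `u` (persons x q matrix, rows in sorted `person_id`
#'   order).
#' @param panel,cohort Data as in [fit_mlm()].
#' @param spec A [model_spec()].
#' @param priors A [prior_control()].
#' @return Scalar log-posterior; non-finite per-person contributions raise
#'   an error naming the offending person ids.
#' @export
joint_log_posterior <- function(params, panel, cohort, spec = model_spec(),
                                priors = prior_control()) {
  md <- assemble_model_data(panel, cohort, spec)
  g <- params$growth; hz <- params$hazard
  B <- g$B[colnames(md$X)]
  if (any(is.na(B)))
    stop("growth$B must be named for design columns: ",
         paste(colnames(md$X), collapse = ", "), call. = FALSE)
  U <- as.matrix(params$u)
  stopifnot(nrow(U) == md$n, ncol(U) == md$q)
  Sg <- as.matrix(g$Sigma)

  mu <- as.numeric(md$X %*% B) + U[md$pid, 1] +
    (if (md$q == 2) U[md$pid, 2] * md$a else 0)
  ll_long_i <- as.numeric(rowsum(
    stats::dnorm(md$y, mu, sqrt(g$sigma2), log = TRUE), md$pid))

  covars <- cbind(start_age = md$cohort$start_age_c,
                  smoker = md$cohort$smoker, srh = md$cohort$srh - 3)
  gamma <- hz$gamma
  eta <- (if (length(gamma))
    as.numeric(covars[, names(gamma), drop = FALSE] %*% gamma)
    else rep(0, md$n)) + as.numeric(U %*% hz$alpha)
  h0 <- hazard_rate(hz$baseline, md$time)
  H0 <- cum_hazard(hz$baseline, md$time)
  ll_surv_i <- md$event * (log(h0) + eta) - H0 * exp(eta)

  ll_u_i <- dmvnorm_log(U, Sg)

  tot_i <- ll_long_i + ll_surv_i + ll_u_i
  if (any(!is.finite(tot_i)))
    stop("non-finite joint log-posterior contribution for person id(s): ",
         paste(utils::head(md$person_id[!is.finite(tot_i)], 10),
               collapse = ", "), call. = FALSE)

  rates <- switch(hz$baseline$type,
                  constant = hz$baseline$rate,
                  piecewise = hz$baseline$rates,
                  stop("priors are defined for constant/piecewise baselines",
                       call. = FALSE))
  lp <- sum(stats::dnorm(B, 0, priors$beta_sd, log = TRUE)) +
    dinvgamma_log(g$sigma2, priors$resid_a, priors$resid_b) +
    (if (md$q == 2)
      as.numeric(dinvwishart_log(Sg, priors$wishart_df,
                                 diag(priors$wishart_scale[1:2])))
     else dinvgamma_log(Sg[1, 1], priors$resid_a,
                        priors$wishart_scale[1] / 2)) +
    sum(stats::dgamma(rates, priors$hazard_a, priors$hazard_b, log = TRUE)) +
    sum(stats::dnorm(gamma, 0, priors$coef_sd, log = TRUE)) +
    sum(stats::dnorm(hz$alpha, 0, priors$coef_sd, log = TRUE))

  sum(tot_i) + lp
}

#' Fit the joint longitudinal-survival model
#'
#' Simultaneous MCMC estimation of the quadratic-growth model and the
#' proportional-hazards mortality model linked by the person-level random
#' effects (shared-random-effects association): the hazard is
#' \eqn{h_i(t) = h_0(t)\exp(\gamma w_i + \alpha_1 u_{0i} + \alpha_2 u_{1i})}.
#' Under death-related dropout this uses the survival information to correct
#' the longitudinal estimates, and vice versa. The sampler is
#' Metropolis-within-Gibbs with person-level latent updates (see
#' [fit_mlm()] for the conjugate blocks; the latent effects use the
#' longitudinal full conditional as an independence proposal, alternated
#' with an adaptive random-walk step, and the hazard coefficients use
#' componentwise adaptive random-walk Metropolis).
#'
#' When `spec$adjusted` is `TRUE` the covariates (entry age, smoking,
#' self-rated health) enter both sub-models.
#'
#' @inheritParams fit_mlm
#' @param init Optional starting values: either a plain list (`B`, `sigma2`,
#'   `Sigma`, `u`, `gamma`, `alpha`, `lambda`) or a list with elements `mlm`
#'   (an `mlm_fit`) and/or `ph` (a `ph_fit`) whose posterior means seed the
#'   chains, the standard practice of initializing a joint model from
#'   standalone fits. Dimension mismatches are reported by parameter name.
#' @param n_intervals,cuts Baseline-hazard grid (defaults to event-time
#'   deciles), shared with [fit_ph()] so two-stage and joint fits are
#'   directly comparable.
#' @return An object of class `joint_fit`: `summary` (growth parameters,
#'   hazard coefficients `gamma_*`, shared parameters `alpha1`/`alpha2`,
#'   baseline levels, and the data log-likelihood trace `lp__`), `scores`
#'   (per-person latent posterior means and SDs), `cuts`, `converged`.
#'   The residual variance reported pertains to the longitudinal sub-model
#'   only.
#' @export
fit_joint <- function(panel, cohort, spec = model_spec(),
                      mcmc = mcmc_control(), priors = prior_control(),
                      init = NULL, n_intervals = 10, cuts = NULL,
                      seed = 1L) {
  md <- assemble_model_data(panel, cohort, spec, n_intervals, cuts)
  init_list <- convert_init(init, md)
  res <- run_sampler(md, mcmc, priors, joint = TRUE, init = init_list,
                     seed = seed)
  summ <- posterior_summary(res$draws, settings = mcmc, seed = seed)
  scores <- data.frame(person_id = md$person_id,
                       u0_hat = res$u_mean[, 1], u0_sd = res$u_sd[, 1])
  if (md$q == 2) {
    scores$u1_hat <- res$u_mean[, 2]
    scores$u1_sd <- res$u_sd[, 2]
  }
  structure(list(summary = summ, scores = scores, spec = spec,
                 cuts = md$cuts, n = md$n, nobs = md$nobs,
                 events = sum(md$event), data = md,
                 converged = converged(summ), accept = res$accept,
                 mcmc = mcmc, priors = priors, seed = seed),
            class = "joint_fit")
}

#' @keywords internal
convert_init <- function(init, md) {
  if (is.null(init)) return(list())
  if (inherits(init$mlm, "mlm_fit") || inherits(init$ph, "ph_fit")) {
    out <- list()
    if (inherits(init$mlm, "mlm_fit")) {
      s <- init$mlm$summary
      pm <- stats::setNames(s$mean, s$param)
      Bcols <- colnames(md$X)
      if (!all(Bcols %in% names(pm)))
        stop("initialization dimension mismatch for B: standalone fit lacks ",
             paste(setdiff(Bcols, names(pm)), collapse = ", "), call. = FALSE)
      out$B <- pm[Bcols]
      out$sigma2 <- unname(pm["var_resid"])
      if (md$q == 2) {
        sd0 <- sqrt(pm["var_u0"]); sd1 <- sqrt(pm["var_u1"])
        cv <- pm["corr_u0u1"] * sd0 * sd1
        out$Sigma <- matrix(c(pm["var_u0"], cv, cv, pm["var_u1"]), 2, 2)
      } else out$Sigma <- matrix(pm["var_u0"], 1, 1)
      sc <- init$mlm$scores
      m <- match(md$person_id, sc$person_id)
      if (any(is.na(m)))
        stop("initialization mismatch: standalone MLM scores missing persons",
             call. = FALSE)
      out$u <- cbind(sc$u0_hat[m],
                     if (md$q == 2) sc$u1_hat[m] else NULL)
    }
    if (inherits(init$ph, "ph_fit")) {
      s <- init$ph$summary
      pm <- stats::setNames(s$mean, s$param)
      gnames <- paste0("gamma_", colnames(md$W))
      if (ncol(md$W) && all(gnames %in% names(pm)))
        out$gamma <- unname(pm[gnames])
    }
    return(out)
  }
  init
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint longitudinal-survival fit (%s%s), %s %s: n = %d, obs = %d, events = %d\n",
              x$spec$form, if (x$spec$adjusted) " + covariates" else "",
              x$spec$stratum, x$spec$domain, x$n, x$nobs, x$events))
  if (!all(x$converged))
    cat("NOT CONVERGED:", paste(names(x$converged)[!x$converged],
                                collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

#' Extract the shared-parameter association estimates
#'
#' Posterior mean and 95% credible interval for the shared parameters
#' `alpha1` (random intercept) and `alpha2` (random linear change), flagged
#' significant when the interval excludes zero.
#'
#' @param fit A `joint_fit`.
#' @return Data frame with `param`, `mean`, `lo`, `hi`, `significant`.
#' @export
extract_shared_association <- function(fit) {
  stopifnot(inherits(fit, "joint_fit"))
  pars <- grep("^alpha", fit$summary$param, value = TRUE)
  if (!all(fit$converged[pars]))
    warning("shared parameters have not passed convergence checks",
            call. = FALSE)
  s <- as.data.frame(fit$summary)[fit$summary$param %in% pars,
                                  c("param", "mean", "lo", "hi")]
  s$significant <- s$lo > 0 | s$hi < 0
  rownames(s) <- NULL
  s
}
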