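#' Parametric proportional-hazards log-likelihood
#'
#' Full parametric log-likelihood
#' \eqn{\sum_i [\delta_i \log h_i(t_i) - H_i(t_i)]} with
#' \eqn{h_i(t) = h_0(t) e^{\eta_i}} and \eqn{H_i(t) = H_0(t) e^{\eta_i}}.
#' For the piecewise-constant baseline the cumulative hazard is piecewise
#' linear in `t`; times beyond the last cut point use the final hazard
#' level (the level extends, by construction, rather than erroring).
#'
#' @param params List with `baseline` (a
#'   [`baseline_hazard`][constant_hazard]) and `coef`, a named vector of
#'   log-hazard coefficients whose names are columns of `data`.
#' @param data Data frame with `time`, `event` and the predictor columns.
#' @return Scalar log-likelihood.
#' @examples
#' d <- data.frame(time = 1, event = 1)
#' log_likelihood_ph(list(baseline = constant_hazard(1), coef = numeric(0)), d)
#' @export
log_likelihood_ph <- function(params, data) {
  stopifnot(inherits(params$baseline, "baseline_hazard"),
            all(c("time", "event") %in% names(data)))
  if (any(data$time <= 0)) stop("times must be positive", call. = FALSE)
  coef <- params$coef
  lin <- if (length(coef)) {
    miss <- setdiff(names(coef), names(data))
    if (length(miss))
      stop("predictor columns missing from data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    as.numeric(as.matrix(data[names(coef)]) %*% coef)
  } else rep(0, nrow(data))
  h0 <- hazard_rate(params$baseline, data$time)
  H0 <- cum_hazard(params$baseline, data$time)
  sum(data$event * (log(h0) + lin)) - sum(H0 * exp(lin))
}

#' Log-posterior of the standalone proportional-hazards model
#'
#' [log_likelihood_ph()] plus the priors: independent gammas on the baseline
#' hazard levels and independent normals on the coefficients. Only constant
#' and piecewise-constant baselines are supported here (the families the
#' samplers use).
#'
#' @inheritParams log_likelihood_ph
#' @param priors A [prior_control()].
#' @return Scalar log-posterior.
#' @export
ph_log_posterior <- function(params, data, priors = prior_control()) {
  rates <- switch(params$baseline$type,
                  constant = params$baseline$rate,
                  piecewise = params$baseline$rates,
                  stop("priors are defined for constant/piecewise baselines",
                       call. = FALSE))
  log_likelihood_ph(params, data) +
    sum(stats::dgamma(rates, priors$hazard_a, priors$hazard_b, log = TRUE)) +
    sum(stats::dnorm(params$coef, 0, priors$coef_sd, log = TRUE))
}

#' Fit the Bayesian proportional-hazards model
#'
#' MCMC fit of the proportional-hazards model with a piecewise-constant
#' baseline hazard (cut points at deciles of the observed event times).
#' Baseline levels have conjugate gamma full conditionals; coefficients are
#' updated by componentwise adaptive random-walk Metropolis. This is the
#' stage-2 model of the two-stage procedure, with MCMC-estimated person
#' scores supplied as fixed predictors.
#'
#' Tied event times (measure-zero under the continuous simulator) are broken
#' by a tiny seeded jitter before the cut points are formed.
#'
#' @param data Data frame with `time`, `event` and predictor columns.
#' @param predictors Character vector of predictor column names (may be
#'   empty for a baseline-only model).
#' @param coef_names Optional named character vector renaming coefficients
#'   in the output (`c(u0_hat = "alpha1")` etc.).
#' @param mcmc A [mcmc_control()].
#' @param priors A [prior_control()].
#' @param n_intervals Number of baseline-hazard intervals.
#' @param cuts Optional explicit interior cut points (overrides
#'   `n_intervals`).
#' @param seed Integer seed.
#' @return An object of class `ph_fit` with `summary`, `cuts`, `converged`.
#' @export
fit_ph <- function(data, predictors = character(0), coef_names = NULL,
                   mcmc = mcmc_control(), priors = prior_control(),
                   n_intervals = 10, cuts = NULL, seed = 1L) {
  stopifnot(all(c("time", "event") %in% names(data)))
  if (sum(data$event) == 0)
    stop("all observations are censored: no events to anchor the baseline ",
         "hazard", call. = FALSE)
  if (any(data$time <= 0)) stop("times must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  time <- data$time
  dup <- duplicated(time) & data$event == 1
  if (any(dup))
    time[dup] <- time[dup] * (1 + 1e-9 * stats::runif(sum(dup)))
  event <- data$event
  Wm <- as.matrix(data[predictors])
  if (length(predictors) >= 2) {
    cc <- stats::cor(Wm)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    if (any(abs(cc) > 0.999, na.rm = TRUE) ||
        qr(cbind(1, Wm))$rank < ncol(Wm) + 1)
      warning("collinear predictor columns in the hazard design", call. = FALSE)
  }

  if (is.null(cuts)) {
    et <- time[event == 1]
    cuts <- if (length(et) >= n_intervals)
      unique(stats::quantile(et, probs = seq_len(n_intervals - 1) /
                               n_intervals, names = FALSE))
    else numeric(0)
  }
  K <- length(cuts) + 1L
  edges <- c(0, cuts)
  n <- nrow(data)
  E <- matrix(0, n, K)
  for (k in seq_len(K)) {
    hi <- if (k < K) edges[k + 1] else Inf
    E[, k] <- pmax(0, pmin(time, hi) - edges[k])
  }
  dk <- as.numeric(rowsum(as.numeric(event),
                          factor(findInterval(time, edges), levels = 1:K)))
  dk[is.na(dk)] <- 0
  m <- length(predictors)

  par_base <- if (m) predictors else character(0)
  if (!is.null(coef_names))
    par_base <- ifelse(par_base %in% names(coef_names),
                       coef_names[par_base], par_base)
  par_names <- c(par_base, paste0("lambda", seq_len(K)), "lp__")

  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(as.integer(seed) + 1000L * (ch - 1L))
    beta <- rep(0, m)
    lambda <- pmax(dk, 0.5) / pmax(colSums(E), 1e-8)
    s_b <- rep(0.1, m); acc <- rep(0, m); tries <- rep(0, m)
    n_iter <- mcmc$burnin + mcmc$iter
    keep <- floor(mcmc$iter / mcmc$thin)
    draws <- matrix(NA_real_, keep, length(par_names),
                    dimnames = list(NULL, par_names))
    ki <- 0
    eta <- if (m) as.numeric(Wm %*% beta) else rep(0, n)
    for (it in seq_len(n_iter)) {
      expEta <- exp(eta)
      expo <- as.numeric(crossprod(E, expEta))
      lambda <- stats::rgamma(K, priors$hazard_a + dk, priors$hazard_b + expo)
      H0 <- as.numeric(E %*% lambda)
      for (j in seq_len(m)) {
        propj <- beta[j] + s_b[j] * stats::rnorm(1)
        deta <- (propj - beta[j]) * Wm[, j]
        dll <- sum(event * deta) - sum((exp(eta + deta) - exp(eta)) * H0) +
          stats::dnorm(propj, 0, priors$coef_sd, log = TRUE) -
          stats::dnorm(beta[j], 0, priors$coef_sd, log = TRUE)
        tries[j] <- tries[j] + 1
        if (log(stats::runif(1)) < dll) {
          beta[j] <- propj; eta <- eta + deta
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= mcmc$burnin && it %% 50 == 0) {
        s_b <- s_b * exp(acc / pmax(tries, 1) - 0.44)
        acc[] <- 0; tries[] <- 0
      }
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0) {
        ki <- ki + 1
        loglam <- log(lambda)[findInterval(time, edges)]
        lp <- sum(event * (loglam + eta)) - sum(exp(eta) * (E %*% lambda))
        draws[ki, ] <- c(beta, lambda, lp)
      }
    }
    draws[seq_len(ki), , drop = FALSE]
  })

  summ <- posterior_summary(chains, settings = mcmc, seed = seed)
  structure(list(summary = summ, cuts = cuts, predictors = predictors,
                 coef_params = par_base, n = n, events = sum(event),
                 converged = converged(summ), mcmc = mcmc, priors = priors,
                 seed = seed),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("Bayesian proportional-hazards fit: n = %d, events = %d, %d baseline intervals\n",
              x$n, x$events, length(x$cuts) + 1))
  if (!all(x$converged))
    cat("NOT CONVERGED:", paste(names(x$converged)[!x$converged],
                                collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}
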