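#' Hazard ratio per 1 SD of a predictor
#'
#' `exp(coef * sd)`: rescales a log-hazard coefficient (per predictor unit)
#' to the hazard ratio associated with a one-standard-deviation difference,
#' making cognitive predictors comparable across domains and scalings.
#' Monotone decreasing in `coef` for fixed `sd > 0`, equal to 1 at `sd = 0`
#' or `coef = 0`.
#'
#' @param coef Log-hazard coefficient(s) per predictor unit.
#' @param sd Predictor standard deviation(s), `>= 0`.
#' @return Hazard ratio(s).
#' @examples
#' scaled_hazard_ratio(-0.234, sqrt(0.32))
#' @export
scaled_hazard_ratio <- function(coef, sd) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  exp(coef * sd)
}

#' Scaled hazard ratios for the cognitive predictors of a fit
#'
#' For a joint fit, the scaling SD of each random effect is the square root
#' of its posterior-mean variance (`var_u0`, `var_u1`), the model-based
#' convention that matches published joint-model tables. For a two-stage
#' fit, the natural scaling uses the empirical SD of the stage-1
#' posterior-mean scores (which are shrunken, so this SD is smaller than the
#' model-based one); both conventions are reported so the discrepancy is
#' visible.
#'
#' @param fit A `joint_fit` or `two_stage_fit`.
#' @return Data frame with `param`, `coef`, `lo`, `hi`, `sd_model`,
#'   `sd_empirical`, `hr_model`, `hr_empirical`.
#' @export
scaled_hr_table <- function(fit) {
  if (inherits(fit, "joint_fit")) {
    s <- fit$summary
    scores <- fit$scores
    vm <- stats::setNames(s$mean, s$param)
    sd_model <- c(alpha1 = sqrt(vm[["var_u0"]]),
                  alpha2 = if ("var_u1" %in% s$param) sqrt(vm[["var_u1"]])
                  else NA)
  } else if (inherits(fit, "two_stage_fit")) {
    s <- fit$ph$summary
    scores <- fit$mlm$scores
    vm <- stats::setNames(fit$mlm$summary$mean, fit$mlm$summary$param)
    sd_model <- c(alpha1 = sqrt(vm[["var_u0"]]),
                  alpha2 = if ("var_u1" %in% fit$mlm$summary$param)
                    sqrt(vm[["var_u1"]]) else NA)
  } else stop("need a joint_fit or two_stage_fit", call. = FALSE)
  sd_emp <- c(alpha1 = stats::sd(scores$u0_hat),
              alpha2 = if ("u1_hat" %in% names(scores))
                stats::sd(scores$u1_hat) else NA)
  pars <- intersect(c("alpha1", "alpha2"), s$param)
  i <- match(pars, s$param)
  out <- data.frame(param = pars, coef = s$mean[i], lo = s$lo[i],
                    hi = s$hi[i],
                    sd_model = unname(sd_model[pars]),
                    sd_empirical = unname(sd_emp[pars]))
  out$hr_model <- scaled_hazard_ratio(out$coef, out$sd_model)
  out$hr_empirical <- scaled_hazard_ratio(out$coef, out$sd_empirical)
  rownames(out) <- NULL
  out
}

#' Credible-interval width ratios between two fits
#'
#' Per-parameter ratio of 95% CI widths, `width_a / width_b`; values below 1
#' mean fit `a` is the more accurate (narrower). This is the comparison used
#' to contrast joint against two-stage estimation.
#'
#' @param fit_a,fit_b Objects with a `posterior_summary` (any fit in this
#'   package), or `posterior_summary` objects directly.
#' @param params Parameter names shared by both fits.
#' @return Named numeric vector of width ratios.
#' @export
ci_width_contrast <- function(fit_a, fit_b, params) {
  ga <- get_summary(fit_a); gb <- get_summary(fit_b)
  w <- function(s, p) {
    i <- match(p, s$param)
    if (any(is.na(i)))
      stop("parameter(s) missing from fit: ",
           paste(p[is.na(i)], collapse = ", "), call. = FALSE)
    s$hi[i] - s$lo[i]
  }
  stats::setNames(w(ga, params) / w(gb, params), params)
}

#' @keywords internal
get_summary <- function(x) {
  if (inherits(x, "posterior_summary")) x
  else if (inherits(x, "two_stage_fit")) x$ph$summary
  else if (!is.null(x$summary)) x$summary
  else stop("cannot extract a posterior summary", call. = FALSE)
}

#' Standardized change per decade
#'
#' Model-implied change in the fixed-effect trajectory over a ten-year age
#' window at a reference covariate profile, divided by a standardizing SD —
#' a scale-free summary of linear decline. The window and SD are
#' conventions, not model quantities, so both are recorded in the result;
#' the default window is ages 70-80 and the default SD is the model-based
#' between-person score SD at the window midpoint
#' (`sqrt(var_u0 + var_resid)`).
#'
#' @param fit An `mlm_fit` or `joint_fit` (quadratic form).
#' @param window Length-2 age window in years (default `c(70, 80)`).
#' @param sd_ref Standardizing SD; default as described above.
#' @param profile Covariate profile passed to [predict_trajectory()].
#' @return Scalar change in SD units per decade, with attributes `window`
#'   and `sd_ref` recording the convention.
#' @export
delta_z_per_decade <- function(fit, window = c(70, 80), sd_ref = NULL,
                               profile = list()) {
  stopifnot(length(window) == 2, diff(window) > 0)
  md <- fit$data
  rng <- range(md$a) + 65
  if (window[1] < rng[1] - 1e-9 || window[2] > rng[2] + 1e-9)
    warning("standardization window extends beyond the observed age support")
  if (is.null(sd_ref)) {
    pm <- stats::setNames(fit$summary$mean, fit$summary$param)
    sd_ref <- sqrt(pm[["var_u0"]] + pm[["var_resid"]])
  }
  tr <- suppressWarnings(predict_trajectory(fit, ages = window,
                                            profile = profile))
  out <- (tr$mean[2] - tr$mean[1]) / sd_ref * (10 / diff(window))
  attr(out, "window") <- window
  attr(out, "sd_ref") <- unname(sd_ref)
  out
}

#' Summary table by measurement occasion
#'
#' Per occasion and sex stratum: number of persons assessed, cumulative
#' deaths by the occasion's median assessment time, median age at
#' assessment, and mean factor score per domain. Counts are non-increasing
#' and cumulative deaths non-decreasing over occasions; occasions with no
#' observations are omitted.
#'
#' @param panel,cohort Data as in [fit_mlm()].
#' @return Data frame, one row per (stratum, occasion).
#' @export
summarize_panel <- function(panel, cohort) {
  m <- match(panel$person_id, cohort$person_id)
  if (any(is.na(m)))
    stop("panel contains person ids absent from the cohort", call. = FALSE)
  sex <- cohort$sex[m]
  elapsed <- panel$age_c - cohort$start_age_c[m]
  rows <- list()
  for (s in unique(cohort$sex)) {
    ids_s <- cohort$person_id[cohort$sex == s]
    for (k in sort(unique(panel$occasion))) {
      sel <- sex == s & panel$occasion == k
      if (!any(sel)) next
      persons <- unique(panel$person_id[sel])
      med_t <- stats::median(elapsed[sel])
      in_s <- cohort$sex == s
      cum_d <- sum(in_s & cohort$event == 1 & cohort$time <= med_t)
      row <- data.frame(stratum = s, occasion = k, n = length(persons),
                        cum_deaths = cum_d,
                        median_age = stats::median(panel$age_c[sel] + 65))
      for (d in sort(unique(panel$domain)))
        row[[paste0("mean_", d)]] <-
          mean(panel$score[sel & panel$domain == d])
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MCMC diagnostics report
#'
#' Scalar convergence table (split-chain statistic, effective sample size,
#' flags against the declared thresholds) plus per-parameter lag-1..20
#' autocorrelations, and optional trace / autocorrelation / density plots
#' written as PNG files. Requires the raw draws, which fits retain by
#' default; a summary stripped of draws raises an error advising a re-run
#' with retention.
#'
#' @param fit Any fit in this package, a [posterior_summary()], or a plain
#'   list of per-chain draw matrices.
#' @param params Parameters to report (default: all non-baseline
#'   parameters).
#' @param plot_dir Optional directory for diagnostic PNGs.
#' @param rhat_max,ess_min Convergence thresholds.
#' @return List with `table` (param, rhat, ess, flag) and `autocorr`
#'   (parameters x lags matrix).
#' @export
mcmc_diagnostics <- function(fit, params = NULL, plot_dir = NULL,
                             rhat_max = 1.05, ess_min = 200) {
  draws <- if (is.list(fit) && !is.object(fit) && is.matrix(fit[[1]])) fit
  else attr(get_summary(fit), "draws")
  if (is.null(draws))
    stop("raw draws were discarded; re-run the fit with draw retention ",
         "to compute diagnostics", call. = FALSE)
  pars <- colnames(draws[[1]])
  if (is.null(params))
    params <- grep("^lambda", pars, value = TRUE, invert = TRUE)
  if (!all(params %in% pars))
    stop("unknown parameter(s): ",
         paste(setdiff(params, pars), collapse = ", "), call. = FALSE)
  tab <- data.frame(
    param = params,
    rhat = vapply(params, function(p)
      split_rhat_one(lapply(draws, function(m) m[, p])), 0),
    ess = vapply(params, function(p)
      ess_one(lapply(draws, function(m) m[, p])), 0))
  tab$flag <- ifelse(!is.na(tab$rhat) & tab$rhat >= rhat_max, "rhat",
                     ifelse(!is.na(tab$ess) & tab$ess <= ess_min, "ess", ""))
  nlag <- min(20, nrow(draws[[1]]) - 1)
  ac <- t(vapply(params, function(p) {
    a <- stats::acf(draws[[1]][, p], lag.max = nlag, plot = FALSE,
                    demean = TRUE)$acf[-1]
    if (all(!is.finite(a))) a[] <- 0
    a
  }, numeric(nlag)))
  colnames(ac) <- paste0("lag", seq_len(nlag))

  if (!is.null(plot_dir)) {
    if (!dir.exists(plot_dir)) dir.create(plot_dir, recursive = TRUE)
    for (p in params) {
      grDevices::png(file.path(plot_dir, paste0(p, ".png")),
                     width = 900, height = 300)
      graphics::par(mfrow = c(1, 3))
      for (ci in seq_along(draws))
        if (ci == 1)
          graphics::plot(draws[[ci]][, p], type = "l", main = paste("trace", p),
                         xlab = "iteration", ylab = p)
        else graphics::lines(draws[[ci]][, p], col = ci)
      stats::acf(draws[[1]][, p], main = paste("acf", p))
      graphics::plot(stats::density(do.call(rbind, draws)[, p]),
                     main = paste("density", p))
      grDevices::dev.off()
    }
  }
  list(table = tab, autocorr = ac)
}
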