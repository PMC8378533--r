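#' @keywords internal
split_rhat_one <- function(chains) {
  # chains: list of numeric vectors (one per chain); split each in half
  halves <- list()
  for (ch in chains) {
    n2 <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[seq_len(n2)], ch[n2 + seq_len(n2)]))
  }
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(1)  # degenerate (constant) parameter
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @keywords internal
ess_one <- function(chains) {
  tryCatch(
    sum(vapply(chains, function(ch) as.numeric(coda::effectiveSize(ch)), 0)),
    error = function(e) NA_real_)
}

#' Summarize MCMC draws
#'
#' Builds the standard per-parameter posterior summary: posterior mean, 95%
#' credible interval (2.5% and 97.5% quantiles of the pooled draws),
#' effective sample size and split-chain convergence statistic (potential
#' scale-reduction factor computed on half-chains).
#'
#' @param draws A list with one matrix per chain (iterations x parameters,
#'   identical column names).
#' @param settings The [mcmc_control()] used (stored as metadata).
#' @param seed Seed used by the sampler (metadata).
#' @return An object of class `posterior_summary`: a data.frame with columns
#'   `param`, `mean`, `lo`, `hi`, `ess`, `rhat`, carrying the raw draws in
#'   `attr(, "draws")`.
#' @export
posterior_summary <- function(draws, settings = NULL, seed = NULL) {
  stopifnot(is.list(draws), length(draws) >= 1, is.matrix(draws[[1]]))
  pars <- colnames(draws[[1]])
  pooled <- do.call(rbind, draws)
  out <- data.frame(
    param = pars,
    mean = colMeans(pooled),
    lo = apply(pooled, 2, stats::quantile, 0.025, names = FALSE),
    hi = apply(pooled, 2, stats::quantile, 0.975, names = FALSE),
    ess = vapply(pars, function(p)
      ess_one(lapply(draws, function(m) m[, p])), 0),
    rhat = vapply(pars, function(p)
      split_rhat_one(lapply(draws, function(m) m[, p])), 0),
    row.names = NULL)
  structure(out, class = c("posterior_summary", "data.frame"),
            draws = draws, settings = settings, seed = seed)
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (", nrow(x), " parameters, ",
      length(attr(x, "draws")), " chains)\n", sep = "")
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, digits)
  df$lo <- signif(df$lo, digits)
  df$hi <- signif(df$hi, digits)
  df$ess <- round(df$ess)
  df$rhat <- round(df$rhat, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flag parameters that have not converged
#'
#' A parameter is declared converged when its split-chain statistic is below
#' `rhat_max` and its effective sample size exceeds `ess_min`. Rather than
#' silently passing, fitting functions attach this check to their results.
#'
#' @param summary A [posterior_summary()].
#' @param rhat_max,ess_min Thresholds (defaults 1.05 and 200).
#' @return Logical vector (TRUE = converged), named by parameter.
#' @export
converged <- function(summary, rhat_max = 1.05, ess_min = 200) {
  stopifnot(inherits(summary, "posterior_summary"))
  ok <- (is.na(summary$rhat) | summary$rhat < rhat_max) &
    (is.na(summary$ess) | summary$ess > ess_min)
  stats::setNames(ok, summary$param)
}

#' @keywords internal
summary_row <- function(summary, param) {
  i <- match(param, summary$param)
  if (is.na(i)) stop("parameter not found in summary: ", param, call. = FALSE)
  summary[i, , drop = FALSE]
}
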