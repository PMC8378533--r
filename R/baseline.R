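#' Baseline hazard specifications
#'
#' Constructors for the baseline hazard \eqn{h_0(t)} used by the survival
#' sub-models and by the cohort simulator. Three families are supported:
#' constant (exponential), Weibull, and piecewise-constant on a grid of cut
#' points. The piecewise-constant family is the workhorse: its cumulative
#' hazard is piecewise linear, so survival-function inversion (for
#' simulation) and the parametric likelihood are closed form.
#'
#' @param rate Constant hazard rate (per year), `> 0`.
#' @param shape,scale Weibull shape and scale; the cumulative hazard is
#'   `(t / scale)^shape`.
#' @param cuts Interior cut points, strictly increasing and positive. The
#'   intervals are `[0, cuts[1]), [cuts[1], cuts[2]), ..., [cuts[K-1], Inf)`.
#' @param rates Hazard level on each interval; `length(cuts) + 1` positive
#'   values. Beyond the last cut point the final level extends indefinitely.
#' @return An object of class `baseline_hazard`.
#' @examples
#' h <- piecewise_hazard(cuts = c(5, 10), rates = c(0.01, 0.02, 0.05))
#' cum_hazard(h, c(1, 7, 20))
#' @export
constant_hazard <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1, is.finite(rate), rate > 0)
  structure(list(type = "constant", rate = rate), class = "baseline_hazard")
}

#' @rdname constant_hazard
#' @export
weibull_hazard <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(type = "weibull", shape = shape, scale = scale),
            class = "baseline_hazard")
}

#' @rdname constant_hazard
#' @export
piecewise_hazard <- function(cuts, rates) {
  cuts <- as.numeric(cuts)
  rates <- as.numeric(rates)
  if (length(cuts) > 0) {
    if (any(diff(c(0, cuts)) <= 0))
      stop("`cuts` must be strictly increasing and positive", call. = FALSE)
  }
  if (length(rates) != length(cuts) + 1)
    stop("need length(cuts) + 1 hazard levels", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("baseline hazard levels must be positive and finite", call. = FALSE)
  structure(list(type = "piecewise", cuts = cuts, rates = rates),
            class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  switch(x$type,
    constant = cat("Constant baseline hazard: rate", x$rate, "per year\n"),
    weibull = cat("Weibull baseline hazard: shape", x$shape,
                  "scale", x$scale, "\n"),
    piecewise = {
      cat("Piecewise-constant baseline hazard,",
          length(x$rates), "levels\n")
      cat("  cuts: ", paste(signif(x$cuts, 4), collapse = ", "), "\n")
      cat("  rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
    })
  invisible(x)
}

#' Cumulative baseline hazard and its inverse
#'
#' `cum_hazard()` evaluates \eqn{H_0(t)}; `invert_cum_hazard()` solves
#' \eqn{H_0(t) = H} for `t`. For the piecewise-constant family the final
#' hazard level extends beyond the last cut point, so both functions are
#' defined for all non-negative arguments.
#'
#' @param baseline A [`baseline_hazard`][constant_hazard] object.
#' @param t Vector of non-negative times (years).
#' @param H Vector of non-negative cumulative-hazard values.
#' @return Numeric vector.
#' @export
cum_hazard <- function(baseline, t) {
  stopifnot(inherits(baseline, "baseline_hazard"), all(t >= 0))
  switch(baseline$type,
    constant = baseline$rate * t,
    weibull = (t / baseline$scale)^baseline$shape,
    piecewise = {
      edges <- c(0, baseline$cuts)
      # time spent in each interval, final interval open-ended
      H <- numeric(length(t))
      for (k in seq_along(baseline$rates)) {
        lo <- edges[k]
        hi <- if (k < length(baseline$rates)) edges[k + 1] else Inf
        H <- H + baseline$rates[k] * pmax(0, pmin(t, hi) - lo)
      }
      H
    })
}

#' @rdname cum_hazard
#' @export
invert_cum_hazard <- function(baseline, H) {
  stopifnot(inherits(baseline, "baseline_hazard"), all(H >= 0))
  switch(baseline$type,
    constant = H / baseline$rate,
    weibull = baseline$scale * H^(1 / baseline$shape),
    piecewise = {
      edges <- c(0, baseline$cuts)
      K <- length(baseline$rates)
      # cumulative hazard at the left edge of each interval
      Hedge <- c(0, cumsum(baseline$rates[-K] * diff(edges)))
      idx <- findInterval(H, Hedge, rightmost.closed = FALSE)
      idx[idx > K] <- K
      edges[idx] + (H - Hedge[idx]) / baseline$rates[idx]
    })
}

#' Instantaneous baseline hazard
#'
#' @inheritParams cum_hazard
#' @return Hazard level at each time.
#' @export
hazard_rate <- function(baseline, t) {
  stopifnot(inherits(baseline, "baseline_hazard"), all(t >= 0))
  switch(baseline$type,
    constant = rep(baseline$rate, length(t)),
    weibull = (baseline$shape / baseline$scale) *
      (t / baseline$scale)^(baseline$shape - 1),
    piecewise = {
      idx <- findInterval(t, c(0, baseline$cuts))
      baseline$rates[idx]
    })
}

#' Draw a survival time by inverse-transform sampling
#'
#' Solves \eqn{S(t) = u} for `t` under the proportional-hazards survival
#' function \eqn{S(t) = \exp\{-H_0(t) e^{\eta}\}} with log-hazard offset
#' `linpred` \eqn{= \eta}. Exact closed form for constant and Weibull
#' baselines; piecewise-linear inversion of the cumulative hazard otherwise.
#'
#' @param u Uniform draws in `(0, 1]`; `u = 1` maps to `t = 0`, `u = 0` is an
#'   error (infinite survival time).
#' @param linpred Log-hazard offsets (recycled against `u`).
#' @param baseline A [`baseline_hazard`][constant_hazard] object.
#' @return Survival times in years.
#' @examples
#' sample_survival_time(exp(-1), 0, constant_hazard(0.1))  # 10 years
#' @export
sample_survival_time <- function(u, linpred, baseline) {
  stopifnot(is.numeric(u), is.numeric(linpred))
  if (any(u <= 0))
    stop("u = 0 corresponds to an infinite survival time; require u in (0, 1]",
         call. = FALSE)
  if (any(u > 1)) stop("u must lie in (0, 1]", call. = FALSE)
  target <- -log(u) * exp(-linpred)
  invert_cum_hazard(baseline, target)
}
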