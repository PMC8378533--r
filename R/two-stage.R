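#' Run the two-stage cognition-mortality analysis
#'
#' Stage 1 fits the standalone growth model and extracts each person's
#' posterior-mean random intercept and linear change; stage 2 feeds those
#' point estimates, as fixed predictors named `alpha1`/`alpha2` for
#' comparability with the joint model, into the Bayesian proportional-hazards
#' model (adding the baseline covariates when `spec$adjusted`). Stage-1
#' uncertainty is deliberately not propagated — that is exactly the
#' approximation the joint model removes, and the source of the attenuation
#' this package is designed to exhibit.
#'
#' @inheritParams fit_mlm
#' @param stage1_spec Optional [model_spec()] for stage 1; defaults to
#'   `spec` itself (so the stage-1 model mirrors the cell's `adjusted` flag).
#' @param n_intervals,cuts Baseline-hazard grid for stage 2.
#' @return An object of class `two_stage_fit`: `mlm` (stage-1 `mlm_fit`),
#'   `ph` (stage-2 `ph_fit`), and `provenance` recording where the stage-2
#'   predictor scores came from.
#' @export
run_two_stage <- function(panel, cohort, spec = model_spec(),
                          mcmc = mcmc_control(), priors = prior_control(),
                          stage1_spec = NULL, n_intervals = 10, cuts = NULL,
                          seed = 1L) {
  if (is.null(stage1_spec)) stage1_spec <- spec
  mlm <- fit_mlm(panel, cohort, stage1_spec, mcmc, priors, seed = seed)
  sc <- mlm$scores

  ch <- cohort[cohort$sex == spec$stratum, , drop = FALSE]
  if (spec$subset == "decedents") ch <- ch[ch$event == 1, , drop = FALSE]
  d <- merge(ch, sc, by = "person_id")
  d$srh_c <- d$srh - 3
  preds <- c("u0_hat", if ("u1_hat" %in% names(sc)) "u1_hat")
  cn <- c(u0_hat = "alpha1", u1_hat = "alpha2")
  if (spec$adjusted) {
    d$start_age <- d$start_age_c
    preds <- c(preds, "start_age", "smoker", "srh_c")
    cn <- c(cn, start_age = "gamma_start_age", smoker = "gamma_smoker",
            srh_c = "gamma_srh")
  }
  ph <- fit_ph(d, predictors = preds, coef_names = cn, mcmc = mcmc,
               priors = priors, n_intervals = n_intervals, cuts = cuts,
               seed = seed + 1L)
  structure(list(mlm = mlm, ph = ph, spec = spec,
                 provenance = list(
                   stage1 = unclass(stage1_spec),
                   score_type = "posterior means of person-level random effects",
                   stage1_seed = seed, n_scores = nrow(sc))),
            class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Two-stage cognition-mortality analysis\n== Stage 1 (growth model) ==\n")
  print(x$mlm)
  cat("== Stage 2 (proportional hazards on stage-1 scores) ==\n")
  print(x$ph)
  invisible(x)
}

#' The 16-cell analysis grid
#'
#' All permutations of statistical framework (two-stage / joint), sex
#' stratum, cognitive domain, and covariate adjustment.
#'
#' @return Data frame with 16 rows and columns `framework`, `stratum`,
#'   `domain`, `adjusted`.
#' @export
analysis_grid <- function() {
  g <- expand.grid(framework = c("two_stage", "joint"),
                   stratum = c("women", "men"),
                   domain = c("Gc", "Gf"),
                   adjusted = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(g$domain, g$stratum, g$adjusted, g$framework), ]
}

#' Run every cell of the analysis grid
#'
#' Fits each grid cell (two-stage or joint, per stratum, domain and
#' adjustment). Failures are isolated per cell: an error is recorded in the
#' result and the grid continues. With `out_dir` set, each completed cell is
#' written as JSON and already-written cells are skipped on re-run
#' (resumability).
#'
#' @inheritParams run_two_stage
#' @param grid Data frame of cells, as from [analysis_grid()] (possibly
#'   filtered).
#' @param out_dir Optional directory for per-cell JSON artifacts and a
#'   combined CSV.
#' @return An object of class `grid_result`: a list of per-cell results
#'   (`two_stage_fit`, `joint_fit`, or `try-error` condition message), with
#'   the grid as an attribute.
#' @export
run_grid <- function(panel, cohort, grid = analysis_grid(),
                     mcmc = mcmc_control(), priors = prior_control(),
                     out_dir = NULL, seed = 1L) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- vector("list", nrow(grid))
  names(res) <- cell_id <- apply(grid, 1, function(r)
    paste(r[["framework"]], r[["stratum"]], r[["domain"]],
          if (as.logical(r[["adjusted"]])) "adj" else "unadj", sep = "_"))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    f <- if (!is.null(out_dir))
      file.path(out_dir, paste0(cell_id[i], ".json")) else NULL
    sp <- model_spec(form = "quadratic", adjusted = cell$adjusted,
                     stratum = cell$stratum, domain = cell$domain)
    res[[i]] <- tryCatch({
      fit <- if (cell$framework == "two_stage")
        run_two_stage(panel, cohort, sp, mcmc, priors,
                      seed = seed + 10L * i)
      else
        fit_joint(panel, cohort, sp, mcmc, priors, seed = seed + 10L * i)
      if (!is.null(f)) write_fit_json(fit, f)
      fit
    }, error = function(e) {
      structure(list(message = conditionMessage(e), cell = cell),
                class = "grid_cell_error")
    })
  }
  out <- structure(res, grid = grid, class = "grid_result")
  if (!is.null(out_dir))
    utils::write.csv(grid_summary(out),
                     file.path(out_dir, "grid_summary.csv"),
                     row.names = FALSE)
  out
}

#' Tabulate hazard coefficients across the grid
#'
#' One row per grid cell, with the raw posterior mean and 95% CI of each
#' hazard coefficient — the comparison-table layout of the analysis:
#' frameworks nested within stratum and domain, unadjusted and adjusted
#' variants side by side.
#'
#' @param grid_result A [run_grid()] result.
#' @return Data frame with one row per (cell, parameter).
#' @export
grid_summary <- function(grid_result) {
  grid <- attr(grid_result, "grid")
  rows <- list()
  for (i in seq_along(grid_result)) {
    fit <- grid_result[[i]]
    cell <- grid[i, ]
    if (inherits(fit, "grid_cell_error")) {
      rows[[i]] <- data.frame(cell, param = NA, mean = NA, lo = NA, hi = NA,
                              error = fit$message)
      next
    }
    s <- if (inherits(fit, "two_stage_fit")) fit$ph$summary else fit$summary
    keep <- grepl("^(alpha|gamma)", s$param)
    rows[[i]] <- data.frame(cell[rep(1, sum(keep)), ],
                            param = s$param[keep], mean = s$mean[keep],
                            lo = s$lo[keep], hi = s$hi[keep], error = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
write_fit_json <- function(fit, path) {
  s <- if (inherits(fit, "two_stage_fit")) fit$ph$summary else fit$summary
  jsonlite::write_json(
    list(class = class(fit),
         summary = as.data.frame(s),
         provenance = if (inherits(fit, "two_stage_fit")) fit$provenance
         else NULL),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
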