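#' Simulate a synthetic longitudinal-survival cohort
#'
#' Generates a cohort in which cognitive factor scores follow the
#' quadratic-growth multilevel model (random intercept and linear change,
#' fixed quadratic) and death times follow a proportional-hazards model whose
#' linear predictor includes the same person-level random effects
#' (`alpha1 * u0 + alpha2 * u1`). Assessments scheduled after death or after
#' the census are removed, so the missingness in the panel is
#' missing-not-at-random whenever the shared parameters are non-zero.
#'
#' All randomness is governed by `config$seed`; the same configuration
#' reproduces byte-identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort_sim`: a list with
#' \describe{
#'   \item{cohort}{one row per person: `person_id`, `sex`, `start_age_c`
#'     (entry age minus 65), `smoker`, `srh`, `event` (1 = death observed),
#'     `time` (years from entry to death or administrative censoring).}
#'   \item{panel}{one row per person, occasion and domain: `person_id`,
#'     `occasion`, `age_c` (age at assessment minus 65), `domain`, `score`.}
#'   \item{latent}{true random effects per person and domain (`u0`, `u1`),
#'     kept for recovery tests.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_cohort(sim_config(n_individuals = 200, seed = 42))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals

  sex <- ifelse(stats::rbinom(n, 1, config$prop_women) == 1, "women", "men")
  ea <- config$entry_age
  sd_age <- diff(ea$iqr) / (2 * stats::qnorm(0.75))
  plo <- stats::pnorm(ea$min, ea$median, sd_age)
  phi <- stats::pnorm(ea$max, ea$median, sd_age)
  entry_age <- stats::qnorm(stats::runif(n, plo, phi), ea$median, sd_age)
  smoker <- stats::rbinom(n, 1, config$prop_smokers)
  srh <- sample.int(5, n, replace = TRUE, prob = config$srh_probs)
  start_age_c <- entry_age - 65
  srh_c <- srh - 3

  # latent random effects, one independent pair per domain
  latent <- list()
  for (d in config$domains) {
    u <- matrix(0, n, 2)
    for (s in c("women", "men")) {
      idx <- which(sex == s)
      g <- config$growth[[s]][[d]]
      S <- re_cov(g)
      if (length(idx))
        u[idx, ] <- MASS::mvrnorm(length(idx), c(0, 0), S)
    }
    latent[[d]] <- u
  }

  # death times from the shared-random-effects hazard
  uh <- latent[[config$hazard_domain]]
  udraw <- stats::runif(n)
  t_death <- numeric(n)
  for (s in c("women", "men")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    hp <- config$hazard[[s]]
    linpred <- hp$gamma["start_age"] * start_age_c[idx] +
      hp$gamma["smoker"] * smoker[idx] + hp$gamma["srh"] * srh_c[idx] +
      hp$alpha1 * uh[idx, 1] + hp$alpha2 * uh[idx, 2]
    t_death[idx] <- sample_survival_time(udraw[idx], linpred, hp$baseline)
  }
  event <- as.integer(t_death <= config$census_horizon)
  time <- pmin(t_death, config$census_horizon)

  cohort <- data.frame(person_id = seq_len(n), sex = sex,
                       start_age_c = start_age_c, smoker = smoker,
                       srh = srh, event = event, time = time)

  # visit schedule: first visit at entry, then gaps ~ U(visit_gap);
  # retention thins later visits independently of outcome and survival
  K <- config$max_occasions
  visit_time <- matrix(0, n, K)
  if (K > 1) {
    gaps <- matrix(stats::runif(n * (K - 1), config$visit_gap[1],
                                config$visit_gap[2]), n, K - 1)
    visit_time[, -1] <- t(apply(gaps, 1, cumsum))
    keep <- matrix(stats::rbinom(n * (K - 1), 1, config$retention) == 1,
                   n, K - 1)
    # a missed visit ends participation (monotone dropout)
    completed <- 1L + apply(keep, 1, function(z) {
      w <- which(!z)
      if (length(w)) w[1] - 1L else length(z)
    })
  } else {
    completed <- rep(1L, n)
  }

  occ_keep <- outer(completed, seq_len(K), ">=")
  panel <- NULL
  for (d in config$domains) {
    u <- latent[[d]]
    score <- matrix(NA_real_, n, K)
    for (s in c("women", "men")) {
      idx <- which(sex == s)
      if (!length(idx)) next
      g <- config$growth[[s]][[d]]
      a <- start_age_c[idx] + visit_time[idx, , drop = FALSE]
      mu <- g$B0 + g$B1 * a + g$B2 * a^2 +
        g$B3 * start_age_c[idx] + g$B4 * start_age_c[idx] * a +
        g$B5 * smoker[idx] + g$B6 * srh_c[idx] +
        u[idx, 1] + u[idx, 2] * a
      eps <- matrix(stats::rnorm(length(idx) * K, 0, sqrt(g$var_resid)),
                    length(idx), K)
      score[idx, ] <- mu + eps
    }
    rows <- which(occ_keep, arr.ind = TRUE)
    panel <- rbind(panel, data.frame(
      person_id = rows[, 1],
      occasion = rows[, 2],
      age_c = start_age_c[rows[, 1]] + visit_time[cbind(rows[, 1], rows[, 2])],
      domain = d,
      score = score[cbind(rows[, 1], rows[, 2])]))
  }
  panel <- panel[order(panel$domain, panel$person_id, panel$occasion), ]
  rownames(panel) <- NULL
  panel <- truncate_panel(panel, cohort)

  latent_df <- do.call(rbind, lapply(config$domains, function(d)
    data.frame(person_id = seq_len(n), domain = d,
               u0 = latent[[d]][, 1], u1 = latent[[d]][, 2])))

  structure(list(cohort = cohort, panel = panel, latent = latent_df,
                 config = config),
            class = "cohort_sim")
}

re_cov <- function(g) {
  sd0 <- sqrt(g$var_u0); sd1 <- sqrt(g$var_u1)
  matrix(c(g$var_u0, g$corr_u0u1 * sd0 * sd1,
           g$corr_u0u1 * sd0 * sd1, g$var_u1), 2, 2)
}

#' Remove assessments scheduled after death or censoring
#'
#' Implements the death-related dropout mechanism: a person contributes
#' observations only while alive and before the census, so all retained
#' assessment ages satisfy `age <= entry age + min(time to death, census)`.
#'
#' @param panel A long panel (`person_id`, `occasion`, `age_c`, `domain`,
#'   `score`).
#' @param cohort A cohort table with `person_id`, `start_age_c`, `time`.
#' @return The panel with out-of-window rows removed (row count
#'   non-increasing).
#' @export
truncate_panel <- function(panel, cohort) {
  orphans <- setdiff(unique(panel$person_id), cohort$person_id)
  if (length(orphans))
    stop("panel contains person ids absent from the cohort: ",
         paste(utils::head(orphans, 20), collapse = ", "), call. = FALSE)
  m <- match(panel$person_id, cohort$person_id)
  elapsed <- panel$age_c - cohort$start_age_c[m]
  out <- panel[elapsed <= cohort$time[m] + 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  n <- nrow(x$cohort)
  cat(sprintf("Synthetic cohort: %d persons, %d panel rows (%s)\n",
              n, nrow(x$panel), paste(x$config$domains, collapse = "/")))
  cat(sprintf("  %.1f%% women, %.1f%% smokers, %.1f%% deceased by census\n",
              100 * mean(x$cohort$sex == "women"),
              100 * mean(x$cohort$smoker),
              100 * mean(x$cohort$event)))
  occ <- table(x$panel$person_id[x$panel$domain == x$config$domains[1]])
  cat(sprintf("  mean completed occasions: %.2f\n", mean(occ)))
  invisible(x)
}
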