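# Brute-force oracle for the joint log-posterior on tiny data: direct
# density products, numeric integration of the cumulative hazard, and prior
# densities written from scratch (inverse-gamma via the gamma density of the
# reciprocal, inverse-Wishart via the Wishart density of the inverse).
brute_joint_lp <- function(params, panel, cohort, spec, priors) {
  ch <- cohort[cohort$sex == spec$stratum, ]
  ch <- ch[order(ch$person_id), ]
  pn <- panel[panel$domain == spec$domain &
                panel$person_id %in% ch$person_id, ]
  g <- params$growth; hz <- params$hazard
  U <- params$u
  Sg <- as.matrix(g$Sigma)
  total <- 0
  for (i in seq_len(nrow(ch))) {
    prs <- pn[pn$person_id == ch$person_id[i], ]
    a <- prs$age_c
    mu <- g$B[["B0"]] + g$B[["B1"]] * a + g$B[["B2"]] * a^2 +
      U[i, 1] + U[i, 2] * a
    total <- total + sum(dnorm(prs$score, mu, sqrt(g$sigma2), log = TRUE))
    eta <- sum(hz$alpha * U[i, ])
    ti <- ch$time[i]
    H <- stats::integrate(function(s) hazard_rate(hz$baseline, s), 0, ti,
                          subdivisions = 4000L, rel.tol = 1e-13)$value
    total <- total + ch$event[i] *
      (log(hazard_rate(hz$baseline, ti)) + eta) - H * exp(eta)
    # bivariate normal density, direct formula
    det <- Sg[1, 1] * Sg[2, 2] - Sg[1, 2]^2
    q <- (Sg[2, 2] * U[i, 1]^2 - 2 * Sg[1, 2] * U[i, 1] * U[i, 2] +
            Sg[1, 1] * U[i, 2]^2) / det
    total <- total - log(2 * pi) - 0.5 * log(det) - 0.5 * q
  }
  # priors
  total <- total + sum(dnorm(g$B, 0, priors$beta_sd, log = TRUE))
  total <- total + dgamma(1 / g$sigma2, priors$resid_a,
                          rate = priors$resid_b, log = TRUE) -
    2 * log(g$sigma2)
  # inverse-Wishart via Wishart density of the inverse
  df <- priors$wishart_df
  Sc <- diag(priors$wishart_scale[1:2])
  p <- 2
  W <- solve(Sg)
  lg2 <- sum(lgamma((df + 1 - 1:p) / 2)) + (p * (p - 1) / 4) * log(pi)
  ldW <- (df - p - 1) / 2 * log(det(W)) - sum(diag(Sc %*% W)) / 2 -
    (df * p / 2) * log(2) + (df / 2) * log(det(Sc)) - lg2
  total <- total + ldW + (p + 1) * log(det(W))
  total <- total + sum(dgamma(hz$baseline$rates, priors$hazard_a,
                              rate = priors$hazard_b, log = TRUE))
  total <- total + sum(dnorm(hz$alpha, 0, priors$coef_sd, log = TRUE))
  total
}

toy_params <- function(alpha = c(-0.04, -0.9)) {
  list(growth = list(B = c(B0 = 0.3, B1 = 0.05, B2 = -0.015),
                     sigma2 = 1.2,
                     Sigma = matrix(c(6, 0.25, 0.25, 0.08), 2, 2)),
       hazard = list(baseline = piecewise_hazard(c(4, 12),
                                                 c(0.03, 0.08, 0.2)),
                     gamma = numeric(0), alpha = alpha))
}
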