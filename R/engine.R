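# Metropolis-within-Gibbs engine shared by fit_mlm() and fit_joint().
#
# Blocks:
#   B        conjugate normal (linear model given random effects)
#   var_resid conjugate inverse-gamma
#   Sigma    conjugate inverse-Wishart (inverse-gamma when q = 1)
#   u_i      exact conjugate draw in the pure longitudinal model; in the
#            joint model, Metropolis with the longitudinal full conditional
#            as independence proposal (acceptance ratio involves only the
#            hazard term), alternating with an adaptive random-walk step
#   lambda_k conjugate gamma (piecewise-exponential likelihood)
#   gamma,alpha  componentwise adaptive random-walk Metropolis
#
# All adaptation happens during burn-in only, so the kept draws target the
# exact posterior.

#' @keywords internal
assemble_model_data <- function(panel, cohort, spec,
                                n_intervals = 10, cuts = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ch <- cohort[cohort$sex == spec$stratum, , drop = FALSE]
  if (spec$subset == "decedents") ch <- ch[ch$event == 1, , drop = FALSE]
  pn <- panel[panel$domain == spec$domain &
                panel$person_id %in% ch$person_id, , drop = FALSE]
  ch <- ch[ch$person_id %in% pn$person_id, , drop = FALSE]
  if (nrow(ch) == 0 || nrow(pn) == 0)
    stop("empty subset: no persons match stratum '", spec$stratum,
         "', domain '", spec$domain, "', subset '", spec$subset, "'",
         call. = FALSE)
  ch <- ch[order(ch$person_id), , drop = FALSE]
  pn <- pn[order(pn$person_id, pn$occasion), , drop = FALSE]
  pid <- match(pn$person_id, ch$person_id)

  a <- pn$age_c
  sa <- ch$start_age_c[pid]
  srh_c <- ch$srh[pid] - 3
  smoker <- ch$smoker[pid]
  X <- switch(spec$form,
    intercept_only = cbind(B0 = rep(1, nrow(pn))),
    linear = cbind(B0 = 1, B1 = a),
    quadratic = cbind(B0 = 1, B1 = a, B2 = a^2))
  if (spec$adjusted) {
    X <- cbind(X, B3 = sa, B5 = smoker, B6 = srh_c)
    if (spec$form != "intercept_only") X <- cbind(X, B4 = sa * a)
    X <- X[, intersect(c("B0", "B1", "B2", "B3", "B4", "B5", "B6"),
                       colnames(X)), drop = FALSE]
  }
  q <- if (spec$form == "intercept_only") 1L else 2L

  n <- nrow(ch)
  ni <- as.numeric(rowsum(rep(1, nrow(pn)), pid, reorder = TRUE))
  Sa <- as.numeric(rowsum(a, pid))
  Saa <- as.numeric(rowsum(a^2, pid))

  W <- if (spec$adjusted)
    cbind(start_age = ch$start_age_c, smoker = ch$smoker, srh = ch$srh - 3)
  else matrix(0, n, 0)

  time <- ch$time
  event <- ch$event
  if (is.null(cuts)) {
    et <- time[event == 1]
    if (length(et) >= n_intervals)
      cuts <- unique(stats::quantile(et, probs = seq_len(n_intervals - 1) /
                                       n_intervals, names = FALSE))
    else cuts <- numeric(0)
  }
  K <- length(cuts) + 1L
  edges <- c(0, cuts)
  E <- matrix(0, n, K)
  for (k in seq_len(K)) {
    hi <- if (k < K) edges[k + 1] else Inf
    E[, k] <- pmax(0, pmin(time, hi) - edges[k])
  }
  int_of_t <- findInterval(time, edges)
  dk <- as.numeric(rowsum(as.numeric(event), factor(int_of_t, levels = 1:K)))
  dk[is.na(dk)] <- 0

  list(spec = spec, y = pn$score, a = a, pid = pid, X = X, q = q,
       n = n, nobs = nrow(pn), ni = ni, Sa = Sa, Saa = Saa,
       person_id = ch$person_id, W = W, time = time, event = event,
       cuts = cuts, E = E, dk = dk,
       panel = pn, cohort = ch)
}

#' @keywords internal
default_init <- function(md, priors, joint) {
  p <- ncol(md$X)
  fit <- stats::lm.fit(md$X, md$y)
  B <- fit$coefficients
  B[is.na(B)] <- 0
  r <- md$y - md$X %*% B
  pm <- as.numeric(rowsum(as.numeric(r), md$pid)) / md$ni
  s2 <- max(stats::var(as.numeric(r)) / 2, 1e-4)
  v0 <- max(stats::var(pm), 1e-3)
  Sigma <- if (md$q == 2) diag(c(v0, 0.01)) else matrix(v0, 1, 1)
  out <- list(B = B, sigma2 = s2, Sigma = Sigma, u = matrix(0, md$n, md$q))
  if (joint) {
    tot_event <- sum(md$event)
    exp_tot <- colSums(md$E)
    out$lambda <- pmax(md$dk, 0.5) / pmax(exp_tot, 1e-8)
    out$gamma <- rep(0, ncol(md$W))
    out$alpha <- rep(0, md$q)
  }
  out
}

#' @keywords internal
check_init <- function(init, md, joint) {
  p <- ncol(md$X)
  if (!is.null(init$B) && length(init$B) != p)
    stop("initialization dimension mismatch for B: expected ", p,
         " fixed effects (", paste(colnames(md$X), collapse = ", "),
         "), got ", length(init$B), call. = FALSE)
  if (!is.null(init$Sigma) && !all(dim(as.matrix(init$Sigma)) == md$q))
    stop("initialization dimension mismatch for Sigma: expected ",
         md$q, "x", md$q, call. = FALSE)
  if (joint) {
    if (!is.null(init$gamma) && length(init$gamma) != ncol(md$W))
      stop("initialization dimension mismatch for gamma: expected ",
           ncol(md$W), " covariate coefficients", call. = FALSE)
    if (!is.null(init$alpha) && length(init$alpha) != md$q)
      stop("initialization dimension mismatch for alpha: expected ",
           md$q, call. = FALSE)
    if (!is.null(init$lambda) && length(init$lambda) != length(md$dk))
      stop("initialization dimension mismatch for lambda: expected ",
           length(md$dk), " baseline levels", call. = FALSE)
  }
  invisible(TRUE)
}

# Translation ("interweaving") moves between fixed effects and latent
# effects. A fixed effect whose design column is constant within person
# (intercept, entry age, smoking, SRH) is confounded with the random
# intercept; one whose column is (person covariate) x age is confounded
# with the random linear change; the fixed quadratic is confounded with the
# per-person projection of age^2 onto span(1, age) -- exact for persons
# with at most two observations. Each move shifts (B_j -> B_j + delta,
# u_i -> u_i - delta * c_i), with delta drawn from its exact Gaussian full
# conditional (random-effects prior + fixed-effect prior + the residual
# mismatch term for the quadratic move, which is the only move that touches
# the likelihood). This removes the slow random-walk mixing of the centered
# parameterization. In the joint model the hazard term is not
# translation-invariant, so each draw is accepted with a Metropolis
# correction exp(delta hazard log-likelihood).
#' @keywords internal
build_interweave_moves <- function(md) {
  cols <- colnames(md$X)
  n <- md$n
  z0 <- rep(0, n)
  person_c <- function(nm) switch(nm,
    B0 = rep(1, n),
    B3 = md$cohort$start_age_c,
    B5 = md$cohort$smoker,
    B6 = md$cohort$srh - 3,
    B1 = rep(1, n),
    B4 = md$cohort$start_age_c,
    NULL)
  moves <- list()
  for (j in seq_along(cols)) {
    nm <- cols[j]
    if (nm == "B2" && md$q == 2) {
      # per-person LS projection of age^2 on (1, age)
      Sy <- as.numeric(rowsum(md$a^2, md$pid))
      Say <- as.numeric(rowsum(md$a^3, md$pid))
      det <- md$ni * md$Saa - md$Sa^2
      one_obs <- det < 1e-10
      c1 <- ifelse(one_obs, 0, (md$ni * Say - md$Sa * Sy) / det)
      c0 <- ifelse(one_obs, Sy / md$ni, (Sy - c1 * md$Sa) / md$ni)
      m <- md$a^2 - c0[md$pid] - c1[md$pid] * md$a
      m[abs(m) < 1e-12] <- 0
      moves[[length(moves) + 1]] <-
        list(j = j, c0 = c0, c1 = c1, m = m, sum_m2 = sum(m^2))
      next
    }
    cc <- person_c(nm)
    if (is.null(cc)) next
    slope <- nm %in% c("B1", "B4")
    if (slope && md$q < 2) next
    moves[[length(moves) + 1]] <-
      list(j = j, c0 = if (slope) z0 else cc, c1 = if (slope) cc else z0,
           m = NULL, sum_m2 = 0)
  }
  moves
}

#' @keywords internal
run_chain <- function(md, mcmc, priors, joint, init, chain_seed) {
  set.seed(chain_seed)
  q <- md$q; n <- md$n; nobs <- md$nobs; p <- ncol(md$X)
  X <- md$X; y <- md$y; a <- md$a; pid <- md$pid
  XtX <- crossprod(X)
  mW <- ncol(md$W)
  K <- length(md$dk)

  st <- default_init(md, priors, joint)
  for (nm in names(init)) st[[nm]] <- init[[nm]]
  B <- as.numeric(st$B); s2 <- st$sigma2
  Sigma <- as.matrix(st$Sigma); U <- st$u
  if (joint) {
    lambda <- st$lambda; gam <- st$gamma; alpha <- st$alpha
  }

  moves <- build_interweave_moves(md)

  # adaptive step sizes
  s_u <- 1.0
  s_beta <- rep(0.1, mW + if (joint) q else 0)
  acc_u <- 0; try_u <- 0
  acc_b <- rep(0, length(s_beta)); try_b <- rep(0, length(s_beta))

  n_iter <- mcmc$burnin + mcmc$iter
  keep_idx <- 0
  par_names <- c(colnames(X),
                 if (q == 2) c("var_u0", "var_u1", "corr_u0u1") else "var_u0",
                 "var_resid")
  if (joint)
    par_names <- c(par_names,
                   if (mW) paste0("gamma_", colnames(md$W)),
                   paste0("alpha", seq_len(q)),
                   paste0("lambda", seq_len(K)), "lp__")
  n_keep <- floor(mcmc$iter / mcmc$thin)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  u_mean <- matrix(0, n, q); u_m2 <- matrix(0, n, q); u_cnt <- 0

  haz_term <- function(U, eta_w, H0) {
    # per-person survival log-likelihood contribution given latent effects
    eta <- eta_w + as.numeric(U %*% alpha)
    md$event * eta - exp(eta) * H0
  }

  for (it in seq_len(n_iter)) {
    adapting <- it <= mcmc$burnin

    ## residuals against fixed effects
    r <- y - as.numeric(X %*% B)
    Sr <- as.numeric(rowsum(r, pid))
    if (q == 2) Sar <- as.numeric(rowsum(r * a, pid))

    ## --- latent random effects ---
    if (q == 2) {
      Om <- chol2inv(chol(Sigma))
      P11 <- md$ni / s2 + Om[1, 1]
      P12 <- md$Sa / s2 + Om[1, 2]
      P22 <- md$Saa / s2 + Om[2, 2]
      det <- P11 * P22 - P12^2
      V11 <- P22 / det; V12 <- -P12 / det; V22 <- P11 / det
      b1 <- Sr / s2; b2 <- Sar / s2
      m1 <- V11 * b1 + V12 * b2
      m2 <- V12 * b1 + V22 * b2
      L11 <- sqrt(V11); L21 <- V12 / L11; L22 <- sqrt(pmax(V22 - L21^2, 1e-300))
      e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
      prop1 <- m1 + L11 * e1
      prop2 <- m2 + L21 * e1 + L22 * e2
      if (!joint) {
        U[, 1] <- prop1; U[, 2] <- prop2
      } else {
        eta_w <- if (mW) as.numeric(md$W %*% gam) else rep(0, n)
        H0 <- as.numeric(md$E %*% lambda)
        if (it %% 2 == 1) {
          # independence proposal from the longitudinal conditional
          cur <- haz_term(U, eta_w, H0)
          prop <- haz_term(cbind(prop1, prop2), eta_w, H0)
          acc <- log(stats::runif(n)) < (prop - cur)
        } else {
          # random-walk refreshment, full conditional ratio
          rw1 <- U[, 1] + s_u * L11 * e1
          rw2 <- U[, 2] + s_u * (L21 * e1 + L22 * e2)
          lp_part <- function(u1v, u2v) {
            lin <- (u1v * b1 + u2v * b2) -
              0.5 * (u1v^2 * (md$ni / s2) + 2 * u1v * u2v * (md$Sa / s2) +
                       u2v^2 * (md$Saa / s2))
            pri <- -0.5 * (Om[1, 1] * u1v^2 + 2 * Om[1, 2] * u1v * u2v +
                             Om[2, 2] * u2v^2)
            lin + pri + haz_term(cbind(u1v, u2v), eta_w, H0)
          }
          acc <- log(stats::runif(n)) < (lp_part(rw1, rw2) - lp_part(U[, 1], U[, 2]))
          prop1 <- rw1; prop2 <- rw2
        }
        U[acc, 1] <- prop1[acc]
        U[acc, 2] <- prop2[acc]
        try_u <- try_u + 1; acc_u <- acc_u + mean(acc)
        if (adapting && it %% 2 == 0 && it %% 50 == 0) {
          rate <- acc_u / try_u
          s_u <- s_u * exp(rate - 0.35)
          acc_u <- 0; try_u <- 0
        }
      }
    } else {
      Om <- 1 / Sigma[1, 1]
      P <- md$ni / s2 + Om
      V <- 1 / P
      m <- V * (Sr / s2)
      prop <- m + sqrt(V) * stats::rnorm(n)
      if (!joint) U[, 1] <- prop
      else {
        eta_w <- if (mW) as.numeric(md$W %*% gam) else rep(0, n)
        H0 <- as.numeric(md$E %*% lambda)
        cur <- haz_term(U, eta_w, H0)
        prp <- haz_term(cbind(prop), eta_w, H0)
        acc <- log(stats::runif(n)) < (prp - cur)
        U[acc, 1] <- prop[acc]
      }
    }

    ## --- fixed effects ---
    uy <- U[pid, 1] + if (q == 2) U[pid, 2] * a else 0
    ystar <- y - uy
    A <- XtX / s2 + diag(1 / priors$beta_sd^2, p)
    bmean <- solve(A, crossprod(X, ystar) / s2)
    Rch <- chol(A)
    B <- as.numeric(bmean + backsolve(Rch, stats::rnorm(p)))

    ## --- residual variance ---
    resid <- ystar - as.numeric(X %*% B)
    SS <- sum(resid^2)
    s2 <- 1 / stats::rgamma(1, priors$resid_a + nobs / 2,
                            priors$resid_b + SS / 2)

    ## --- random-effects covariance ---
    if (q == 2) {
      Sp <- diag(priors$wishart_scale[1:2]) + crossprod(U)
      df <- priors$wishart_df + n
      Wdraw <- stats::rWishart(1, df, chol2inv(chol(Sp)))[, , 1]
      Sigma <- chol2inv(chol(Wdraw))
    } else {
      Sigma[1, 1] <- 1 / stats::rgamma(1, priors$resid_a + n / 2,
                                       priors$wishart_scale[1] / 2 +
                                         sum(U[, 1]^2) / 2)
    }

    ## --- interweaving translation moves (fixed effect <-> latent mean) ---
    if (length(moves)) {
      OmI <- if (q == 2) chol2inv(chol(Sigma)) else matrix(1 / Sigma[1, 1], 1, 1)
      if (joint) {
        eta_cur <- (if (mW) as.numeric(md$W %*% gam) else rep(0, n)) +
          as.numeric(U %*% alpha)
        H0_cur <- as.numeric(md$E %*% lambda)
      }
      e_cur <- resid  # y - XB - Zu, invariant under the exact moves
      for (mv in moves) {
        c0 <- mv$c0; c1 <- if (q == 2) mv$c1 else NULL
        quadC <- OmI[1, 1] * sum(c0^2) +
          (if (q == 2) 2 * OmI[1, 2] * sum(c0 * c1) +
             OmI[2, 2] * sum(c1^2) else 0)
        cross <- OmI[1, 1] * sum(c0 * U[, 1]) +
          (if (q == 2) OmI[1, 2] * (sum(c0 * U[, 2]) + sum(c1 * U[, 1])) +
             OmI[2, 2] * sum(c1 * U[, 2]) else 0)
        prec <- quadC + mv$sum_m2 / s2 + 1 / priors$beta_sd^2
        num <- cross - B[mv$j] / priors$beta_sd^2 +
          (if (!is.null(mv$m)) sum(e_cur * mv$m) / s2 else 0)
        delta <- num / prec + stats::rnorm(1) / sqrt(prec)
        ok <- TRUE
        if (joint) {
          deta <- -delta * (alpha[1] * c0 +
                              if (q == 2) alpha[2] * c1 else 0)
          dll <- sum(md$event * deta) -
            sum((exp(eta_cur + deta) - exp(eta_cur)) * H0_cur)
          ok <- log(stats::runif(1)) < dll
          if (ok) eta_cur <- eta_cur + deta
        }
        if (ok) {
          B[mv$j] <- B[mv$j] + delta
          U[, 1] <- U[, 1] - delta * c0
          if (q == 2) U[, 2] <- U[, 2] - delta * c1
          if (!is.null(mv$m)) e_cur <- e_cur - delta * mv$m
        }
      }
    }

    if (joint) {
      ## --- baseline hazard levels (conjugate gamma) ---
      eta <- (if (mW) as.numeric(md$W %*% gam) else rep(0, n)) +
        as.numeric(U %*% alpha)
      expEta <- exp(eta)
      expo <- as.numeric(crossprod(md$E, expEta))
      lambda <- stats::rgamma(K, priors$hazard_a + md$dk,
                              priors$hazard_b + expo)
      H0 <- as.numeric(md$E %*% lambda)

      ## --- hazard coefficients, componentwise adaptive RW ---
      coefs <- c(gam, alpha)
      Xs <- if (mW) cbind(md$W, U) else U
      for (j in seq_along(coefs)) {
        prop_j <- coefs[j] + s_beta[j] * stats::rnorm(1)
        deta <- (prop_j - coefs[j]) * Xs[, j]
        dll <- sum(md$event * deta) - sum((exp(eta + deta) - expEta) * H0) +
          (stats::dnorm(prop_j, 0, priors$coef_sd, log = TRUE) -
             stats::dnorm(coefs[j], 0, priors$coef_sd, log = TRUE))
        try_b[j] <- try_b[j] + 1
        if (log(stats::runif(1)) < dll) {
          coefs[j] <- prop_j
          eta <- eta + deta
          expEta <- exp(eta)
          acc_b[j] <- acc_b[j] + 1
        }
      }
      if (adapting && it %% 50 == 0) {
        rate <- acc_b / pmax(try_b, 1)
        s_beta <- s_beta * exp(rate - 0.44)
        acc_b[] <- 0; try_b[] <- 0
      }
      if (mW) gam <- coefs[seq_len(mW)]
      alpha <- coefs[mW + seq_len(q)]
    }

    ## --- store ---
    if (!adapting && ((it - mcmc$burnin) %% mcmc$thin == 0)) {
      keep_idx <- keep_idx + 1
      row <- c(B,
               if (q == 2) c(Sigma[1, 1], Sigma[2, 2],
                             Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]))
               else Sigma[1, 1],
               s2)
      if (joint) {
        eta <- (if (mW) as.numeric(md$W %*% gam) else rep(0, n)) +
          as.numeric(U %*% alpha)
        H0 <- as.numeric(md$E %*% lambda)
        loglam <- log(lambda)[findInterval(md$time, c(0, md$cuts))]
        surv_ll <- sum(md$event * (loglam + eta)) - sum(exp(eta) * H0)
        r2 <- y - as.numeric(X %*% B) - (U[pid, 1] +
                                           if (q == 2) U[pid, 2] * a else 0)
        long_ll <- -0.5 * nobs * log(2 * pi * s2) - sum(r2^2) / (2 * s2)
        lp <- long_ll + surv_ll
        row <- c(row, if (mW) gam else NULL, alpha, lambda, lp)
      }
      draws[keep_idx, ] <- row
      u_cnt <- u_cnt + 1
      dlt <- U - u_mean
      u_mean <- u_mean + dlt / u_cnt
      u_m2 <- u_m2 + dlt * (U - u_mean)
    }
  }

  u_sd <- sqrt(u_m2 / max(u_cnt - 1, 1))
  list(draws = draws[seq_len(keep_idx), , drop = FALSE],
       u_mean = u_mean, u_sd = u_sd,
       accept = list(u = if (try_u > 0) acc_u / try_u else NA_real_),
       step = list(u = s_u, beta = s_beta))
}

#' @keywords internal
run_sampler <- function(md, mcmc, priors, joint, init = list(), seed = 1L) {
  check_init(init, md, joint)
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    run_chain(md, mcmc, priors, joint, init,
              chain_seed = as.integer(seed) + 1000L * (ch - 1L)))
  draws <- lapply(chains, `[[`, "draws")
  u_mean <- Reduce(`+`, lapply(chains, `[[`, "u_mean")) / length(chains)
  # pooled posterior SD: within-chain variance + between-chain spread
  u_sd <- sqrt(Reduce(`+`, lapply(chains, function(c)
    c$u_sd^2 + (c$u_mean - u_mean)^2)) / length(chains))
  list(draws = draws, u_mean = u_mean, u_sd = u_sd,
       accept = lapply(chains, `[[`, "accept"))
}
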