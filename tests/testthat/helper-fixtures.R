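# Shared fixtures built in code: small simulated datasets with known truths.

# Simulated patient table with arms assigned completely at random
# (equal 1/4) under a given scenario truth.
make_patients <- function(n, scenario, seed, delay = 6, duration = 36) {
  set.seed(seed)
  pr <- sample_profile(n, scenario$prevalence)
  arm <- sample(c("control", "T1", "T2", "T3"), n, replace = TRUE)
  p <- response_probability(scenario, arm, pr)
  acc <- build_accrual(n, duration)
  tibble::tibble(
    index = seq_len(n), b1 = pr$b1, b2 = pr$b2, b3 = pr$b3,
    profile = pr$profile, recruit_time = acc$recruit_time,
    arm = arm, outcome = sample_outcome(p),
    outcome_time = acc$recruit_time + delay
  )
}

# A strong linked-effect truth used by several posterior tests:
# T1 doubles response (0.3 -> 0.6) in B1-positive patients.
strong_s2 <- function() scenario_library()[["S2"]]

# Independent posterior reference via self-normalised importance sampling.
# The proposal is a wide multivariate t centred at the classical glm ML fit
# (an independent estimation route), so no code is shared with the package's
# Laplace path. Returns a function(contrast) -> posterior P(c'beta > 0).
is_reference <- function(patients, priors, n_draws = 2e5, seed = 99,
                         scale = 1.6, df = 5) {
  X <- build_design_matrix(patients)
  y <- attr(X, "y")
  prec <- numeric(16); pmean <- numeric(16)
  if (!is.null(priors$linked_pairs)) {
    idx <- 7L + (priors$linked_pairs[, 1] - 1L) * 3L + priors$linked_pairs[, 2]
    prec[idx] <- 1 / priors$linked_var
    pmean[idx] <- priors$linked_mean
  }
  # own damped-Newton maximiser of the penalised log-likelihood (proposal
  # centre only; weight correction below is exact regardless)
  beta <- numeric(16)
  for (it in 1:60) {
    mu <- stats::plogis(drop(X %*% beta))
    g <- drop(crossprod(X, y - mu)) - prec * (beta - pmean)
    H <- crossprod(X * sqrt(mu * (1 - mu))) + diag(prec + 1e-3, 16)
    step_v <- solve(H, g)
    if (max(abs(step_v)) > 2) step_v <- step_v * 2 / max(abs(step_v))
    beta <- pmin(pmax(beta + step_v, priors$box_low), priors$box_high)
    if (max(abs(step_v)) < 1e-8) break
  }
  ctr <- beta
  Sig <- solve(crossprod(X * sqrt(stats::plogis(drop(X %*% ctr)) *
                                    (1 - stats::plogis(drop(X %*% ctr))))) +
                 diag(prec + 1e-3, 16))
  L <- t(chol(Sig)) * scale
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * 16), 16, n_draws)
  chi <- sqrt(stats::rchisq(n_draws, df) / df)
  D <- t(ctr + L %*% sweep(Z, 2, chi, "/"))          # n_draws x 16 mvt draws
  # log target (likelihood + prior) minus log proposal density, in chunks
  lw <- numeric(n_draws)
  for (ix in split(seq_len(n_draws), ceiling(seq_len(n_draws) / 10000))) {
    eta <- D[ix, , drop = FALSE] %*% t(X)
    lw[ix] <- drop(eta %*% y) -
      rowSums(ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  lw <- lw - colSums(prec * (t(D) - pmean)^2) / 2 +
    (df + 16) / 2 * log1p(colSums(Z^2) / chi^2 / df)
  lw[!apply(D >= priors$box_low & D <= priors$box_high, 1L, all)] <- -Inf
  wgt <- exp(lw - max(lw))
  out <- function(contrast) {
    s <- drop(D %*% contrast)
    sum(wgt * (s > 0)) / sum(wgt)
  }
  attr(out, "ess") <- sum(wgt)^2 / sum(wgt^2)
  out
}
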