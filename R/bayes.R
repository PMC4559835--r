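#' Prior specification for the interim Bayesian model
#'
#' All 16 regression coefficients receive flat priors on a box (default
#' \[-10, 10\]) except the treatment-biomarker interactions named in
#' `linked_pairs`, which receive an informative normal prior (default
#' mean 1, variance 1). In the linked-BAR design the linked pairs are the
#' diagonal `(T1,B1), (T2,B2), (T3,B3)`; the non-linked BAR design uses no
#' informative priors.
#'
#' @param linked_pairs Two-column matrix (or list of length-2 vectors) of
#'   (treatment, biomarker) index pairs; `NULL` for none.
#' @param linked_mean,linked_var Normal prior mean and variance for linked
#'   interactions.
#' @param box_low,box_high Bounds of the flat priors.
#' @return An object of class `prior_spec`.
#' @export
#' @examples
#' prior_spec()                      # linked-BAR default
#' prior_spec(linked_pairs = NULL)   # fully uninformative
prior_spec <- function(linked_pairs = cbind(1:3, 1:3),
                       linked_mean = 1, linked_var = 1,
                       box_low = -10, box_high = 10) {
  if (is.list(linked_pairs)) linked_pairs <- do.call(rbind, linked_pairs)
  if (!is.null(linked_pairs)) {
    linked_pairs <- matrix(as.integer(linked_pairs), ncol = 2L)
    stopifnot(all(linked_pairs %in% 1:3))
  }
  stopifnot(box_low < box_high, linked_var > 0)
  structure(
    list(linked_pairs = linked_pairs, linked_mean = linked_mean,
         linked_var = linked_var, box_low = box_low, box_high = box_high),
    class = "prior_spec"
  )
}

coef_names <- function() {
  c("intercept", paste0("theta", 1:3), paste0("beta", 1:3),
    paste0("gamma", rep(1:3, each = 3), rep(1:3, 3)))
}

# position of gamma_{kj} in the 16-coefficient layout
gamma_pos <- function(k, j) 7L + (k - 1L) * 3L + j

#' Design matrix of the 16-parameter logistic model
#'
#' One row per patient, columns in the fixed order: intercept, three
#' treatment main effects, three biomarker main effects, nine
#' treatment-by-biomarker interactions (row-major, treatment by biomarker).
#' The interaction column `gamma_kj` is 1 iff the patient is on arm `k`
#' and positive for biomarker `j`.
#'
#' @param patients Data frame with columns `b1`, `b2`, `b3`, `arm`, and
#'   `outcome` (no pending outcomes allowed).
#' @return Numeric matrix with 16 named columns; the response is attached
#'   as attribute `"y"`.
#' @export
build_design_matrix <- function(patients) {
  if (anyNA(patients$outcome) || anyNA(patients$arm)) {
    rlang::abort("all patients must have an assigned arm and observed outcome")
  }
  b <- as.matrix(patients[, c("b1", "b2", "b3")])
  k <- match(patients$arm, arm_levels()) - 1L
  design_matrix_raw(b, k, patients$outcome)
}

# numerically stable log(1 + exp(x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Laplace approximation to the posterior of the 16-parameter model.
# Returns mode, upper Cholesky factor of the observed information
# (+ prior precision, + ridge if needed) and the prior box.
laplace_fit <- function(X, y, priors, start = NULL) {
  p <- ncol(X)
  prec <- numeric(p)
  pmean <- numeric(p)
  if (!is.null(priors$linked_pairs)) {
    idx <- gamma_pos(priors$linked_pairs[, 1L], priors$linked_pairs[, 2L])
    prec[idx] <- 1 / priors$linked_var
    pmean[idx] <- priors$linked_mean
  }
  nlp <- function(b) {
    eta <- drop(X %*% b)
    -(sum(y * eta) - sum(softplus(eta))) + sum(prec * (b - pmean)^2) / 2
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    -drop(crossprod(X, y - stats::plogis(eta))) + prec * (b - pmean)
  }
  start <- if (is.null(start)) pmean else pmin(pmax(start, priors$box_low + 1e-6),
                                              priors$box_high - 1e-6)
  opt <- stats::optim(start, nlp, grad, method = "L-BFGS-B",
                      lower = priors$box_low, upper = priors$box_high,
                      control = list(maxit = 300))
  mode <- opt$par
  w <- {
    pr <- stats::plogis(drop(X %*% mode))
    pr * (1 - pr)
  }
  H <- crossprod(X * sqrt(w)) + diag(prec, p)
  R <- NULL
  ridge <- 0
  repeat {
    R <- tryCatch(chol(H + diag(ridge, p)), error = function(e) NULL)
    if (!is.null(R)) break
    ridge <- if (ridge == 0) 1e-4 else ridge * 10
  }
  # flat directions (no data, no prior curvature) are pinned by the ridge
  if (ridge == 0 && any(diag(H) < 1e-8)) {
    R <- chol(H + diag(1e-4, p))
    ridge <- 1e-4
  }
  list(mode = mode, chol_info = R, ridge = ridge,
       box = c(priors$box_low, priors$box_high), convergence = opt$convergence)
}

# contrast matrix giving, per (profile, arm), the coefficients of the
# arm-vs-control log-odds difference: theta_k + sum_j b_j gamma_kj
superiority_contrasts <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    pt <- profile_table()
    C <- matrix(0, 24L, 16L, dimnames = list(NULL, coef_names()))
    r <- 0L
    for (pr in 1:8) {
      b <- as.numeric(pt[pr, c("b1", "b2", "b3")])
      for (k in 1:3) {
        r <- r + 1L
        C[r, 1L + k] <- 1
        C[r, gamma_pos(k, 1:3)] <- b
      }
    }
    attr(C, "profile") <- rep(1:8, each = 3L)
    attr(C, "arm") <- rep(1:3, 8L)
    memo <<- C
    C
  }
})

# design matrix from raw vectors (no data-frame overhead); k is 0..3
design_matrix_raw <- function(b, k, y) {
  n <- length(k)
  X <- matrix(0, n, 16L, dimnames = list(NULL, coef_names()))
  X[, 1L] <- 1
  for (a in 1:3) X[k == a, 1L + a] <- 1
  X[, 5:7] <- b
  for (a in 1:3) {
    rows <- k == a
    if (any(rows)) X[rows, (5L + 3L * a):(7L + 3L * a)] <- b[rows, , drop = FALSE]
  }
  attr(X, "y") <- as.integer(y)
  X
}

#' Interim Bayesian fit and superiority probabilities
#'
#' Fits the Bayesian logistic regression on patients with observed outcomes
#' and returns, for every biomarker profile `b` and experimental arm `k`,
#' the posterior probability `p_k(b)` that the arm beats control for that
#' profile, i.e. that `theta_k + sum_j b_j gamma_kj > 0`.
#'
#' The posterior is approximated by a Laplace (multivariate normal)
#' approximation at the penalised mode: flat box priors contribute bounds,
#' informative normal priors quadratic penalties; the covariance is the
#' inverse observed information (ridged by 1e-4 if singular); draws are
#' truncated to the prior box and the probabilities estimated from
#' `n_draws` posterior draws.
#'
#' @param patients Data frame of patients with observed outcomes (see
#'   [build_design_matrix()]); ignored when `prior_only = TRUE`.
#' @param priors A [prior_spec()].
#' @param n_draws Number of posterior draws (>= 1000).
#' @param start Optional coefficient vector used to warm-start the
#'   optimiser (e.g. the previous interim's mode).
#' @param prior_only If `TRUE`, sample from the prior alone (no data);
#'   used for prior predictive checks.
#' @return An object of class `posterior_summary`: a list with the 8 x 3
#'   `superiority` matrix (rows keyed by profile bit-string), the posterior
#'   `mode`, `n_outcomes` and `draws_used`.
#' @export
fit_posterior <- function(patients, priors = prior_spec(), n_draws = 4000,
                          start = NULL, prior_only = FALSE) {
  stopifnot(n_draws >= 1000)
  p <- 16L
  if (prior_only) {
    draws <- matrix(stats::runif(n_draws * p, priors$box_low, priors$box_high),
                    n_draws, p)
    if (!is.null(priors$linked_pairs)) {
      idx <- gamma_pos(priors$linked_pairs[, 1L], priors$linked_pairs[, 2L])
      for (i in idx) {
        draws[, i] <- pmin(pmax(stats::rnorm(n_draws, priors$linked_mean,
                                             sqrt(priors$linked_var)),
                                priors$box_low), priors$box_high)
      }
    }
    mode <- NULL
    n_out <- 0L
  } else {
    if (is.null(patients) || nrow(patients) == 0L) {
      rlang::abort("fit_posterior() requires at least one observed outcome")
    }
    X <- build_design_matrix(patients)
    return(.fit_posterior_X(X, attr(X, "y"), priors, n_draws, start))
  }
  C <- superiority_contrasts()
  S <- draws %*% t(C)
  sup <- matrix(colMeans(S > 0), nrow = 8L, byrow = TRUE,
                dimnames = list(profile_table()$key, arm_levels()[-1L]))
  structure(
    list(superiority = sup, mode = mode, n_outcomes = n_out,
         draws_used = n_draws, priors = priors),
    class = "posterior_summary"
  )
}

# fit path on a pre-built design matrix (hot path for the trial engine)
.fit_posterior_X <- function(X, y, priors, n_draws, start = NULL) {
  p <- 16L
  fit <- laplace_fit(X, y, priors, start = start)
  Z <- matrix(stats::rnorm(n_draws * p), p, n_draws)
  draws <- t(backsolve(fit$chol_info, Z) + fit$mode)
  draws <- pmin(pmax(draws, priors$box_low), priors$box_high)
  C <- superiority_contrasts()
  S <- draws %*% t(C)
  sup <- matrix(colMeans(S > 0), nrow = 8L, byrow = TRUE,
                dimnames = list(profile_table()$key, arm_levels()[-1L]))
  structure(
    list(superiority = sup, mode = fit$mode, n_outcomes = nrow(X),
         draws_used = n_draws, priors = priors),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> n_outcomes =", x$n_outcomes,
      "draws =", x$draws_used, "\n")
  print(round(x$superiority, 3))
  invisible(x)
}

#' Superiority probabilities for one biomarker profile
#'
#' @param summary A `posterior_summary` from [fit_posterior()].
#' @param profile Length-3 indicator vector `c(b1, b2, b3)` or a bit-string
#'   such as `"100"`.
#' @return Named length-3 vector of `P(arm k beats control | data)`.
#' @export
superiority_for_profile <- function(summary, profile) {
  stopifnot(inherits(summary, "posterior_summary"))
  key <- if (is.character(profile)) profile else paste0(profile[1], profile[2], profile[3])
  row <- summary$superiority[key, ]
  stats::setNames(as.numeric(row), colnames(summary$superiority))
}

#' Export a posterior summary as JSON
#'
#' Profiles are keyed by their `b1b2b3` bit-string.
#'
#' @param summary A `posterior_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_json <- function(summary, path) {
  x <- apply(summary$superiority, 1L, function(r) as.list(r), simplify = FALSE)
  jsonlite::write_json(
    list(superiority = x, n_outcomes = summary$n_outcomes,
         draws_used = summary$draws_used),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
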