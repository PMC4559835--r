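#' Define a simulation truth
#'
#' A scenario fixes the data-generating logistic model for patient response
#' together with the biomarker prevalences. The model on the log-odds scale is
#'
#' \deqn{\mathrm{logit}\, P(Y=1) = \mu + \theta_k + \sum_j \beta_j b_j +
#'       \sum_j \gamma_{kj} b_j,}
#'
#' where `k` indexes the assigned experimental arm (the treatment main effect
#' \eqn{\theta_k} and interactions \eqn{\gamma_{kj}} vanish on control) and
#' `b_j` are the biomarker indicators.
#'
#' @param name Scenario label.
#' @param prevalence Length-3 biomarker prevalences.
#' @param mu Intercept (log-odds of response on control for an all-negative
#'   patient).
#' @param theta Length-3 treatment main effects.
#' @param beta Length-3 biomarker (prognostic) main effects.
#' @param gamma 3x3 matrix of treatment-by-biomarker interactions; entry
#'   `[k, j]` applies to patients on treatment `k` positive for biomarker `j`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, prevalence = c(0.3, 0.3, 0.3),
                          mu = stats::qlogis(0.3),
                          theta = c(0, 0, 0), beta = c(0, 0, 0),
                          gamma = matrix(0, 3, 3)) {
  check_prevalence(prevalence)
  theta <- as.numeric(theta); beta <- as.numeric(beta)
  gamma <- matrix(as.numeric(gamma), 3L, 3L)
  stopifnot(length(theta) == 3L, length(beta) == 3L, is.finite(mu))
  if (!all(is.finite(c(theta, beta, gamma)))) {
    rlang::abort("scenario coefficients must be finite")
  }
  structure(
    list(name = as.character(name), prevalence = as.numeric(prevalence),
         mu = as.numeric(mu), theta = theta, beta = beta, gamma = gamma),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, "\n", sep = "")
  cat("  prevalence:", format(x$prevalence), "\n")
  cat("  mu:", format(x$mu), " (control response ",
      format(round(stats::plogis(x$mu), 3)), ")\n", sep = "")
  nz <- which(x$gamma != 0, arr.ind = TRUE)
  if (any(x$theta != 0)) {
    cat("  theta:", format(x$theta), "\n")
  }
  if (nrow(nz)) {
    for (r in seq_len(nrow(nz))) {
      cat("  gamma[T", nz[r, 1], ", B", nz[r, 2], "] = ",
          format(x$gamma[nz[r, , drop = FALSE]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Response probability under a scenario
#'
#' Evaluates the scenario's logistic model for given arm(s) and biomarker
#' profile(s).
#'
#' @param spec A [scenario_spec()].
#' @param arm Arm label(s): `"control"`, `"T1"`, `"T2"`, `"T3"`.
#' @param profile Either a length-3 indicator vector `c(b1, b2, b3)` or a
#'   data frame with columns `b1`, `b2`, `b3`.
#' @return Numeric vector of response probabilities in (0, 1).
#' @export
#' @examples
#' s2 <- scenario_library()[["S2"]]
#' response_probability(s2, "T1", c(1, 0, 0))  # 0.6
response_probability <- function(spec, arm, profile) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.data.frame(profile)) {
    b <- as.matrix(profile[, c("b1", "b2", "b3")])
  } else {
    b <- matrix(as.numeric(profile), ncol = 3L)
  }
  k <- match(arm, arm_levels()) - 1L
  if (anyNA(k)) rlang::abort("unknown arm label")
  n <- max(nrow(b), length(k))
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (length(k) == 1L && n > 1L) k <- rep(k, n)
  eta <- spec$mu + drop(b %*% spec$beta) +
    ifelse(k > 0L, spec$theta[pmax(k, 1L)], 0) +
    ifelse(k > 0L, rowSums(b * spec$gamma[pmax(k, 1L), , drop = FALSE]), 0)
  stats::plogis(eta)
}

# 8 x 4 matrix of response probabilities (profiles x arms), used by the
# trial engine to avoid re-evaluating the model per patient.
response_matrix <- function(spec) {
  b <- profile_matrix()
  base <- spec$mu + drop(b %*% spec$beta)
  eta <- cbind(base,
               base + spec$theta[1] + drop(b %*% spec$gamma[1, ]),
               base + spec$theta[2] + drop(b %*% spec$gamma[2, ]),
               base + spec$theta[3] + drop(b %*% spec$gamma[3, ]))
  dimnames(eta) <- list(profile_table()$key, arm_levels())
  stats::plogis(eta)
}

#' Sample binary outcomes
#'
#' @param p Response probabilities.
#' @return Integer 0/1 draws, one per element of `p`.
#' @export
sample_outcome <- function(p) {
  if (any(p < 0 | p > 1)) rlang::abort("probabilities must lie in [0, 1]")
  as.integer(stats::runif(length(p)) < p)
}

#' Uniform accrual schedule
#'
#' Recruitment is deterministic and uniform: patient `i` of `n_total` arrives
#' at `duration * i / n_total` months. A constant accrual rate is assumed and
#' recruitment is never paused for interim analyses.
#'
#' @param n_total Number of patients.
#' @param duration Accrual period in months.
#' @return A tibble with columns `index` and `recruit_time`.
#' @export
#' @examples
#' tail(build_accrual(350, 36), 1)  # last patient at month 36
build_accrual <- function(n_total, duration) {
  if (!is.numeric(n_total) || n_total < 1 || !is.numeric(duration) || duration <= 0) {
    rlang::abort("`n_total` must be >= 1 and `duration` > 0")
  }
  n_total <- as.integer(n_total)
  tibble::tibble(index = seq_len(n_total),
                 recruit_time = duration * seq_len(n_total) / n_total)
}

#' The eight benchmark scenarios
#'
#' Returns the library of simulation truths used to characterise the designs.
#' All scenarios share a control response rate of 0.30 (`mu = logit(0.3)`),
#' biomarker prevalence 0.3 and no prognostic main effects. A "doubling"
#' interaction raises the response from 0.30 to 0.60
#' (`delta_plus = logit(0.6) - logit(0.3)`); a "detrimental" interaction
#' lowers it from 0.30 to 0.11 (`delta_minus = logit(0.11) - logit(0.3)`).
#'
#' * S1: global null - every arm behaves like control everywhere.
#' * S2: T1 doubles response in B1-positive patients (linked effect).
#' * S3: T1 doubles response in B2-positive patients (unlinked effect).
#' * S4: T1 gives a moderate benefit in all groups (`theta_1 = theta4`).
#' * S5: T1 detrimental in B1-positive patients.
#' * S6: T1 detrimental in B2-positive patients.
#' * S7: T1 doubles response in B1-positive and is detrimental in
#'   B2-positive patients.
#' * S8: T1 detrimental and T2 doubling, both in B1-positive patients.
#'
#' @param prevalence Biomarker prevalences shared by all scenarios.
#' @param theta4 Treatment main effect for scenario 4 (default 0.63,
#'   about half the doubling effect).
#' @return Named list of [scenario_spec()] objects `S1`..`S8`.
#' @export
scenario_library <- function(prevalence = c(0.3, 0.3, 0.3), theta4 = 0.63) {
  dplus <- stats::qlogis(0.6) - stats::qlogis(0.3)
  dminus <- stats::qlogis(0.11) - stats::qlogis(0.3)
  g <- function(...) {
    m <- matrix(0, 3, 3)
    for (e in list(...)) m[e[[1]], e[[2]]] <- e[[3]]
    m
  }
  sp <- function(name, gamma = matrix(0, 3, 3), theta = c(0, 0, 0)) {
    scenario_spec(name, prevalence = prevalence, theta = theta, gamma = gamma)
  }
  list(
    S1 = sp("S1"),
    S2 = sp("S2", g(list(1, 1, dplus))),
    S3 = sp("S3", g(list(1, 2, dplus))),
    S4 = sp("S4", theta = c(theta4, 0, 0)),
    S5 = sp("S5", g(list(1, 1, dminus))),
    S6 = sp("S6", g(list(1, 2, dminus))),
    S7 = sp("S7", g(list(1, 1, dplus), list(1, 2, dminus))),
    S8 = sp("S8", g(list(1, 1, dminus), list(2, 1, dplus)))
  )
}

#' Write / read a scenario as a flat YAML or JSON file
#'
#' The interaction matrix is stored row-major (treatment by biomarker).
#'
#' @param spec A [scenario_spec()].
#' @param path File path; format chosen from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a [scenario_spec()].
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- list(name = spec$name, prevalence = spec$prevalence, mu = spec$mu,
            theta = spec$theta, beta = spec$beta,
            gamma = as.numeric(t(spec$gamma)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @param path File path to read.
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_spec(x$name, prevalence = unlist(x$prevalence), mu = x$mu,
                theta = unlist(x$theta), beta = unlist(x$beta),
                gamma = matrix(unlist(x$gamma), 3, 3, byrow = TRUE))
}
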