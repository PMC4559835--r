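#' The twelve subgroup hypotheses
#'
#' Nine hypotheses concern the effect of treatment `k` in patients positive
#' for biomarker `j` (contrast `theta_k + gamma_kj`); three concern each
#' treatment in patients negative for every biomarker (contrast `theta_k`).
#'
#' @return A tibble with columns `hypothesis`, `treatment`, `biomarker`.
#' @export
hypothesis_table <- function() {
  tibble::tibble(
    hypothesis = c(t(outer(paste0("T", 1:3), c(paste0("B", 1:3), "neg"),
                           function(a, b) paste0(a, "_in_", b)))),
    treatment = rep(1:3, each = 4L),
    biomarker = rep(c(1:3, NA_integer_), 3L)
  )
}

# 12 x 16 contrast matrix for the hypotheses (memoised)
hypothesis_contrasts <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    h <- hypothesis_table()
    C <- matrix(0, nrow(h), 16L, dimnames = list(h$hypothesis, coef_names()))
    for (r in seq_len(nrow(h))) {
      C[r, 1L + h$treatment[r]] <- 1
      if (!is.na(h$biomarker[r])) C[r, gamma_pos(h$treatment[r], h$biomarker[r])] <- 1
    }
    memo <<- C
    C
  }
})

# Firth bias-reduced logistic regression (Newton iterations on the
# modified score). X must have full column rank.
firth_fit <- function(X, y, max_iter = 100L, tol = 1e-6) {
  p <- ncol(X)
  beta <- numeric(p)
  delta <- rep(Inf, p)
  Iinv <- diag(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    I <- crossprod(X * sqrt(w))
    R <- tryCatch(chol(I), error = function(e) NULL)
    if (is.null(R)) R <- chol(I + diag(1e-6, p))
    Iinv <- chol2inv(R)
    h <- rowSums((X %*% Iinv) * X) * w
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(Iinv %*% U)
    m <- max(abs(delta))
    if (m > 5) delta <- delta * (5 / m)      # damp large steps
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(coefficients = beta, vcov = Iinv,
       converged = max(abs(delta)) < tol, iterations = it)
}

#' Final classical logistic fit
#'
#' Maximum-likelihood logistic regression of outcome on the 16-column design
#' matrix. If the ML fit fails to converge or shows signs of separation
#' (runaway coefficients or an unusable information matrix), the model is
#' refitted with Firth's bias-reduced likelihood, which stays finite under
#' separation. Columns with no data (e.g. an interaction cell that recruited
#' nobody) are dropped and flagged non-estimable.
#'
#' @param patients Patient tibble with all outcomes observed.
#' @return An object of class `linkbar_final_fit` with elements
#'   `coefficients` (length 16, 0 for non-estimable terms), `vcov`
#'   (16 x 16), `estimable` (logical 16), `converged`, `method`
#'   (`"ml"` or `"firth"`) and `n`.
#' @export
fit_final_model <- function(patients) {
  X <- build_design_matrix(patients)
  y <- attr(X, "y")
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  Xe <- X[, keep, drop = FALSE]

  coefs <- numeric(16L)
  V <- matrix(0, 16L, 16L, dimnames = list(coef_names(), coef_names()))
  estimable <- logical(16L)
  estimable[keep] <- TRUE

  ml <- tryCatch(
    suppressWarnings(stats::glm.fit(Xe, y, family = stats::binomial())),
    error = function(e) NULL
  )
  use_firth <- is.null(ml) || !ml$converged || anyNA(ml$coefficients) ||
    any(abs(ml$coefficients) > 8)
  Ve <- NULL
  if (!use_firth) {
    w <- ml$weights
    info <- crossprod(Xe * sqrt(w))
    Ve <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(Ve)) use_firth <- TRUE
  }
  if (use_firth) {
    ff <- firth_fit(Xe, y)
    coefs[keep] <- ff$coefficients
    V[keep, keep] <- ff$vcov
    method <- "firth"
    converged <- ff$converged
  } else {
    coefs[keep] <- ml$coefficients
    V[keep, keep] <- Ve
    method <- "ml"
    converged <- TRUE
  }
  names(coefs) <- coef_names()
  structure(
    list(coefficients = coefs, vcov = V, estimable = estimable,
         converged = converged, method = method, n = nrow(patients)),
    class = "linkbar_final_fit"
  )
}

#' One-sided Wald tests of the twelve hypotheses
#'
#' Each hypothesis contrast is estimated from the final fit; its Wald
#' statistic is the estimate divided by its standard error from the fit
#' covariance, and the hypothesis is rejected when the statistic exceeds
#' `threshold` (benefit direction only: harmful effects never reject).
#' Contrasts involving a non-estimable coefficient get statistic 0.
#'
#' @param fit A `linkbar_final_fit`.
#' @param threshold Rejection threshold (default 1.5, a one-sided normal
#'   tail probability of about 0.067).
#' @return A tibble with one row per hypothesis: `hypothesis`, `estimate`,
#'   `std_error`, `wald`, `rejected`, `estimable`.
#' @export
wald_statistics <- function(fit, threshold = 1.5) {
  stopifnot(inherits(fit, "linkbar_final_fit"))
  C <- hypothesis_contrasts()
  est <- unname(drop(C %*% fit$coefficients))
  v <- unname(rowSums((C %*% fit$vcov) * C))
  ok <- unname(drop((C != 0) %*% !fit$estimable) == 0) & v > 0
  wald <- ifelse(ok, est / sqrt(pmax(v, .Machine$double.eps)), 0)
  tibble::new_tibble(list(
    hypothesis = rownames(C),
    estimate = ifelse(ok, est, NA_real_),
    std_error = ifelse(ok, sqrt(v), NA_real_),
    wald = wald,
    rejected = wald > threshold,
    estimable = ok
  ), nrow = nrow(C))
}

#' Collect rejections into a recommendation set
#'
#' @param results Tibble from [wald_statistics()].
#' @return A list with `rejected` (character vector of hypothesis ids) and
#'   `any` (`TRUE` if at least one hypothesis was rejected).
#' @export
summarise_recommendations <- function(results) {
  stopifnot(all(c("hypothesis", "rejected") %in% names(results)))
  rej <- results$hypothesis[results$rejected]
  list(rejected = rej, any = length(rej) > 0L)
}

#' @export
print.linkbar_final_fit <- function(x, ...) {
  cat("<linkbar_final_fit> n =", x$n, "method =", x$method,
      if (!x$converged) "(not converged)", "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @method tidy linkbar_final_fit
#' @export
tidy.linkbar_final_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = ifelse(x$estimable, x$coefficients, NA_real_),
    std.error = ifelse(x$estimable, se, NA_real_),
    statistic = ifelse(x$estimable & se > 0, x$coefficients / se, NA_real_)
  )
}

#' @method glance linkbar_final_fit
#' @export
glance.linkbar_final_fit <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method, converged = x$converged,
                 n_estimable = sum(x$estimable))
}
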