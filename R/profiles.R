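#' Biomarker profiles
#'
#' Patients carry three binary biomarkers B1, B2, B3, giving eight possible
#' biomarker profiles. Profiles are indexed 1..8 in the order of the
#' three-bit string `b1 b2 b3` (all-negative = "000" = index 1,
#' triple-positive = "111" = index 8).
#'
#' @return A tibble with one row per profile: `profile` (index 1..8),
#'   `key` (bit-string), and indicator columns `b1`, `b2`, `b3`.
#' @export
#' @examples
#' profile_table()
profile_table <- function() {
  g <- expand.grid(b3 = 0:1, b2 = 0:1, b1 = 0:1)[, c("b1", "b2", "b3")]
  tibble::tibble(
    profile = seq_len(8L),
    key = paste0(g$b1, g$b2, g$b3),
    b1 = as.integer(g$b1),
    b2 = as.integer(g$b2),
    b3 = as.integer(g$b3)
  )
}

#' Map biomarker indicators to the profile index
#'
#' @param b1,b2,b3 Binary indicators (vectors recycle as usual).
#' @return Integer profile indices in 1..8.
#' @export
profile_index <- function(b1, b2, b3) {
  as.integer(1L + 4L * b1 + 2L * b2 + b3)
}

#' Bit-string key of a profile
#' @inheritParams profile_index
#' @return Character vector such as "101".
#' @export
profile_key <- function(b1, b2, b3) paste0(b1, b2, b3)

arm_levels <- function() c("control", "T1", "T2", "T3")

# 8 x 3 indicator matrix of the profiles, row i = profile index i
profile_matrix <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      pt <- profile_table()
      memo <<- cbind(b1 = pt$b1, b2 = pt$b2, b3 = pt$b3)
    }
    memo
  }
})

#' Sample biomarker profiles
#'
#' Draws the three biomarkers independently, each positive with its own
#' prevalence. This is the population model used throughout: biomarker
#' statuses are mutually independent Bernoulli variables.
#'
#' @param n Number of patients.
#' @param prevalence Numeric length-3 vector of positivity probabilities
#'   for B1, B2, B3, each in \[0, 1\].
#' @return A tibble with columns `b1`, `b2`, `b3` and `profile`.
#' @export
#' @examples
#' set.seed(1)
#' sample_profile(5, c(0.3, 0.3, 0.3))
sample_profile <- function(n, prevalence) {
  check_prevalence(prevalence)
  u <- matrix(stats::runif(n * 3L), nrow = n, ncol = 3L)
  b <- matrix(as.integer(u < rep(prevalence, each = n)), nrow = n)
  tibble::tibble(
    b1 = b[, 1L], b2 = b[, 2L], b3 = b[, 3L],
    profile = profile_index(b[, 1L], b[, 2L], b[, 3L])
  )
}

check_prevalence <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 3L ||
      anyNA(prevalence) || any(prevalence < 0) || any(prevalence > 1)) {
    rlang::abort("`prevalence` must be three probabilities in [0, 1].")
  }
  invisible(prevalence)
}
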