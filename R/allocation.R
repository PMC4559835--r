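#' Tuning constants of the adaptive allocation rule
#'
#' @param weight_exponent Exponent applied to the superiority probabilities
#'   when forming experimental arm weights (default 1: allocation in
#'   proportion to the posterior probabilities).
#' @param control_gain Sensitivity `eta` of the control-matching correction
#'   (default 1.25).
#' @param min_prob Optional floor applied to every arm's probability before
#'   renormalisation (default 0; must be < 0.25).
#' @return An object of class `bar_tuning`.
#' @export
bar_tuning <- function(weight_exponent = 1, control_gain = 1.25, min_prob = 0,
                       ramp = 0) {
  stopifnot(weight_exponent >= 0, control_gain >= 0,
            min_prob >= 0, min_prob < 0.25, ramp >= 0)
  structure(list(weight_exponent = weight_exponent,
                 control_gain = control_gain, min_prob = min_prob,
                 ramp = ramp),
            class = "bar_tuning")
}

#' Initial randomisation probabilities
#'
#' Before any interim data exist, the linked designs (LB, PT) randomise each
#' patient equally between control and the experimental treatments linked to
#' the patient's positive biomarkers; all-negative patients are randomised
#' equally across control and all three treatments. The non-linked designs
#' (NLB, ER) randomise every patient equally across all four arms.
#'
#' @param profile Length-3 indicator vector `c(b1, b2, b3)`.
#' @param variant Design variant: `"LB"`, `"NLB"`, `"PT"` or `"ER"`.
#' @return Length-4 probability vector over (control, T1, T2, T3).
#' @export
#' @examples
#' initial_allocation(c(1, 0, 1), "LB")  # control, T1, T3 each 1/3
initial_allocation <- function(profile, variant) {
  if (!variant %in% c("LB", "NLB", "PT", "ER")) {
    rlang::abort(sprintf("unknown design variant '%s'", variant))
  }
  b <- as.numeric(profile)
  stopifnot(length(b) == 3L, all(b %in% c(0, 1)))
  if (variant %in% c("NLB", "ER") || sum(b) == 0) {
    return(stats::setNames(rep(0.25, 4L), arm_levels()))
  }
  w <- c(1, b)
  stats::setNames(w / sum(w), arm_levels())
}

# 8 x 4 table of initial probabilities, one row per profile (memoised)
initial_allocation_table <- local({
  memo <- list()
  function(variant) {
    if (is.null(memo[[variant]])) {
      b <- profile_matrix()
      memo[[variant]] <<- t(vapply(seq_len(8L), function(i) {
        initial_allocation(b[i, ], variant)
      }, numeric(4L)))
    }
    memo[[variant]]
  }
})

#' Response-adaptive allocation probabilities for one profile
#'
#' Experimental arm `k` gets weight `p_k ^ weight_exponent`, where `p_k` is
#' its posterior superiority probability for this profile. The control arm
#' is anchored to the best-recruiting experimental arm `k*` (the one with
#' the largest count `n_star` for this profile; ties broken by the larger
#' weight, then the lower index) and corrected exponentially by the
#' control's recruitment deficit,
#' `w_0 = w_k* * exp(eta * (n_star - n_0) / (n_b + 1))`, with `n_0` the
#' control count and `n_b` the profile total. At the flow equilibrium the
#' control recruits at exactly the rate of the largest experimental arm,
#' so its expected count tracks that arm's count ("control matching").
#' Weights are normalised to probabilities. Between interims the
#' superiority probabilities are frozen, so the rule can be recomputed
#' after every recruit from counts alone.
#'
#' @param superiority Length-3 vector `p_k` in \[0, 1\].
#' @param counts Length-4 vector of patients of this profile already
#'   assigned to (control, T1, T2, T3).
#' @param tuning A [bar_tuning()].
#' @return Length-4 probability vector over (control, T1, T2, T3).
#' @export
#' @examples
#' bar_weights(c(0.8, 0.4, 0.2), c(4, 10, 4, 2))
bar_weights <- function(superiority, counts, tuning = bar_tuning()) {
  p <- as.numeric(superiority)
  stopifnot(length(p) == 3L, all(p >= 0), all(p <= 1),
            length(counts) == 4L, all(counts >= 0))
  stats::setNames(.bar_w(p, counts, tuning$weight_exponent,
                         tuning$control_gain, tuning$min_prob),
                  arm_levels())
}

# validation-free kernel used inside the per-patient trial loop.
# Both the control's anchor weight and its deficit refer to the same arm
# (the best-recruiting one): anchoring the weight to max_k w_k instead
# leaves a persistent log(w_max / w_k*) flow imbalance that over-recruits
# control by O(n_b / eta) patients in profiles without a clear winner.
.bar_w <- function(p, counts, weight_exponent, control_gain, min_prob) {
  w <- p^weight_exponent
  mx <- max(w)
  if (mx == 0) {
    # degenerate posterior: equal split over control + arms with mass
    keep <- c(TRUE, p > 0)
    return(keep / sum(keep))
  }
  nstar <- max(counts[2L], counts[3L], counts[4L])
  kstar <- which(counts[2:4] == nstar)
  if (length(kstar) > 1L) kstar <- kstar[which.max(w[kstar])]
  w0 <- w[kstar] * exp(control_gain * (nstar - counts[1L]) / (sum(counts) + 1))
  v <- c(w0, w)
  out <- v / sum(v)
  if (min_prob > 0) {
    out <- pmax(out, min_prob)
    out <- out / sum(out)
  }
  out
}

#' Draw an arm from an allocation row
#'
#' @param alloc_row Length-4 probability vector summing to 1.
#' @param u Optional uniform deviate in \[0, 1); drawn if missing.
#' @return Arm label.
#' @export
assign_arm <- function(alloc_row, u = stats::runif(1L)) {
  pr <- as.numeric(alloc_row)
  if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
    rlang::abort("allocation row must be non-negative and sum to 1")
  }
  arm_levels()[findInterval(u, cumsum(pr), left.open = TRUE) + 1L]
}
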