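#' Monte-Carlo operating characteristics of a design under one scenario
#'
#' Runs `n_reps` independent trials and reports, for each of the twelve
#' hypotheses plus "any", the fraction of replicates in which it was
#' rejected, with binomial Monte-Carlo standard errors. Replicate `r` is
#' seeded from `(seed, rep_offset + r)`, so results do not depend on the
#' worker count and two half-sized runs with offsets `0` and `n_reps/2`
#' pool to exactly one full run.
#'
#' @param design A [design_config()].
#' @param scenario A [scenario_spec()].
#' @param n_reps Number of replicate trials.
#' @param seed Root seed.
#' @param workers Number of forked workers (1 = serial); reduction is in
#'   replicate order regardless.
#' @param rep_offset Offset added to replicate ids when deriving seeds.
#' @param collect Optional function applied to each `linkbar_trial`; the
#'   per-replicate results are returned in the `"collected"` attribute.
#' @return A tibble with one row per hypothesis (13 rows: 12 hypotheses and
#'   `"any"`): `design`, `scenario`, `hypothesis`, `n_reps`, `prob`,
#'   `mc_se`. The replicate-level logical rejection matrix is attached as
#'   attribute `"rejections"`.
#' @export
#' @examples
#' \donttest{
#' oc <- run_oc(design_config("ER"), scenario_library()[["S1"]],
#'              n_reps = 50, seed = 1)
#' }
run_oc <- function(design, scenario, n_reps, seed, workers = 1L,
                   rep_offset = 0L, collect = NULL) {
  stopifnot(n_reps >= 1)
  one <- function(r) {
    tr <- run_trial(design, scenario, seed = seed_stream(seed, rep_offset + r))
    rej <- tidy(tr)$rejected
    list(rej = c(rej, any = any(rej)),
         extra = if (!is.null(collect)) collect(tr))
  }
  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_reps), one, mc.cores = workers)
  } else {
    lapply(seq_len(n_reps), one)
  }
  rejections <- do.call(rbind, lapply(res, `[[`, "rej"))
  colnames(rejections) <- c(hypothesis_table()$hypothesis, "any")
  prob <- colMeans(rejections)
  out <- tibble::tibble(
    design = design$variant, scenario = scenario$name,
    hypothesis = colnames(rejections), n_reps = as.integer(n_reps),
    prob = as.numeric(prob),
    mc_se = sqrt(prob * (1 - prob) / n_reps)
  )
  attr(out, "rejections") <- rejections
  if (!is.null(collect)) attr(out, "collected") <- lapply(res, `[[`, "extra")
  class(out) <- c("linkbar_oc", class(out))
  out
}

#' Mean allocation trajectory for one biomarker profile
#'
#' Tracks, replicate by replicate, the live allocation row of the given
#' profile immediately before each patient is assigned, and averages over
#' replicates. This is the quantity plotted when studying how a BAR design
#' moves allocation towards effective arms as evidence accumulates.
#'
#' @param design A [design_config()].
#' @param scenario Simulation truth.
#' @param profile Profile index 1..8 or indicator vector `c(b1, b2, b3)`.
#' @param n_reps Replicates to average over.
#' @param seed Root seed.
#' @return A tibble of class `linkbar_trajectory` with columns `index`,
#'   `arm`, `mean_prob`.
#' @export
allocation_trajectory <- function(design, scenario, profile, n_reps, seed) {
  if (length(profile) == 3L) profile <- profile_index(profile[1], profile[2], profile[3])
  stopifnot(profile %in% 1:8)
  acc <- matrix(0, design$n_total, 4L)
  for (r in seq_len(n_reps)) {
    tr <- run_trial(design, scenario, seed = seed_stream(seed, r),
                    analyse = FALSE, track_profile = profile)
    acc <- acc + tr$trajectory
  }
  acc <- acc / n_reps
  out <- tibble::tibble(
    index = rep(seq_len(design$n_total), 4L),
    arm = factor(rep(arm_levels(), each = design$n_total), levels = arm_levels()),
    mean_prob = as.numeric(acc)
  )
  attr(out, "design") <- design$variant
  attr(out, "profile") <- profile
  class(out) <- c("linkbar_trajectory", class(out))
  out
}

#' Power across a grid of B1 prevalences
#'
#' Re-runs the operating characteristics for the hypothesis "recommend T1
#' in B1-positive patients" while the prevalence of B1 varies over `grid`;
#' B2 and B3 keep their scenario prevalences.
#'
#' @param designs Character vector of design variants.
#' @param scenario Base scenario (its B1 prevalence is overridden).
#' @param grid Increasing vector of B1 prevalences in (0, 1).
#' @param n_reps Replicates per grid point and design.
#' @param seed Root seed.
#' @param ... Passed to [design_config()] for each variant.
#' @return A tibble of class `linkbar_sweep` with columns `design`,
#'   `prevalence`, `power`, `mc_se`.
#' @export
prevalence_sweep <- function(designs, scenario, grid = seq(0.1, 0.5, by = 0.025),
                             n_reps, seed, ...) {
  stopifnot(all(grid > 0), all(grid < 1), all(diff(grid) > 0))
  rows <- list()
  for (d in designs) {
    cfg <- design_config(d, ...)
    for (g in seq_along(grid)) {
      sc <- scenario_spec(scenario$name,
                          prevalence = c(grid[g], scenario$prevalence[2:3]),
                          mu = scenario$mu, theta = scenario$theta,
                          beta = scenario$beta, gamma = scenario$gamma)
      oc <- run_oc(cfg, sc, n_reps = n_reps,
                   seed = seed_stream(seed, 1000L * match(d, designs) + g))
      p <- oc$prob[oc$hypothesis == "T1_in_B1"]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        design = d, prevalence = grid[g], power = p,
        mc_se = sqrt(p * (1 - p) / n_reps)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("linkbar_sweep", class(out))
  out
}

#' Sensitivity of power to design parameters
#'
#' Sweeps one design knob and reports power for the linked hypothesis
#' "T1 in B1-positive" and the unlinked "T1 in B2-positive".
#'
#' @param axis One of `"n_stages"`, `"prior_mean"`, `"recruitment_rate"`
#'   (patients per month; converted to an accrual duration at fixed
#'   `n_total`).
#' @param values Grid of axis values.
#' @param design Base [design_config()], modified per value.
#' @param scenario Simulation truth.
#' @param n_reps Replicates per value.
#' @param seed Root seed.
#' @return A tibble of class `linkbar_sweep` with columns `axis`, `value`,
#'   `hypothesis`, `power`, `mc_se`.
#' @export
sensitivity_grid <- function(axis = c("n_stages", "prior_mean", "recruitment_rate"),
                             values, design, scenario, n_reps, seed) {
  axis <- match.arg(axis)
  rows <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    cfg <- design
    if (axis == "n_stages") {
      cfg$n_stages <- as.integer(v)
    } else if (axis == "prior_mean") {
      cfg$priors <- prior_spec(linked_pairs = cfg$priors$linked_pairs,
                               linked_mean = v,
                               linked_var = cfg$priors$linked_var,
                               box_low = cfg$priors$box_low,
                               box_high = cfg$priors$box_high)
    } else {
      cfg$accrual_duration <- cfg$n_total / v
    }
    oc <- run_oc(cfg, scenario, n_reps = n_reps, seed = seed_stream(seed, i))
    for (h in c("T1_in_B1", "T1_in_B2")) {
      p <- oc$prob[oc$hypothesis == h]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        axis = axis, value = v, hypothesis = h, power = p,
        mc_se = sqrt(p * (1 - p) / n_reps)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("linkbar_sweep", class(out))
  out
}

#' Export allocation-table snapshots to CSV
#'
#' One row per stage and profile, with the four arm probabilities.
#'
#' @param trial A `linkbar_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation_csv <- function(trial, path) {
  rows <- purrr::map_dfr(trial$allocation_history, function(a) {
    tibble::tibble(stage = a$stage, profile = rownames(a$probs),
                   control = a$probs[, 1L], T1 = a$probs[, 2L],
                   T2 = a$probs[, 3L], T3 = a$probs[, 4L])
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
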