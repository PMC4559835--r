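#' Trial design configuration
#'
#' Bundles every design parameter of a simulated trial. Defaults reproduce
#' the benchmark setting: 350 patients accrued uniformly over 36 months,
#' four interim analyses (the first after 100 recruits, the rest equally
#' spaced), a 6-month outcome delay and a one-sided Wald rejection
#' threshold of 1.5 at the final analysis.
#'
#' @param variant `"LB"` (linked BAR), `"NLB"` (non-linked BAR),
#'   `"PT"` (parallel-group stratified) or `"ER"` (equal randomisation).
#'   PT and ER never update their initial allocation; LB and NLB refit the
#'   Bayesian model at each interim.
#' @param n_total Maximum number of patients.
#' @param n_first_interim Recruitment count triggering the first interim.
#' @param n_stages Number of stages (interims + final); 5 means 4 interims.
#' @param delay Outcome delay in months.
#' @param accrual_duration Accrual period in months.
#' @param priors A [prior_spec()]; defaults to linked informative priors for
#'   LB and fully flat priors otherwise.
#' @param tuning A [bar_tuning()].
#' @param wald_threshold One-sided Wald rejection threshold.
#' @param n_draws Posterior draws per interim fit.
#' @param seed Optional default seed used by [run_trial()] when no seed is
#'   passed explicitly.
#' @return An object of class `design_config`.
#' @export
design_config <- function(variant = c("LB", "NLB", "PT", "ER"),
                          n_total = 350L, n_first_interim = 100L,
                          n_stages = 5L, delay = 6, accrual_duration = 36,
                          priors = NULL, tuning = bar_tuning(),
                          wald_threshold = 1.5, n_draws = 4000L,
                          seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(n_first_interim < n_total, n_stages >= 1L, delay >= 0,
            accrual_duration > 0)
  if (is.null(priors)) {
    priors <- if (variant == "LB") prior_spec() else prior_spec(linked_pairs = NULL)
  }
  structure(
    list(variant = variant, n_total = as.integer(n_total),
         n_first_interim = as.integer(n_first_interim),
         n_stages = as.integer(n_stages), delay = delay,
         accrual_duration = accrual_duration, priors = priors,
         tuning = tuning, wald_threshold = wald_threshold,
         n_draws = as.integer(n_draws), seed = seed),
    class = "design_config"
  )
}

#' Interim analysis schedule
#'
#' The first interim triggers at `n_first` recruits; the remaining
#' `n_interims - 1` are equally spaced over the rest of recruitment,
#' rounding half up.
#'
#' @param n_total Total patients.
#' @param n_first First trigger count.
#' @param n_interims Number of interim analyses.
#' @return Strictly increasing integer vector of trigger counts.
#' @export
#' @examples
#' interim_schedule(350, 100, 4)  # 100 163 225 288
interim_schedule <- function(n_total, n_first, n_interims) {
  if (n_first >= n_total || n_interims < 1L) {
    rlang::abort("need n_first < n_total and n_interims >= 1")
  }
  i <- seq_len(n_interims) - 1L
  # round half up (base round() rounds half to even)
  trig <- as.integer(n_first + floor(i * (n_total - n_first) / n_interims + 0.5))
  if (any(diff(trig) <= 0)) rlang::abort("interim schedule is not strictly increasing")
  trig
}

#' Patients with observed outcomes at a given time
#'
#' Interim fits only use patients whose outcome has matured: recruitment
#' time plus the fixed delay is at or before `now`.
#'
#' @param patients Patient tibble with a `recruit_time` column.
#' @param now Calendar time in months.
#' @param delay Outcome delay in months.
#' @return The subset of `patients` with observed outcomes.
#' @export
available_outcomes <- function(patients, now, delay) {
  patients[patients$recruit_time + delay <= now, , drop = FALSE]
}

# derive reproducible sub-seeds; kept below 2^31 and exact in doubles
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483563 * 69069 + k * 1234567) %% 2147483563 + 1)
}

#' Simulate one complete trial
#'
#' Recruits `n_total` patients along the uniform accrual schedule, assigns
#' each from the live allocation table, refits the Bayesian model at each
#' interim (adaptive variants only) on outcomes available after the delay,
#' recomputes the control-matching weight after every recruit, and runs the
#' final classical analysis once all outcomes are observed.
#'
#' @param design A [design_config()].
#' @param scenario A [scenario_spec()] giving the simulation truth.
#' @param seed Integer seed; the trial is deterministic given
#'   `(seed, design, scenario)`.
#' @param analyse If `FALSE`, skip the final analysis (used for
#'   allocation-trajectory studies).
#' @param track_profile Optional profile index 1..8; if given, the live
#'   allocation row for that profile is recorded before every assignment
#'   and returned as the `trajectory` element.
#' @return An object of class `linkbar_trial`: patient tibble (with the
#'   allocation probabilities in force at each assignment), per-stage
#'   allocation tables, per-interim posterior summaries, an interim log,
#'   and the final recommendations.
#' @export
#' @examples
#' \donttest{
#' tr <- run_trial(design_config("PT"), scenario_library()[["S2"]], seed = 1)
#' glance(tr)
#' }
run_trial <- function(design, scenario, seed = design$seed,
                      analyse = TRUE, track_profile = NULL) {
  stopifnot(inherits(design, "design_config"), inherits(scenario, "scenario_spec"))
  if (is.null(seed)) rlang::abort("a seed is required")
  n <- design$n_total
  n_interims <- design$n_stages - 1L

  set.seed(as.integer(seed) %% 2147483647)
  prof_u <- matrix(stats::runif(n * 3L), n, 3L)
  out_u <- stats::runif(n)
  asg_u <- stats::runif(n)
  interim_seeds <- if (n_interims > 0L) sample.int(2147483646L, n_interims) else integer()

  b <- matrix(as.integer(prof_u < rep(scenario$prevalence, each = n)), n, 3L)
  prof <- profile_index(b[, 1L], b[, 2L], b[, 3L])
  accrual <- build_accrual(n, design$accrual_duration)
  rt <- accrual$recruit_time
  P <- response_matrix(scenario)        # 8 x 4 response probabilities
  init_tab <- initial_allocation_table(design$variant)

  adaptive <- design$variant %in% c("LB", "NLB")
  schedule <- if (adaptive && n_interims > 0L) {
    interim_schedule(n, design$n_first_interim, n_interims)
  } else {
    integer()
  }

  arm_i <- integer(n)                    # 0..3
  probs <- matrix(NA_real_, n, 4L)       # allocation row used per patient
  stage_i <- integer(n)
  counts <- matrix(0L, 8L, 4L)
  superiority <- NULL
  allocation_history <- list(allocation_table(init_tab, stage = 0L))
  posterior_history <- list()
  interim_log <- list()
  traj <- if (!is.null(track_profile)) matrix(NA_real_, n, 4L) else NULL
  stage <- 0L
  mode_prev <- NULL

  if (!adaptive) {
    # static designs: the initial rule applies to all patients, so
    # assignment vectorises
    cum <- t(apply(init_tab, 1L, cumsum))
    cm <- cum[prof, 1:3, drop = FALSE]
    arm_i <- rowSums(asg_u > cm)
    probs <- init_tab[prof, , drop = FALSE]
    if (!is.null(traj)) traj <- matrix(init_tab[track_profile, ], n, 4L, byrow = TRUE)
    return(finish_trial(design, scenario, seed, analyse,
                        b, prof, rt, arm_i, probs, stage_i, out_u, P,
                        allocation_history, posterior_history,
                        interim_log, traj))
  }

  we <- design$tuning$weight_exponent
  cg <- design$tuning$control_gain
  mp <- design$tuning$min_prob
  rmp <- design$tuning$ramp
  for (i in seq_len(n)) {
    pr <- prof[i]
    e_i <- if (rmp > 0) we * (i / n)^rmp else we
    row <- if (is.null(superiority)) {
      init_tab[pr, ]
    } else {
      .bar_w(superiority[pr, ], counts[pr, ], e_i, cg, mp)
    }
    if (!is.null(traj)) {
      traj[i, ] <- if (is.null(superiority)) init_tab[track_profile, ] else
        .bar_w(superiority[track_profile, ], counts[track_profile, ], e_i, cg, mp)
    }
    a <- findInterval(asg_u[i], cumsum(row), left.open = TRUE) + 1L
    arm_i[i] <- a - 1L
    probs[i, ] <- row
    stage_i[i] <- stage
    counts[pr, a] <- counts[pr, a] + 1L

    if (length(schedule) && stage < n_interims && i == schedule[stage + 1L]) {
      stage <- stage + 1L
      now <- rt[i]
      avail <- which(rt + design$delay <= now)
      if (length(avail) == 0L) {
        interim_log[[length(interim_log) + 1L]] <-
          list(stage = stage, trigger = i, now = now, n_outcomes = 0L,
               refit = FALSE)
      } else {
        Xa <- design_matrix_raw(
          b[avail, , drop = FALSE], arm_i[avail],
          as.integer(out_u[avail] < P[cbind(prof[avail], arm_i[avail] + 1L)])
        )
        set.seed(interim_seeds[stage])
        post <- .fit_posterior_X(Xa, attr(Xa, "y"), design$priors,
                                 design$n_draws, start = mode_prev)
        mode_prev <- post$mode
        superiority <- post$superiority
        posterior_history[[length(posterior_history) + 1L]] <- post
        snap <- t(vapply(1:8, function(p8) {
          .bar_w(superiority[p8, ], counts[p8, ], e_i, cg, mp)
        }, numeric(4L)))
        allocation_history[[length(allocation_history) + 1L]] <-
          allocation_table(snap, stage = stage)
        interim_log[[length(interim_log) + 1L]] <-
          list(stage = stage, trigger = i, now = now,
               n_outcomes = length(avail), refit = TRUE)
      }
    }
  }

  finish_trial(design, scenario, seed, analyse,
               b, prof, rt, arm_i, probs, stage_i, out_u, P,
               allocation_history, posterior_history, interim_log, traj)
}

finish_trial <- function(design, scenario, seed, analyse,
                         b, prof, rt, arm_i, probs, stage_i, out_u, P,
                         allocation_history, posterior_history,
                         interim_log, traj) {
  n <- length(prof)
  outcome <- as.integer(out_u < P[cbind(prof, arm_i + 1L)])
  patients <- tibble::new_tibble(list(
    index = seq_len(n),
    b1 = b[, 1L], b2 = b[, 2L], b3 = b[, 3L], profile = prof,
    recruit_time = rt,
    arm = arm_levels()[arm_i + 1L],
    outcome = outcome,
    outcome_time = rt + design$delay,
    stage = stage_i,
    p_control = probs[, 1L], p_T1 = probs[, 2L],
    p_T2 = probs[, 3L], p_T3 = probs[, 4L]
  ), nrow = n)

  recommendations <- NULL
  final_fit <- NULL
  tests <- NULL
  if (analyse) {
    final_fit <- fit_final_model(patients)
    tests <- wald_statistics(final_fit, threshold = design$wald_threshold)
    recommendations <- summarise_recommendations(tests)
  }

  structure(
    list(patients = patients, allocation_history = allocation_history,
         posterior_history = posterior_history,
         interim_log = dplyr::bind_rows(interim_log),
         final_fit = final_fit, tests = tests,
         recommendations = recommendations,
         trajectory = traj, design = design, scenario = scenario$name,
         seed = seed),
    class = "linkbar_trial"
  )
}

allocation_table <- function(probs, stage) {
  dimnames(probs) <- list(profile_table()$key, arm_levels())
  structure(list(probs = probs, stage = stage), class = "allocation_table")
}

#' @export
print.allocation_table <- function(x, ...) {
  cat("<allocation_table> stage", x$stage, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
print.linkbar_trial <- function(x, ...) {
  cat("<linkbar_trial> ", x$design$variant, " design, scenario ", x$scenario,
      ", n = ", nrow(x$patients), ", seed ", x$seed, "\n", sep = "")
  if (!is.null(x$recommendations)) {
    rec <- x$recommendations
    cat("  rejected:", if (length(rec$rejected)) paste(rec$rejected, collapse = ", ")
        else "none", "\n")
  }
  invisible(x)
}

#' @method tidy linkbar_trial
#' @export
tidy.linkbar_trial <- function(x, ...) {
  if (is.null(x$tests)) rlang::abort("trial was run with analyse = FALSE")
  x$tests
}

#' @method glance linkbar_trial
#' @export
glance.linkbar_trial <- function(x, ...) {
  rec <- x$recommendations
  tibble::tibble(
    variant = x$design$variant, scenario = x$scenario,
    n_patients = nrow(x$patients),
    n_interim_fits = length(x$posterior_history),
    n_rejected = if (is.null(rec)) NA_integer_ else length(rec$rejected),
    any_rejected = if (is.null(rec)) NA else rec$any,
    method = if (is.null(x$final_fit)) NA_character_ else x$final_fit$method
  )
}

#' Serialise a trial to JSON
#'
#' @param trial A `linkbar_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  x <- list(
    variant = trial$design$variant, scenario = trial$scenario,
    seed = trial$seed,
    patients = trial$patients,
    allocation = lapply(trial$allocation_history, function(a) {
      list(stage = a$stage, probs = as.data.frame(a$probs))
    }),
    recommendations = if (!is.null(trial$recommendations)) {
      list(rejected = trial$recommendations$rejected,
           any = trial$recommendations$any)
    }
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}
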