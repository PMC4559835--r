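test_that("interim schedule is equally spaced with half-up rounding", {
  expect_equal(interim_schedule(350, 100, 4), c(100L, 163L, 225L, 288L))
  expect_equal(interim_schedule(350, 100, 1), 100L)
  expect_error(interim_schedule(100, 100, 4), "n_first")
})

test_that("outcome availability respects the delay", {
  acc <- build_accrual(350, 36)
  # at the 100th patient's recruit time with a 6-month delay, exactly the
  # first 41 patients have matured outcomes
  now <- acc$recruit_time[100]
  avail <- available_outcomes(acc, now, 6)
  expect_equal(max(avail$index), 41L)
  expect_equal(nrow(available_outcomes(acc, now, 0)), 100L)
  expect_equal(nrow(available_outcomes(acc, 5.9, 6)), 0L)
})

test_that("trials are deterministic given the seed", {
  s2 <- scenario_library()[["S2"]]
  d <- design_config("LB", n_total = 120L, n_first_interim = 60L,
                     n_stages = 3L, n_draws = 1000L)
  a <- run_trial(d, s2, seed = 42)
  b <- run_trial(d, s2, seed = 42)
  expect_identical(a$patients, b$patients)
  expect_identical(a$recommendations, b$recommendations)
  c <- run_trial(d, s2, seed = 43)
  expect_false(identical(a$patients$arm, c$patients$arm))
})

test_that("static variants never update allocation", {
  s2 <- scenario_library()[["S2"]]
  er <- run_trial(design_config("ER"), s2, seed = 7)
  expect_length(er$allocation_history, 1L)
  expect_true(all(er$allocation_history[[1]]$probs == 0.25))
  expect_true(all(er$patients$stage == 0L))

  pt <- run_trial(design_config("PT"), s2, seed = 7)
  expect_length(pt$allocation_history, 1L)
  # B1-only patients in PT can only ever receive control or T1
  b1only <- dplyr::filter(pt$patients, profile == 5L)
  expect_true(all(b1only$arm %in% c("control", "T1")))
})

test_that("recruitment timing is shared across variants for a fixed seed", {
  s1 <- scenario_library()[["S1"]]
  rts <- lapply(c("LB", "NLB", "PT", "ER"), function(v) {
    run_trial(design_config(v, n_total = 80L, n_first_interim = 40L,
                            n_stages = 2L, n_draws = 1000L),
              s1, seed = 5, analyse = FALSE)$patients$recruit_time
  })
  for (k in 2:4) expect_identical(rts[[1]], rts[[k]])
})

test_that("adaptive trials log one interim per trigger and record histories", {
  s2 <- scenario_library()[["S2"]]
  d <- design_config("LB", n_draws = 1000L)
  tr <- run_trial(d, s2, seed = 11)
  expect_equal(tr$interim_log$trigger, c(100L, 163L, 225L, 288L))
  expect_equal(tr$interim_log$n_outcomes[1], 41L)
  expect_true(all(tr$interim_log$refit))
  expect_length(tr$posterior_history, 4L)
  expect_length(tr$allocation_history, 5L)
  # every allocation row used is a probability vector
  pm <- as.matrix(tr$patients[, c("p_control", "p_T1", "p_T2", "p_T3")])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
})

test_that("replaying histories against the patient table reproduces every allocation row", {
  s8 <- scenario_library()[["S8"]]
  d <- design_config("NLB", n_draws = 1000L)
  tr <- run_trial(d, s8, seed = 23)
  pats <- tr$patients
  sched <- interim_schedule(d$n_total, d$n_first_interim, d$n_stages - 1L)
  counts <- matrix(0L, 8L, 4L)
  stage <- 0L
  recomputed <- matrix(NA_real_, nrow(pats), 4L)
  for (i in seq_len(nrow(pats))) {
    pr <- pats$profile[i]
    if (stage == 0L) {
      recomputed[i, ] <- initial_allocation(
        c(pats$b1[i], pats$b2[i], pats$b3[i]), d$variant)
    } else {
      sup <- tr$posterior_history[[stage]]$superiority[pr, ]
      recomputed[i, ] <- bar_weights(sup, counts[pr, ], d$tuning)
    }
    a <- match(pats$arm[i], c("control", "T1", "T2", "T3"))
    counts[pr, a] <- counts[pr, a] + 1L
    if (stage < length(sched) && i == sched[stage + 1L]) stage <- stage + 1L
  }
  used <- as.matrix(pats[, c("p_control", "p_T1", "p_T2", "p_T3")])
  expect_equal(unname(used), unname(recomputed), tolerance = 1e-12)
})

test_that("a harmful linked arm is starved of allocation when feedback is immediate", {
  # delay 0 and several interims: allocation to T1 for B1-positive patients
  # under the detrimental truth should end far below its starting share
  s5 <- scenario_library()[["S5"]]
  d <- design_config("LB", n_total = 200L, n_first_interim = 50L,
                     n_stages = 5L, delay = 0, n_draws = 1000L)
  late <- vapply(1:200, function(k) {
    tr <- run_trial(d, s5, seed = 300 + k, analyse = FALSE,
                    track_profile = 5L)
    mean(tr$trajectory[180:200, 2])
  }, numeric(1))
  expect_lt(mean(late), 0.2)  # started at 0.5
})

test_that("trials serialise to JSON", {
  tr <- run_trial(design_config("ER"), scenario_library()[["S1"]], seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_trial_json(tr, f)
  x <- jsonlite::read_json(f)
  expect_equal(x$variant, "ER")
  expect_length(x$patients$index, 350L)
})
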