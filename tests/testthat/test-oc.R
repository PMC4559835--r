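small_design <- function(variant) {
  design_config(variant, n_total = 60L, n_first_interim = 30L,
                n_stages = 2L, n_draws = 1000L)
}

test_that("single-replicate probabilities are 0/1 and accounting is exact", {
  s1 <- scenario_library()[["S1"]]
  oc1 <- run_oc(small_design("ER"), s1, n_reps = 1, seed = 3)
  expect_true(all(oc1$prob %in% c(0, 1)))
  oc <- run_oc(small_design("ER"), s1, n_reps = 25, seed = 3)
  expect_equal(nrow(oc), 13L)
  # rejection fractions times n_reps are integer counts
  expect_equal(oc$prob * oc$n_reps, round(oc$prob * oc$n_reps))
  expect_equal(oc$mc_se, sqrt(oc$prob * (1 - oc$prob) / oc$n_reps))
  rej <- attr(oc, "rejections")
  expect_equal(dim(rej), c(25L, 13L))
  expect_equal(unname(colMeans(rej)), oc$prob)
})

test_that("split-seed halves pool to the full run", {
  s2 <- scenario_library()[["S2"]]
  d <- small_design("LB")
  full <- attr(run_oc(d, s2, n_reps = 20, seed = 17), "rejections")
  h1 <- attr(run_oc(d, s2, n_reps = 10, seed = 17), "rejections")
  h2 <- attr(run_oc(d, s2, n_reps = 10, seed = 17, rep_offset = 10), "rejections")
  expect_equal(rbind(h1, h2), full)
})

test_that("ER power is invariant to relabelling B1 and B2 across scenarios 2 and 3", {
  lib <- scenario_library()
  d <- design_config("ER")
  oc2 <- run_oc(d, lib$S2, n_reps = 400, seed = 19)
  oc3 <- run_oc(d, lib$S3, n_reps = 400, seed = 20)
  p2 <- oc2$prob[oc2$hypothesis == "T1_in_B1"]
  p3 <- oc3$prob[oc3$hypothesis == "T1_in_B2"]
  se <- sqrt(p2 * (1 - p2) / 400 + p3 * (1 - p3) / 400)
  expect_lt(abs(p2 - p3), 3 * se)
})

test_that("trajectories start at the design's initial rule", {
  lib <- scenario_library()
  b1only <- 5L
  tr_lb <- allocation_trajectory(design_config("LB", n_draws = 1000L),
                                 lib$S2, b1only, n_reps = 3, seed = 4)
  early <- dplyr::filter(tr_lb, index < 100)
  expect_equal(unique(early$mean_prob[early$arm == "control"]), 0.5)
  expect_equal(unique(early$mean_prob[early$arm == "T1"]), 0.5)
  expect_equal(unique(early$mean_prob[early$arm == "T2"]), 0)

  tr_nlb <- allocation_trajectory(design_config("NLB", n_draws = 1000L),
                                  lib$S2, b1only, n_reps = 3, seed = 4)
  expect_true(all(dplyr::filter(tr_nlb, index < 100)$mean_prob == 0.25))

  tr_er <- allocation_trajectory(design_config("ER"), lib$S2, c(1, 0, 0),
                                 n_reps = 2, seed = 4)
  expect_true(all(tr_er$mean_prob == 0.25))
})

test_that("prevalence sweep varies only B1 and returns tidy power curves", {
  sw <- prevalence_sweep("ER", scenario_library()[["S2"]],
                         grid = c(0.15, 0.45), n_reps = 120, seed = 8)
  expect_equal(names(sw), c("design", "prevalence", "power", "mc_se"))
  expect_equal(nrow(sw), 2L)
  # power to detect the B1-linked effect grows with B1 prevalence
  expect_lt(sw$power[1], sw$power[2])
  expect_error(prevalence_sweep("ER", scenario_library()[["S2"]],
                                grid = c(0.5, 0.1), n_reps = 10, seed = 1))
})

test_that("sensitivity grid sweeps the requested axis", {
  s2 <- scenario_library()[["S2"]]
  d <- small_design("LB")
  sg <- sensitivity_grid("prior_mean", c(0, 1), d, s2, n_reps = 5, seed = 2)
  expect_setequal(unique(sg$hypothesis), c("T1_in_B1", "T1_in_B2"))
  expect_equal(nrow(sg), 4L)
  sg2 <- sensitivity_grid("recruitment_rate", c(7, 11), d, s2,
                          n_reps = 3, seed = 2)
  expect_equal(unique(sg2$axis), "recruitment_rate")
  # one-stage designs never refit
  d1 <- design_config("LB", n_total = 60L, n_first_interim = 30L, n_stages = 1L)
  tr <- run_trial(d1, s2, seed = 1)
  expect_length(tr$posterior_history, 0L)
})

test_that("autoplot methods return ggplot objects", {
  tr <- allocation_trajectory(design_config("ER"), scenario_library()[["S1"]],
                              5L, n_reps = 2, seed = 1)
  expect_s3_class(autoplot(tr), "ggplot")
  sw <- prevalence_sweep("ER", scenario_library()[["S2"]],
                         grid = c(0.2, 0.4), n_reps = 5, seed = 1)
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("allocation snapshots export to CSV", {
  tr <- run_trial(small_design("LB"), scenario_library()[["S2"]], seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_allocation_csv(tr, f)
  x <- utils::read.csv(f)
  expect_equal(names(x), c("stage", "profile", "control", "T1", "T2", "T3"))
  expect_true(all(abs(rowSums(x[, 3:6]) - 1) < 1e-9))
})
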