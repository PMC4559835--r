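test_that("design matrix has the fixed 16-column structure", {
  pats <- tibble::tibble(
    b1 = c(0, 1, 1), b2 = c(0, 0, 1), b3 = c(0, 1, 0),
    arm = c("control", "T1", "T3"), outcome = c(0L, 1L, 0L)
  )
  X <- build_design_matrix(pats)
  expect_equal(ncol(X), 16L)
  # control, all-negative: intercept only
  expect_equal(unname(X[1, ]), c(1, rep(0, 15)))
  # T1 patient positive for B1 and B3: intercept, theta1, beta1, beta3,
  # gamma11, gamma13
  on <- c("intercept", "theta1", "beta1", "beta3", "gamma11", "gamma13")
  expect_equal(unname(X[2, on]), rep(1, 6))
  expect_equal(sum(X[2, ]), 6)
  # T3 patient positive for B1 and B2 hits gamma31, gamma32
  expect_equal(unname(X[3, c("theta3", "gamma31", "gamma32")]), rep(1, 3))
  expect_error(build_design_matrix(dplyr::mutate(pats, outcome = NA)),
               "observed outcome")
})

test_that("prior-only superiority is one half under flat symmetric priors", {
  set.seed(11)
  post <- fit_posterior(NULL, prior_spec(linked_pairs = NULL),
                        n_draws = 20000, prior_only = TRUE)
  # 3 SE bound: the check is on the maximum over 24 (correlated)
  # Monte-Carlo estimates, so a per-entry 2 SE band is exceeded by chance
  tol <- 3 * sqrt(0.25 / post$draws_used)
  expect_true(all(abs(post$superiority - 0.5) < tol))
  expect_lt(abs(mean(post$superiority) - 0.5), 2 * sqrt(0.25 / post$draws_used))
})

test_that("linked informative priors favour the linked pair a priori", {
  set.seed(12)
  post <- fit_posterior(NULL, prior_spec(), n_draws = 20000, prior_only = TRUE)
  # on its own biomarker profile the linked arm carries the N(1,1) prior;
  # the flat theta prior dilutes the shift, but it stays above one half
  expect_gt(post$superiority["100", "T1"], 0.52)
  expect_gt(post$superiority["010", "T2"], 0.52)
  expect_gt(post$superiority["001", "T3"], 0.52)
  expect_error(fit_posterior(NULL, prior_spec()), "observed outcome")
})

test_that("Laplace superiority agrees with an exact importance-sampling reference", {
  pats <- make_patients(200, strong_s2(), seed = 31)
  ctr <- rep(0, 16); ctr[2] <- 1; ctr[8] <- 1   # theta1 + gamma11
  for (pri in list(prior_spec(linked_pairs = NULL), prior_spec())) {
    ref <- is_reference(pats, pri, n_draws = 4e5, seed = 1)
    expect_gt(attr(ref, "ess"), 1000)
    set.seed(5)
    lp <- fit_posterior(pats, pri, n_draws = 50000)
    expect_lt(abs(lp$superiority["100", "T1"] - ref(ctr)), 0.02)
  }
})

test_that("superiority approaches certainty as data accumulate on a true effect", {
  # p_1(B1-only) should exceed 0.95 with 300 observed outcomes under the
  # doubling truth (averaged over a few datasets)
  ps <- vapply(1:4, function(k) {
    pats <- make_patients(300, strong_s2(), seed = 100 + k)
    set.seed(k)
    fit_posterior(pats, prior_spec(), n_draws = 4000)$superiority["100", "T1"]
  }, numeric(1))
  expect_gt(mean(ps), 0.95)
})

test_that("two independent draw seeds give near-identical superiority tables", {
  pats <- make_patients(250, strong_s2(), seed = 77)
  pri <- prior_spec()
  set.seed(1); a <- fit_posterior(pats, pri, n_draws = 8000)
  set.seed(2); b <- fit_posterior(pats, pri, n_draws = 8000)
  expect_lt(max(abs(a$superiority - b$superiority)), 0.03)
})

test_that("profile lookup is a pure accessor", {
  pats <- make_patients(150, strong_s2(), seed = 3)
  set.seed(4)
  post <- fit_posterior(pats, prior_spec(), n_draws = 2000)
  v1 <- superiority_for_profile(post, c(1, 0, 0))
  v2 <- superiority_for_profile(post, "100")
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))
  expect_equal(unname(superiority_for_profile(post, c(0, 0, 0))),
               unname(post$superiority["000", ]))
})

test_that("posterior summaries export to JSON keyed by profile bit-string", {
  pats <- make_patients(100, strong_s2(), seed = 8)
  set.seed(9)
  post <- fit_posterior(pats, prior_spec(), n_draws = 1000)
  f <- withr::local_tempfile(fileext = ".json")
  write_posterior_json(post, f)
  x <- jsonlite::read_json(f)
  expect_setequal(names(x$superiority), profile_table()$key)
  expect_equal(x$n_outcomes, 100L)
})
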