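# Decision-analytic outputs: NMB/INMB/ICER, CEAC, tornado, horizons.

small_bundle <- function(n = 150, seed = 5) {
  model_bundle(cohort_n = n, horizon = 40, seed = seed)
}

test_that("nmb is the linear identity", {
  expect_equal(nmb(42092, 12.65, 12728), 12728 * 12.65 - 42092)
  expect_identical(nmb(0, 0, 5000), 0)
  expect_identical(nmb(100, 1, 0), -100)
  expect_error(nmb(1, 1, -1), "non-negative")
})

test_that("icer labels dominance and instability", {
  mk <- function(cost, qaly) list(cost = cost, qaly = qaly)
  expect_identical(icer(mk(90, 1.1), mk(100, 1.0))$verdict, "dominant")
  expect_identical(icer(mk(110, 0.9), mk(100, 1.0))$verdict, "dominated")
  r <- icer(mk(1100, 1.1), mk(100, 1.0))
  expect_identical(r$verdict, "icer")
  expect_equal(r$icer, 10000)
  expect_identical(icer(mk(200, 1.0), mk(100, 1.0))$verdict, "unstable")
})

test_that("paired INMB is antisymmetric with a sign-correct point estimate", {
  bundle <- small_bundle()
  res <- run_base_case(bundle, arms = c("exenatide", "liraglutide"))
  a <- res$liraglutide; b <- res$exenatide
  iab <- inmb_paired(a, b, seed = 2)
  iba <- inmb_paired(b, a, seed = 2)
  expect_equal(iab$inmb, -iba$inmb, tolerance = 1e-9)

  # arm vs itself: exactly zero with a degenerate CI
  self <- inmb_paired(a, a)
  expect_identical(self$inmb, 0)
  expect_identical(self$ci, c(0, 0))

  # a costlier clone with equal QALYs must have negative INMB
  worse <- a; worse$cost <- a$cost + 500
  iw <- inmb_paired(worse, a, seed = 3)
  expect_equal(iw$inmb, -500, tolerance = 1e-9)
  expect_error(inmb_paired(a, list(n = 10)), "equal cohort")
})

test_that("constructed per-patient NMB shifts are recovered", {
  bundle <- small_bundle()
  res <- run_base_case(bundle, arms = "exenatide")
  a <- res$exenatide
  shifted <- a
  set.seed(9)
  shifted$cost <- a$cost - 500 + rnorm(a$n, 0, 50)
  ii <- inmb_paired(shifted, a, seed = 4)
  se <- sd(shifted$cost - a$cost) / sqrt(a$n)
  expect_lt(abs(ii$inmb - 500), 3 * se)
  expect_true(ii$ci[1] < 500 && ii$ci[2] > 500)
})

test_that("arm summaries satisfy the NMB identity to numeric precision", {
  bundle <- small_bundle()
  res <- run_base_case(bundle, arms = c("exenatide", "loxenatide"))
  for (r in res) {
    s <- arm_summary(r, wtp = 12728)
    expect_equal(s$nmb, 12728 * s$qaly - s$cost, tolerance = 1e-9)
  }
})

test_that("CEAC probabilities are normalised, tie-split and cross where designed", {
  # dominant arm wins everywhere
  psa <- structure(list(
    cost = cbind(A = rep(10, 50), B = rep(1000, 50)),
    qaly = cbind(A = rep(2, 50), B = rep(1, 50)),
    failed = integer(0)), class = "psa_result")
  cc <- compute_ceac(psa, wtp_grid = c(0, 10000))
  expect_true(all(cc$probability[cc$arm == "A"] == 1))

  # k identical arms each win 1/k by uniform tie-splitting
  psa_tie <- structure(list(
    cost = cbind(A = rep(5, 20), B = rep(5, 20), C = rep(5, 20)),
    qaly = cbind(A = rep(1, 20), B = rep(1, 20), C = rep(1, 20)),
    failed = integer(0)), class = "psa_result")
  cc_tie <- compute_ceac(psa_tie, wtp_grid = c(0, 12728))
  expect_true(all(abs(cc_tie$probability - 1 / 3) < 1e-12))

  # designed crossing: NMB order flips at wtp* = 10000
  psa_x <- structure(list(
    cost = cbind(A = rep(0, 10), B = rep(10000, 10)),
    qaly = cbind(A = rep(0, 10), B = rep(1, 10)),
    failed = integer(0)), class = "psa_result")
  grid <- seq(0, 20000, by = 400)
  cc_x <- compute_ceac(psa_x, wtp_grid = grid)
  pa <- cc_x[cc_x$arm == "A", ]
  crossing <- min(pa$wtp[pa$probability < 0.5])
  expect_lte(abs(crossing - 10000), 400)

  # normalisation at every grid point
  sums <- tapply(cc_x$probability, cc_x$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(compute_ceac(psa, wtp_grid = numeric(0)), "empty")
})

test_that("PSA is reproducible and collapses to the base case when fixed", {
  bundle <- model_bundle(cohort_n = 80, horizon = 25, seed = 3)
  p1 <- run_psa(bundle, iterations = 4, cohort_n = 60, seed = 13)
  p2 <- run_psa(bundle, iterations = 4, cohort_n = 60, seed = 13)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qaly, p2$qaly)
  expect_identical(dim(p1$cost), c(4L, 6L))
  expect_false(anyNA(p1$cost))

  # an all-fixed parameter table makes every iteration identical
  fixed_params <- fixture_params()
  fixed_params$table$family <- "fixed"
  fixed_params$table$low <- fixed_params$table$mean
  fixed_params$table$high <- fixed_params$table$mean
  fixed_set <- glp1sim:::new_parameter_set(fixed_params$table)
  bundle_f <- model_bundle(params = fixed_set, cohort_n = 60, horizon = 25,
                           seed = 3)
  pf <- run_psa(bundle_f, iterations = 2, cohort_n = 60, seed = 13)
  expect_equal(pf$cost[1, ], pf$cost[2, ], tolerance = 1e-12)
})

test_that("tornado entries respond to prices and ignore unread parameters", {
  bundle <- model_bundle(cohort_n = 60, horizon = 20, seed = 7)
  tor <- one_way_sa(bundle, arm = "loxenatide",
                    parameters = c("Cost_exenatide_600ug",
                                   "Cost_loxenatide_100ug",
                                   "Prop_past_smoker", "Discount"),
                    top = 10)
  expect_identical(names(tor), c("parameter", "inmb_low", "inmb_high",
                                 "range"))
  expect_true(all(diff(tor$range) <= 1e-12))
  # raising the comparator price raises the INMB of the arm under study
  ex <- tor[tor$parameter == "Cost_exenatide_600ug", ]
  expect_gt(ex$inmb_high, ex$inmb_low)
  # raising the arm's own price lowers its INMB
  lox <- tor[tor$parameter == "Cost_loxenatide_100ug", ]
  expect_lt(lox$inmb_high, lox$inmb_low)
  # a parameter the simulation never reads has zero range
  smoker <- tor[tor$parameter == "Prop_past_smoker", ]
  expect_lt(smoker$range, 1e-9)
  # degenerate parameters are skipped with a warning
  expect_warning(one_way_sa(bundle, arm = "loxenatide",
                            parameters = "Prop_insulin_use"),
                 "no bounds")
})

test_that("scenario horizons accumulate monotonically and match shapes", {
  bundle <- model_bundle(cohort_n = 60, horizon = 40, seed = 9)
  sc <- scenario_horizons(bundle, horizons = c(10, 20, 30, 40))
  expect_identical(nrow(sc), 24L)
  for (arm in regimen_labels()) {
    sub <- sc[sc$arm == arm, ]
    sub <- sub[order(sub$horizon), ]
    expect_true(all(diff(sub$cost) >= -1e-9))
    expect_true(all(diff(sub$qaly) >= -1e-9))
  }
  # a horizon at or beyond the lifetime equals the base case
  res <- run_base_case(bundle, arms = "exenatide", horizon = 40)
  expect_equal(sc$cost[sc$arm == "exenatide" & sc$horizon == 40],
               mean(res$exenatide$cost), tolerance = 1e-9)
})
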