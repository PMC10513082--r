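# Microsimulation: treatment effects, accrual arithmetic, discounting,
# common random numbers, closed-form limits.

test_that("6-month treatment effects scale endpoints multiplicatively", {
  st <- reference_state()
  st$hba1c <- 8.5
  prof <- null_profile()
  prof$effects <- c(hba1c = -0.10, bmi = 0, sbp = 0, dbp = 0)
  st2 <- apply_treatment_effects(st, prof)
  expect_equal(st2$hba1c, 7.65, tolerance = 1e-12)
  expect_identical(st2$bmi, st$bmi)

  # zero change rates leave the state unchanged
  st3 <- apply_treatment_effects(st, null_profile())
  expect_identical(st3$hba1c, st$hba1c)

  prof$effects <- prof$effects[-1]
  expect_error(apply_treatment_effects(st, prof), "hba1c")
})

test_that("drug costing follows pack content and titration schedules", {
  draw <- base_case_draw(fixture_params())
  profs <- treatment_profiles()
  # dulaglutide maintenance year: 22.26 USD/week x 52
  expect_equal(glp1sim:::glp1_drug_cost(profs$dulaglutide, draw, 2),
               1157.52, tolerance = 1e-9)
  # exenatide year 1: 4 titration weeks at half dose
  expect_equal(glp1sim:::glp1_drug_cost(profs$exenatide, draw, 1),
               60.96 * (4 * 70 + 48 * 140) / 600, tolerance = 1e-9)
  # semaglutide maintenance: 1 mg/week from a 2 mg pack
  expect_equal(glp1sim:::glp1_drug_cost(profs$semaglutide, draw, 2),
               71.54 * 52 / 2, tolerance = 1e-9)
})

test_that("cost accrual splits event-year and following-year components", {
  draw <- base_case_draw(fixture_params())
  n <- 3
  cats <- glp1sim:::complication_categories()
  zero <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
  new_events <- zero; new_events[1, "mi"] <- 1L
  active <- zero; active[2, "mi"] <- 1L
  rec <- list(alive = rep(TRUE, n), died = rep(FALSE, n),
              new_events = new_events, active = active,
              hypo_events = rep(0L, n), routine_cost = rep(0, n),
              n_aes = rep(0, n), bmi = rep(26.5, n), base_bmi = rep(26.5, n))
  cm <- accrue_costs(rec, draw)
  expect_equal(unname(cm[1, "mi"]), 7800.45)
  expect_equal(unname(cm[2, "mi"]), 455.4)
  expect_equal(sum(cm[3, ]), 0)
})

test_that("utility accrual matches the worked decrements and floors at zero", {
  draw <- base_case_draw(fixture_params())
  n <- 3
  cats <- glp1sim:::complication_categories()
  zero <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
  active <- zero
  active[2, "hf"] <- 1L
  active[3, c("hf", "mi", "stroke", "amputation", "renal_failure",
              "ulcer")] <- 1L
  rec <- list(alive = rep(TRUE, n), died = rep(FALSE, n),
              new_events = zero, active = active,
              hypo_events = rep(0L, n), routine_cost = rep(0, n),
              n_aes = rep(0, n), bmi = rep(26.5, n), base_bmi = rep(26.5, n))
  u <- accrue_utilities(rec, draw)
  # uncomplicated year: 1 - 0.06
  expect_equal(u$utility[1], 0.94, tolerance = 1e-12)
  # add heart failure (0.25)
  expect_equal(u$utility[2], 0.69, tolerance = 1e-12)
  # stacked decrements exceeding 1 are floored at 0
  expect_identical(u$utility[3], 0)
})

test_that("discounting uses the end-of-cycle convention", {
  expect_equal(discount_stream(c(100, 100), 0.05),
               100 / 1.05 + 100 / 1.05^2, tolerance = 1e-12)
  expect_equal(discount_stream(c(100, 100), 0.05), 185.94, tolerance = 0.01)
  expect_equal(discount_stream(c(7, 7, 7), 0), 21)
  expect_equal(discount_stream(1, 0.05), 0.95238, tolerance = 1e-5)
  expect_error(discount_stream(1, -0.1), "non-negative")
})

test_that("forced death in year one accrues one life-year and end-of-life cost", {
  cohort <- uniform_cohort(5)
  draw <- zero_event_draw()
  res <- run_arm(cohort, null_profile(), model = NULL, draw = draw,
                 life_table = constant_life_table(1 - 1e-12), seed = 1,
                 horizon = 10)
  expect_identical(res$life_years, rep(1, 5))
  # cost = (year-1 drug + metformin + end-of-life) discounted once
  drug <- glp1sim:::routine_cost(null_profile(), draw, 1, TRUE, cohort$duration)[1]
  expected <- (drug + 22987.5) / 1.05
  expect_equal(res$cost, rep(expected, 5), tolerance = 1e-9)
  expect_equal(unname(res$cost_by_category[1, "end_of_life"]),
               22987.5 / 1.05, tolerance = 1e-9)
})

test_that("zero-event world matches the discounted utility annuity exactly", {
  h <- 10
  cohort <- uniform_cohort(20)
  res <- run_arm(cohort, null_profile(), model = NULL,
                 draw = zero_event_draw(),
                 life_table = constant_life_table(1e-15), seed = 2,
                 horizon = h)
  annuity <- sum(0.94 / 1.05^(1:h))
  expect_lt(max(abs(res$qaly - annuity)), 1e-9)
  expect_identical(res$life_years, rep(as.numeric(h), 20))
  expect_true(all(res$censored))
  # no complication costs in a zero-probability world
  expect_identical(sum(res$cost_by_category[,
    glp1sim:::complication_categories()]), 0)
})

test_that("common random numbers make identical arms bit-identical", {
  cohort <- sample_cohort(300, fixture_params(), seed = 4)
  model <- gen_risk_coefficients()
  lt <- gen_life_table()
  draw <- base_case_draw(fixture_params())
  p1 <- treatment_profiles()$dulaglutide
  p2 <- p1; p2$drug <- "dulaglutide-clone"
  r1 <- run_arm(cohort, p1, model, draw, lt, seed = 11, horizon = 60)
  r2 <- run_arm(cohort, p2, model, draw, lt, seed = 11, horizon = 60)
  expect_identical(r1$cost, r2$cost)
  expect_identical(r1$qaly, r2$qaly)
  expect_identical(r1$life_years, r2$life_years)
  # and a rerun of the same arm reproduces itself exactly
  r3 <- run_arm(cohort, p1, model, draw, lt, seed = 11, horizon = 60)
  expect_identical(r1$cost, r3$cost)
})

test_that("discounted totals never exceed undiscounted and fall with the rate", {
  cohort <- sample_cohort(200, fixture_params(), seed = 6)
  model <- gen_risk_coefficients()
  lt <- gen_life_table()
  draw <- base_case_draw(fixture_params())
  prof <- treatment_profiles()$exenatide
  res <- lapply(c(0, 0.05, 0.08), function(r)
    run_arm(cohort, prof, model, draw, lt, seed = 21, horizon = 60,
            discount_rate = r))
  expect_true(all(res[[2]]$cost <= res[[1]]$cost + 1e-9))
  expect_true(all(res[[3]]$cost <= res[[2]]$cost + 1e-9))
  expect_true(all(res[[3]]$qaly <= res[[2]]$qaly + 1e-9))
  r5 <- res[[2]]
  expect_true(all(r5$cost <= r5$cost_undiscounted + 1e-9))
  expect_true(all(r5$qaly <= r5$qaly_undiscounted + 1e-9))
  expect_true(all(r5$life_years >= r5$qaly - 1e-9))
})

test_that("per-complication ledgers add up to the complication cost totals", {
  cohort <- sample_cohort(300, fixture_params(), seed = 8)
  model <- gen_risk_coefficients()
  res <- run_arm(cohort, treatment_profiles()$liraglutide, model,
                 base_case_draw(fixture_params()), gen_life_table(),
                 seed = 31, horizon = 60)
  bk <- complication_breakdown(res)
  cats <- glp1sim:::complication_categories()
  expect_equal(bk$sum[bk$measure == "cost"],
               sum(bk[bk$measure == "cost", cats]), tolerance = 1e-9)
  expect_equal(bk$sum[bk$measure == "cost"],
               mean(rowSums(res$cost_by_category[, cats])), tolerance = 1e-9)
})

test_that("simulate_patient returns a coherent trajectory", {
  st <- uniform_cohort(1)
  traj <- simulate_patient(st, null_profile(), model = NULL,
                           draw = zero_event_draw(),
                           life_table = constant_life_table(0.3), seed = 7,
                           horizon = 50)
  expect_s3_class(traj, "trajectory")
  expect_false(traj$censored)
  expect_identical(traj$death_year, as.integer(traj$life_years))
  traj2 <- simulate_patient(st, null_profile(), model = NULL,
                            draw = zero_event_draw(),
                            life_table = constant_life_table(0.3), seed = 7,
                            horizon = 50)
  expect_identical(traj$cost, traj2$cost)
  expect_identical(traj$death_year, traj2$death_year)
})
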