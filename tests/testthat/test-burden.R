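# Burden GLM: IRLS correctness, parameter recovery, error calibration.

test_that("gaussian-identity IRLS equals the least-squares solution", {
  d <- gen_glm_dataset(2000, 300, -200, sd = 800, seed = 11)
  X <- cbind(`(Intercept)` = 1, poor_hba1c = d$poor_hba1c,
             high_bmi = d$high_bmi, age = d$age, female = d$female,
             sbp = d$sbp)
  fit <- irls_fit(X, d$outcome, "gaussian", "identity")
  ols <- stats::lm.fit(X, d$outcome)$coefficients
  expect_lt(max(abs(fit$coefficients - ols)), 1e-8)
  expect_true(fit$converged)

  # independent cross-check of coefficients and SEs against stats::glm
  gfit <- stats::glm(d$outcome ~ poor_hba1c + high_bmi + age + female + sbp,
                     data = d, family = gaussian())
  expect_lt(max(abs(fit$coefficients - coef(gfit))), 1e-8)
  expect_lt(max(abs(fit$se - summary(gfit)$coefficients[, 2])), 1e-6)
})

test_that("gamma/log IRLS recovers multiplicative effects and matches glm", {
  d <- gen_glm_dataset(20000, 0.2, -0.1, intercept = 8,
                       noise_family = "gamma", shape = 15, seed = 12)
  X <- cbind(`(Intercept)` = 1, poor_hba1c = d$poor_hba1c,
             high_bmi = d$high_bmi, age = d$age, female = d$female,
             sbp = d$sbp)
  fit <- irls_fit(X, d$outcome, "gamma", "log")
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["poor_hba1c"]] - 0.2),
            3 * fit$se[["poor_hba1c"]])
  gfit <- stats::glm(d$outcome ~ poor_hba1c + high_bmi + age + female + sbp,
                     data = d, family = Gamma(link = "log"))
  expect_lt(max(abs(fit$coefficients - coef(gfit))), 1e-6)
})

test_that("IRLS rejects degenerate inputs informatively", {
  X <- cbind(a = rep(1, 20), b = rep(2, 20))  # collinear
  expect_error(irls_fit(X, rnorm(20)), "collinear")
  expect_error(irls_fit(matrix(1, 3, 5), rnorm(3)), "more observations")
  expect_error(irls_fit(cbind(1, rnorm(20)), c(-1, rexp(19)),
                        family = "gamma", link = "log"), "positive")
})

test_that("injected cost and QALY effects are recovered at scale", {
  # +667 USD on the cost scale, gaussian noise
  d <- gen_glm_dataset(1e5, 667, 0, sd = 2000, seed = 13)
  X <- cbind(`(Intercept)` = 1, poor_hba1c = d$poor_hba1c,
             high_bmi = d$high_bmi, age = d$age, female = d$female,
             sbp = d$sbp)
  fit <- irls_fit(X, d$outcome)
  expect_lt(abs(fit$coefficients[["poor_hba1c"]] - 667),
            3 * fit$se[["poor_hba1c"]])

  # -0.013 QALY-scale effect
  d2 <- gen_glm_dataset(1e5, -0.013, 0.017, intercept = 0.4, sd = 0.05,
                        seed = 14)
  fit2 <- irls_fit(cbind(1, d2$poor_hba1c, d2$high_bmi, d2$age, d2$female,
                         d2$sbp), d2$outcome)
  expect_lt(abs(fit2$coefficients[2] + 0.013), 3 * fit2$se[2])
  expect_lt(abs(fit2$coefficients[3] - 0.017), 3 * fit2$se[3])
})

test_that("burden_analysis reports marginal effects on the outcome scale", {
  # deterministic outcome equal to 100 x exposure: marginal effect exactly 100
  set.seed(15)
  n <- 400
  tab <- data.frame(
    hba1c = c(rep(6.5, n / 2), rep(8, n / 2)), bmi = runif(n, 22, 28),
    age = rnorm(n, 55, 5), female = rbinom(n, 1, 0.5),
    sbp = rnorm(n, 125, 10), dbp = rnorm(n, 78, 8),
    duration = rnorm(n, 6, 1), smoker_current = rbinom(n, 1, 0.2),
    ckd_stage = 0, history_mi = 0, history_stroke = 0)
  tab$complication_cost <- 100 * (tab$hba1c > 7)
  tab$complication_disutility <- 0.5 * (tab$bmi > 25)
  rep <- burden_analysis(tab,
    cost_spec = glm_spec("cost", "gaussian", "identity",
                         covariates = c("age", "female", "sbp")),
    disu_spec = glm_spec("disutility", "gaussian", "identity",
                         covariates = c("age", "female", "sbp")))
  eff <- rep$cost$effects
  expect_equal(eff$effect[eff$exposure == "poor_hba1c"], 100,
               tolerance = 1e-8)
  deff <- rep$disutility$effects
  expect_equal(deff$effect[deff$exposure == "high_bmi"], 0.5,
               tolerance = 1e-8)

  # single-level exposure refused
  tab2 <- tab; tab2$hba1c <- 8
  expect_error(burden_analysis(tab2), "single level")
})

test_that("exposure test keeps its nominal type-I error under the null", {
  reps <- 500
  rejections <- 0
  for (r in seq_len(reps)) {
    d <- gen_glm_dataset(200, 0, 0, sd = 500, seed = 2000 + r)
    X <- cbind(1, d$poor_hba1c, d$high_bmi, d$age, d$female, d$sbp)
    fit <- irls_fit(X, d$outcome)
    if (fit$p_value[2] < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  tol <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), tol)
})

test_that("burden_analysis runs on pooled simulation output", {
  bundle <- model_bundle(cohort_n = 150, horizon = 30, seed = 17)
  res <- run_base_case(bundle, arms = c("exenatide", "loxenatide"))
  tab <- do.call(rbind, lapply(res, patient_table))
  rep <- burden_analysis(tab)
  for (nm in c("cost", "disutility")) {
    expect_true(rep[[nm]]$fit$converged)
    expect_true(all(rep[[nm]]$effects$p_value >= 0 &
                      rep[[nm]]$effects$p_value <= 1))
  }
})
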