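# Network meta-analysis: network structure, estimation, convergence and
# consistency diagnostics.

test_that("build_network counts edges and detects disconnection", {
  eff <- rbind(A = c(hba1c = 0), B = c(hba1c = -0.1), C = c(hba1c = -0.2))
  cfg <- nma_config(treatments = c("A", "B", "C"), true_effects = eff,
                    heterogeneity_sd = c(hba1c = 0),
                    studies = list(S1 = c("A", "B"), S2 = c("B", "C")),
                    noise_sd = c(hba1c = 0.1), seed = 1)
  ds <- gen_nma_dataset(cfg, endpoints = "hba1c")
  net <- build_network(ds, "hba1c")
  expect_true(net$connected)
  expect_identical(net$edges$n_studies, c(1L, 1L))
  expect_setequal(paste(net$edges$t1, net$edges$t2), c("A B", "B C"))

  # single-arm study rejected at validation
  ds_bad <- ds[-1, ]
  expect_error(build_network(ds_bad, "hba1c"), "single arm")

  # the nine-trial roster: 7 nodes, connected
  full <- gen_nma_dataset(nma_config(seed = 2))
  net_full <- build_network(full, "hba1c")
  expect_identical(length(net_full$treatments), 7L)
  expect_true(net_full$connected)
})

test_that("two-arm common-effect NMA matches the inverse-variance oracle", {
  cfg <- pairwise_config(n_studies = 20, delta = -0.10, n = 400,
                         noise = 0.1, het = 0, seed = 21)
  ds <- gen_nma_dataset(cfg, endpoints = "hba1c")
  oracle <- pooled_pairwise(ds)
  fit <- fit_nma(ds, "hba1c", reference = "A", chains = 4, kept = 4000,
                 burnin = 1000, seed = 2, tau_fixed = 0)
  row <- fit$summary[fit$summary$treatment == "B", ]
  expect_lt(abs(row$mean - oracle["mean"]), 3 * oracle["se"])
  # posterior SD agrees with the closed-form SE within Monte-Carlo slack
  expect_lt(abs(row$sd - oracle["se"]) / oracle["se"], 0.25)
})

test_that("NMA recovers known truths on the six-regimen network", {
  ds <- gen_nma_dataset(nma_config(seed = 31))
  truth <- attr(ds, "truths")
  fit <- fit_nma(ds, "hba1c", reference = "placebo", chains = 4,
                 kept = 4000, burnin = 1000, seed = 3)
  expect_true(fit$converged)
  for (i in seq_len(nrow(fit$summary))) {
    tr <- fit$summary$treatment[i]
    true_contrast <- truth[tr, "hba1c"] - truth["placebo", "hba1c"]
    expect_lt(abs(fit$summary$mean[i] - true_contrast),
              3 * fit$summary$sd[i])
  }
})

test_that("identical arms everywhere centre all contrasts at zero", {
  eff <- rbind(A = c(hba1c = -0.1), B = c(hba1c = -0.1),
               C = c(hba1c = -0.1))
  cfg <- nma_config(treatments = c("A", "B", "C"), true_effects = eff,
                    heterogeneity_sd = c(hba1c = 0),
                    studies = list(S1 = c("A", "B"), S2 = c("B", "C"),
                                   S3 = c("A", "C")),
                    n_per_arm = 2000, noise_sd = c(hba1c = 0.05), seed = 7)
  ds <- gen_nma_dataset(cfg, endpoints = "hba1c")
  fit <- fit_nma(ds, "hba1c", reference = "A", chains = 2, kept = 3000,
                 burnin = 500, seed = 5, tau_fixed = 0)
  for (i in seq_len(nrow(fit$summary)))
    expect_lt(abs(fit$summary$mean[i]), 3 * fit$summary$sd[i])
})

test_that("posterior summaries are bit-identical under a fixed seed", {
  ds <- gen_nma_dataset(pairwise_config(n_studies = 4, seed = 2),
                        endpoints = "hba1c")
  f1 <- fit_nma(ds, "hba1c", chains = 2, kept = 500, burnin = 100, seed = 9)
  f2 <- fit_nma(ds, "hba1c", chains = 2, kept = 500, burnin = 100, seed = 9)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$tau, f2$tau)
})

test_that("gelman_rubin follows its conventions and matches coda", {
  # identical constant chains: R-hat 1 by the zero-variance convention
  const <- replicate(3, rep(2.5, 100), simplify = FALSE)
  expect_identical(unname(gelman_rubin(const)), 1)

  # well-mixed chains from a common distribution
  set.seed(4)
  mixed <- replicate(4, rnorm(1e4), simplify = FALSE)
  expect_lt(gelman_rubin(mixed), 1.01)

  # designed divergence
  apart <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(apart), 1.1)

  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")

  # independent cross-check against coda's PSRF on the same draws
  set.seed(8)
  chains <- replicate(4, cumsum(rnorm(2000)) / 40, simplify = FALSE)
  ours <- gelman_rubin(chains)
  coda_rhat <- coda::gelman.diag(coda::as.mcmc.list(
    lapply(chains, coda::mcmc)), autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(ours - coda_rhat), 0.15)
})

test_that("relative_effects is reference-invariant with exact self-contrasts", {
  ds <- gen_nma_dataset(nma_config(seed = 13))
  fit <- fit_nma(ds, "bmi", reference = "placebo", chains = 2, kept = 2000,
                 burnin = 500, seed = 4)
  tab_p <- relative_effects(fit, "placebo")
  tab_e <- relative_effects(fit, "exenatide")
  pick <- function(tab, a, b) tab[tab$t1 == a & tab$t2 == b, ]$mean
  expect_equal(pick(tab_p, "placebo", "dulaglutide"),
               pick(tab_e, "placebo", "dulaglutide"), tolerance = 1e-12)
  # consistency: A->C = A->B + B->C for posterior means
  expect_equal(pick(tab_p, "placebo", "semaglutide"),
               pick(tab_p, "placebo", "liraglutide") +
                 pick(tab_p, "liraglutide", "semaglutide"),
               tolerance = 1e-9)
  expect_error(relative_effects(fit, "nosuch"), "unknown reference")
})

test_that("node-splitting separates consistent from inconsistent evidence", {
  # consistent triangle: small |direct - indirect|, p typically > 0.05
  ds_ok <- triangle_dataset(shift_ac = 0, n = 2000, seed = 41)
  ns_ok <- node_split(ds_ok, "hba1c", c("A", "C"), chains = 2, kept = 3000,
                      burnin = 500, seed = 6)
  expect_gt(ns_ok$p_value, 0.05)

  # inconsistency injected into the A:C design: detected at large n
  ds_bad <- triangle_dataset(shift_ac = -0.10, n = 2000, seed = 42)
  ns_bad <- node_split(ds_bad, "hba1c", c("A", "C"), chains = 2,
                       kept = 3000, burnin = 500, seed = 6)
  expect_lt(ns_bad$p_value, 0.05)

  # star network: no indirect path
  eff <- rbind(A = c(hba1c = 0), B = c(hba1c = -0.1), C = c(hba1c = -0.2))
  star <- nma_config(treatments = c("A", "B", "C"), true_effects = eff,
                     heterogeneity_sd = c(hba1c = 0),
                     studies = list(S1 = c("A", "B"), S2 = c("A", "C")),
                     noise_sd = c(hba1c = 0.1), seed = 2)
  ds_star <- gen_nma_dataset(star, endpoints = "hba1c")
  expect_error(node_split(ds_star, "hba1c", c("A", "B")), "splittable|indirect")
})

test_that("design-by-treatment statistic behaves under the null and at boundaries", {
  # I^2 boundary identities hold exactly
  expect_identical(i_squared(2, 2), 0)
  expect_identical(i_squared(4, 2), 50)
  expect_identical(i_squared(0, 0), 0)

  # p-values roughly uniform across consistent replicates
  ps <- vapply(1:40, function(r) {
    ds <- triangle_dataset(shift_ac = 0, n = 300, noise = 0.1,
                           studies_per_design = 2, seed = 100 + r)
    design_by_treatment(ds, "hba1c")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(is.finite(ps)))

  # a large injected inconsistency is detected
  ds_bad <- triangle_dataset(shift_ac = -0.15, n = 2000,
                             studies_per_design = 2, seed = 77)
  expect_lt(design_by_treatment(ds_bad, "hba1c")$p_value, 0.01)

  # single-design network: not estimable
  ds2 <- gen_nma_dataset(pairwise_config(n_studies = 3, seed = 3),
                         endpoints = "hba1c")
  dbt <- design_by_treatment(ds2, "hba1c")
  expect_false(dbt$estimable)
})
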