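# Decision-analytic outputs and uncertainty analyses: NMB/INMB/ICER,
# complication breakdowns, one-way sensitivity analysis, PSA with CEAC,
# and scenario horizons.

#' Convert NMA contrasts into absolute per-arm change rates
#'
#' Relative effects (contrasts versus a reference arm) are anchored to the
#' reference arm's observed trial change rate:
#' `arm rate = anchor rate + contrast` on the difference scale.
#'
#' @param fits named list of `nma_result` objects, one per endpoint.
#' @param anchors named list, per endpoint: `list(treatment =, rate =)` —
#'   the reference treatment and its observed change rate.
#' @param treatments arms to tabulate (default the six regimens).
#' @return list with `mean` and `sd` matrices (treatment x endpoint); `sd`
#'   is the posterior SD of each contrast (0 for the anchor arm), used for
#'   the normal effect draws of the PSA.
#' @export
arm_effects <- function(fits, anchors, treatments = regimen_labels()) {
  endpoints <- names(fits)
  mean_m <- sd_m <- matrix(NA_real_, length(treatments), length(endpoints),
                           dimnames = list(treatments, endpoints))
  for (ep in endpoints) {
    fit <- fits[[ep]]
    anc <- anchors[[ep]]
    if (is.null(anc)) stopf("no anchor for endpoint '%s'", ep)
    contrasts <- relative_effects(fit, reference = anc$treatment)
    for (tr in treatments) {
      if (tr == anc$treatment) {
        mean_m[tr, ep] <- anc$rate; sd_m[tr, ep] <- 0
      } else {
        row <- contrasts[contrasts$t1 == anc$treatment & contrasts$t2 == tr, ]
        if (!nrow(row)) stopf("treatment '%s' absent from NMA for '%s'", tr, ep)
        mean_m[tr, ep] <- anc$rate + row$mean
        sd_m[tr, ep] <- row$sd
      }
    }
  }
  list(mean = mean_m, sd = sd_m)
}

#' Bundle the model inputs for the decision analyses
#'
#' Convenience container holding everything the base case, PSA, one-way SA
#' and scenario analyses need.
#'
#' @param params a `parameter_set`.
#' @param risk_model a `risk_model`.
#' @param life_table a `life_table`.
#' @param effects list with `mean` (and optionally `sd`) matrices
#'   (arm x endpoint) of 6-month change rates; see [arm_effects()].
#' @param cohort_n cohort size for the base case.
#' @param horizon simulation horizon in years.
#' @param seed master seed (cohort sampling and event streams derive from
#'   it).
#' @return a `model_bundle`.
#' @export
model_bundle <- function(params = default_parameters(),
                         risk_model = gen_risk_coefficients(),
                         life_table = gen_life_table(),
                         effects = list(mean = default_true_effects()[
                           regimen_labels(), , drop = FALSE],
                           sd = NULL),
                         cohort_n = 2000, horizon = 100L, seed = 1L) {
  if (is.null(effects$sd)) {
    effects$sd <- effects$mean * 0
  }
  structure(list(params = params, risk_model = risk_model,
                 life_table = life_table, effects = effects,
                 cohort_n = cohort_n, horizon = horizon,
                 seed = as.integer(seed)),
            class = "model_bundle")
}

bundle_cohort <- function(bundle, n = bundle$cohort_n) {
  sample_cohort(n, bundle$params, seed = child_seed(bundle$seed, 0L, 13L))
}

#' Run the base case: all six arms on a common cohort
#'
#' Every arm is simulated on the same cohort with the same event-stream
#' seed (common random numbers), at the parameter table means.
#'
#' @param bundle a [model_bundle()].
#' @param arms arm labels to run.
#' @param draw optional `parameter_draw` (defaults to the base case means).
#' @param cohort optional pre-sampled cohort.
#' @param horizon optional horizon override.
#' @return named list of `simulation_result`s.
#' @export
run_base_case <- function(bundle, arms = regimen_labels(), draw = NULL,
                          cohort = NULL, horizon = NULL) {
  draw <- draw %||% base_case_draw(bundle$params)
  cohort <- cohort %||% bundle_cohort(bundle)
  horizon <- horizon %||% bundle$horizon
  profiles <- treatment_profiles(bundle$effects$mean)
  out <- list()
  for (arm in arms) {
    out[[arm]] <- run_arm(cohort, profiles[[arm]], bundle$risk_model, draw,
                          bundle$life_table,
                          seed = child_seed(bundle$seed, 1L, 17L),
                          horizon = horizon)
  }
  out
}

#' Net monetary benefit
#'
#' `NMB = wtp x QALY - cost`.
#'
#' @param cost cost (USD).
#' @param qaly quality-adjusted life-years.
#' @param wtp willingness-to-pay threshold (USD/QALY, >= 0).
#' @return NMB in USD (vectorised).
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stopf("wtp must be non-negative")
  wtp * qaly - cost
}

#' Summarise one arm
#'
#' Mean cost, QALY, life-years and NMB with patient-level 95% confidence
#' intervals (first-order Monte-Carlo uncertainty across patients).
#'
#' @param result a `simulation_result`.
#' @param wtp willingness-to-pay threshold.
#' @return one-row data.frame.
#' @export
arm_summary <- function(result, wtp = 12728) {
  ci <- function(x) {
    se <- sd(x) / sqrt(length(x))
    c(mean(x), mean(x) - 1.96 * se, mean(x) + 1.96 * se)
  }
  co <- ci(result$cost); qa <- ci(result$qaly); lyr <- ci(result$life_years)
  nm <- ci(nmb(result$cost, result$qaly, wtp))
  data.frame(arm = result$arm, cost = co[1], cost_low = co[2],
             cost_high = co[3], qaly = qa[1], qaly_low = qa[2],
             qaly_high = qa[3], life_years = lyr[1], ly_low = lyr[2],
             ly_high = lyr[3], nmb = nm[1], nmb_low = nm[2],
             nmb_high = nm[3])
}

#' Incremental net monetary benefit between two paired arms
#'
#' Mean of per-patient NMB differences under common random numbers, with a
#' percentile-bootstrap 95% CI over patients.
#'
#' @param result,reference `simulation_result`s run on the same cohort.
#' @param wtp willingness-to-pay threshold.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `inmb`, `ci` (length 2), `arm`, `reference`.
#' @export
inmb_paired <- function(result, reference, wtp = 12728, n_boot = 2000,
                        seed = 1L) {
  if (result$n != reference$n)
    stopf("INMB requires equal cohort sizes (%d vs %d)", result$n,
          reference$n)
  diff <- nmb(result$cost, result$qaly, wtp) -
    nmb(reference$cost, reference$qaly, wtp)
  est <- mean(diff)
  if (all(diff == diff[1])) {
    ci <- c(est, est)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(child_seed(seed, 0L, 19L))
    boots <- vapply(seq_len(n_boot), function(b)
      mean(diff[sample.int(length(diff), replace = TRUE)]), numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  list(arm = result$arm, reference = reference$arm, inmb = est, ci = ci,
       wtp = wtp)
}

#' Incremental cost-effectiveness ratio with dominance verdicts
#'
#' `ICER = (cost - cost_ref) / (QALY - QALY_ref)`.  Cheaper-and-more-
#' effective arms are labelled `dominant`, costlier-and-less-effective
#' `dominated`; a QALY difference below `min_delta_qaly` is flagged
#' unstable and no ratio is reported (with near-identical effectiveness the
#' ratio is uninformative).
#'
#' @param summary,reference one-row data.frames from [arm_summary()] (or
#'   any objects with `cost` and `qaly` fields).
#' @param min_delta_qaly instability threshold on the QALY difference.
#' @return list with `delta_cost`, `delta_qaly`, `icer` (NA when not
#'   applicable), `verdict` (`"dominant"`, `"dominated"`, `"icer"`,
#'   `"unstable"`).
#' @export
icer <- function(summary, reference, min_delta_qaly = 1e-6) {
  dc <- summary$cost - reference$cost
  dq <- summary$qaly - reference$qaly
  if (abs(dq) < min_delta_qaly)
    return(list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
                verdict = "unstable"))
  if (dc <= 0 && dq > 0)
    return(list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
                verdict = "dominant"))
  if (dc >= 0 && dq < 0)
    return(list(delta_cost = dc, delta_qaly = dq, icer = NA_real_,
                verdict = "dominated"))
  list(delta_cost = dc, delta_qaly = dq, icer = dc / dq, verdict = "icer")
}

#' Complication cost and disutility breakdown
#'
#' Mean discounted per-patient cost and disutility by complication
#' category, with a `sum` column equal to the row total by construction.
#'
#' @param result a `simulation_result`.
#' @return data.frame with rows `cost` and `disutility`, the 12
#'   complication categories, and `sum`.
#' @export
complication_breakdown <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  cats <- complication_categories()
  extra <- setdiff(colnames(result$disutility_by_category), cats)
  if (length(extra))
    stopf("unknown complication category in ledger: %s",
          paste(extra, collapse = ", "))
  costs <- colMeans(result$cost_by_category[, cats, drop = FALSE])
  disu <- colMeans(result$disutility_by_category[, cats, drop = FALSE])
  out <- rbind(data.frame(arm = result$arm, measure = "cost",
                          as.list(costs), sum = sum(costs)),
               data.frame(arm = result$arm, measure = "disutility",
                          as.list(disu), sum = sum(disu)))
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration: one joint parameter draw, one normal draw of the NMA
#' effects, and a common-random-number simulation of every arm on a reduced
#' cohort; the per-arm mean cost and QALY are recorded.  Production scale
#' is 50,000 iterations; desk runs use reduced settings.  Failed iterations
#' are recorded and excluded with a warning, never silently dropped.
#'
#' @param bundle a [model_bundle()].
#' @param iterations number of PSA iterations (>= 1).
#' @param cohort_n per-iteration cohort size.
#' @param seed master PSA seed.
#' @param arms arm labels.
#' @return a `psa_result`: `cost` and `qaly` matrices (iterations x arms),
#'   `failed` (indices), seeds.
#' @export
run_psa <- function(bundle, iterations = 1000, cohort_n = 500, seed = 1L,
                    arms = regimen_labels()) {
  stopifnot(iterations >= 1)
  cohort <- sample_cohort(cohort_n, bundle$params,
                          seed = child_seed(seed, 0L, 23L))
  cost <- qaly <- matrix(NA_real_, iterations, length(arms),
                         dimnames = list(NULL, arms))
  failed <- integer(0)
  for (i in seq_len(iterations)) {
    ok <- tryCatch({
      draw <- sample_draw(bundle$params, seed, i)
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(child_seed(seed, i, 29L))
      z <- matrix(rnorm(length(bundle$effects$mean)),
                  nrow(bundle$effects$mean))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      eff <- bundle$effects$mean + bundle$effects$sd * z
      profiles <- treatment_profiles(eff)
      # event streams are held fixed across iterations (and arms), so PSA
      # spread reflects parameter uncertainty only
      sim_seed <- child_seed(seed, 0L, 31L)
      for (arm in arms) {
        res <- run_arm(cohort, profiles[[arm]], bundle$risk_model, draw,
                       bundle$life_table, seed = sim_seed,
                       horizon = bundle$horizon)
        cost[i, arm] <- mean(res$cost)
        qaly[i, arm] <- mean(res$qaly)
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- c(failed, i)
  }
  if (length(failed)) {
    warnf("PSA: %d of %d iterations failed and were excluded",
          length(failed), iterations)
    cost <- cost[-failed, , drop = FALSE]
    qaly <- qaly[-failed, , drop = FALSE]
  }
  structure(list(cost = cost, qaly = qaly, failed = failed,
                 iterations = iterations, cohort_n = cohort_n, seed = seed),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the fraction of PSA iterations in
#' which each arm attains the highest NMB; exact ties are split uniformly,
#' so the probabilities sum to 1 at every grid point.
#'
#' @param psa a `psa_result`.
#' @param wtp_grid WTP grid (USD/QALY); the default spans 0-40,000 in steps
#'   of 400.
#' @return data.frame `wtp, arm, probability` (class `ceac_curve`).
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 40000, by = 400)) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) stopf("empty WTP grid")
  if (!nrow(psa$cost)) stopf("empty PSA result")
  arms <- colnames(psa$cost)
  rows <- list()
  for (w in wtp_grid) {
    benefit <- w * psa$qaly - psa$cost
    wins <- numeric(length(arms))
    maxes <- apply(benefit, 1, max)
    for (i in seq_len(nrow(benefit))) {
      tied <- which(benefit[i, ] >= maxes[i] - 1e-12)
      wins[tied] <- wins[tied] + 1 / length(tied)
    }
    rows[[length(rows) + 1]] <- data.frame(wtp = w, arm = arms,
                                           probability = wins / nrow(benefit))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set to its low and high bound with everything else at
#' base case, and the INMB of `arm` versus `reference` is recomputed under
#' identical random streams.  Entries are sorted by descending range;
#' parameters without bounds (point masses) are skipped with a warning.
#'
#' @param bundle a [model_bundle()].
#' @param arm arm under study.
#' @param reference comparator (exenatide by convention).
#' @param parameters parameter names to vary (default: every non-degenerate
#'   parameter in the table).
#' @param top keep the largest `top` entries (default 10, tornado
#'   convention).
#' @param cohort optional pre-sampled cohort.
#' @return data.frame `parameter, inmb_low, inmb_high, range`, sorted.
#' @export
one_way_sa <- function(bundle, arm, reference = "exenatide",
                       parameters = NULL, top = 10, cohort = NULL) {
  params <- bundle$params
  if (is.null(parameters))
    parameters <- params$table$name[!vapply(params$specs,
                                            function(s) s$degenerate,
                                            logical(1))]
  cohort <- cohort %||% bundle_cohort(bundle)
  profiles <- treatment_profiles(bundle$effects$mean)
  sim_seed <- child_seed(bundle$seed, 1L, 17L)
  base <- base_case_draw(params)
  eval_inmb <- function(draw) {
    r1 <- run_arm(cohort, profiles[[arm]], bundle$risk_model, draw,
                  bundle$life_table, seed = sim_seed,
                  horizon = bundle$horizon)
    r0 <- run_arm(cohort, profiles[[reference]], bundle$risk_model, draw,
                  bundle$life_table, seed = sim_seed,
                  horizon = bundle$horizon)
    mean(nmb(r1$cost, r1$qaly, params$wtp) -
           nmb(r0$cost, r0$qaly, params$wtp))
  }
  rows <- list()
  for (p in parameters) {
    spec <- params$specs[[p]]
    if (is.null(spec)) { warnf("one_way_sa: unknown parameter '%s' skipped", p); next }
    if (spec$degenerate || spec$high - spec$low < 1e-12) {
      warnf("one_way_sa: parameter '%s' has no bounds; skipped", p)
      next
    }
    d_lo <- base; d_lo$values[[p]] <- spec$low
    d_hi <- base; d_hi$values[[p]] <- spec$high
    rows[[p]] <- data.frame(parameter = p, inmb_low = eval_inmb(d_lo),
                            inmb_high = eval_inmb(d_hi))
  }
  if (!length(rows))
    return(data.frame(parameter = character(), inmb_low = numeric(),
                      inmb_high = numeric(), range = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$range <- abs(out$inmb_high - out$inmb_low)
  out <- out[order(-out$range), ]
  head(out, top)
}

#' Scenario analysis over research time limits
#'
#' Re-runs every arm truncated at each horizon with identical seeds and
#' tabulates cost, QALY and NMB per arm per horizon.
#'
#' @param bundle a [model_bundle()].
#' @param horizons positive integer horizons (default 10/20/30/40 years).
#' @param arms arm labels.
#' @return data.frame `horizon, arm, cost, qaly, life_years, nmb`.
#' @export
scenario_horizons <- function(bundle, horizons = c(10, 20, 30, 40),
                              arms = regimen_labels()) {
  stopifnot(all(horizons >= 1))
  cohort <- bundle_cohort(bundle)
  rows <- list()
  for (h in horizons) {
    res <- run_base_case(bundle, arms = arms, cohort = cohort, horizon = h)
    for (arm in arms) {
      r <- res[[arm]]
      rows[[length(rows) + 1]] <- data.frame(
        horizon = h, arm = arm, cost = mean(r$cost), qaly = mean(r$qaly),
        life_years = mean(r$life_years),
        nmb = mean(nmb(r$cost, r$qaly, bundle$params$wtp)))
    }
  }
  do.call(rbind, rows)
}
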