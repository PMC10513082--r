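# Per-patient lifetime simulation under one treatment arm: 6-month
# treatment effects, adverse events, year-5 switch to insulin glargine,
# annual event sampling, cost and utility accrual, discounting.

complication_categories <- function() {
  c("mi", "stroke", "hf", "ihd", "pvd", "amputation", "neuropathy",
    "ulcer", "renal_failure", "cataract", "retinopathy", "hypoglycemia")
}

# Cost parameter names per chronic complication: event year / following year.
# Renal failure is costed per year (event and following alike); retinopathy
# per event only; hypoglycaemia per event.
complication_cost_map <- function() {
  list(
    mi            = c("Cost_MI_event_year", "Cost_MI_following_year"),
    stroke        = c("Cost_stroke_event_year", "Cost_stroke_following_year"),
    hf            = c("Cost_CHF_event_year", "Cost_CHF_following_year"),
    ihd           = c("Cost_IHD_event_year", "Cost_IHD_following_year"),
    pvd           = c("Cost_PVD_event_year", "Cost_PVD_following_year"),
    amputation    = c("Cost_amputation_event_year", "Cost_amputation_following_year"),
    neuropathy    = c("Cost_neuropathy_event_year", "Cost_neuropathy_following_year"),
    ulcer         = c("Cost_skin_ulcer_event_year", "Cost_skin_ulcer_following_year"),
    renal_failure = c("Cost_renal_failure_per_year", "Cost_renal_failure_per_year"),
    cataract      = c("Cost_cataract_event_year", "Cost_cataract_following_year"),
    retinopathy   = c("Cost_retinopathy_per_event", NA)
  )
}

# Disutility parameter names per complication: event year / chronic.
complication_disu_map <- function() {
  list(
    mi            = c("Disu_MI_event_year", "Disu_MI_following"),
    stroke        = c("Disu_stroke_event_year", "Disu_stroke_following"),
    hf            = c("Disu_CHF", "Disu_CHF"),
    ihd           = c("Disu_IHD", "Disu_IHD"),
    pvd           = c("Disu_PVD", "Disu_PVD"),
    amputation    = c("Disu_amputation_event", "Disu_amputation_post"),
    neuropathy    = c("Disu_neuropathy", "Disu_neuropathy"),
    ulcer         = c("Disu_skin_ulcer", "Disu_skin_ulcer"),
    renal_failure = c("Disu_renal_failure", "Disu_renal_failure"),
    cataract      = c("Disu_cataract", "Disu_cataract"),
    retinopathy   = c("Disu_retinopathy", "Disu_retinopathy")
  )
}

#' Treatment profiles for the six regimens
#'
#' Dosing and titration schedules, pack pricing, trial-period adverse-event
#' profiles (events with rates >5% plus hypoglycaemia) and 6-month
#' endpoint change rates for each regimen.  Doses are expressed in the unit
#' of the pack-content label; the weekly drug cost is
#' `pack price x weekly dose / pack content`.  The lixisenatide pack is the
#' marketed 14-dose (280 ug) pen.
#'
#' @param effects matrix (arm x endpoint) of 6-month change rates applied at
#'   treatment start; defaults to the synthetic generating truths
#'   ([default_true_effects()]).  Use [arm_effects()] to derive them from a
#'   fitted NMA.
#' @return named list of `treatment_profile` objects.
#' @export
treatment_profiles <- function(effects = default_true_effects()) {
  mk <- function(drug, pack_param, pack_content, titration, maintenance,
                 aes) {
    eff <- effects[drug, c("hba1c", "bmi", "sbp", "dbp")]
    structure(list(drug = drug, pack_param = pack_param,
                   pack_content = pack_content,
                   titration = titration,  # data.frame(weeks, dose_per_week)
                   maintenance = maintenance,  # dose per week
                   ae_params = aes, effects = eff),
              class = "treatment_profile")
  }
  list(
    exenatide = mk("exenatide", "Cost_exenatide_600ug", 600,
      data.frame(weeks = 4, dose_per_week = 70), 140,
      paste0("AE_exenatide_", c("nausea", "diarrhea", "urti", "vomiting",
                                "dizziness", "sinusitis", "hypoglycemia",
                                "back_pain"))),
    liraglutide = mk("liraglutide", "Cost_liraglutide_18mg", 18,
      data.frame(weeks = c(1, 1), dose_per_week = c(4.2, 8.4)), 12.6,
      paste0("AE_liraglutide_", c("nausea", "diarrhea", "vomiting",
                                  "dizziness", "sinusitis", "constipation",
                                  "decreased_appetite"))),
    loxenatide = mk("loxenatide", "Cost_loxenatide_100ug", 100,
      data.frame(weeks = numeric(), dose_per_week = numeric()), 100,
      paste0("AE_loxenatide_", c("nausea", "diarrhea", "vomiting",
                                 "hypoglycemia"))),
    dulaglutide = mk("dulaglutide", "Cost_dulaglutide_1.5mg", 1.5,
      data.frame(weeks = numeric(), dose_per_week = numeric()), 1.5,
      paste0("AE_dulaglutide_", c("nausea", "diarrhea", "vomiting",
                                  "dizziness", "sinusitis",
                                  "decreased_appetite"))),
    semaglutide = mk("semaglutide", "Cost_semaglutide_2mg", 2,
      data.frame(weeks = c(4, 4), dose_per_week = c(0.25, 0.5)), 1,
      paste0("AE_semaglutide_", c("nausea", "diarrhea", "urti", "vomiting",
                                  "dizziness", "sinusitis", "constipation",
                                  "hypoglycemia", "lipase_increased",
                                  "decreased_appetite"))),
    lixisenatide = mk("lixisenatide", "Cost_lixisenatide_20ug", 280,
      data.frame(weeks = c(1, 1), dose_per_week = c(70, 105)), 140,
      paste0("AE_lixisenatide_", c("nausea", "diarrhea", "vomiting",
                                   "hypoglycemia")))
  )
}

# Annual GLP-1RA drug cost for a given treatment year (1-based).
# Titration weeks are costed at the titration dose; the remainder of year 1
# and all later years at the maintenance dose.
glp1_drug_cost <- function(profile, draw, year) {
  price <- param(draw, profile$pack_param)
  if (year == 1) {
    tw <- sum(profile$titration$weeks)
    dose <- sum(profile$titration$weeks * profile$titration$dose_per_week) +
      (52 - tw) * profile$maintenance
  } else {
    dose <- 52 * profile$maintenance
  }
  price * dose / profile$pack_content
}

# Annual routine (non-complication) therapy cost for one cycle.
# Years on GLP-1RA: drug + metformin.  After the switch: insulin glargine
# plus the duration-dependent antidiabetic therapy cost.
routine_cost <- function(profile, draw, year, on_glp1, duration) {
  if (on_glp1) {
    met <- param(draw, "Cost_metformin_500mg") *
      param(draw, "Dose_metformin_mg_per_day") * 365 / 500
    rep(glp1_drug_cost(profile, draw, year) + met, length(duration))
  } else {
    ins <- param(draw, "Cost_insulin_glargine_300IU") *
      param(draw, "Dose_insulin_glargine_IU_per_day") * 365 / 300
    anti <- ifelse(duration >= 10, param(draw, "Cost_antidiabetic_over10y"),
                   ifelse(duration > 5, param(draw, "Cost_antidiabetic_5to10y"),
                          0))
    ins + anti
  }
}

#' Apply 6-month treatment effects to a baseline state
#'
#' Each endpoint is multiplied by `1 + change rate` for the arm (change
#' rates are fractions of baseline; reductions are negative).
#'
#' @param state cohort data.frame.
#' @param profile a `treatment_profile` carrying `effects` for `hba1c`,
#'   `bmi`, `sbp`, `dbp`.
#' @return the post-effect state.
#' @export
apply_treatment_effects <- function(state, profile) {
  eff <- profile$effects
  for (ep in c("hba1c", "bmi", "sbp", "dbp")) {
    v <- unname(eff[ep])
    if (length(v) != 1 || is.na(v))
      stopf("profile '%s': missing effect for endpoint '%s'",
            profile$drug, ep)
    state[[ep]] <- state[[ep]] * (1 + v)
  }
  state$treatment <- profile$drug
  state
}

#' Per-cycle cost accrual
#'
#' Turns one cycle record into a per-patient cost matrix by category:
#' the twelve complication categories plus `drug` (all routine therapy) and
#' `end_of_life`.  Complication costs are split event-year versus
#' following-year; renal failure is costed per year, retinopathy per event,
#' hypoglycaemia per event.  All values USD, undiscounted.
#'
#' @param rec cycle record: list with `alive` (logical), `died` (logical),
#'   `new_events` / `active` (patient x complication 0/1 matrices),
#'   `hypo_events` (integer), `routine_cost` (numeric), `died` end-of-life
#'   accrual applies once.
#' @param draw a `parameter_draw`.
#' @return matrix patients x (12 complications + drug + end_of_life).
#' @export
accrue_costs <- function(rec, draw) {
  cats <- complication_categories()
  n <- length(rec$alive)
  out <- matrix(0, n, length(cats) + 2,
                dimnames = list(NULL, c(cats, "drug", "end_of_life")))
  a <- rec$alive
  cmap <- complication_cost_map()
  for (cat in names(cmap)) {
    prm <- cmap[[cat]]
    newe <- rec$new_events[, cat] > 0 & a
    act <- rec$active[, cat] > 0 & a & !newe
    out[newe, cat] <- out[newe, cat] + param(draw, prm[1])
    if (!is.na(prm[2]))
      out[act, cat] <- out[act, cat] + param(draw, prm[2])
  }
  out[, "hypoglycemia"] <- rec$hypo_events * param(draw, "Cost_hypoglycemia_per_event") * a
  out[a, "drug"] <- rec$routine_cost[a]
  out[rec$died & a, "end_of_life"] <- param(draw, "Cost_end_of_life")
  if (any(out < 0)) stopf("negative cost accrued")
  out
}

#' Per-cycle utility accrual
#'
#' Cycle utility is `1 - baseline T2DM disutility - active comorbidity
#' disutilities - AE disutility (first treatment year) - BMI-deviation
#' term`, floored at 0 and capped at 1.  The BMI term credits
#' `Utility_BMI_per_unit_decrease` per kg/m2 below the pre-treatment
#' baseline and debits `Disu_BMI_per_unit_increase` per kg/m2 above it.
#'
#' @param rec cycle record (see [accrue_costs()]) with additionally
#'   `n_aes` (AE count, year 1), `bmi`, `base_bmi`.
#' @param draw a `parameter_draw`.
#' @return list: `utility` (per patient, 0 for the dead), `by_category`
#'   (patient x 12 matrix of comorbidity disutility decrements).
#' @export
accrue_utilities <- function(rec, draw) {
  cats <- complication_categories()
  n <- length(rec$alive)
  disu <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  a <- rec$alive
  dmap <- complication_disu_map()
  for (cat in names(dmap)) {
    prm <- dmap[[cat]]
    newe <- rec$new_events[, cat] > 0 & a
    act <- rec$active[, cat] > 0 & a & !newe
    disu[newe, cat] <- param(draw, prm[1])
    disu[act, cat] <- param(draw, prm[2])
  }
  disu[, "hypoglycemia"] <- rec$hypo_events * param(draw, "Disu_hypoglycemia") * a
  ae_disu <- rec$n_aes * param(draw, "Disu_AE_grade12")
  bmi_term <- param(draw, "Disu_BMI_per_unit_increase") *
    pmax(rec$bmi - rec$base_bmi, 0) -
    param(draw, "Utility_BMI_per_unit_decrease") *
    pmax(rec$base_bmi - rec$bmi, 0)
  utility <- 1 - param(draw, "Disu_T2DM_base") - rowSums(disu) - ae_disu -
    bmi_term
  utility <- pmin(pmax(utility, 0), 1)
  utility[!a] <- 0
  list(utility = utility, by_category = disu)
}

#' Discount a per-cycle value stream
#'
#' End-of-cycle convention: cycle `t` (1-based) contributes
#' `value / (1 + rate)^t`.
#'
#' @param values numeric vector of per-cycle values.
#' @param rate annual discount rate (>= 0).
#' @return discounted total.
#' @examples
#' discount_stream(c(100, 100), 0.05)  # 185.94
#' @export
discount_stream <- function(values, rate) {
  sum(values * discount_factors(length(values), rate))
}

# Core vectorised cohort engine.  All random draws are made in a fixed
# order and fixed count per cycle (death, 11 event outcomes, hypoglycaemia;
# plus 12 AE slots in year 1) for every patient whether alive or dead, so
# that two arms run with the same seed consume identical random number
# streams (common random numbers).
run_cohort_sim <- function(cohort, profile, model, draw, life_table,
                           seed = 1L, horizon = 100L, discount_rate = NULL,
                           switch_after = 5L, apply_effects = TRUE,
                           record = FALSE) {
  n <- nrow(cohort)
  stopifnot(n >= 1)
  rate <- discount_rate %||% param(draw, "Discount")
  if (rate < 0) stopf("negative discount rate")
  state <- cohort
  state$treatment <- profile$drug
  state$years_on_treatment <- 0
  base_bmi <- state$bmi
  if (apply_effects) state <- apply_treatment_effects(state, profile)
  post_effect_state <- state

  cats <- complication_categories()
  evs <- setdiff(risk_outcomes(), "mortality")  # 11 drawn outcomes
  chronic <- evs  # absorbing comorbidity flags
  active <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
  for (cat in chronic) active[, cat] <- as.integer(state[[cat]] > 0)

  cost_cat_disc <- matrix(0, n, length(cats) + 2,
                          dimnames = list(NULL, c(cats, "drug", "end_of_life")))
  disu_cat_disc <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  cost_disc <- cost_undisc <- qaly_disc <- qaly_undisc <- ly <- numeric(n)
  p_hypo <- param(draw, "Incidence_severe_hypoglycemia")
  ae_probs <- vapply(profile$ae_params, function(p) param(draw, p),
                     numeric(1))
  records <- if (record) vector("list", horizon) else NULL

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, 0L, stream = 3L))

  for (t in seq_len(horizon)) {
    if (!any(state$alive)) break
    u_death <- runif(n)
    u_ev <- matrix(runif(n * length(evs)), n, length(evs),
                   dimnames = list(NULL, evs))
    u_hypo <- runif(n)
    u_ae <- if (t == 1) matrix(runif(n * 12), n, 12) else NULL

    a <- state$alive
    X <- covariate_matrix(state)
    p_death <- numeric(n)
    q_nat <- life_table_qx(life_table, state$age, state$female)
    if (!is.null(model)) {
      eqm <- model$equations[["mortality"]]
      nm <- setdiff(names(eqm$coefficients), "(Intercept)")
      eta <- eqm$coefficients[["(Intercept)"]] +
        as.vector(X[, nm, drop = FALSE] %*% eqm$coefficients[nm])
      p_death <- pmax(plogis(eta), q_nat)
    } else p_death <- q_nat
    died <- a & (u_death < p_death)

    new_events <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
    if (!is.null(model)) {
      at_risk <- a & !died   # death first: the dying skip new events
      for (oc in evs) {
        eq <- model$equations[[oc]]
        nm <- setdiff(names(eq$coefficients), "(Intercept)")
        eta <- eq$coefficients[["(Intercept)"]] +
          as.vector(X[, nm, drop = FALSE] %*% eq$coefficients[nm])
        p <- plogis(eta)
        new_events[, oc] <- as.integer(at_risk & active[, oc] == 0L &
                                         u_ev[, oc] < p)
      }
    }
    hypo_events <- as.integer(a & u_hypo < p_hypo)

    n_aes <- numeric(n)
    if (t == 1 && length(ae_probs)) {
      for (j in seq_along(ae_probs))
        n_aes <- n_aes + as.integer(a & u_ae[, j] < ae_probs[j])
    }

    on_glp1 <- t <= switch_after
    rc <- routine_cost(profile, draw, t, on_glp1, state$duration)
    rec <- list(year = t, alive = a, died = died, new_events = new_events,
                active = active, hypo_events = hypo_events,
                routine_cost = rc, n_aes = n_aes, bmi = state$bmi,
                base_bmi = base_bmi)
    cmat <- accrue_costs(rec, draw)
    umat <- accrue_utilities(rec, draw)
    df <- (1 + rate)^-t
    cost_cat_disc <- cost_cat_disc + cmat * df
    disu_cat_disc <- disu_cat_disc + umat$by_category * df
    ctot <- rowSums(cmat)
    cost_disc <- cost_disc + ctot * df
    cost_undisc <- cost_undisc + ctot
    qaly_disc <- qaly_disc + umat$utility * df
    qaly_undisc <- qaly_undisc + umat$utility
    ly <- ly + as.numeric(a)

    if (record)
      records[[t]] <- list(year = t, state = state, died = which(died),
                           events = which(new_events > 0, arr.ind = TRUE),
                           cost = ctot, utility = umat$utility)

    active <- pmax(active, new_events)
    state$mi <- pmax(state$mi, active[, "mi"])
    state$stroke <- pmax(state$stroke, active[, "stroke"])
    for (oc in c("ihd", "hf", "pvd", "neuropathy", "amputation", "ulcer",
                 "renal_failure", "cataract", "retinopathy"))
      state[[oc]] <- pmax(state[[oc]], active[, oc])
    state$alive[died] <- FALSE
    if (!is.null(model)) state <- progress_risk_factors(state, model)
    else {
      i <- state$alive
      state$age[i] <- state$age[i] + 1
      state$duration[i] <- state$duration[i] + 1
    }
  }

  list(state = state, post_effect_state = post_effect_state,
       cost_disc = cost_disc, cost_undisc = cost_undisc,
       qaly_disc = qaly_disc, qaly_undisc = qaly_undisc,
       life_years = ly, cost_by_category = cost_cat_disc,
       disutility_by_category = disu_cat_disc,
       censored = state$alive, records = records,
       discount_rate = rate, horizon = horizon, seed = seed)
}

#' Simulate one patient and return the full trajectory
#'
#' Single-patient run of the cohort engine with per-cycle recording.
#'
#' @param state single-row cohort data.frame.
#' @param profile a `treatment_profile`.
#' @param model a `risk_model` (or `NULL` for life-table-only mortality).
#' @param draw a `parameter_draw`.
#' @param life_table a `life_table`.
#' @param seed,horizon,discount_rate,switch_after see [run_arm()].
#' @return a `trajectory`: list with per-cycle `records`, `death_year`
#'   (NA if censored at the horizon), `censored`, and discounted totals.
#' @export
simulate_patient <- function(state, profile, model, draw, life_table,
                             seed = 1L, horizon = 100L,
                             discount_rate = NULL, switch_after = 5L) {
  stopifnot(nrow(state) == 1, state$alive)
  sim <- run_cohort_sim(state, profile, model, draw, life_table,
                        seed = seed, horizon = horizon,
                        discount_rate = discount_rate,
                        switch_after = switch_after, record = TRUE)
  recs <- Filter(Negate(is.null), sim$records)
  death_year <- NA_integer_
  for (r in recs) if (length(r$died)) { death_year <- r$year; break }
  structure(list(records = recs, death_year = death_year,
                 censored = is.na(death_year),
                 cost = sim$cost_disc, qaly = sim$qaly_disc,
                 life_years = sim$life_years,
                 cost_by_category = sim$cost_by_category[1, ],
                 disutility_by_category = sim$disutility_by_category[1, ]),
            class = "trajectory")
}

#' Simulate a full arm
#'
#' Runs every patient of the cohort under one treatment profile with common
#' random numbers: the random streams are keyed by `(seed, cycle, purpose)`
#' and consumed in identical order for every arm, so arms run on the same
#' cohort and seed differ only through treatment parameters.
#'
#' @param cohort cohort data.frame from [sample_cohort()].
#' @param profile a `treatment_profile`.
#' @param model a `risk_model` (or `NULL`: life-table mortality only, no
#'   complication events).
#' @param draw a `parameter_draw`.
#' @param life_table a `life_table`.
#' @param seed integer seed for the event streams.
#' @param horizon number of annual cycles (default 100 covers a lifetime
#'   from any adult starting age; patients alive at the horizon are flagged
#'   censored).
#' @param discount_rate annual discount rate; defaults to the draw's
#'   `Discount` parameter.
#' @param switch_after years on the GLP-1RA before the switch to insulin
#'   glargine (default 5).
#' @param apply_effects apply the profile's 6-month effects at entry.
#' @return a `simulation_result`: arm label, per-patient discounted `cost`,
#'   `qaly`, `life_years`, per-complication discounted cost and disutility
#'   matrices, censoring flags and run metadata.
#' @export
run_arm <- function(cohort, profile, model, draw, life_table, seed = 1L,
                    horizon = 100L, discount_rate = NULL, switch_after = 5L,
                    apply_effects = TRUE) {
  sim <- run_cohort_sim(cohort, profile, model, draw, life_table,
                        seed = seed, horizon = horizon,
                        discount_rate = discount_rate,
                        switch_after = switch_after,
                        apply_effects = apply_effects, record = FALSE)
  structure(list(
    arm = profile$drug, n = nrow(cohort),
    cost = sim$cost_disc, qaly = sim$qaly_disc,
    cost_undiscounted = sim$cost_undisc,
    qaly_undiscounted = sim$qaly_undisc,
    life_years = sim$life_years,
    cost_by_category = sim$cost_by_category,
    disutility_by_category = sim$disutility_by_category,
    censored = sim$censored,
    post_effect_state = sim$post_effect_state,
    discount_rate = sim$discount_rate, horizon = horizon, seed = seed),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s: n = %d, horizon %d, discount %g\n",
              x$arm, x$n, x$horizon, x$discount_rate))
  cat(sprintf("  mean cost %.0f USD, mean QALY %.3f, mean life-years %.2f (%d censored)\n",
              mean(x$cost), mean(x$qaly), mean(x$life_years),
              sum(x$censored)))
  invisible(x)
}

#' Per-patient results table
#'
#' One row per patient: arm, discounted cost/QALY, life-years, achieved
#' (post-treatment-effect) HbA1c and BMI, baseline covariates, lifetime
#' complication cost and disutility.  This is the input format of
#' [burden_analysis()].
#'
#' @param result a `simulation_result`.
#' @return data.frame.
#' @export
patient_table <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  st <- result$post_effect_state
  data.frame(
    arm = result$arm,
    cost = result$cost, qaly = result$qaly,
    life_years = result$life_years,
    complication_cost = rowSums(result$cost_by_category[,
      complication_categories(), drop = FALSE]),
    complication_disutility = rowSums(result$disutility_by_category),
    hba1c = st$hba1c, bmi = st$bmi, age = st$age, female = st$female,
    duration = st$duration, sbp = st$sbp, dbp = st$dbp,
    smoker_current = st$smoker_current, ckd_stage = st$ckd_stage,
    history_mi = st$mi, history_stroke = st$stroke)
}
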