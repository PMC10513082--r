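# Baseline cohort sampling and one-cycle risk evaluation.
#
# A cohort is a plain data.frame with one row per patient; the columns
# below are the full patient state.  Vectorised operations over this frame
# are what make a 30,000-patient lifetime simulation tractable in R.

cohort_columns <- function() {
  c("age", "female", "duration", "smoker_current", "smoker_past",
    "hba1c", "bmi", "sbp", "dbp", "hdl", "ldl", "triglycerides",
    "hemoglobin", "wbc", "egfr",
    "insulin_use", "noninsulin_agents", "antihypertensives", "statins",
    "atrial_fibrillation", "mi", "ihd", "hf", "stroke", "pvd", "neuropathy",
    "amputation", "ulcer", "renal_failure", "retinopathy", "cataract",
    "ckd_stage", "alive", "treatment", "years_on_treatment")
}

cohort_frame <- function(n) {
  out <- as.data.frame(matrix(0, nrow = n, ncol = length(cohort_columns())))
  names(out) <- cohort_columns()
  out$alive <- rep(TRUE, n)
  out$treatment <- rep(NA_character_, n)
  out
}

#' Sample a baseline cohort from the parameter table
#'
#' Continuous baselines are drawn from their fitted uncertainty
#' distributions and binary flags as Bernoulli draws from the baseline
#' proportions; covariates are sampled independently (the table supplies
#' marginals only).  CKD stage is drawn as a single categorical from the
#' four stage proportions.  Reproducible from `seed`.
#'
#' @param n cohort size (>= 1).
#' @param params a `parameter_set` containing the baseline rows.
#' @param seed integer seed.
#' @return a cohort data.frame (class `glp1_cohort`), one row per patient.
#' @examples
#' cohort <- sample_cohort(100, default_parameters(), seed = 1)
#' @export
sample_cohort <- function(n, params = default_parameters(), seed = 1L) {
  stopifnot(n >= 1, inherits(params, "parameter_set"))
  need <- c("Age_baseline", "Prop_female", "Duration_diabetes",
            "Prop_current_smoker", "Prop_past_smoker", "HbA1c_baseline",
            "BMI_baseline", "SBP_baseline", "DBP_baseline", "HDL_baseline",
            "LDL_baseline", "Triglycerides_baseline", "Hemoglobin_baseline",
            "WBC_baseline", "eGFR_baseline", "Prop_insulin_use",
            "Prop_noninsulin_agents", "Prop_antihypertensives",
            "Prop_statins", "Prop_atrial_fibrillation", "Prop_MI",
            "Prop_IHD", "Prop_HF", "Prop_cerebrovascular", "Prop_PVD",
            "Prop_neuropathy", "Prop_amputation", "Prop_mild_CKD",
            "Prop_mild_moderate_CKD", "Prop_moderate_severe_CKD",
            "Prop_severe_CKD", "Prop_renal_failure", "Prop_retinopathy",
            "Prop_cataract", "Prop_ulcer")
  missing <- setdiff(need, names(params$specs))
  if (length(missing))
    stopf("sample_cohort: baseline parameter(s) missing: %s",
          paste(missing, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, 0L, stream = 7L))

  draw_cont <- function(name) sample_spec(params$specs[[name]], n)
  draw_flag <- function(name) {
    p <- params$specs[[name]]$mean
    rbinom(n, 1, p)
  }
  cohort <- cohort_frame(n)
  cohort$age <- pmin(pmax(draw_cont("Age_baseline"), 18), 110)
  cohort$female <- draw_flag("Prop_female")
  cohort$duration <- pmax(draw_cont("Duration_diabetes"), 0)
  cohort$smoker_current <- draw_flag("Prop_current_smoker")
  # past smoker only among non-current
  past <- draw_flag("Prop_past_smoker")
  cohort$smoker_past <- ifelse(cohort$smoker_current == 1, 0, past)
  cohort$hba1c <- pmin(pmax(draw_cont("HbA1c_baseline"), 4), 20)
  cohort$bmi <- pmin(pmax(draw_cont("BMI_baseline"), 10), 80)
  cohort$sbp <- draw_cont("SBP_baseline")
  cohort$dbp <- draw_cont("DBP_baseline")
  cohort$hdl <- draw_cont("HDL_baseline")
  cohort$ldl <- draw_cont("LDL_baseline")
  cohort$triglycerides <- draw_cont("Triglycerides_baseline")
  cohort$hemoglobin <- draw_cont("Hemoglobin_baseline")
  cohort$wbc <- draw_cont("WBC_baseline")
  cohort$egfr <- draw_cont("eGFR_baseline")
  cohort$insulin_use <- draw_flag("Prop_insulin_use")
  cohort$noninsulin_agents <- draw_flag("Prop_noninsulin_agents")
  cohort$antihypertensives <- draw_flag("Prop_antihypertensives")
  cohort$statins <- draw_flag("Prop_statins")
  cohort$atrial_fibrillation <- draw_flag("Prop_atrial_fibrillation")
  cohort$mi <- draw_flag("Prop_MI")
  cohort$ihd <- draw_flag("Prop_IHD")
  cohort$hf <- draw_flag("Prop_HF")
  cohort$stroke <- draw_flag("Prop_cerebrovascular")
  cohort$pvd <- draw_flag("Prop_PVD")
  cohort$neuropathy <- draw_flag("Prop_neuropathy")
  cohort$amputation <- draw_flag("Prop_amputation")
  cohort$ulcer <- draw_flag("Prop_ulcer")
  cohort$renal_failure <- draw_flag("Prop_renal_failure")
  cohort$retinopathy <- draw_flag("Prop_retinopathy")
  cohort$cataract <- draw_flag("Prop_cataract")
  # CKD stage: categorical draw over none / mild / mild-moderate /
  # moderate-severe / severe
  p_ckd <- c(params$specs[["Prop_mild_CKD"]]$mean,
             params$specs[["Prop_mild_moderate_CKD"]]$mean,
             params$specs[["Prop_moderate_severe_CKD"]]$mean,
             params$specs[["Prop_severe_CKD"]]$mean)
  p_all <- c(max(0, 1 - sum(p_ckd)), p_ckd)
  cohort$ckd_stage <- sample(0:4, n, replace = TRUE, prob = p_all)
  class(cohort) <- c("glp1_cohort", "data.frame")
  cohort
}

# Covariate matrix (patients x covariates) used by the risk equations.
covariate_matrix <- function(cohort) {
  cbind(age = cohort$age, female = cohort$female,
        duration = cohort$duration, hba1c = cohort$hba1c, bmi = cohort$bmi,
        sbp = cohort$sbp, smoker_current = cohort$smoker_current,
        ckd_stage = cohort$ckd_stage, prior_mi = cohort$mi,
        prior_stroke = cohort$stroke)
}

covariate_vector <- function(state) covariate_matrix(state)[1, ]

#' Annual event probability from a logistic risk equation
#'
#' `p = plogis(intercept + sum(beta * x))` over the equation's covariate
#' subset; always strictly inside (0, 1).
#'
#' @param equation one element of a `risk_model`'s `equations` list.
#' @param state cohort data.frame (any number of rows); all rows must be
#'   alive.
#' @return numeric vector of annual probabilities, one per row.
#' @export
annual_event_probability <- function(equation, state) {
  if (!all(state$alive))
    stopf("annual_event_probability: dead patients are never advanced")
  beta <- equation$coefficients
  nm <- setdiff(names(beta), "(Intercept)")
  X <- covariate_matrix(state)
  absent <- setdiff(nm, colnames(X))
  if (length(absent))
    stopf("outcome '%s': covariate(s) %s missing from patient state",
          equation$outcome, paste(absent, collapse = ", "))
  eta <- beta[["(Intercept)"]] + as.vector(X[, nm, drop = FALSE] %*% beta[nm])
  plogis(eta)
}

#' Blended annual death probability
#'
#' Diabetic all-cause mortality from the model's mortality equation, floored
#' by the natural (life-table) mortality for the patient's age and sex:
#' `max(model, table)`.  Ages beyond the table use the terminal row.
#'
#' @param state cohort data.frame (alive rows).
#' @param model a `risk_model` (or `NULL` to use the life table alone).
#' @param life_table a `life_table`.
#' @return numeric vector of annual death probabilities.
#' @export
death_probability <- function(state, model, life_table) {
  q_nat <- life_table_qx(life_table, state$age, state$female)
  if (is.null(model)) return(q_nat)
  q_mod <- annual_event_probability(model$equations[["mortality"]], state)
  pmax(q_mod, q_nat)
}

#' Advance risk factors by one annual cycle
#'
#' Deterministic drift applied to HbA1c, BMI, SBP and DBP per the model's
#' progression rules; age and diabetes duration increment by one year.
#' Dead patients are returned unchanged.
#'
#' @param state cohort data.frame.
#' @param model a `risk_model` carrying `progression` (named drift vector).
#' @return the updated state.
#' @export
progress_risk_factors <- function(state, model) {
  drift <- model$progression
  i <- state$alive
  state$hba1c[i] <- pmin(pmax(state$hba1c[i] + (drift[["hba1c"]] %||% 0), 4), 20)
  state$bmi[i] <- pmin(pmax(state$bmi[i] + (drift[["bmi"]] %||% 0), 10), 80)
  state$sbp[i] <- state$sbp[i] + (drift[["sbp"]] %||% 0)
  state$dbp[i] <- state$dbp[i] + (drift[["dbp"]] %||% 0)
  state$age[i] <- state$age[i] + 1
  state$duration[i] <- state$duration[i] + 1
  state$years_on_treatment[i] <- state$years_on_treatment[i] + 1
  state
}

#' @rdname sample_cohort
#' @param cohort a cohort to write.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
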