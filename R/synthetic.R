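# Generators for every model input the published evidence base does not
# supply in machine-readable form: trial-arm aggregates with known truths,
# calibrated stand-in risk equations, a parametric life table, and
# patient-level GLM test data.

#' The six regimens and their trial network
#'
#' @return character vector of the six GLP-1RA arm labels.
#' @export
regimen_labels <- function() {
  c("exenatide", "liraglutide", "loxenatide", "dulaglutide", "semaglutide",
    "lixisenatide")
}

# The nine-trial roster: designs (treatment sets) mirroring the phase-III
# evidence network.  The glimepiride arm of LEAD-2 is outside the network of
# interest and omitted; lixisenatide blood-pressure data are encoded from
# the substituted sister trial under the same study label.
default_study_designs <- function() {
  list(
    "SUSTAIN-7"  = c("semaglutide", "dulaglutide"),
    "AWARD-6"    = c("dulaglutide", "liraglutide"),
    "Exendin-4"  = c("placebo", "exenatide"),
    "LEAD-2"     = c("liraglutide", "placebo"),
    "AWARD-5"    = c("dulaglutide", "placebo"),
    "GetGoal-X"  = c("lixisenatide", "exenatide"),
    "GetGoal-M"  = c("lixisenatide", "placebo"),
    "GetGoal-F1" = c("lixisenatide", "placebo"),
    "Gao-2020"   = c("loxenatide", "placebo")
  )
}

#' Default 6-month change-rate truths for the synthetic trial generator
#'
#' Fractional changes from baseline (negative = reduction) per treatment
#' and endpoint.  Magnitudes are realistic for the drug class; these are
#' known truths for recovery testing, not published trial values.
#' @return matrix (treatment x endpoint).
#' @export
# Default 6-month change-rate truths (fraction change from baseline) used by
# the synthetic trial generator.  Magnitudes are realistic for the drug
# class (HbA1c reductions of 10-17%, modest BMI and BP reductions);
# loxenatide is given the strongest HbA1c effect, semaglutide the strongest
# BMI effect, consistent with the qualitative ordering reported for these
# regimens.  These are *known truths* for recovery testing, not published
# values (the trial supplement is not public).
default_true_effects <- function() {
  rbind(
    placebo      = c(hba1c = -0.02, bmi = -0.002, sbp = -0.005, dbp = -0.004),
    exenatide    = c(hba1c = -0.12, bmi = -0.020, sbp = -0.020, dbp = -0.012),
    liraglutide  = c(hba1c = -0.14, bmi = -0.022, sbp = -0.022, dbp = -0.013),
    loxenatide   = c(hba1c = -0.16, bmi = -0.018, sbp = -0.018, dbp = -0.011),
    dulaglutide  = c(hba1c = -0.13, bmi = -0.016, sbp = -0.019, dbp = -0.012),
    semaglutide  = c(hba1c = -0.15, bmi = -0.030, sbp = -0.025, dbp = -0.014),
    lixisenatide = c(hba1c = -0.11, bmi = -0.015, sbp = -0.017, dbp = -0.010)
  )
}

#' Configuration for the synthetic trial-network generator
#'
#' @param treatments character vector of treatment labels (including the
#'   placebo/anchor arm).
#' @param true_effects matrix (treatment x endpoint) of true mean change
#'   rates; rownames must cover `treatments`.
#' @param heterogeneity_sd named numeric, between-study SD per endpoint.
#' @param studies named list of character vectors: each study's design
#'   (treatment set).
#' @param n_per_arm number of patients per arm (recycled over studies).
#' @param noise_sd named numeric, within-arm observation SD per endpoint
#'   (arm-level SE is `noise_sd / sqrt(n)`).
#' @param seed integer seed.
#' @return a `synthetic_nma_config` list.
#' @export
nma_config <- function(treatments = rownames(default_true_effects()),
                       true_effects = default_true_effects(),
                       heterogeneity_sd = c(hba1c = 0.01, bmi = 0.003,
                                            sbp = 0.004, dbp = 0.003),
                       studies = default_study_designs(),
                       n_per_arm = 200,
                       noise_sd = c(hba1c = 0.10, bmi = 0.04,
                                    sbp = 0.05, dbp = 0.04),
                       seed = 1L) {
  if (!all(unlist(studies) %in% treatments))
    stopf("study designs reference treatments absent from 'treatments'")
  if (!all(treatments %in% rownames(true_effects)))
    stopf("true_effects must have a row for every treatment")
  structure(list(treatments = treatments, true_effects = true_effects,
                 heterogeneity_sd = heterogeneity_sd, studies = studies,
                 n_per_arm = rep_len(n_per_arm, length(studies)),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_nma_config")
}

# Connectivity of a list of designs over a set of treatments.
network_connected <- function(designs, treatments) {
  if (!length(treatments)) return(TRUE)
  reached <- treatments[1]
  repeat {
    grow <- unique(unlist(designs[vapply(designs, function(d)
      any(d %in% reached), logical(1))]))
    if (all(grow %in% reached)) break
    reached <- union(reached, grow)
  }
  all(treatments %in% reached)
}

#' Generate a synthetic trial-network dataset with known truths
#'
#' Arm-level observed change rates are drawn as
#' `truth + study random effect + sampling noise` with sampling SD
#' `noise_sd / sqrt(n)`.  The generating truths are attached so that
#' network-meta-analysis recovery can be tested.
#'
#' @param config a [nma_config()] object.
#' @param endpoints endpoints to generate (columns of `true_effects`).
#' @return an `nma_dataset`: data.frame with columns
#'   `study, design, treatment, endpoint, mean_change_rate, sd, n`, plus
#'   attributes `truths` and `config`.
#' @export
gen_nma_dataset <- function(config = nma_config(),
                            endpoints = colnames(config$true_effects)) {
  stopifnot(inherits(config, "synthetic_nma_config"))
  used <- unique(unlist(config$studies))
  if (!network_connected(config$studies, used))
    stopf("study network is disconnected; refusing to generate")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  rows <- list()
  for (si in seq_along(config$studies)) {
    study <- names(config$studies)[si]
    design <- config$studies[[si]]
    n <- config$n_per_arm[si]
    if (n < 2) stopf("study '%s': need n >= 2 per arm", study)
    for (ep in endpoints) {
      # one random study effect per endpoint, shared by all arms
      # (study-level shift), plus independent arm-level heterogeneity
      mu_i <- rnorm(1, 0, config$heterogeneity_sd[[ep]])
      for (tr in design) {
        truth <- config$true_effects[tr, ep]
        obs <- truth + mu_i + rnorm(1, 0, config$noise_sd[[ep]] / sqrt(n))
        rows[[length(rows) + 1]] <- data.frame(
          study = study, design = paste(sort(design), collapse = ":"),
          treatment = tr, endpoint = ep,
          mean_change_rate = obs, sd = config$noise_sd[[ep]], n = n)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truths") <- config$true_effects
  attr(out, "config") <- config
  class(out) <- c("nma_dataset", "data.frame")
  out
}

#' Read / write trial-network datasets
#'
#' Flat CSV with columns `study,design,treatment,endpoint,mean_change_rate,sd,n`.
#' @param x an `nma_dataset` (for write).
#' @param path file path.
#' @export
write_nma_dataset <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nma_dataset
#' @export
read_nma_dataset <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "design", "treatment", "endpoint", "mean_change_rate",
            "sd", "n")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stopf("NMA dataset %s: missing column(s) %s", path,
          paste(missing, collapse = ", "))
  class(out) <- c("nma_dataset", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Risk-equation stand-ins

#' The thirteen risk-model outcomes
#'
#' Twelve annual event equations (all-cause mortality, four macrovascular
#' and seven microvascular outcomes); risk-factor progression is the
#' thirteenth component of the model.
#' @return character vector of outcome names.
#' @export
risk_outcomes <- function() {
  c("mortality", "mi", "ihd", "hf", "stroke", "pvd", "neuropathy",
    "amputation", "ulcer", "renal_failure", "cataract", "retinopathy")
}

# Covariates entering the synthetic risk equations, with the documented
# default gradient for each outcome.  The schema accepts any subset per
# outcome; real coefficient files in the same JSON format are drop-in
# replacements.
default_gradients <- function() {
  base <- c(age = 0.05, female = -0.20, duration = 0.02, hba1c = 0.15,
            bmi = 0.02, sbp = 0.01, smoker_current = 0.30, ckd_stage = 0.10)
  g <- list()
  for (oc in risk_outcomes()) g[[oc]] <- base
  g$mortality["age"] <- 0.09
  g$renal_failure["ckd_stage"] <- 0.60
  g$retinopathy["hba1c"] <- 0.25
  g$neuropathy["hba1c"] <- 0.20
  g$mi <- c(base, prior_mi = 0.70)
  g$stroke <- c(base, prior_stroke = 0.70)
  g
}

#' Reference patient used for risk-equation calibration
#'
#' A patient at the baseline table means with no comorbidities: the state at
#' which calibrated equations return exactly their target annual
#' probability.
#'
#' @param params a `parameter_set` (defaults to the packaged table).
#' @return single-row cohort data.frame (see [sample_cohort()]).
#' @export
reference_state <- function(params = default_parameters()) {
  m <- setNames(params$table$mean, params$table$name)
  cohort_frame(1)[1, , drop = FALSE] |>
    within({
      age <- m[["Age_baseline"]]; female <- 0
      duration <- m[["Duration_diabetes"]]
      hba1c <- m[["HbA1c_baseline"]]; bmi <- m[["BMI_baseline"]]
      sbp <- m[["SBP_baseline"]]; dbp <- m[["DBP_baseline"]]
      hdl <- m[["HDL_baseline"]]; ldl <- m[["LDL_baseline"]]
      triglycerides <- m[["Triglycerides_baseline"]]
      hemoglobin <- m[["Hemoglobin_baseline"]]; wbc <- m[["WBC_baseline"]]
      egfr <- m[["eGFR_baseline"]]
    })
}

#' Default annual calibration targets for the synthetic risk equations
#'
#' Event targets are the baseline comorbidity prevalences of the parameter
#' table converted to annual incidences by dividing by the mean diabetes
#' duration (6 years), floored at 0.002 for outcomes with zero baseline
#' prevalence; mortality is set to 0.008/yr at the reference state (blended
#' upward by the life table at older ages).
#'
#' @param params a `parameter_set`.
#' @return named numeric vector of annual probabilities.
#' @export
default_risk_targets <- function(params = default_parameters()) {
  m <- setNames(params$table$mean, params$table$name)
  dur <- m[["Duration_diabetes"]]
  prev <- c(mi = m[["Prop_MI"]], ihd = m[["Prop_IHD"]], hf = m[["Prop_HF"]],
            stroke = m[["Prop_cerebrovascular"]], pvd = m[["Prop_PVD"]],
            neuropathy = m[["Prop_neuropathy"]],
            amputation = m[["Prop_amputation"]], ulcer = m[["Prop_ulcer"]],
            renal_failure = m[["Prop_renal_failure"]],
            cataract = m[["Prop_cataract"]],
            retinopathy = m[["Prop_retinopathy"]])
  targets <- pmax(prev / dur, 0.002)
  c(mortality = 0.008, targets)
}

#' Generate calibrated synthetic risk equations
#'
#' Builds the 13-equation annual risk model: 12 logistic-link event
#' equations (all-cause mortality, four macrovascular and seven
#' microvascular outcomes) plus deterministic risk-factor progression rules.
#' Intercepts are solved in closed form so that the annual probability at
#' `reference` equals each calibration target exactly; gradient signs are
#' honored by construction.
#'
#' @param targets named numeric vector of annual event probabilities in
#'   (0, 1), one per outcome of [risk_outcomes()].
#' @param reference single-row cohort data.frame (see [reference_state()]).
#' @param gradients named list of coefficient vectors per outcome.
#' @param progression named numeric: deterministic annual drift added to
#'   `hba1c` (%), `bmi` (kg/m2), `sbp` and `dbp` (mmHg) each cycle.
#' @return a `risk_model`: list of `equations` (each with `outcome`, `link`,
#'   `coefficients` incl. `(Intercept)`), `progression`, and `reference`.
#' @export
gen_risk_coefficients <- function(targets = default_risk_targets(),
                                  reference = reference_state(),
                                  gradients = default_gradients(),
                                  progression = c(hba1c = 0.1, bmi = 0.1,
                                                  sbp = 0.5, dbp = 0.2)) {
  missing <- setdiff(risk_outcomes(), names(targets))
  if (length(missing))
    stopf("calibration targets missing for outcome(s): %s",
          paste(missing, collapse = ", "))
  equations <- list()
  for (oc in risk_outcomes()) {
    p <- targets[[oc]]
    if (!is.finite(p) || p <= 0 || p >= 1)
      stopf("calibration target for '%s' must be in (0, 1), got %g", oc, p)
    beta <- gradients[[oc]]
    x <- covariate_vector(reference)[names(beta)]
    if (anyNA(x))
      stopf("reference state lacks covariate(s) %s for outcome '%s'",
            paste(names(beta)[is.na(x)], collapse = ", "), oc)
    intercept <- qlogis(p) - sum(beta * x)
    equations[[oc]] <- list(outcome = oc, link = "logistic",
                            coefficients = c("(Intercept)" = intercept, beta))
  }
  structure(list(equations = equations, progression = progression,
                 targets = targets),
            class = "risk_model")
}

#' Read / write risk-model coefficient files
#'
#' JSON schema: `{"equations": {outcome: {link, coefficients}}, "progression": {...}}`.
#' @param model a `risk_model`.
#' @param path file path.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  payload <- list(
    equations = lapply(model$equations, function(eq)
      list(outcome = eq$outcome, link = eq$link,
           coefficients = as.list(eq$coefficients))),
    progression = as.list(model$progression))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  equations <- lapply(payload$equations, function(eq)
    list(outcome = eq$outcome, link = eq$link,
         coefficients = unlist(eq$coefficients)))
  structure(list(equations = equations,
                 progression = unlist(payload$progression)),
            class = "risk_model")
}

# ---------------------------------------------------------------------------
# Life table

#' Generate a Gompertz-Makeham life table
#'
#' Deterministic sex-by-age table of annual death probabilities
#' `q(x) = 1 - exp(-(a + b * exp(c * x)))` over ages 18-100, standing in for
#' a national census table (any table in the same `sex,age,qx` CSV format
#' may be substituted).  Probabilities reaching 1 before age 100 are clipped
#' at 0.999 with a warning.
#'
#' @param a Makeham background hazard (per year).
#' @param b Gompertz level at age 0.
#' @param c Gompertz log-slope per year of age.
#' @param female_factor multiplier on `b` for women (< 1: lower mortality).
#' @param ages integer vector of ages covered.
#' @return a `life_table` data.frame with columns `sex, age, qx`.
#' @export
gen_life_table <- function(a = 4e-4, b = 3e-5, c = 0.095,
                           female_factor = 0.6, ages = 18:100) {
  clipped <- FALSE
  qx_for <- function(bb) {
    haz <- a + bb * exp(c * ages)
    q <- 1 - exp(-haz)
    if (any(q >= 1)) {
      clipped <<- TRUE
      q <- pmin(q, 0.999)
    }
    q
  }
  out <- rbind(
    data.frame(sex = "male", age = ages, qx = qx_for(b)),
    data.frame(sex = "female", age = ages, qx = qx_for(b * female_factor)))
  if (clipped)
    warnf("life table: death probability reached 1 before age %d; clipped at 0.999",
          max(ages))
  class(out) <- c("life_table", "data.frame")
  out
}

#' A constant-hazard life table (testing/validation aid)
#'
#' @param q constant annual death probability applied to every age and sex.
#' @param ages ages covered.
#' @return a `life_table`.
#' @export
constant_life_table <- function(q, ages = 18:100) {
  out <- rbind(data.frame(sex = "male", age = ages, qx = q),
               data.frame(sex = "female", age = ages, qx = q))
  class(out) <- c("life_table", "data.frame")
  out
}

#' @rdname gen_life_table
#' @param table a `life_table` to write.
#' @param path file path (CSV, columns `sex,age,qx`).
#' @export
write_life_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname gen_life_table
#' @export
read_life_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "age", "qx") %in% names(out)))
  class(out) <- c("life_table", "data.frame")
  out
}

# Annual death probability lookup; ages beyond the table use the terminal
# row (warned once per lookup call).
life_table_qx <- function(table, age, female) {
  sex <- ifelse(female > 0, "female", "male")
  out <- numeric(length(age))
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    sub <- table[table$sex == s, ]
    sub <- sub[order(sub$age), ]
    a <- pmin(pmax(round(age[idx]), min(sub$age)), max(sub$age))
    out[idx] <- sub$qx[match(a, sub$age)]
  }
  out
}

# ---------------------------------------------------------------------------
# GLM test data

#' Generate a patient-level dataset with known exposure effects
#'
#' Emulates the burden-GLM input: covariates, binary indicators for
#' inadequate HbA1c control (>7%) and high BMI (>25 kg/m2), and an outcome
#' generated from a stated family with known coefficients, for parameter-
#' recovery testing of [irls_fit()] and [burden_analysis()].
#'
#' @param n number of patients (>= 50).
#' @param effect_hba1c true additive (gaussian) or log-scale (gamma) effect
#'   of the poor-HbA1c indicator on the outcome.
#' @param effect_bmi same for the high-BMI indicator.
#' @param intercept outcome intercept on the link scale.
#' @param noise_family `"gaussian"` (identity link, additive noise `sd`) or
#'   `"gamma"` (log link, multiplicative gamma noise with `shape`).
#' @param sd gaussian noise SD.
#' @param shape gamma noise shape.
#' @param seed integer seed.
#' @return data.frame with columns `hba1c, bmi, poor_hba1c, high_bmi, age,
#'   female, sbp, outcome`; attribute `truth` holds the generating
#'   coefficients.
#' @export
gen_glm_dataset <- function(n, effect_hba1c, effect_bmi, intercept = 9000,
                            noise_family = c("gaussian", "gamma"),
                            sd = 1000, shape = 20, seed = 1L) {
  if (n < 50) stopf("gen_glm_dataset: need n >= 50, got %d", n)
  noise_family <- match.arg(noise_family)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hba1c <- rnorm(n, 7.2, 0.8)
  bmi <- rnorm(n, 25.5, 2.5)
  age <- rnorm(n, 55, 8)
  female <- rbinom(n, 1, 0.44)
  sbp <- rnorm(n, 125, 12)
  poor_hba1c <- as.integer(hba1c > 7)
  high_bmi <- as.integer(bmi > 25)
  eta <- intercept + effect_hba1c * poor_hba1c + effect_bmi * high_bmi +
    5 * (age - 55) - 50 * female + 2 * (sbp - 125)
  if (noise_family == "gaussian") {
    outcome <- eta + rnorm(n, 0, sd)
  } else {
    mu <- exp(intercept + effect_hba1c * poor_hba1c + effect_bmi * high_bmi +
                0.002 * (age - 55) - 0.01 * female + 0.001 * (sbp - 125))
    outcome <- rgamma(n, shape = shape, rate = shape / mu)
  }
  out <- data.frame(hba1c, bmi, poor_hba1c, high_bmi, age, female, sbp,
                    outcome)
  attr(out, "truth") <- c(intercept = intercept, poor_hba1c = effect_hba1c,
                          high_bmi = effect_bmi)
  out
}
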