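# Shared fixtures, built in code at test time.

fixture_params <- function() default_parameters()

# Base-case draw with the recurring severe-hypoglycaemia incidence zeroed:
# the "zero-event world" used by the closed-form checks.
zero_event_draw <- function(params = fixture_params()) {
  draw <- base_case_draw(params)
  draw$values[["Incidence_severe_hypoglycemia"]] <- 0
  draw
}

# A treatment profile with no adverse events and zero 6-month effects,
# leaving drug cost as the only treatment-specific quantity.
null_profile <- function(drug = "dulaglutide") {
  prof <- treatment_profiles()[[drug]]
  prof$ae_params <- character(0)
  prof$effects[] <- 0
  prof
}

# Small cohort of identical "reference" patients (all-fixed baselines, no
# comorbidities) for closed-form checks.
uniform_cohort <- function(n, age = 55) {
  ref <- reference_state()
  cohort <- ref[rep(1, n), , drop = FALSE]
  cohort$age <- age
  rownames(cohort) <- NULL
  class(cohort) <- c("glp1_cohort", "data.frame")
  cohort
}

# Two-treatment network: n_studies A-vs-B trials with configurable truth.
pairwise_config <- function(n_studies = 20, delta = -0.10, n = 200,
                            noise = 0.1, het = 0, seed = 1) {
  eff <- rbind(A = c(hba1c = 0), B = c(hba1c = delta))
  studies <- setNames(rep(list(c("A", "B")), n_studies),
                      paste0("S", seq_len(n_studies)))
  nma_config(treatments = c("A", "B"), true_effects = eff,
             heterogeneity_sd = c(hba1c = het), studies = studies,
             n_per_arm = n, noise_sd = c(hba1c = noise), seed = seed)
}

# Triangle network A-B, B-C, A-C with optional inconsistency shift added
# to the A-C arm of the A:C design.
triangle_dataset <- function(delta_ab = -0.05, delta_ac = -0.12,
                             shift_ac = 0, n = 500, noise = 0.1,
                             studies_per_design = 3, seed = 1) {
  eff <- rbind(A = c(hba1c = 0), B = c(hba1c = delta_ab),
               C = c(hba1c = delta_ac))
  studies <- list()
  for (i in seq_len(studies_per_design)) {
    studies[[paste0("AB", i)]] <- c("A", "B")
    studies[[paste0("BC", i)]] <- c("B", "C")
    studies[[paste0("AC", i)]] <- c("A", "C")
  }
  cfg <- nma_config(treatments = c("A", "B", "C"), true_effects = eff,
                    heterogeneity_sd = c(hba1c = 0), studies = studies,
                    n_per_arm = n, noise_sd = c(hba1c = noise), seed = seed)
  ds <- gen_nma_dataset(cfg, endpoints = "hba1c")
  if (shift_ac != 0) {
    idx <- grepl("^AC", ds$study) & ds$treatment == "C"
    ds$mean_change_rate[idx] <- ds$mean_change_rate[idx] + shift_ac
  }
  ds
}

# Closed-form inverse-variance fixed-effect pairwise estimate (independent
# oracle for the two-arm NMA check).
pooled_pairwise <- function(ds, t1 = "A", t2 = "B") {
  studies <- unique(ds$study)
  est <- se2 <- numeric(0)
  for (s in studies) {
    di <- ds[ds$study == s, ]
    y1 <- di[di$treatment == t1, ]; y2 <- di[di$treatment == t2, ]
    if (!nrow(y1) || !nrow(y2)) next
    est <- c(est, y2$mean_change_rate - y1$mean_change_rate)
    se2 <- c(se2, y1$sd^2 / y1$n + y2$sd^2 / y2$n)
  }
  w <- 1 / se2
  c(mean = sum(w * est) / sum(w), se = sqrt(1 / sum(w)))
}
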