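# Pipeline orchestration: staged execution from a single configuration,
# with a run manifest for reproducibility.  An Rscript wrapper around
# run_pipeline() ships in inst/scripts/run_pipeline.R for shell use; the
# function surface is the primary interface.

#' Build a pipeline run configuration
#'
#' @param stage one of `"gen-synthetic"`, `"nma"`, `"base-case"`, `"psa"`,
#'   `"sa"`, `"scenarios"`, `"burden"`.
#' @param output_dir directory for stage outputs (created if needed).
#' @param seed mandatory integer seed; there is no silent nondeterminism.
#' @param parameter_table optional path to a parameter table (default: the
#'   packaged fixture).
#' @param risk_model optional path to a risk-model JSON (default: the
#'   calibrated synthetic model).
#' @param nma_dataset optional path to a trial-network CSV (default:
#'   generated synthetically from `seed`).
#' @param cohort_n,horizon,discount_rate,wtp simulation settings.
#' @param psa_iterations,psa_cohort_n PSA settings.
#' @param sa_arm tornado arm for the `sa` stage.
#' @param nma_kept,nma_burnin,nma_chains MCMC settings for the `nma` stage.
#' @return a `run_config` list.
#' @export
run_config <- function(stage, output_dir, seed,
                       parameter_table = NULL, risk_model = NULL,
                       nma_dataset = NULL, cohort_n = 2000, horizon = 100,
                       discount_rate = 0.05, wtp = 12728,
                       psa_iterations = 200, psa_cohort_n = 200,
                       sa_arm = "loxenatide",
                       nma_kept = 5000, nma_burnin = 1000, nma_chains = 4) {
  stage <- match.arg(stage, c("gen-synthetic", "nma", "base-case", "psa",
                              "sa", "scenarios", "burden"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stopf("run_config: a seed is mandatory")
  structure(as.list(environment()), class = "run_config")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

config_bundle <- function(config) {
  params <- if (is.null(config$parameter_table)) default_parameters()
  else load_parameter_table(config$parameter_table)
  risk <- if (is.null(config$risk_model)) gen_risk_coefficients()
  else read_risk_model(config$risk_model)
  model_bundle(params = params, risk_model = risk,
               life_table = gen_life_table(),
               cohort_n = config$cohort_n, horizon = config$horizon,
               seed = config$seed)
}

#' Execute one pipeline stage
#'
#' Runs the requested stage, writes its CSV/JSON outputs under the
#' configured directory, and returns (and writes) a manifest of seeds and
#' settings.  Identical config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return list with `stage`, `outputs` (named paths and objects), and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  paths <- character(0)
  seed <- config$seed

  if (config$stage == "gen-synthetic") {
    ds <- gen_nma_dataset(nma_config(seed = seed))
    p1 <- file.path(config$output_dir, "nma_dataset.csv")
    write_nma_dataset(ds, p1)
    model <- gen_risk_coefficients()
    p2 <- file.path(config$output_dir, "risk_model.json")
    write_risk_model(model, p2)
    lt <- gen_life_table()
    p3 <- file.path(config$output_dir, "life_table.csv")
    write_life_table(lt, p3)
    out <- list(nma_dataset = ds, risk_model = model, life_table = lt)
    paths <- c(p1, p2, p3)
  } else if (config$stage == "nma") {
    ds <- if (is.null(config$nma_dataset))
      gen_nma_dataset(nma_config(seed = seed))
    else read_nma_dataset(config$nma_dataset)
    fits <- list()
    for (ep in unique(ds$endpoint)) {
      fits[[ep]] <- fit_nma(ds, ep, chains = config$nma_chains,
                            kept = config$nma_kept,
                            burnin = config$nma_burnin,
                            seed = child_seed(seed, match(ep, unique(ds$endpoint))))
      p <- file.path(config$output_dir, paste0("nma_", ep, ".csv"))
      write.csv(fits[[ep]]$summary, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    diag <- do.call(rbind, lapply(names(fits), function(ep)
      data.frame(endpoint = ep, parameter = names(fits[[ep]]$rhat),
                 rhat = fits[[ep]]$rhat, row.names = NULL)))
    pd <- file.path(config$output_dir, "nma_diagnostics.csv")
    write.csv(diag, pd, row.names = FALSE)
    paths <- c(paths, pd)
    out <- list(fits = fits, diagnostics = diag)
  } else if (config$stage == "base-case") {
    bundle <- config_bundle(config)
    res <- run_base_case(bundle)
    summ <- do.call(rbind, lapply(res, arm_summary, wtp = config$wtp))
    rownames(summ) <- NULL
    p <- file.path(config$output_dir, "base_case.csv")
    write.csv(summ, p, row.names = FALSE)
    bk <- do.call(rbind, lapply(res, complication_breakdown))
    pb <- file.path(config$output_dir, "breakdown.csv")
    write.csv(bk, pb, row.names = FALSE)
    out <- list(results = res, summary = summ, breakdown = bk)
    paths <- c(p, pb)
  } else if (config$stage == "psa") {
    bundle <- config_bundle(config)
    psa <- run_psa(bundle, iterations = config$psa_iterations,
                   cohort_n = config$psa_cohort_n, seed = seed)
    ceac <- compute_ceac(psa)
    p <- file.path(config$output_dir, "ceac.csv")
    write.csv(ceac, p, row.names = FALSE)
    out <- list(psa = psa, ceac = ceac)
    paths <- p
  } else if (config$stage == "sa") {
    bundle <- config_bundle(config)
    tor <- one_way_sa(bundle, arm = config$sa_arm)
    p <- file.path(config$output_dir,
                   paste0("tornado_", config$sa_arm, ".csv"))
    write.csv(tor, p, row.names = FALSE)
    out <- list(tornado = tor)
    paths <- p
  } else if (config$stage == "scenarios") {
    bundle <- config_bundle(config)
    sc <- scenario_horizons(bundle)
    p <- file.path(config$output_dir, "scenarios.csv")
    write.csv(sc, p, row.names = FALSE)
    out <- list(scenarios = sc)
    paths <- p
  } else if (config$stage == "burden") {
    bundle <- config_bundle(config)
    res <- run_base_case(bundle)
    tab <- do.call(rbind, lapply(res, patient_table))
    report <- burden_analysis(tab)
    p <- file.path(config$output_dir, "burden_effects.csv")
    write.csv(rbind(cbind(outcome = "cost", report$cost$effects),
                    cbind(outcome = "disutility",
                          report$disutility$effects)),
              p, row.names = FALSE)
    out <- list(report = report, table = tab)
    paths <- p
  }

  manifest <- list(stage = config$stage, seed = seed,
                   settings = config[setdiff(names(config),
                                             c("stage", "output_dir"))],
                   outputs = paths)
  pm <- file.path(config$output_dir,
                  paste0("manifest_", config$stage, ".json"))
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  list(stage = config$stage, outputs = out, paths = paths,
       manifest = manifest)
}

#' Human-readable markdown summary of pipeline outputs
#'
#' @param outputs the return value of [run_pipeline()] (or a list of
#'   them).
#' @param wtp willingness-to-pay used for rankings.
#' @return character scalar of markdown.
#' @export
write_report <- function(outputs, wtp = 12728) {
  if (!is.null(outputs$stage)) outputs <- list(outputs)
  lines <- c("# Pipeline report", "")
  for (o in outputs) {
    lines <- c(lines, sprintf("## Stage: %s", o$stage), "")
    if (o$stage == "base-case" && !is.null(o$outputs$summary)) {
      s <- o$outputs$summary
      s <- s[order(-s$nmb), ]
      lines <- c(lines, "Arms ranked by NMB:", "")
      for (i in seq_len(nrow(s)))
        lines <- c(lines, sprintf(
          "%d. %s — cost %.0f USD, QALY %.3f, NMB %.0f USD",
          i, s$arm[i], s$cost[i], s$qaly[i], s$nmb[i]))
      lines <- c(lines, "")
    }
    if (o$stage == "psa") {
      if (is.null(o$outputs$psa) || !nrow(o$outputs$psa$cost)) {
        lines <- c(lines, "PSA produced no iterations.", "")
      } else {
        ceac <- o$outputs$ceac
        at <- ceac[abs(ceac$wtp - wtp) == min(abs(ceac$wtp - wtp)), ]
        at <- at[order(-at$probability), ]
        lines <- c(lines, sprintf(
          "Probability most cost-effective at WTP %.0f:", at$wtp[1]), "")
        for (i in seq_len(nrow(at)))
          lines <- c(lines, sprintf("- %s: %.1f%%", at$arm[i],
                                    100 * at$probability[i]))
        lines <- c(lines, "")
      }
    }
    if (!is.null(o$manifest)) {
      lines <- c(lines, sprintf("Seed: %s", o$manifest$seed),
                 sprintf("Outputs: %s",
                         paste(o$manifest$outputs, collapse = ", ")), "")
    }
  }
  paste(lines, collapse = "\n")
}
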