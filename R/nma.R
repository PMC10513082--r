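# Bayesian random-effects network meta-analysis of 6-month change rates,
# with convergence (Gelman-Rubin) and consistency (node-splitting,
# design-by-treatment) diagnostics.  MCMC runs in JAGS via rjags; all data
# preparation, diagnostics and summaries are package code.

# Subset an nma_dataset to one endpoint and validate its structure.
endpoint_data <- function(dataset, endpoint) {
  stopifnot(is.data.frame(dataset))
  d <- dataset[dataset$endpoint == endpoint, , drop = FALSE]
  if (!nrow(d)) stopf("no rows for endpoint '%s'", endpoint)
  arms_per_study <- table(d$study)
  if (any(arms_per_study < 2))
    stopf("study with a single arm: %s",
          paste(names(arms_per_study)[arms_per_study < 2], collapse = ", "))
  if (any(d$sd <= 0)) stopf("non-positive dispersion in endpoint '%s'", endpoint)
  d
}

#' Summarise an evidence network
#'
#' Nodes, direct-comparison edges with study counts, and a connectivity
#' verdict for one endpoint of a trial dataset.
#'
#' @param dataset an `nma_dataset`.
#' @param endpoint endpoint label (defaults to the first present).
#' @return list with `treatments`, `edges` (data.frame `t1,t2,n_studies`),
#'   `connected`, and `isolated` (treatments unreachable from the first).
#' @export
build_network <- function(dataset, endpoint = dataset$endpoint[1]) {
  d <- endpoint_data(dataset, endpoint)
  designs <- lapply(split(d$treatment, d$study), unique)
  treatments <- sort(unique(d$treatment))
  pairs <- do.call(rbind, lapply(designs, function(tr) {
    tr <- sort(tr)
    if (length(tr) < 2) return(NULL)
    t(combn(tr, 2))
  }))
  key <- paste(pairs[, 1], pairs[, 2], sep = " vs ")
  counts <- table(key)
  edges <- data.frame(
    t1 = sub(" vs .*", "", names(counts)),
    t2 = sub(".* vs ", "", names(counts)),
    n_studies = as.integer(counts), row.names = NULL)
  # reachability from the first treatment
  reached <- treatments[1]
  repeat {
    grow <- unique(unlist(designs[vapply(designs, function(x)
      any(x %in% reached), logical(1))]))
    if (all(grow %in% reached)) break
    reached <- union(reached, grow)
  }
  list(treatments = treatments, edges = edges,
       connected = all(treatments %in% reached),
       isolated = setdiff(treatments, reached))
}

nma_model_re <- "
model {
  for (i in 1:ns) {
    w[i, 1] <- 0
    delta[i, 1] <- 0
    mu[i] ~ dnorm(0, 1.0E-4)
    for (k in 1:na[i]) {
      y[i, k] ~ dnorm(theta[i, k], prec[i, k])
      theta[i, k] <- mu[i] + delta[i, k]
    }
    for (k in 2:na[i]) {
      delta[i, k] ~ dnorm(md[i, k], taud[i, k])
      md[i, k] <- d[t[i, k]] - d[t[i, 1]] + sw[i, k]
      taud[i, k] <- pr * 2 * (k - 1) / k
      w[i, k] <- delta[i, k] - d[t[i, k]] + d[t[i, 1]]
      sw[i, k] <- sum(w[i, 1:(k - 1)]) / (k - 1)
    }
  }
  d[1] <- 0
  for (k in 2:nt) { d[k] ~ dnorm(0, 1.0E-4) }
  tau ~ dunif(0, 5)
  pr <- 1 / (tau * tau)
}"

nma_model_fe <- "
model {
  for (i in 1:ns) {
    mu[i] ~ dnorm(0, 1.0E-4)
    for (k in 1:na[i]) {
      y[i, k] ~ dnorm(theta[i, k], prec[i, k])
      theta[i, k] <- mu[i] + d[t[i, k]] - d[t[i, 1]]
    }
  }
  d[1] <- 0
  for (k in 2:nt) { d[k] ~ dnorm(0, 1.0E-4) }
}"

# Arrange one endpoint's arms into the ragged (study x arm) JAGS layout.
nma_jags_data <- function(d, treatments, scale) {
  studies <- unique(d$study)
  ns <- length(studies)
  na <- integer(ns)
  maxa <- max(table(d$study))
  y <- prec <- tmat <- matrix(NA_real_, ns, maxa)
  for (i in seq_len(ns)) {
    di <- d[d$study == studies[i], , drop = FALSE]
    # reference-most arm first for a stable baseline
    di <- di[order(match(di$treatment, treatments)), , drop = FALSE]
    na[i] <- nrow(di)
    obs <- di$mean_change_rate
    if (scale == "log_ratio") {
      if (any(obs >= 0))
        stopf("log_ratio scale requires strictly negative change rates (reductions); study '%s' violates this", studies[i])
      se <- (di$sd / sqrt(di$n)) / abs(obs)  # delta method on log|y|
      obs <- log(-obs)
    } else {
      se <- di$sd / sqrt(di$n)
    }
    y[i, seq_len(na[i])] <- obs
    prec[i, seq_len(na[i])] <- 1 / se^2
    tmat[i, seq_len(na[i])] <- match(di$treatment, treatments)
  }
  list(ns = ns, nt = length(treatments), na = na, y = y, prec = prec,
       t = tmat, studies = studies)
}

#' Fit a Bayesian random-effects network meta-analysis
#'
#' Normal-likelihood arm-based model on observed per-arm change rates with
#' vague priors (normal(0, 100^2) on basic parameters and study baselines,
#' uniform(0, 5) on the heterogeneity SD tau), sampled with parallel Markov
#' chains in JAGS.  Production settings are 4 chains of 50,000 kept
#' iterations after 10,000 burn-in; reduced settings are appropriate for
#' desk runs and tests.  Convergence is assessed with the split-chain
#' Gelman-Rubin statistic; any parameter with R-hat above `rhat_limit`
#' flags the result (never silently accepted).
#'
#' @param dataset an `nma_dataset`.
#' @param endpoint endpoint label.
#' @param reference reference treatment (basic parameters are effects vs
#'   this arm).
#' @param chains number of parallel chains (>= 2).
#' @param kept kept iterations per chain after burn-in.
#' @param burnin burn-in iterations.
#' @param seed integer seed; fixes all posterior summaries.
#' @param scale `"difference"` (mean differences of change rates, default)
#'   or `"log_ratio"` (ratios of change-rate magnitudes modelled on the log
#'   scale; requires all-negative observed rates).
#' @param tau_fixed if `0`, fits the common-effect model (no heterogeneity);
#'   `NULL` (default) estimates tau.
#' @param rhat_limit convergence flag threshold.
#' @return an `nma_result`: `summary` (data.frame per non-reference
#'   treatment: mean, sd, 2.5/97.5% CrI), `tau` summary, `draws` (list of
#'   per-chain matrices), `rhat`, `converged`, and metadata.
#' @export
fit_nma <- function(dataset, endpoint, reference = NULL, chains = 4,
                    kept = 50000, burnin = 10000, seed = 1L,
                    scale = c("difference", "log_ratio"), tau_fixed = NULL,
                    rhat_limit = 1.05) {
  scale <- match.arg(scale)
  d <- endpoint_data(dataset, endpoint)
  net <- build_network(d, endpoint)
  if (!net$connected)
    stopf("network disconnected for endpoint '%s'; isolated: %s", endpoint,
          paste(net$isolated, collapse = ", "))
  treatments <- net$treatments
  if (is.null(reference)) reference <- treatments[1]
  if (!reference %in% treatments)
    stopf("reference '%s' not in network", reference)
  treatments <- c(reference, setdiff(treatments, reference))
  if (chains < 2) stopf("need at least 2 chains")

  jd <- nma_jags_data(d, treatments, scale)
  random_effects <- is.null(tau_fixed)
  model_str <- if (random_effects) nma_model_re else nma_model_fe
  data_list <- jd[c("ns", "nt", "na", "y", "prec", "t")]
  monitor <- if (random_effects) c("d", "tau") else "d"

  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(mu = rep(0, jd$ns),
                d = c(NA, rep(0, jd$nt - 1)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = child_seed(seed, ch, stream = 11L))
    if (random_effects) ini$tau <- 0.5 + 0.5 * (ch - 1) / chains
    ini
  })
  jm <- rjags::jags.model(textConnection(model_str), data = data_list,
                          inits = inits, n.chains = chains, n.adapt = 500,
                          quiet = TRUE)
  stats::update(jm, n.iter = burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor, n.iter = kept,
                              progress.bar = "none")

  keep_cols <- c(paste0("d[", 2:jd$nt, "]"), if (random_effects) "tau")
  draws <- lapply(samp, function(ch) {
    m <- as.matrix(ch)[, keep_cols, drop = FALSE]
    colnames(m) <- c(treatments[-1], if (random_effects) "tau")
    m
  })
  rhat <- gelman_rubin(draws)
  pooled <- do.call(rbind, draws)
  eff <- pooled[, treatments[-1], drop = FALSE]
  summary <- data.frame(
    treatment = treatments[-1],
    mean = colMeans(eff),
    sd = apply(eff, 2, sd),
    lower = apply(eff, 2, quantile, 0.025),
    upper = apply(eff, 2, quantile, 0.975),
    row.names = NULL)
  tau_summary <- if (random_effects)
    c(mean = mean(pooled[, "tau"]), sd = sd(pooled[, "tau"]),
      lower = unname(quantile(pooled[, "tau"], 0.025)),
      upper = unname(quantile(pooled[, "tau"], 0.975)))
  else c(mean = 0, sd = 0, lower = 0, upper = 0)

  res <- structure(list(
    endpoint = endpoint, reference = reference, treatments = treatments,
    scale = scale, summary = summary, tau = tau_summary, draws = draws,
    rhat = rhat, converged = all(rhat < rhat_limit),
    chains = chains, kept = kept, burnin = burnin, seed = seed,
    random_effects = random_effects), class = "nma_result")
  if (!res$converged)
    warnf("NMA for endpoint '%s' flagged: max R-hat %.3f > %.2f", endpoint,
          max(rhat), rhat_limit)
  res
}

#' @export
print.nma_result <- function(x, ...) {
  cat(sprintf("<nma_result> endpoint %s, reference %s (%s scale)\n",
              x$endpoint, x$reference, x$scale))
  cat(sprintf("  %d chains x %d kept (burn-in %d); max R-hat %.4f%s\n",
              x$chains, x$kept, x$burnin, max(x$rhat),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, per monitored parameter.  Chains with zero total variance (all
#' constant) return 1 by convention.
#'
#' @param chains list (>= 2) of equal-length numeric matrices
#'   (iterations x parameters) or vectors.
#' @return named numeric vector of R-hat values (>= 1 up to numeric noise).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stopf("gelman_rubin requires at least 2 chains")
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1,
                                       dimnames = list(NULL, "par"))
    ch
  })
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1 || lens[1] < 10)
    stopf("chains must have equal lengths >= 10")
  half <- floor(lens[1] / 2)
  split_chains <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(half), , drop = FALSE],
         ch[(half + 1):(2 * half), , drop = FALSE])), recursive = FALSE)
  pars <- colnames(chains[[1]])
  out <- setNames(numeric(length(pars)), pars)
  m <- length(split_chains)
  n <- half
  for (j in seq_along(pars)) {
    x <- vapply(split_chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (!is.finite(W) || W <= 0) { out[j] <- 1; next }
    vhat <- (n - 1) / n * W + B / n
    out[j] <- sqrt(vhat / W)
  }
  out
}

#' Full pairwise contrast table from an NMA fit
#'
#' All pairwise contrasts with posterior means and 95% credible intervals,
#' re-expressed against any reference.  Re-referencing is an affine
#' relabelling: pairwise contrasts are unchanged.
#'
#' @param result an `nma_result`.
#' @param reference treatment whose column of contrasts to anchor
#'   (defaults to the fit's reference).
#' @return data.frame with columns `t1, t2, mean, sd, lower, upper` where
#'   the value is the effect of `t2` relative to `t1`.
#' @export
relative_effects <- function(result, reference = result$reference) {
  stopifnot(inherits(result, "nma_result"))
  if (!reference %in% result$treatments)
    stopf("unknown reference '%s'", reference)
  pooled <- do.call(rbind, result$draws)
  basic <- cbind(0, pooled[, result$treatments[-1], drop = FALSE])
  colnames(basic) <- result$treatments
  # order treatments with the requested reference first
  trts <- c(reference, setdiff(result$treatments, reference))
  rows <- list()
  for (a in trts) for (b in trts) {
    if (a == b) next
    diff <- basic[, b] - basic[, a]
    rows[[length(rows) + 1]] <- data.frame(
      t1 = a, t2 = b, mean = mean(diff), sd = sd(diff),
      lower = unname(quantile(diff, 0.025)),
      upper = unname(quantile(diff, 0.975)))
  }
  do.call(rbind, rows)
}

#' Node-splitting local inconsistency check
#'
#' Separates the evidence on one comparison into its direct component (a
#' pairwise random-effects fit of the studies containing both treatments)
#' and its indirect component (the network fit with those studies removed),
#' and tests their difference with a two-sided normal-approximation
#' p-value.
#'
#' @param dataset an `nma_dataset`.
#' @param endpoint endpoint label.
#' @param comparison length-2 character vector `c(t1, t2)`; the split
#'   contrast is `t2` minus `t1`.
#' @param random_effects estimate tau inside each sub-fit (default FALSE:
#'   common-effect sub-fits, which keep the direct estimate identified when
#'   only one direct study exists).
#' @inheritParams fit_nma
#' @return list with `direct`, `indirect` (each mean/sd), `difference`,
#'   `p_value`, and the two underlying fits.
#' @export
node_split <- function(dataset, endpoint, comparison, chains = 4,
                       kept = 5000, burnin = 1000, seed = 1L,
                       scale = c("difference", "log_ratio"),
                       random_effects = FALSE) {
  scale <- match.arg(scale)
  tau_fixed <- if (random_effects) NULL else 0
  stopifnot(length(comparison) == 2)
  d <- endpoint_data(dataset, endpoint)
  designs <- lapply(split(d$treatment, d$study), unique)
  has_both <- vapply(designs, function(tr) all(comparison %in% tr),
                     logical(1))
  direct_studies <- names(designs)[has_both]
  if (!length(direct_studies))
    stopf("comparison %s vs %s has no direct evidence; not splittable",
          comparison[1], comparison[2])
  dir_data <- d[d$study %in% direct_studies & d$treatment %in% comparison, ]
  ind_data <- d[!d$study %in% direct_studies, ]
  if (!nrow(ind_data))
    stopf("comparison %s vs %s has no indirect evidence; not splittable",
          comparison[1], comparison[2])
  ind_net <- build_network(ind_data, endpoint)
  if (!all(comparison %in% ind_net$treatments) || !ind_net$connected)
    stopf("no indirect path between %s and %s once direct studies are removed",
          comparison[1], comparison[2])
  fit_dir <- fit_nma(dir_data, endpoint, reference = comparison[1],
                     chains = chains, kept = kept, burnin = burnin,
                     seed = child_seed(seed, 1L), scale = scale,
                     tau_fixed = tau_fixed)
  fit_ind <- fit_nma(ind_data, endpoint, reference = comparison[1],
                     chains = chains, kept = kept, burnin = burnin,
                     seed = child_seed(seed, 2L), scale = scale,
                     tau_fixed = tau_fixed)
  ind_contrasts <- relative_effects(fit_ind)
  ind_row <- ind_contrasts[ind_contrasts$t1 == comparison[1] &
                           ind_contrasts$t2 == comparison[2], ]
  dir_row <- fit_dir$summary[fit_dir$summary$treatment == comparison[2], ]
  diff <- dir_row$mean - ind_row$mean
  se <- sqrt(dir_row$sd^2 + ind_row$sd^2)
  list(comparison = comparison,
       direct = c(mean = dir_row$mean, sd = dir_row$sd),
       indirect = c(mean = ind_row$mean, sd = ind_row$sd),
       difference = diff,
       p_value = 2 * pnorm(-abs(diff) / se),
       fit_direct = fit_dir, fit_indirect = fit_ind)
}

#' Inconsistency fraction from a chi-square decomposition
#'
#' `I^2 = max(0, (Q - df) / Q) * 100`; defined as 0 when `Q = 0`.
#' @param Q chi-square statistic.
#' @param df its degrees of freedom.
#' @return percentage between 0 and 100.
#' @export
i_squared <- function(Q, df) {
  if (Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Design-by-treatment global inconsistency test
#'
#' Two-stage generalized-least-squares decomposition: within-study contrasts
#' versus the study baseline arm (with full within-study covariance) are
#' fitted under the consistency model and under the full design-by-treatment
#' interaction model; the drop in the weighted residual sum of squares is
#' the inconsistency chi-square.
#'
#' @param dataset an `nma_dataset`.
#' @param endpoint endpoint label.
#' @return list with `Q`, `df`, `p_value`, `I2`; when no design shares a
#'   comparison with another (df = 0) the result carries
#'   `estimable = FALSE`.
#' @export
design_by_treatment <- function(dataset, endpoint) {
  d <- endpoint_data(dataset, endpoint)
  treatments <- sort(unique(d$treatment))
  studies <- unique(d$study)
  ys <- list(); Xc <- list(); Xf <- list(); Ls <- list()
  design_of <- character(0)
  for (s in studies) {
    di <- d[d$study == s, ]
    di <- di[order(match(di$treatment, treatments)), ]
    k <- nrow(di)
    se2 <- (di$sd / sqrt(di$n))^2
    yy <- di$mean_change_rate[-1] - di$mean_change_rate[1]
    V <- matrix(se2[1], k - 1, k - 1); diag(V) <- se2[-1] + se2[1]
    design <- paste(sort(unique(di$treatment)), collapse = ":")
    # consistency design matrix: contrast t_k - t_1 in basic parameters
    xc <- matrix(0, k - 1, length(treatments),
                 dimnames = list(NULL, treatments))
    for (j in 2:k) {
      xc[j - 1, di$treatment[j]] <- 1
      xc[j - 1, di$treatment[1]] <- xc[j - 1, di$treatment[1]] - 1
    }
    ys[[s]] <- yy; Xc[[s]] <- xc; Ls[[s]] <- chol(solve(V))
    design_of <- c(design_of, rep(design, k - 1))
  }
  y <- unlist(ys)
  Xcons <- do.call(rbind, Xc)[, -1, drop = FALSE]  # first treatment = ref
  # full model: separate basic parameters per design
  udesigns <- unique(design_of)
  Xfull <- do.call(cbind, lapply(udesigns, function(dg) {
    X <- do.call(rbind, Xc)[, -1, drop = FALSE]
    X[design_of != dg, ] <- 0
    colnames(X) <- paste(dg, colnames(X), sep = ".")
    X
  }))
  # whiten per study and stack
  Lw <- matrix(0, length(y), length(y))
  pos <- 1
  for (s in studies) {
    k <- length(ys[[s]])
    Lw[pos:(pos + k - 1), pos:(pos + k - 1)] <- Ls[[s]]
    pos <- pos + k
  }
  yw <- as.vector(Lw %*% y)
  fit_q <- function(X) {
    Xw <- Lw %*% X
    f <- lm.fit(Xw, yw)
    list(Q = sum(f$residuals^2), rank = f$rank)
  }
  fc <- fit_q(Xcons)
  ff <- fit_q(Xfull)
  Q <- fc$Q - ff$Q
  df <- ff$rank - fc$rank
  if (df <= 0)
    return(list(Q = 0, df = 0, p_value = NA_real_, I2 = NA_real_,
                estimable = FALSE))
  list(Q = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE),
       I2 = i_squared(Q, df), estimable = TRUE)
}
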