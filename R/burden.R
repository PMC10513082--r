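# GLM relating HbA1c / BMI control to lifetime comorbidity burden.
# The fitter is an explicit iteratively-reweighted-least-squares
# implementation; stats::glm serves as an independent cross-check in the
# test-suite.

#' Specification for a burden GLM
#'
#' @param outcome `"cost"` or `"disutility"`.
#' @param family `"gaussian"` or `"gamma"`.
#' @param link `"identity"` or `"log"`.
#' @param hba1c_cut HbA1c control cut-point (%); above it counts as
#'   inadequate glycaemic control (WHO-referenced 7.0).
#' @param bmi_cut BMI cut-point (kg/m2); above it counts as ineffective
#'   weight control (WHO-referenced 25.0).
#' @param covariates covariate column names adjusted for.
#' @return a `glm_spec`.
#' @export
glm_spec <- function(outcome = c("cost", "disutility"),
                     family = c("gaussian", "gamma"),
                     link = c("identity", "log"),
                     hba1c_cut = 7.0, bmi_cut = 25.0,
                     covariates = c("age", "female", "sbp", "dbp",
                                    "duration", "smoker_current",
                                    "ckd_stage", "history_mi",
                                    "history_stroke")) {
  structure(list(outcome = match.arg(outcome), family = match.arg(family),
                 link = match.arg(link), hba1c_cut = hba1c_cut,
                 bmi_cut = bmi_cut, covariates = covariates),
            class = "glm_spec")
}

glm_family_funs <- function(family, link) {
  if (family == "gaussian" && link == "identity") {
    list(linkfun = identity, linkinv = identity, mu_eta = function(eta) rep(1, length(eta)),
         variance = function(mu) rep(1, length(mu)),
         dev = function(y, mu) sum((y - mu)^2))
  } else if (family == "gamma" && link == "log") {
    list(linkfun = log, linkinv = exp, mu_eta = exp,
         variance = function(mu) mu^2,
         dev = function(y, mu) 2 * sum((y - mu) / mu - log(y / mu)))
  } else if (family == "gaussian" && link == "log") {
    list(linkfun = log, linkinv = exp, mu_eta = exp,
         variance = function(mu) rep(1, length(mu)),
         dev = function(y, mu) sum((y - mu)^2))
  } else if (family == "gamma" && link == "identity") {
    list(linkfun = identity, linkinv = identity,
         mu_eta = function(eta) rep(1, length(eta)),
         variance = function(mu) mu^2,
         dev = function(y, mu) 2 * sum((y - mu) / mu - log(y / mu)))
  } else stopf("unsupported family/link pair %s/%s", family, link)
}

#' Fit a GLM by iteratively reweighted least squares
#'
#' Explicit IRLS: weighted least squares on the working response until the
#' relative deviance change falls below `tol` (default 1e-8) or `max_iter`
#' iterations.  The gaussian-identity case solves the normal equations in
#' one step and equals ordinary least squares exactly.
#'
#' @param X design matrix (patients x columns, including an intercept
#'   column).
#' @param y outcome vector (strictly positive for the gamma family).
#' @param family,link distribution family and link; supported pairs are
#'   gaussian/identity, gamma/log, gaussian/log and gamma/identity.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter iteration cap; non-convergence flags the fit.
#' @return a `glm_fit`: `coefficients`, `se`, `z`, `p_value`, `deviance`,
#'   `iterations`, `converged`, `dispersion`, plus the inputs needed for
#'   prediction.
#' @export
irls_fit <- function(X, y, family = "gaussian", link = "identity",
                     tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stopf("need more observations (%d) than columns (%d)", n, p)
  if (family == "gamma" && any(y <= 0))
    stopf("gamma family requires strictly positive outcomes")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stopf("singular design: collinear column(s) %s",
          paste(bad, collapse = ", "))
  }
  f <- glm_family_funs(family, link)
  mu <- if (link == "log") pmax(y, 0.1 * mean(abs(y)) + 1e-8) else
    rep(mean(y), n)
  eta <- f$linkfun(mu)
  dev <- f$dev(y, mu)
  converged <- FALSE
  iter <- 0
  beta <- NULL
  repeat {
    iter <- iter + 1
    me <- f$mu_eta(eta)
    w <- me^2 / f$variance(mu)
    z <- eta + (y - mu) / me
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- as.vector(X %*% beta)
    mu <- f$linkinv(eta)
    dev_new <- f$dev(y, mu)
    if (is.finite(dev) && abs(dev_new - dev) / (abs(dev) + 0.1) < tol) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
    if (iter >= max_iter) break
  }
  # dispersion: 1 for none; Pearson estimate for gamma/gaussian scale
  me <- f$mu_eta(eta)
  w <- me^2 / f$variance(mu)
  pearson <- sum((y - mu)^2 / f$variance(mu))
  dispersion <- pearson / (n - p)
  XtWX <- crossprod(X * sqrt(w))
  cov_beta <- dispersion * solve(XtWX)
  se <- sqrt(diag(cov_beta))
  zval <- beta / se
  structure(list(coefficients = beta, se = se, z = zval,
                 p_value = 2 * pnorm(-abs(zval)), deviance = dev,
                 iterations = iter, converged = converged,
                 dispersion = dispersion, family = family, link = link,
                 X = X, fitted = mu),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s/%s, deviance %.4g, %d iteration(s)%s\n",
              x$family, x$link, x$deviance, x$iterations,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                   p = x$p_value), digits = 4)
  invisible(x)
}

# Average marginal effect of a binary exposure column on the outcome scale.
marginal_effect <- function(fit, column) {
  f <- glm_family_funs(fit$family, fit$link)
  X1 <- X0 <- fit$X
  X1[, column] <- 1; X0[, column] <- 0
  mean(f$linkinv(as.vector(X1 %*% fit$coefficients)) -
         f$linkinv(as.vector(X0 %*% fit$coefficients)))
}

#' Burden of comorbidities versus HbA1c and BMI control
#'
#' Dichotomizes achieved HbA1c (> `hba1c_cut`: inadequate glycaemic
#' control) and BMI (> `bmi_cut`: ineffective weight control), fits the
#' cost and disutility outcomes by IRLS with all other patient
#' characteristics as covariates, and reports the average marginal effect
#' of each exposure on the outcome scale with normal-approximation CIs and
#' p-values.
#'
#' @param table patient-level data.frame (see [patient_table()]); must
#'   carry `hba1c`, `bmi`, the covariates, and the outcome columns
#'   `complication_cost` and `complication_disutility`.
#' @param cost_spec,disu_spec [glm_spec()]s for the two outcomes.  Cost
#'   defaults to gamma/log; disutility to gaussian/identity.
#' @param pool_arms include the arm label as a covariate when several arms
#'   are pooled.
#' @return a `burden_report`: per outcome, the fit and a data.frame of
#'   exposure effects (`exposure, effect, se, p_value`).
#' @export
burden_analysis <- function(table,
                            cost_spec = glm_spec("cost", "gamma", "log"),
                            disu_spec = glm_spec("disutility", "gaussian",
                                                 "identity"),
                            pool_arms = TRUE) {
  need <- c("hba1c", "bmi", "complication_cost", "complication_disutility")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stopf("patient table lacks column(s): %s", paste(missing, collapse = ", "))
  build <- function(spec) {
    poor_hba1c <- as.integer(table$hba1c > spec$hba1c_cut)
    high_bmi <- as.integer(table$bmi > spec$bmi_cut)
    if (length(unique(poor_hba1c)) < 2)
      stopf("HbA1c exposure has a single level; no contrast")
    if (length(unique(high_bmi)) < 2)
      stopf("BMI exposure has a single level; no contrast")
    covs <- intersect(spec$covariates, names(table))
    X <- cbind(`(Intercept)` = 1, poor_hba1c = poor_hba1c,
               high_bmi = high_bmi,
               as.matrix(table[covs]))
    if (pool_arms && "arm" %in% names(table) &&
        length(unique(table$arm)) > 1) {
      arms <- sort(unique(table$arm))[-1]
      for (a in arms) X <- cbind(X, as.integer(table$arm == a))
      colnames(X)[(ncol(X) - length(arms) + 1):ncol(X)] <-
        paste0("arm_", arms)
    }
    X
  }
  fit_one <- function(spec) {
    y <- if (spec$outcome == "cost") table$complication_cost else
      table$complication_disutility
    X <- build(spec)
    if (spec$family == "gamma") {
      shift <- 0
      if (any(y <= 0)) {
        shift <- abs(min(y)) + 1e-6 * max(abs(y), 1)
        y <- y + shift
      }
      fit <- irls_fit(X, y, spec$family, spec$link)
    } else fit <- irls_fit(X, y, spec$family, spec$link)
    effects <- do.call(rbind, lapply(c("poor_hba1c", "high_bmi"),
      function(col) {
        data.frame(exposure = col, effect = marginal_effect(fit, col),
                   coefficient = fit$coefficients[[col]],
                   se = fit$se[[col]], p_value = fit$p_value[[col]])
      }))
    rownames(effects) <- NULL
    list(spec = spec, fit = fit, effects = effects)
  }
  structure(list(cost = fit_one(cost_spec), disutility = fit_one(disu_spec)),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  for (nm in c("cost", "disutility")) {
    cat(sprintf("Outcome: %s (%s/%s)\n", nm, x[[nm]]$spec$family,
                x[[nm]]$spec$link))
    print(x[[nm]]$effects, digits = 4)
  }
  invisible(x)
}
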