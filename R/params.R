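#' Fit an uncertainty distribution to a mean and range
#'
#' Builds a `distribution_spec` whose mean equals `mean` exactly and whose
#' central 95% interval approximates `(low, high)`.  The range column of the
#' parameter table is read as a 95% interval; when mean and interval are
#' jointly infeasible (as for price parameters whose mean coincides with an
#' endpoint) the mean is matched exactly and the interval in a least-squares
#' sense.  A zero-width range (`low == mean == high`) yields a point mass
#' whatever the declared family.
#'
#' Families follow the usual second-order-uncertainty conventions: gamma for
#' costs and positive clinical quantities, beta for probabilities,
#' proportions and utilities, normal for relative effects, fixed for
#' point-mass parameters.
#'
#' @param family one of `"gamma"`, `"beta"`, `"normal"`, `"fixed"`.
#' @param mean point value of the parameter.
#' @param low,high range endpoints, `low <= mean <= high`.
#' @param name optional parameter name used in error messages.
#' @return an object of class `distribution_spec` with elements `family`,
#'   `mean`, `low`, `high`, `degenerate`, and the fitted shape parameters
#'   (`shape`/`rate` for gamma, `shape1`/`shape2` for beta, `sd` for normal).
#' @examples
#' fit_distribution("gamma", 100, 50, 150)
#' fit_distribution("beta", 0.05, 0, 0.08)
#' @export
fit_distribution <- function(family, mean, low, high, name = NULL) {
  family <- match.arg(family, c("gamma", "beta", "normal", "fixed"))
  who <- if (is.null(name)) family else name
  if (!all(is.finite(c(mean, low, high))))
    stopf("non-finite mean/range for parameter '%s'", who)
  if (low > mean + 1e-12 || mean > high + 1e-12)
    stopf("parameter '%s': range ordering violated (low %g, mean %g, high %g)",
          who, low, mean, high)

  spec <- list(family = family, mean = mean, low = low, high = high,
               degenerate = FALSE)
  class(spec) <- "distribution_spec"

  if (family == "fixed" || (high - low) < 1e-12) {
    if (family == "fixed" && (abs(low - mean) > 1e-12 || abs(high - mean) > 1e-12))
      stopf("parameter '%s': fixed family requires low = mean = high", who)
    spec$degenerate <- TRUE
    return(spec)
  }

  if (family == "beta") {
    if (low < -1e-12 || high > 1 + 1e-12)
      stopf("parameter '%s': beta requires support within [0, 1]", who)
    if (mean <= 0 || mean >= 1)
      stopf("parameter '%s': beta mean must lie strictly in (0, 1)", who)
    # mean fixed: shape2 = shape1 (1 - m) / m; fit shape1 to the interval
    obj <- function(loga) {
      a <- exp(loga); b <- a * (1 - mean) / mean
      (qbeta(0.025, a, b) - low)^2 + (qbeta(0.975, a, b) - high)^2
    }
    opt <- optimize(obj, c(-7, 12))
    spec$shape1 <- exp(opt$minimum)
    spec$shape2 <- spec$shape1 * (1 - mean) / mean
  } else if (family == "gamma") {
    if (mean <= 0)
      stopf("parameter '%s': gamma requires mean > 0", who)
    if (low < 0)
      stopf("parameter '%s': gamma requires non-negative support", who)
    obj <- function(logs) {
      s <- exp(logs); r <- s / mean
      (qgamma(0.025, s, r) - low)^2 + (qgamma(0.975, s, r) - high)^2
    }
    opt <- optimize(obj, c(-7, 15))
    spec$shape <- exp(opt$minimum)
    spec$rate <- spec$shape / mean
  } else { # normal
    spec$sd <- (high - low) / (2 * qnorm(0.975))
  }
  spec
}

#' Sample from a fitted distribution spec
#'
#' @param spec a `distribution_spec`.
#' @param n number of draws.
#' @return numeric vector of length `n`; constant for degenerate specs.
#' @export
sample_spec <- function(spec, n = 1) {
  stopifnot(inherits(spec, "distribution_spec"))
  if (spec$degenerate) return(rep(spec$mean, n))
  switch(spec$family,
    gamma  = rgamma(n, spec$shape, spec$rate),
    beta   = rbeta(n, spec$shape1, spec$shape2),
    normal = rnorm(n, spec$mean, spec$sd))
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("<distribution_spec> %s: mean %g, range (%g, %g)%s\n",
              x$family, x$mean, x$low, x$high,
              if (x$degenerate) " [point mass]" else ""))
  invisible(x)
}

new_parameter_set <- function(table, discount_rate = 0.05, wtp = 12728,
                              exchange_rate = 6.693) {
  stopifnot(is.data.frame(table))
  specs <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    fit_distribution(row$family, row$mean, row$low, row$high, name = row$name)
  })
  names(specs) <- table$name
  structure(list(table = table, specs = specs,
                 discount_rate = discount_rate, wtp = wtp,
                 exchange_rate = exchange_rate),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters (%s)\n", nrow(x$table),
              paste(sprintf("%s: %d", names(table(x$table$group)),
                            as.integer(table(x$table$group))), collapse = ", ")))
  cat(sprintf("  discount %g/yr, WTP %g USD/QALY, exchange rate %g CNY/USD\n",
              x$discount_rate, x$wtp, x$exchange_rate))
  invisible(x)
}

#' @export
length.parameter_set <- function(x) nrow(x$table)

param_schema <- c("name", "mean", "low", "high", "family", "units", "group")

#' Read / write a parameter table
#'
#' The on-disk schema is a flat table with columns
#' `name,mean,low,high,family,units,group` (CSV with a header row, or an
#' equivalent JSON array of records).  `load_parameter_table()` validates the
#' schema, fits every distribution, and returns a `parameter_set`;
#' `save_parameter_table()` writes one back losslessly (full numeric
#' precision), so `load(save(x))` round-trips exactly.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param discount_rate,wtp,exchange_rate analysis-level constants attached to
#'   the set: annual discount rate, willingness-to-pay threshold (USD per
#'   QALY; the 2021 Chinese per-capita GDP of 12,728 by default) and the
#'   CNY-per-USD conversion applied upstream of the table.
#' @return `load_parameter_table()`: a `parameter_set`.
#' @export
load_parameter_table <- function(path, discount_rate = 0.05, wtp = 12728,
                                 exchange_rate = 6.693) {
  if (!file.exists(path)) stopf("parameter table not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    if (length(tab) == 0) tab <- data.frame()
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0) {
    tab <- data.frame(name = character(), mean = numeric(), low = numeric(),
                      high = numeric(), family = character(),
                      units = character(), group = character(),
                      stringsAsFactors = FALSE)
    return(new_parameter_set(tab, discount_rate, wtp, exchange_rate))
  }
  missing <- setdiff(param_schema, names(tab))
  if (length(missing))
    stopf("parameter table %s: missing column(s) %s", path,
          paste(missing, collapse = ", "))
  tab <- tab[param_schema]
  for (col in c("mean", "low", "high")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")
    if (any(is.na(v)))
      stopf("parameter table %s: unparseable number in column '%s', row %d",
            path, col, which(is.na(v))[1])
    tab[[col]] <- v
  }
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup))
    stopf("parameter table %s: duplicate name '%s' (row %d)", path, dup[1],
          which(tab$name == dup[1])[2])
  new_parameter_set(tab, discount_rate, wtp, exchange_rate)
}

#' @rdname load_parameter_table
#' @param set a `parameter_set` to write.
#' @export
save_parameter_table <- function(set, path) {
  stopifnot(inherits(set, "parameter_set"))
  tab <- set$table
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    # format with full precision; write.csv would round via as.character
    out <- tab
    for (col in c("mean", "low", "high"))
      out[[col]] <- vapply(tab[[col]], function(v) format(v, digits = 17),
                           character(1))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' The packaged base-case parameter table
#'
#' Loads the parameter fixture shipped with the package: clinical baselines,
#' trial-period adverse-event rates, unit costs (USD, converted from CNY at
#' 6.693) and health-state (dis)utilities, each with mean, 95% range and
#' distribution family.
#'
#' @inheritParams load_parameter_table
#' @param format `"csv"` or `"json"` fixture variant (identical content).
#' @return a `parameter_set`.
#' @export
default_parameters <- function(format = c("csv", "json"), discount_rate = 0.05,
                               wtp = 12728, exchange_rate = 6.693) {
  format <- match.arg(format)
  path <- system.file("extdata",
                      paste0("parameters_table1.", format),
                      package = "glp1sim", mustWork = TRUE)
  load_parameter_table(path, discount_rate, wtp, exchange_rate)
}

#' Draw one joint parameter sample
#'
#' One independent joint draw across all parameters of the set (no
#' correlation structure), as used per iteration of the probabilistic
#' sensitivity analysis.  Identical `(seed, draw_index)` pairs reproduce
#' identical draws.
#'
#' @param set a `parameter_set`.
#' @param seed integer RNG seed.
#' @param draw_index 1-based index of the draw (PSA iteration number).
#' @return a `parameter_draw`: list with `values` (named numeric vector),
#'   `draw_index`, `seed`.
#' @export
sample_draw <- function(set, seed, draw_index = 1L) {
  stopifnot(inherits(set, "parameter_set"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, draw_index))
  values <- vapply(set$specs, sample_spec, numeric(1), n = 1)
  structure(list(values = values, draw_index = as.integer(draw_index),
                 seed = as.integer(seed)),
            class = "parameter_draw")
}

#' Point-value draw of a parameter set
#'
#' Returns a `parameter_draw` at the table means (the base case).
#' @param set a `parameter_set`.
#' @export
base_case_draw <- function(set) {
  stopifnot(inherits(set, "parameter_set"))
  values <- setNames(set$table$mean, set$table$name)
  structure(list(values = values, draw_index = 0L, seed = NA_integer_),
            class = "parameter_draw")
}

#' Validate a parameter set
#'
#' Reports (never errors on) violations: range ordering, distribution support
#' violations, and missing names required by the simulation profile.
#'
#' @param set a `parameter_set`.
#' @param required optional character vector of parameter names the intended
#'   analysis needs.
#' @return data.frame with columns `name` and `problem`; zero rows when clean.
#' @export
validate_parameters <- function(set, required = NULL) {
  stopifnot(inherits(set, "parameter_set"))
  tab <- set$table
  problems <- list()
  add <- function(name, problem)
    problems[[length(problems) + 1]] <<- data.frame(name = name,
                                                    problem = problem)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$low > r$mean || r$mean > r$high)
      add(r$name, sprintf("range ordering violated: %g (%g-%g)",
                          r$mean, r$low, r$high))
    if (r$family == "beta" && (r$low < 0 || r$high > 1))
      add(r$name, "beta parameter outside [0, 1]")
    if (r$family == "gamma" && r$low < 0)
      add(r$name, "gamma parameter with negative lower bound")
    if (!r$family %in% c("gamma", "beta", "normal", "fixed"))
      add(r$name, sprintf("unknown family '%s'", r$family))
    if (!nzchar(r$units)) add(r$name, "empty units")
  }
  for (nm in setdiff(required %||% character(), tab$name))
    add(nm, "required parameter missing")
  if (length(problems)) do.call(rbind, problems)
  else data.frame(name = character(), problem = character())
}

# Resolve one parameter value from a draw, with a clear error when absent.
param <- function(draw, name) {
  v <- draw$values[[name]]
  if (is.null(v)) stopf("parameter '%s' missing from draw", name)
  v
}
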