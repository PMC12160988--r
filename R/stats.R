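# The statistical arm: matching, standardization, adjusted logistic and
# linear models, group comparisons and the sensitivity-analysis battery.

#' Standardize a variable to zero mean and unit variance
#'
#' Uses the population convention (divisor n) on the reference sample; the
#' centering and scaling constants are attached for reuse on new data.
#'
#' @param values Numeric vector to transform.
#' @param reference Sample defining the mean and SD (default: `values`).
#' @return Z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(values, reference = values) {
  m <- mean(reference)
  s <- sd_pop(reference)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant variable", call. = FALSE)
  structure((values - m) / s, center = m, scale = s)
}

#' Default covariate set of the adjusted models
#'
#' Age, sex, binary ethnicity (White / non-White), hypertension, cataract,
#' diabetes, previous eye surgery and disc area. Age and disc area are
#' standardized inside the fits; reference levels are male, White, condition
#' absent.
#'
#' @return Character vector of column names.
#' @export
pd_covariates <- function() {
  c("age", "sex", "ethnicity_white", "hypertension", "cataract", "diabetes",
    "eye_surgery", "disc_area")
}

#' Binary covariates subject to the sparse-exposure rule
#'
#' Binary covariates that are removed from an adjusted model when their
#' minority level holds fewer than five members of the case group (in the
#' original analysis this rule bites for diabetes, present in only two
#' prevalent cases).
#'
#' @return Character vector of column names.
#' @export
sparse_covariates <- function() {
  c("diabetes", "hypertension", "cataract", "eye_surgery", "ethnicity_white")
}

# Build the model frame shared by the logistic and linear fits: standardized
# measure / age / disc area (divisor n, on the analysis sample), sex as a
# factor with male reference, non-White indicator so White is the reference.
build_model_frame <- function(data, measure, covariates, sd_reference = NULL) {
  mf <- data.frame(row.names = seq_len(nrow(data)))
  if (is.null(sd_reference)) {
    z <- standardize(data[[measure]])
  } else {
    z <- (data[[measure]] - mean(data[[measure]])) / sd_reference
    attr(z, "scale") <- sd_reference
  }
  mf$measure_z <- as.numeric(z)
  sd_used <- attr(z, "scale") %||% sd_pop(data[[measure]])
  for (cv in covariates) {
    v <- data[[cv]]
    mf[[cv]] <- switch(cv,
      age = as.numeric(standardize(v)),
      disc_area = as.numeric(standardize(v)),
      sex = factor(v, levels = c("male", "female")),
      ethnicity_white = factor(ifelse(v, "White", "non_White"),
                               levels = c("White", "non_White")),
      v)
  }
  list(frame = mf, sd_of_measure = sd_used)
}

drop_missing_rows <- function(data, cols) {
  use <- stats::complete.cases(data[, cols, drop = FALSE])
  list(data = data[use, , drop = FALSE], n_dropped = sum(!use))
}

new_pallor_model <- function(fields) {
  structure(fields, class = "pallor_model")
}

#' Adjusted logistic model: case status on standardized pallor
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, at most 50
#' iterations) of a binary outcome on a standardized pallor measure plus
#' covariates. Reports the odds ratio per SD increase with Wald 95% CI.
#' Rows with missing values in any used column are dropped and counted. A
#' binary covariate named in `drop_sparse` is removed when its minority level
#' holds fewer than `min_exposed` members of the case group: with only a
#' couple of exposed cases such a covariate cannot be adjusted for (its
#' coefficient diverges) and is excluded instead. Detected separation or
#' non-convergence of the pallor coefficient yields `converged = FALSE` and
#' no silent estimate.
#'
#' @param data Participant data frame.
#' @param outcome Name of a logical (or 0/1) case-status column.
#' @param measure Pallor measure column to test.
#' @param covariates Adjustment set; default [pd_covariates()].
#' @param drop_sparse Covariates subject to the sparse-exposure rule.
#' @param min_exposed Exposure threshold of that rule.
#' @return An object of class `pallor_model`.
#' @export
fit_logistic <- function(data, outcome, measure, covariates = pd_covariates(),
                         drop_sparse = sparse_covariates(), min_exposed = 5) {
  covariates <- intersect(covariates, names(data))
  used_cols <- c(outcome, measure, covariates)
  dm <- drop_missing_rows(data, used_cols)
  data <- dm$data
  y <- as.logical(data[[outcome]])
  if (length(unique(y)) != 2)
    stop("outcome must be binary with both levels present", call. = FALSE)

  dropped <- character(0)
  for (cv in intersect(drop_sparse, covariates)) {
    v <- as.logical(data[[cv]])
    if (min(sum(v & y), sum(!v & y)) < min_exposed) {
      covariates <- setdiff(covariates, cv)
      dropped <- c(dropped, cv)
    }
  }

  bm <- build_model_frame(data, measure, covariates)
  mf <- cbind(.y = y, bm$frame)
  form <- stats::as.formula(paste(".y ~ measure_z",
                                  if (length(covariates))
                                    paste("+", paste(covariates, collapse = " + "))
                                  else ""))
  warned <- character(0)
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(),
               data = mf,
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  b <- co["measure_z", "Estimate"]
  se <- co["measure_z", "Std. Error"]
  p <- co["measure_z", "Pr(>|z|)"]
  # separation matters when it destabilises the reported pallor coefficient
  separated <- any(grepl("fitted probabilities numerically 0 or 1", warned)) &&
    (!is.finite(se) || se > 10 || abs(b) > 10)
  converged <- isTRUE(fit$converged) && !separated && is.finite(se) && se < 10

  new_pallor_model(list(
    measure = measure, type = "logistic", scale = "odds_ratio_per_sd",
    estimate = exp(b), coefficient = b, se = se,
    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se), p = p,
    n_cases = sum(y), n_controls = sum(!y), n = length(y),
    n_dropped_missing = dm$n_dropped,
    covariates = covariates, dropped_covariates = dropped,
    converged = converged,
    diagnostics = if (converged) character(0) else
      c(if (separated) "separation detected", warned),
    sd_of_measure = bm$sd_of_measure, fit = fit))
}

#' Adjusted linear model for disc pallor and disease duration
#'
#' Ordinary least squares relating a standardized pallor measure to years
#' since (or to) diagnosis, adjusted for covariates. Two reporting scales are
#' supported, because a dimensionless pallor z-score and a duration in years
#' can sit on either side of the model: `response = "pallor"` regresses the
#' standardized measure on duration (slope in SD units per year);
#' `response = "duration"` regresses duration on the standardized measure
#' (slope in years per SD).
#'
#' @param data Participant data frame (typically one case arm).
#' @param measure Pallor measure column.
#' @param duration Duration column (e.g. `years_since_dx`).
#' @param covariates Adjustment set; default [pd_covariates()].
#' @param response Which variable is the model outcome (see above).
#' @param sd_reference Optional externally-defined SD of the measure (e.g.
#'   the control-arm SD) used for standardization; default: the
#'   population SD of the fitting sample.
#' @param drop_sparse,min_exposed Sparse-exposure covariate rule, as in
#'   [fit_logistic()].
#' @return An object of class `pallor_model` (with `se` and t-based `p`).
#' @export
fit_linear <- function(data, measure, duration, covariates = pd_covariates(),
                       response = c("pallor", "duration"),
                       sd_reference = NULL,
                       drop_sparse = sparse_covariates(), min_exposed = 5) {
  response <- match.arg(response)
  covariates <- intersect(covariates, names(data))
  used_cols <- c(measure, duration, covariates)
  dm <- drop_missing_rows(data, used_cols)
  data <- dm$data

  dropped <- character(0)
  for (cv in intersect(drop_sparse, covariates)) {
    v <- as.logical(data[[cv]])
    if (min(sum(v), sum(!v)) < min_exposed) {
      covariates <- setdiff(covariates, cv)
      dropped <- c(dropped, cv)
    }
  }
  if (nrow(data) <= length(covariates) + 2)
    stop("too few observations (", nrow(data), ") for ",
         length(covariates) + 2, " parameters", call. = FALSE)

  bm <- build_model_frame(data, measure, covariates, sd_reference = sd_reference)
  mf <- bm$frame
  mf$duration <- data[[duration]]
  rhs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  form <- if (response == "pallor")
    stats::as.formula(paste("measure_z ~ duration", rhs))
  else
    stats::as.formula(paste("duration ~ measure_z", rhs))
  fit <- stats::lm(form, data = mf)
  sm <- summary(fit)
  term <- if (response == "pallor") "duration" else "measure_z"
  b <- sm$coefficients[term, "Estimate"]
  se <- sm$coefficients[term, "Std. Error"]
  p <- sm$coefficients[term, "Pr(>|t|)"]

  new_pallor_model(list(
    measure = measure, type = "linear",
    scale = if (response == "pallor") "sd_per_year" else "years_per_sd",
    estimate = b, coefficient = b, se = se,
    ci_low = b - 1.96 * se, ci_high = b + 1.96 * se, p = p,
    n = nrow(data), n_dropped_missing = dm$n_dropped,
    covariates = covariates, dropped_covariates = dropped,
    converged = TRUE, diagnostics = character(0),
    sd_of_measure = bm$sd_of_measure, fit = fit))
}

#' @export
print.pallor_model <- function(x, digits = 3, ...) {
  lab <- switch(x$scale,
                odds_ratio_per_sd = "OR per SD",
                sd_per_year = "beta (SD/year)",
                years_per_sd = "beta (years/SD)")
  cat(sprintf("%s model, measure '%s': %s = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$type, x$measure, lab, x$estimate, x$ci_low, x$ci_high, x$p))
  if (x$type == "logistic")
    cat(sprintf("  n = %d cases / %d controls", x$n_cases, x$n_controls))
  else cat(sprintf("  n = %d", x$n))
  cat(sprintf("; 1 SD of %s = %.3g\n", x$measure, x$sd_of_measure))
  if (length(x$dropped_covariates))
    cat("  covariates dropped (sparse exposure):",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  if (!x$converged)
    cat("  NOT CONVERGED:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pallor_model <- function(object, ...) {
  print(object)
  cat("\nfull coefficient table:\n")
  stats::printCoefmat(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.pallor_model <- function(object, ...) stats::coef(object$fit)

#' @export
confint.pallor_model <- function(object, ...) {
  ci <- c(object$ci_low, object$ci_high)
  names(ci) <- c("2.5 %", "97.5 %")
  ci
}

#' @export
predict.pallor_model <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.pallor_model <- function(object, ...) stats::residuals(object$fit, ...)

#' Tidy one-row summary of a fitted model
#'
#' @param model A `pallor_model`.
#' @return One-row data frame mirroring the reporting layout of the
#'   case-control tables (measure, 1 SD, estimate, CI, SE, p, n).
#' @export
model_row <- function(model) {
  data.frame(measure = model$measure, type = model$type, scale = model$scale,
             sd = model$sd_of_measure, estimate = model$estimate,
             se = model$se, ci_low = model$ci_low, ci_high = model$ci_high,
             p = model$p,
             n_cases = model$n_cases %||% NA_integer_,
             n_controls = model$n_controls %||% NA_integer_,
             n = model$n, converged = model$converged,
             stringsAsFactors = FALSE)
}

#' Age- and sex-matched control selection
#'
#' 1:`ratio` matching without replacement: exact on sex, greedy
#' nearest-neighbour on age, cases visited in random order under the given
#' seed. Balance is reported as the standardized mean difference (SMD) of age
#' before and after matching.
#'
#' @param cases,pool Data frames with the matching variables (and ideally an
#'   `id` column; row numbers are used otherwise).
#' @param vars Matching variables: numeric ones are matched nearest-neighbour,
#'   others exactly. Default age (nearest) and sex (exact).
#' @param ratio Controls per case.
#' @param seed Optional seed for the case visit order.
#' @return An object of class `match_result`: `pairs` (case_id, control_id),
#'   `balance`, and the selected control ids.
#' @export
match_controls <- function(cases, pool, vars = c("age", "sex"), ratio = 1,
                           seed = NULL) {
  for (v in vars) {
    if (!v %in% names(cases) || !v %in% names(pool))
      stop("matching variable '", v, "' missing", call. = FALSE)
  }
  if (nrow(pool) < ratio * nrow(cases))
    stop("control pool smaller than ratio x cases", call. = FALSE)
  num_vars <- vars[vapply(vars, function(v) is.numeric(cases[[v]]), logical(1))]
  ex_vars <- setdiff(vars, num_vars)
  case_id <- if ("id" %in% names(cases)) cases$id else paste0("case", seq_len(nrow(cases)))
  pool_id <- if ("id" %in% names(pool)) pool$id else paste0("ctrl", seq_len(nrow(pool)))

  stratum <- function(df) {
    if (length(ex_vars) == 0) rep("all", nrow(df))
    else do.call(paste, c(lapply(ex_vars, function(v) as.character(df[[v]])),
                          sep = "|"))
  }
  cs <- stratum(cases); ps <- stratum(pool)
  for (s in unique(cs)) {
    if (sum(ps == s) < ratio * sum(cs == s))
      stop("insufficient controls in stratum '", s, "': need ",
           ratio * sum(cs == s), ", have ", sum(ps == s), call. = FALSE)
  }

  order_idx <- local_seed(seed, sample.int(nrow(cases)))
  used <- rep(FALSE, nrow(pool))
  pairs <- vector("list", nrow(cases) * ratio)
  k <- 0L
  for (i in order_idx) {
    cand <- which(!used & ps == cs[i])
    d <- if (length(num_vars))
      rowSums(abs(outer(rep(1, length(cand)), unlist(cases[i, num_vars])) -
                    as.matrix(pool[cand, num_vars, drop = FALSE])))
    else rep(0, length(cand))
    sel <- cand[order(d)][seq_len(ratio)]
    used[sel] <- TRUE
    for (s in sel) {
      k <- k + 1L
      pairs[[k]] <- data.frame(case_id = case_id[i], control_id = pool_id[s],
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  matched <- pool[used, , drop = FALSE]

  smd <- function(a, b) {
    s <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(s) || s == 0) 0 else (mean(a) - mean(b)) / s
  }
  balance <- do.call(rbind, lapply(num_vars, function(v)
    data.frame(variable = v,
               smd_before = smd(cases[[v]], pool[[v]]),
               smd_after = smd(cases[[v]], matched[[v]]))))

  structure(list(pairs = pairs, balance = balance,
                 control_ids = pool_id[used], matched = matched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("matched %d pairs (1:1 without replacement)\n", nrow(x$pairs)))
  if (!is.null(x$balance)) print(x$balance, row.names = FALSE)
  invisible(x)
}

#' Two-group comparison of a study variable
#'
#' Welch t-test when the variable is continuous; chi-squared on the 2x2 table
#' when both the grouping and the variable are dichotomous. The continuity
#' handling of the 2x2 test is explicit in the configuration.
#'
#' @param table Data frame.
#' @param variable Column to compare.
#' @param group Grouping column name (default `"group"`).
#' @param groups The two group levels to compare.
#' @param continuity_correction Yates correction for the 2x2 chi-squared
#'   (default `FALSE`).
#' @return List: `method`, `statistic`, `p`, and group summaries.
#' @export
compare_groups <- function(table, variable, group = "group",
                           groups = NULL,
                           continuity_correction = FALSE) {
  g <- table[[group]]
  if (is.null(groups)) groups <- unique(g)[1:2]
  sub <- table[g %in% groups, , drop = FALSE]
  gv <- factor(sub[[group]], levels = groups)
  v <- sub[[variable]]
  if (is.numeric(v) && length(unique(v)) > 2) {
    tt <- stats::t.test(v ~ gv)
    list(method = "welch_t", statistic = unname(tt$statistic), p = tt$p.value,
         means = tapply(v, gv, mean))
  } else if (is.logical(v) || length(unique(stats::na.omit(v))) <= 2) {
    tab <- table(gv, factor(v))
    if (any(dim(tab) != 2) || identical(tab[1, ], tab[2, ])) {
      # degenerate or identical rows: chi-squared statistic 0, p = 1
      if (any(dim(tab) != 2))
        return(list(method = "chisq", statistic = 0, p = 1, table = tab))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity_correction))
    list(method = "chisq", statistic = unname(ct$statistic), p = ct$p.value,
         table = tab, continuity_correction = continuity_correction)
  } else {
    stop("variable '", variable, "' is neither continuous nor dichotomous",
         call. = FALSE)
  }
}

#' Sensitivity-analysis battery
#'
#' Refits a base model after each exclusion scenario and reports how the
#' estimate and its significance move. A scenario that empties a group (or
#' leaves too few rows to fit) is flagged and skipped rather than fitted.
#'
#' @param data Participant data frame.
#' @param base Named list describing the base fit: `type` (`"logistic"` or
#'   `"linear"`) plus the arguments of [fit_logistic()] / [fit_linear()].
#' @param scenarios Named list of exclusion predicates (one-sided formulas or
#'   logical column names, as in [apply_exclusions()]); rows where the
#'   predicate is `TRUE` are removed.
#' @param alpha Significance level used in the comparison table.
#' @return An object of class `sensitivity_result`: `base` model, `models`
#'   per scenario, and a `comparison` data frame.
#' @export
run_sensitivity <- function(data, base, scenarios = list(), alpha = 0.05) {
  fit_one <- function(d) {
    args <- base[setdiff(names(base), "type")]
    args$data <- d
    do.call(if (base$type == "logistic") fit_logistic else fit_linear, args)
  }
  base_model <- fit_one(data)
  models <- list()
  rows <- list(cbind(scenario = "base", n_removed = 0L,
                     model_row(base_model), skipped = FALSE))
  for (nm in names(scenarios)) {
    ex <- apply_exclusions(data, scenarios[nm])
    d2 <- ex$table
    removed <- ex$log$n_removed[1]
    skipped <- FALSE
    m <- NULL
    if (base$type == "logistic") {
      y <- as.logical(d2[[base$outcome]])
      if (length(unique(stats::na.omit(y))) < 2) skipped <- TRUE
    }
    if (!skipped) {
      m <- tryCatch(fit_one(d2), error = function(e) NULL)
      skipped <- is.null(m)
    }
    models[[nm]] <- m
    row <- if (skipped) {
      na_row <- model_row(base_model)
      na_row[, !vapply(na_row, is.character, logical(1))] <- NA
      na_row$measure <- base_model$measure
      cbind(scenario = nm, n_removed = removed, na_row, skipped = TRUE)
    } else {
      cbind(scenario = nm, n_removed = removed, model_row(m), skipped = FALSE)
    }
    rows[[length(rows) + 1]] <- row
  }
  comparison <- do.call(rbind, rows)
  comparison$significant <- !is.na(comparison$p) & comparison$p < alpha
  comparison$estimate_shift <- comparison$estimate - base_model$estimate
  rownames(comparison) <- NULL
  structure(list(base = base_model, models = models, comparison = comparison,
                 alpha = alpha),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, digits = 3, ...) {
  cat("sensitivity analysis (base measure:", x$base$measure, ")\n")
  cols <- c("scenario", "n_removed", "estimate", "ci_low", "ci_high", "p",
            "significant", "skipped")
  df <- x$comparison[, cols]
  df[3:6] <- lapply(df[3:6], function(v) round(as.numeric(v), digits))
  print(df, row.names = FALSE)
  invisible(x)
}
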