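# Synthetic matched case-control cohort generator with known effect sizes.

arm_defaults <- function() {
  list(
    control = list(age = c(62.7, 5.25), female = 148 / 381,
                   ethnicity = c(White = 368, Black = 3, South_Asian = 6,
                                 Other_Mixed = 4) / 381,
                   hypertension = 130 / 381, diabetes = 19 / 381,
                   cataract = 19 / 381, eye_surgery = 21 / 381,
                   disc_area = c(25200, 5370)),
    prevalent_pd = list(age = c(61.1, 6.29), female = 36 / 89,
                        ethnicity = c(White = 83, Black = 1, South_Asian = 3,
                                      Other_Mixed = 2) / 89,
                        hypertension = 26 / 89, diabetes = 2 / 89,
                        cataract = 5 / 89, eye_surgery = 5 / 89,
                        disc_area = c(25000, 5110)),
    incident_pd = list(age = c(62.9, 5.05), female = 123 / 317,
                       ethnicity = c(White = 292, Black = 9, South_Asian = 11,
                                     Other_Mixed = 5) / 317,
                       hypertension = 128 / 317, diabetes = 16 / 317,
                       cataract = 22 / 317, eye_surgery = 27 / 317,
                       disc_area = c(25400, 5870))
  )
}

default_pallor_moments <- function() {
  list(mean = c(global = 1.27, temporal = 1.41, temporal_inferior = 1.26,
                nasal_inferior = 1.12, nasal = 1.17, nasal_superior = 1.17,
                temporal_superior = 1.25, pmb = 1.44, nt_ratio = 0.84),
       sd = c(global = 0.23, temporal = 0.30, temporal_inferior = 0.23,
              nasal_inferior = 0.19, nasal = 0.20, nasal_superior = 0.19,
              temporal_superior = 0.26, pmb = 0.31, nt_ratio = 0.09))
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the covariate and pallor distributions of the study
#' population this generator emulates: a control arm, a prevalent-PD arm
#' (diagnosed before imaging, carrying years-since-diagnosis) and an
#' incident-PD arm (diagnosed after imaging, carrying years-to-diagnosis).
#' Case status is tied to the latent standardized pallor through configurable
#' log-odds per SD, so refitting recovers known truth.
#'
#' @param n_control,n_prevalent,n_incident Arm sizes.
#' @param arms Per-arm covariate distribution parameters; see the default
#'   structure (means/SDs for age and disc area, proportions otherwise).
#' @param pallor_mean,pallor_sd Control-arm mean and SD per pallor measure.
#' @param pallor_cor Common correlation between the nine standardized pallor
#'   measures (they share one annulus).
#' @param log_or_prevalent,log_or_incident Named vectors: true log-odds of
#'   case status per SD of the named measure(s).
#' @param duration_model `"years_per_sd"` (durations depend on pallor;
#'   duration is the modelled outcome, in years per SD) or `"sd_per_year"`
#'   (durations are drawn from the duration distribution and pallor receives
#'   a `slope x years` increment in control-SD units).
#' @param duration_slope_prevalent,duration_slope_incident Named vectors of
#'   true duration slopes on the scale set by `duration_model`.
#' @param duration_mean,duration_max Mean (exponential) and truncation of
#'   years since diagnosis.
#' @param duration_outlier_threshold,duration_outlier_frac Long-duration
#'   point mass: with probability `duration_outlier_frac` the duration is
#'   drawn uniformly between the threshold and `duration_max`.
#' @param duration_sd Residual SD of duration in the `"years_per_sd"` model.
#' @param duration_effect_min_years In `"sd_per_year"` mode, the pallor
#'   increment applies only to durations above this value (0 = all); used to
#'   construct cohorts whose duration effect is carried entirely by the
#'   long-duration tail.
#' @param incident_duration_mean,incident_duration_max Years-to-diagnosis
#'   distribution for the incident arm.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_control = 381, n_prevalent = 89, n_incident = 317,
                          arms = arm_defaults(),
                          pallor_mean = default_pallor_moments()$mean,
                          pallor_sd = default_pallor_moments()$sd,
                          pallor_cor = 0.8,
                          log_or_prevalent = c(global = log(1.39)),
                          log_or_incident = c(global = log(1.06)),
                          duration_model = c("years_per_sd", "sd_per_year"),
                          duration_slope_prevalent = c(global = 1.37),
                          duration_slope_incident = c(global = -0.11),
                          duration_mean = 5, duration_max = 25,
                          duration_outlier_threshold = 15,
                          duration_outlier_frac = 5 / 89,
                          duration_sd = 4.5,
                          duration_effect_min_years = 0,
                          incident_duration_mean = 5,
                          incident_duration_max = 14) {
  duration_model <- match.arg(duration_model)
  meas <- pallor_measures()
  stopifnot(all(meas %in% names(pallor_mean)), all(meas %in% names(pallor_sd)))
  if (any(pallor_sd[meas] <= 0)) stop("pallor SDs must be > 0", call. = FALSE)
  if (pallor_cor <= -1 / 8 || pallor_cor >= 1)
    stop("pallor_cor must give a positive-definite equicorrelation matrix",
         call. = FALSE)
  for (b in c(list(log_or_prevalent, log_or_incident,
                   duration_slope_prevalent, duration_slope_incident)))
    if (length(b) && !all(names(b) %in% meas))
      stop("effect names must be pallor measures", call. = FALSE)
  for (arm in names(arms)) {
    a <- arms[[arm]]
    pr <- c(a$female, a$ethnicity, a$hypertension, a$diabetes, a$cataract,
            a$eye_surgery)
    if (any(pr < 0 | pr > 1)) stop("proportions must be in [0, 1]", call. = FALSE)
    if (a$age[2] <= 0 || a$disc_area[2] <= 0) stop("SDs must be > 0", call. = FALSE)
  }
  structure(list(n_control = n_control, n_prevalent = n_prevalent,
                 n_incident = n_incident, arms = arms,
                 pallor_mean = pallor_mean[meas], pallor_sd = pallor_sd[meas],
                 pallor_cor = pallor_cor,
                 log_or_prevalent = log_or_prevalent,
                 log_or_incident = log_or_incident,
                 duration_model = duration_model,
                 duration_slope_prevalent = duration_slope_prevalent,
                 duration_slope_incident = duration_slope_incident,
                 duration_mean = duration_mean, duration_max = duration_max,
                 duration_outlier_threshold = duration_outlier_threshold,
                 duration_outlier_frac = duration_outlier_frac,
                 duration_sd = duration_sd,
                 duration_effect_min_years = duration_effect_min_years,
                 incident_duration_mean = incident_duration_mean,
                 incident_duration_max = incident_duration_max),
            class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("cohort params: %d controls, %d prevalent, %d incident; cor %.2f\n",
              x$n_control, x$n_prevalent, x$n_incident, x$pallor_cor))
  cat("  prevalent log-OR/SD:",
      paste(sprintf("%s=%.3f", names(x$log_or_prevalent), x$log_or_prevalent),
            collapse = " "), "\n")
  cat("  duration model:", x$duration_model, "\n")
  invisible(x)
}

effect_vector <- function(named, meas) {
  b <- stats::setNames(rep(0, length(meas)), meas)
  if (length(named)) b[names(named)] <- named
  b
}

# Draw durations: exponential (truncated at the outlier threshold) plus a
# configurable uniform point mass above the threshold.
draw_durations <- function(n, mean, max, threshold, outlier_frac) {
  rate <- 1 / mean
  out <- numeric(n)
  is_out <- stats::runif(n) < outlier_frac
  out[is_out] <- stats::runif(sum(is_out), threshold, max)
  u <- stats::runif(sum(!is_out)) * stats::pexp(threshold, rate)
  out[!is_out] <- stats::qexp(u, rate)
  pmax(out, 0.05)
}

# mvrnorm wrapper that always returns an n x p matrix (n = 0 or 1 included).
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  if (n == 0) return(matrix(numeric(0), 0, p))
  m <- MASS::mvrnorm(n, rep(0, p), Sigma)
  if (is.null(dim(m))) m <- matrix(m, 1, p)
  m
}

# Solve multinomial-logit intercepts so that the superpopulation fractions of
# the two case arms match their target shares; conditioning the multinomial
# logit on any {case arm, control} pair leaves the configured binary log-OR
# exact under retrospective (fixed-arm-size) sampling.
solve_intercepts <- function(z, bp, bi, fp, fi) {
  lp_p <- as.vector(z %*% bp)
  lp_i <- as.vector(z %*% bi)
  ap <- log(fp / (1 - fp - fi)); ai <- log(fi / (1 - fp - fi))
  for (k in 1:60) {
    ep <- exp(ap + lp_p); ei <- exp(ai + lp_i)
    den <- 1 + ep + ei
    ap <- ap + log(fp / mean(ep / den))
    ai <- ai + log(fi / mean(ei / den))
  }
  c(ap, ai)
}

#' Generate a synthetic participant table
#'
#' Draws the latent standardized pallor vector from a multivariate normal
#' with the configured correlation, assigns control / prevalent / incident
#' status through a multinomial-logit superpopulation whose pallor
#' coefficients equal the configured log-ORs (intercepts solved numerically
#' to hit the target arm fractions), draws covariates per arm from the
#' configured distributions, applies the configured duration mechanism, and
#' reports pallor on the natural scale (control mean/SD applied).
#'
#' @param params A [cohort_params()].
#' @param seed Optional integer seed.
#' @return Data frame, one row per participant: `id`, `group`, covariates,
#'   `years_since_dx` (prevalent only), `years_to_dx` (incident only) and the
#'   nine pallor measures. The generating parameters are attached as
#'   `attr(, "params")`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  local_seed(seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(params) {
  meas <- pallor_measures()
  p <- length(meas)
  Sigma <- matrix(params$pallor_cor, p, p); diag(Sigma) <- 1
  bp <- effect_vector(params$log_or_prevalent, meas)
  bi <- effect_vector(params$log_or_incident, meas)
  n_arm <- c(control = params$n_control, prevalent_pd = params$n_prevalent,
             incident_pd = params$n_incident)
  total <- sum(n_arm)
  if (total < 1) stop("empty cohort requested", call. = FALSE)

  null_effects <- all(bp == 0) && all(bi == 0)
  z_by_arm <- list()
  if (null_effects || params$n_control == 0) {
    for (arm in names(n_arm))
      z_by_arm[[arm]] <- rmvn(n_arm[[arm]], Sigma)
  } else {
    fp <- n_arm[["prevalent_pd"]] / total
    fi <- n_arm[["incident_pd"]] / total
    if (fp + fi >= 1) stop("case fractions must leave room for controls", call. = FALSE)
    zs <- rmvn(20000, Sigma)
    al <- solve_intercepts(zs, bp, bi, max(fp, 1e-9), max(fi, 1e-9))
    need <- n_arm
    got <- list(control = NULL, prevalent_pd = NULL, incident_pd = NULL)
    for (round in 1:40) {
      if (all(vapply(names(need), function(a) NROW(got[[a]]) >= need[[a]],
                     logical(1)))) break
      zpool <- rmvn(max(4 * total, 2000), Sigma)
      ep <- exp(al[1] + as.vector(zpool %*% bp))
      ei <- exp(al[2] + as.vector(zpool %*% bi))
      den <- 1 + ep + ei
      u <- stats::runif(nrow(zpool))
      status <- ifelse(u < ep / den, "prevalent_pd",
                       ifelse(u < (ep + ei) / den, "incident_pd", "control"))
      for (arm in names(got))
        got[[arm]] <- rbind(got[[arm]], zpool[status == arm, , drop = FALSE])
    }
    for (arm in names(n_arm)) {
      if (NROW(got[[arm]]) < n_arm[[arm]])
        stop("unattainable arm allocation for ", arm,
             " (case fraction not reachable)", call. = FALSE)
      z_by_arm[[arm]] <- got[[arm]][seq_len(n_arm[[arm]]), , drop = FALSE]
    }
  }

  rows <- lapply(names(n_arm), function(arm) {
    n <- n_arm[[arm]]
    if (n == 0) return(NULL)
    a <- params$arms[[arm]]
    z <- z_by_arm[[arm]]
    colnames(z) <- meas
    eth <- sample(names(a$ethnicity), n, replace = TRUE, prob = a$ethnicity)
    df <- data.frame(
      group = arm,
      age = stats::rnorm(n, a$age[1], a$age[2]),
      sex = ifelse(stats::runif(n) < a$female, "female", "male"),
      ethnicity = eth,
      ethnicity_white = eth == "White",
      hypertension = stats::runif(n) < a$hypertension,
      diabetes = stats::runif(n) < a$diabetes,
      cataract = stats::runif(n) < a$cataract,
      eye_surgery = stats::runif(n) < a$eye_surgery,
      disc_area = stats::rnorm(n, a$disc_area[1], a$disc_area[2]),
      years_since_dx = NA_real_, years_to_dx = NA_real_,
      stringsAsFactors = FALSE)

    if (arm == "prevalent_pd") {
      slope <- effect_vector(params$duration_slope_prevalent, meas)
      if (params$duration_model == "sd_per_year") {
        yrs <- draw_durations(n, params$duration_mean, params$duration_max,
                              params$duration_outlier_threshold,
                              params$duration_outlier_frac)
        eff <- ifelse(yrs > params$duration_effect_min_years, yrs, 0)
        z <- z + outer(eff, slope)
      } else {
        yrs <- params$duration_mean + as.vector(z %*% slope) +
          stats::rnorm(n, 0, params$duration_sd)
        yrs <- pmin(pmax(yrs, 0.05), params$duration_max)
      }
      df$years_since_dx <- yrs
    }
    if (arm == "incident_pd") {
      slope <- effect_vector(params$duration_slope_incident, meas)
      if (params$duration_model == "sd_per_year") {
        yrs <- draw_durations(n, params$incident_duration_mean,
                              params$incident_duration_max,
                              params$incident_duration_max + 1, 0)
        eff <- yrs
        z <- z + outer(eff, slope)
      } else {
        yrs <- params$incident_duration_mean + as.vector(z %*% slope) +
          stats::rnorm(n, 0, params$duration_sd)
        yrs <- pmin(pmax(yrs, 0.05), params$incident_duration_max)
      }
      df$years_to_dx <- yrs
    }
    nat <- sweep(sweep(z, 2, params$pallor_sd[meas], "*"), 2,
                 params$pallor_mean[meas], "+")
    nat <- pmax(nat, 0.01)
    cbind(df, as.data.frame(nat))
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("p%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- params
  out
}

#' Apply exclusion rules to a participant table
#'
#' Rules are applied in their declared order; each removes the rows where its
#' predicate is `TRUE` (`NA` counts as not excluded) and the per-rule removal
#' counts are logged, mirroring a sample-derivation flowchart.
#'
#' @param table Participant data frame.
#' @param rules Named list; each element either the name of a logical column
#'   or a one-sided formula, e.g. `~ years_since_dx > 15`.
#' @return List: `table` (filtered), `log` (rule, n_removed, n_remaining).
#' @export
apply_exclusions <- function(table, rules = list()) {
  log <- data.frame(rule = character(0), n_removed = integer(0),
                    n_remaining = integer(0))
  if (length(rules) == 0) return(list(table = table, log = log))
  if (is.null(names(rules)) || any(names(rules) == ""))
    names(rules) <- vapply(seq_along(rules), function(i)
      if (!is.null(names(rules)) && nzchar(names(rules)[i])) names(rules)[i]
      else paste0("rule", i), character(1))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (inherits(r, "formula")) {
      vars <- all.vars(r)
      missing_vars <- setdiff(vars, names(table))
      if (length(missing_vars))
        stop("exclusion rule '", nm, "' references unknown column(s): ",
             paste(missing_vars, collapse = ", "), call. = FALSE)
      flag <- eval(r[[2]], envir = table)
    } else {
      if (!r %in% names(table))
        stop("exclusion rule '", nm, "' references unknown column: ", r,
             call. = FALSE)
      flag <- table[[r]]
    }
    flag <- !is.na(flag) & as.logical(flag)
    table <- table[!flag, , drop = FALSE]
    log <- rbind(log, data.frame(rule = nm, n_removed = sum(flag),
                                 n_remaining = nrow(table)))
  }
  rownames(table) <- NULL
  list(table = table, log = log)
}
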