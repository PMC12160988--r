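# Matching, standardization, adjusted models, comparisons, sensitivity.

test_that("standardize uses the population-SD convention", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), sqrt(2 / 3), tolerance = 1e-12)

  already <- as.numeric(standardize(rnorm(50)))
  expect_equal(as.numeric(standardize(already)), already, tolerance = 1e-9)
  expect_equal(mean(as.numeric(standardize(runif(100)))), 0, tolerance = 1e-9)

  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("the logistic fit equals a brute-force Newton reference", {
  d <- make_toy_glm_table(n = 30, seed = 42)
  d$global <- d$measure
  m <- fit_logistic(d, "case", "global",
                    covariates = c("age", "sexfemale", "hyp"),
                    drop_sparse = character(0))
  ref <- oracle_logistic(toy_design(d), as.numeric(d$case))
  expect_equal(unname(coef(m)), unname(ref), tolerance = 1e-6)
  expect_equal(m$estimate, exp(ref[2]), tolerance = 1e-6)
  expect_true(m$ci_low <= m$estimate && m$estimate <= m$ci_high)
})

test_that("perfect separation is reported, not silently estimated", {
  d <- data.frame(global = c(1:10 / 10, 2 + 1:10 / 10),
                  case = rep(c(FALSE, TRUE), each = 10))
  m <- fit_logistic(d, "case", "global", covariates = character(0),
                    drop_sparse = character(0))
  expect_false(m$converged)
  expect_true(length(m$diagnostics) > 0)
})

test_that("the diabetes rule drops the covariate for sparse case exposure", {
  set.seed(8)
  n <- 400
  d <- data.frame(global = rnorm(n, 1.3, 0.25), age = rnorm(n, 62, 5),
                  sex = sample(c("male", "female"), n, TRUE),
                  ethnicity_white = TRUE,
                  hypertension = rbinom(n, 1, 0.35) == 1,
                  diabetes = FALSE, cataract = rbinom(n, 1, 0.3) == 1,
                  eye_surgery = rbinom(n, 1, 0.3) == 1,
                  disc_area = rnorm(n, 25000, 5000),
                  case = rep(c(TRUE, FALSE), n / 2))
  d$diabetes[d$case][1:2] <- TRUE    # two exposed cases only
  d$diabetes[!d$case][1:20] <- TRUE
  m <- fit_logistic(d, "case", "global")
  expect_true("diabetes" %in% m$dropped_covariates)
  expect_false("diabetes" %in% m$covariates)
  expect_true("hypertension" %in% m$covariates)
})

test_that("the linear fit matches closed-form OLS and is exact when noise-free", {
  # 3-point line: hand-computable OLS
  d3 <- data.frame(global = c(1.0, 1.2, 1.4), years_since_dx = c(0, 5, 10))
  m3 <- fit_linear(d3, "global", "years_since_dx", covariates = character(0),
                   response = "pallor", sd_reference = 1)
  # z = global - mean; slope = cov(y, z)/var(y) = 0.04
  expect_equal(m3$estimate, 0.04, tolerance = 1e-9)

  # noise-free y = 0.1 * years in z units, covariates present but inert
  set.seed(3)
  n <- 60
  d <- data.frame(years_since_dx = runif(n, 0, 20), age = rnorm(n, 62, 5),
                  sex = sample(c("male", "female"), n, TRUE),
                  disc_area = rnorm(n, 25000, 5000))
  d$global <- 1.2 + 0.23 * (0.1 * d$years_since_dx)
  m <- fit_linear(d, "global", "years_since_dx",
                  covariates = c("age", "sex", "disc_area"),
                  response = "pallor", sd_reference = 0.23)
  expect_equal(m$estimate, 0.1, tolerance = 1e-9)

  ref <- oracle_ols(cbind(1, d$years_since_dx), (d$global - mean(d$global)) / 0.23)
  m0 <- fit_linear(d, "global", "years_since_dx", covariates = character(0),
                   response = "pallor", sd_reference = 0.23)
  expect_equal(m0$estimate, ref[2], tolerance = 1e-9)

  expect_error(fit_linear(d[1:4, ], "global", "years_since_dx",
                          covariates = c("age", "sex", "disc_area"),
                          response = "pallor"), "too few")
})

test_that("duration slopes are null-calibrated in independent replicates", {
  set.seed(17)
  p <- cohort_params(n_control = 0, n_prevalent = 89, n_incident = 0,
                     log_or_prevalent = numeric(0), log_or_incident = numeric(0),
                     duration_model = "sd_per_year",
                     duration_slope_prevalent = numeric(0))
  hits <- replicate(200, {
    tab <- generate_cohort(p)
    m <- fit_linear(tab, "global", "years_since_dx", response = "pallor")
    abs(m$estimate) < 2 * m$se
  })
  expect_gte(mean(hits), 0.93)
})

test_that("group comparisons use Welch t and the stated chi-squared form", {
  d <- data.frame(group = rep(c("a", "b"), each = 20),
                  x = rep(c(TRUE, FALSE), 20))
  r <- compare_groups(d, "x")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  d2 <- data.frame(group = rep(c("a", "b"), c(20, 20)),
                   x = c(rep(c(TRUE, FALSE), c(10, 10)),
                         rep(c(TRUE, FALSE), c(20, 0))))
  r2 <- compare_groups(d2, "x")
  # hand-computed uncorrected chi-squared: n(ad-bc)^2 / row/col products
  expect_equal(r2$statistic, 40 * (10 * 0 - 10 * 20)^2 / (20 * 20 * 30 * 10),
               tolerance = 1e-9)

  set.seed(2)
  d3 <- data.frame(group = rep(c("a", "b"), each = 1000),
                   x = c(rnorm(1000, 0), rnorm(1000, 1)))
  expect_lt(compare_groups(d3, "x")$p, 1e-10)

  d4 <- data.frame(group = rep(c("a", "b"), each = 5),
                   x = letters[1:10])
  expect_error(compare_groups(d4, "x"), "neither")
})

test_that("matching is exact on sex, nearest on age, and improves balance", {
  set.seed(5)
  cases <- data.frame(id = paste0("c", 1:40), age = runif(40, 50, 70),
                      sex = rep(c("male", "female"), 20))
  # a pool holding an exact twin for every case
  twins <- cases; twins$id <- paste0("t", 1:40)
  filler <- data.frame(id = paste0("f", 1:60), age = runif(60, 40, 80),
                       sex = sample(c("male", "female"), 60, TRUE))
  pool <- rbind(twins, filler)
  mt <- match_controls(cases, pool, seed = 1)
  expect_equal(nrow(mt$pairs), 40)
  expect_equal(mt$balance$smd_after, 0, tolerance = 1e-9)
  expect_true(all(sort(mt$control_ids) == sort(twins$id)))

  # age-shifted pool: matching still shrinks the imbalance
  shifted <- data.frame(id = paste0("s", 1:200), age = runif(200, 55, 75),
                        sex = sample(c("male", "female"), 200, TRUE))
  mt2 <- match_controls(cases, shifted, seed = 1)
  expect_lt(abs(mt2$balance$smd_after), abs(mt2$balance$smd_before))
  expect_equal(length(mt2$control_ids), nrow(cases))
  expect_false(any(duplicated(mt2$control_ids)))

  all_male <- data.frame(id = paste0("m", 1:100), age = runif(100, 50, 70),
                         sex = "male")
  expect_error(match_controls(cases, all_male, seed = 1), "stratum 'female'")
})

test_that("sensitivity scenarios refit, and the long-duration tail drives the slope", {
  p <- cohort_params(n_control = 0, n_prevalent = 89, n_incident = 0,
                     log_or_prevalent = numeric(0), log_or_incident = numeric(0),
                     duration_model = "sd_per_year",
                     duration_slope_prevalent = c(global = 1.0),
                     duration_outlier_frac = 12 / 89,
                     duration_effect_min_years = 15)
  tab <- generate_cohort(p, seed = 19)
  # fixed SD unit so the base and refitted slopes share a scale
  base <- list(type = "linear", measure = "global",
               duration = "years_since_dx", response = "pallor",
               sd_reference = 0.23)

  empty <- run_sensitivity(tab, base)
  expect_equal(nrow(empty$comparison), 1)

  sens <- run_sensitivity(tab, base, scenarios = list(
    no_outliers = ~ years_since_dx > 15,
    noop = ~ years_since_dx > 1e6))
  cmp <- sens$comparison
  b0 <- cmp$estimate[cmp$scenario == "base"]
  b1 <- cmp$estimate[cmp$scenario == "no_outliers"]
  expect_lt(abs(b1), abs(b0) / 3)
  expect_gt(cmp$p[cmp$scenario == "no_outliers"], 0.05)
  expect_true(cmp$significant[cmp$scenario == "base"])
  expect_equal(cmp$estimate[cmp$scenario == "noop"], b0, tolerance = 1e-12)
})
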