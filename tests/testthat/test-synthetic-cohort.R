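# Cohort generator: moments, effect-size consistency, exclusions.

test_that("control-arm moments match the configured distributions", {
  n <- 30000
  tab <- generate_cohort(cohort_params(n_control = n, n_prevalent = 0,
                                       n_incident = 0), seed = 21)
  p <- attr(tab, "params")
  a <- p$arms$control
  mc3 <- function(sd) 3 * sd / sqrt(n)            # 3 Monte-Carlo SEs
  expect_lt(abs(mean(tab$age) - a$age[1]), mc3(a$age[2]))
  expect_lt(abs(mean(tab$sex == "female") - a$female), mc3(0.5))
  expect_lt(abs(mean(tab$hypertension) - a$hypertension), mc3(0.5))
  expect_lt(abs(mean(tab$diabetes) - a$diabetes), mc3(0.25))
  expect_lt(abs(mean(!tab$ethnicity_white) - 13 / 381), mc3(0.2))
  expect_lt(abs(mean(tab$disc_area) - a$disc_area[1]), mc3(a$disc_area[2]))
  for (m in pallor_measures()) {
    expect_lt(abs(mean(tab[[m]]) - p$pallor_mean[[m]]),
              mc3(p$pallor_sd[[m]]))
    expect_lt(abs(sd(tab[[m]]) - p$pallor_sd[[m]]), 0.01)
  }
  # configured cross-measure correlation
  expect_equal(cor(tab$global, tab$nasal), 0.8, tolerance = 0.02)
})

test_that("duration fields exist exactly for the matching arm and stay positive", {
  tab <- generate_cohort(cohort_params(n_control = 50, n_prevalent = 40,
                                       n_incident = 60), seed = 5)
  expect_true(all(is.na(tab$years_since_dx[tab$group != "prevalent_pd"])))
  expect_true(all(tab$years_since_dx[tab$group == "prevalent_pd"] > 0))
  expect_true(all(is.na(tab$years_to_dx[tab$group != "incident_pd"])))
  expect_true(all(tab$years_to_dx[tab$group == "incident_pd"] > 0))
  expect_true(all(as.matrix(tab[pallor_measures()]) > 0))
})

test_that("the long-duration point mass hits its configured rate", {
  p <- cohort_params(n_control = 0, n_prevalent = 20000, n_incident = 0,
                     log_or_prevalent = numeric(0), log_or_incident = numeric(0),
                     duration_model = "sd_per_year",
                     duration_slope_prevalent = numeric(0),
                     duration_outlier_frac = 5 / 89)
  tab <- generate_cohort(p, seed = 9)
  yrs <- tab$years_since_dx
  expect_lt(abs(mean(yrs > 15) - 5 / 89), 3 * sqrt(0.056 * 0.944 / 20000))
  expect_true(all(yrs <= 25))
})

test_that("a configured odds ratio is recovered by a large single fit", {
  p <- cohort_params(n_control = 5000, n_prevalent = 5000, n_incident = 0,
                     log_or_prevalent = c(global = log(1.5)))
  tab <- generate_cohort(p, seed = 31)
  tab$case <- tab$group == "prevalent_pd"
  m <- fit_logistic(tab, "case", "global")
  expect_true(m$converged)
  expect_equal(m$estimate, 1.5, tolerance = 0.05)
  expect_true(m$ci_low <= m$estimate && m$estimate <= m$ci_high)
})

test_that("null effects yield a null odds ratio in expectation", {
  set.seed(61)
  coefs <- replicate(150, {
    p <- cohort_params(n_control = 381, n_prevalent = 89, n_incident = 0,
                       log_or_prevalent = numeric(0),
                       log_or_incident = numeric(0))
    tab <- generate_cohort(p)
    tab$case <- tab$group == "prevalent_pd"
    fit_logistic(tab, "case", "global")$coefficient
  })
  expect_equal(exp(mean(coefs)), 1, tolerance = 0.04)
})

test_that("exclusion rules are ordered, logged and order-insensitive on disjoint flags", {
  tab <- generate_cohort(cohort_params(n_control = 10, n_prevalent = 0,
                                       n_incident = 0), seed = 2)
  same <- apply_exclusions(tab)
  expect_identical(same$table, tab)
  expect_equal(nrow(same$log), 0)

  tab$flag_a <- c(TRUE, TRUE, rep(FALSE, 8))
  tab$flag_b <- c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  ex <- apply_exclusions(tab, list(dementia = "flag_a"))
  expect_equal(nrow(ex$table), 8)
  expect_equal(ex$log$n_removed, 2)

  ab <- apply_exclusions(tab, list(a = "flag_a", b = "flag_b"))
  ba <- apply_exclusions(tab, list(b = "flag_b", a = "flag_a"))
  expect_setequal(ab$table$id, ba$table$id)

  expect_error(apply_exclusions(tab, list(x = "no_such_column")), "unknown column")
  expect_error(apply_exclusions(tab, list(x = ~ not_a_col > 1)), "unknown column")
  # formula rules work on derived conditions
  exf <- apply_exclusions(tab, list(young = ~ age < 60))
  expect_true(all(exf$table$age >= 60))
})

test_that("invalid cohort parameters are rejected", {
  sd_bad <- pallorkit:::default_pallor_moments()$sd
  sd_bad[["global"]] <- -1
  expect_error(cohort_params(pallor_sd = sd_bad), "SD")
  expect_error(cohort_params(pallor_cor = 1.2), "positive-definite")
  expect_error(cohort_params(log_or_prevalent = c(bogus = 0.5)), "measure")
  bad_arms <- pallorkit:::arm_defaults()
  bad_arms$control$female <- 1.4
  expect_error(cohort_params(arms = bad_arms), "proportions")
})
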