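test_that("one-parameter MLE matches a grid-search oracle of the closed form", {
  # 40 movers (1 -> 4 over one year) out of 100: closed-form likelihood
  # n11 * (-a) + n12 * log(1 - e^-a)
  n11 <- 60; n12 <- 40
  panel <- two_state_panel(n11, n12)
  prof <- function(la) panel_loglik(two_state_theta(exp(la), 0), panel)
  mle <- exp(stats::optimize(prof, c(-4, 1), maximum = TRUE, tol = 1e-9)$maximum)
  grid <- seq(0.05, 2, by = 1e-4)
  oracle <- grid[which.max(n11 * (-grid) + n12 * log(1 - exp(-grid)))]
  expect_equal(mle, oracle, tolerance = 1e-4)
})

test_that("fitting improves on the crude initial values and reports honestly", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 300, seed = 31))
  panel <- cohort$panel
  fit <- fit_mwm(panel)
  expect_s3_class(fit, "mwm_fit")
  expect_true(fit$converged)
  expect_gte(fit$loglik, panel_loglik(c(crude_init(panel)), panel))
  expect_identical(fit$n_subjects, 300L)
  expect_false(is.null(fit$vcov))
  expect_identical(dim(fit$vcov), c(14L, 14L))
  expect_equal(logLik(fit)[1], fit$loglik)
  expect_identical(length(coef(fit)), 14L)
})

test_that("a covariate that is constant zero leaves baseline intensities unchanged", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 250, seed = 33))
  panel <- cohort$panel
  panel$zero_cov <- 0L
  f0 <- fit_mwm(panel)
  f1 <- fit_mwm(as_mwm_panel(panel), covariates = "zero_cov")
  expect_lt(max(abs(f1$logq - f0$logq)), 1e-6)
})

test_that("intensity table applies the log-scale CI formula", {
  logq <- log(c(0.64, rep(0.3, 13)))
  V <- diag(c(0.1^2, rep(0.04, 13)))
  tab <- intensity_table(fake_fit(logq, vcov = V))
  expect_equal(tab$estimate[1], 0.64, tolerance = 1e-12)
  expect_equal(tab$lower[1], 0.64 * exp(-0.196), tolerance = 1e-12)
  expect_equal(tab$upper[1], 0.64 * exp(0.196), tolerance = 1e-12)
  # zero variance collapses the interval onto the estimate
  tab0 <- intensity_table(fake_fit(rep(0, 14), vcov = diag(0, 14)))
  expect_true(all(tab0$estimate == 1 & tab0$lower == 1 & tab0$upper == 1))
  # missing vcov: point estimates with absent intervals
  tabNA <- intensity_table(fake_fit(logq))
  expect_true(all(is.na(tabNA$lower)))
  expect_equal(tabNA$estimate[1], 0.64, tolerance = 1e-12)
})

test_that("sojourn table inverts the exit rate with delta-method intervals", {
  # make state 3 effectively single-edge with rate 0.26
  logq <- rep(-60, 14)
  logq[13] <- log(0.26)  # MHO -> MUO carries the whole exit rate
  fit <- fake_fit(logq, vcov = diag(0, 14))
  tab <- sojourn_table(fit)
  expect_identical(nrow(tab), 6L)
  expect_named(tab, c("state", "mean", "se", "lower", "upper"))
  expect_equal(tab$mean[3], 1 / 0.26, tolerance = 1e-6)
  expect_equal(tab$lower[3], tab$mean[3], tolerance = 1e-6)
  expect_equal(tab$upper[3], tab$mean[3], tolerance = 1e-6)
})

test_that("hazard-ratio table exponentiates coefficients and their intervals", {
  beta <- matrix(0, 14, 1, dimnames = list(NULL, "female"))
  beta[2, 1] <- log(2)
  V <- diag(c(rep(1e-6, 14), rep(0.1^2, 14)))
  fit <- fake_fit(rep(log(0.3), 14), beta = beta, covariates = "female",
                  vcov = V)
  tab <- hazard_ratio_table(fit)
  expect_identical(nrow(tab), 14L)
  row <- tab[tab$from == "MHOW" & tab$to == "MHNW", ]
  expect_equal(row$hr, 2, tolerance = 1e-12)
  expect_equal(row$lower, 2 * exp(-0.196), tolerance = 1e-12)
  ref <- tab[tab$from == "MHNW" & tab$to == "MHOW", ]
  expect_equal(ref$hr, 1, tolerance = 1e-12)
  expect_equal(ref$lower, exp(-0.196), tolerance = 1e-12)
  expect_equal(ref$upper, exp(0.196), tolerance = 1e-12)
  expect_error(hazard_ratio_table(fake_fit(rep(0, 14))), "no covariates")
})

test_that("fitted intensity CIs cover the generating values on most edges", {
  fx <- recovery_fixture()
  truth <- mwtrans:::edge_rates(fx$config$Q0)
  tab <- intensity_table(fx$fit)
  covered <- tab$lower <= truth & truth <= tab$upper
  expect_gte(sum(covered), 12L)
})

test_that("prediction and summary methods expose the fitted model", {
  fx <- recovery_fixture()
  pred <- predict(fx$fit, origin = "MHNW", horizon = 6)
  expect_identical(nrow(pred), 7L * 6L)
  expect_true(all(abs(tapply(pred$probability, pred$time, sum) - 1) < 1e-8))
  s <- summary(fx$fit)
  expect_s3_class(s, "summary.mwm_fit")
  expect_identical(nrow(s$intensities), 14L)
  expect_identical(nrow(s$sojourn), 6L)
  out <- capture.output(print(s))
  expect_true(any(grepl("sojourn", out, ignore.case = TRUE)))
})

test_that("stratified and univariable fits return one model per group", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 400, seed = 35))
  fits <- fit_stratified(cohort$panel, by = "female")
  expect_identical(length(fits), 2L)
  expect_true(all(vapply(fits, inherits, logical(1), "mwm_fit")))
  expect_identical(sum(vapply(fits, function(f) f$n_subjects, integer(1))),
                   400L)
})
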