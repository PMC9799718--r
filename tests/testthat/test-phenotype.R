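test_that("weight categories follow the BMI cut-offs with closed lower bounds", {
  expect_identical(classify_weight(c(21.48, 23.999, 24, 27.999, 28, 35)),
                   c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(classify_weight(18.4), "underweight")
  expect_error(classify_weight(NaN), "non-finite")
  # monotone non-decreasing in BMI
  bmi <- sort(runif(200, 18.5, 40))
  expect_true(all(diff(classify_weight(bmi)) >= 0))
})

test_that("metabolic status counts the four criteria with the stated sides", {
  # TG and HDL criteria met, count 2 -> unhealthy
  expect_identical(classify_metabolic("female", 118, 76, 5.2, 1.90, 1.01), 1L)
  # all-normal male medians -> healthy
  expect_identical(classify_metabolic("male", 114, 69, 5.18, 0.80, 1.41), 0L)
  # one criterion only -> still healthy
  expect_identical(classify_metabolic("male", 135, 80, 5.0, 1.0, 1.2), 0L)
  # medication counts as the blood-pressure criterion; FPG boundary is closed
  expect_identical(classify_metabolic("female", 110, 70, 5.6, 1.0, 1.5,
                                      on_antihypertensive = TRUE), 1L)
  # sex-specific HDL threshold: 1.2 is low for a female, normal for a male
  expect_identical(classify_metabolic("female", 110, 70, 5.6, 1.0, 1.2), 1L)
  expect_error(classify_metabolic("male", NA, 70, 5.0, 1.0, 1.2), "incomplete")
  expect_error(classify_metabolic("male", 110, 70, 5.0, 1.0, 1.2,
                                  require_pg2h = TRUE), "incomplete")
})

test_that("threshold boundaries classify on the stated sides", {
  # >= thresholds: value at threshold meets the criterion, just below does not
  expect_identical(classify_metabolic("male", 130, 70, 5.0, 1.69, 1.5), 0L)
  # SBP and DBP at threshold both feed the single blood-pressure criterion
  expect_identical(classify_metabolic("male", 130, 85, 5.0, 1.0, 1.5), 0L)
  expect_identical(classify_metabolic("male", 130, 70, 5.6, 1.0, 1.5), 1L)
  expect_identical(classify_metabolic("male", 129.9, 84.9, 5.6, 1.7, 1.5), 1L)
  # strict < for HDL: exactly 1.0 (male) is not low
  expect_identical(classify_metabolic("male", 130, 70, 5.0, 1.0, 1.0), 0L)
  expect_identical(classify_metabolic("male", 130, 70, 5.0, 1.0, 0.999), 1L)
})

test_that("adding a criterion never flips unhealthy back to healthy", {
  set.seed(42)
  for (i in 1:50) {
    sbp <- runif(1, 100, 160); dbp <- runif(1, 60, 100)
    fpg <- runif(1, 4.5, 7); tg <- runif(1, 0.5, 3); hdl <- runif(1, 0.7, 2)
    base <- classify_metabolic("male", sbp, dbp, fpg, tg, hdl)
    worse <- c(
      classify_metabolic("male", 140, dbp, fpg, tg, hdl),
      classify_metabolic("male", sbp, dbp, 6.5, tg, hdl),
      classify_metabolic("male", sbp, dbp, fpg, 2.5, hdl),
      classify_metabolic("male", sbp, dbp, fpg, tg, 0.8)
    )
    expect_true(all(worse >= base))
  }
})

test_that("phenotype classification is a bijection of the level grid", {
  grid <- expand.grid(w = 0:2, m = 0:1)
  idx <- classify_phenotype(grid$w, grid$m)
  expect_setequal(idx, 1:6)
  expect_identical(classify_phenotype(0, 0), 1L)
  expect_identical(mwt_states()[classify_phenotype(1, 0)], "MHOW")
  expect_identical(mwt_states()[classify_phenotype(2, 1)], "MUO")
  expect_error(classify_phenotype(3, 0), "invalid")
})

test_that("covariate dichotomization uses strict thresholds", {
  z <- dichotomize_covariates("male", 45, 40, 40, 133, 420)
  expect_true(all(z == 0))
  z <- dichotomize_covariates("female", 46, 41, 40, 100, 361)
  expect_identical(unlist(z[, c("female", "middle_aged", "alt_elevated",
                                "ua_elevated")], use.names = FALSE),
                   c(1L, 1L, 1L, 1L))
  # sex-specific creatinine: 107 is elevated for a female, not for a male
  expect_identical(dichotomize_covariates("female", 30, 20, 20, 107, 300)$scr_elevated, 1L)
  expect_identical(dichotomize_covariates("male", 30, 20, 20, 107, 300)$scr_elevated, 0L)
})

test_that("classify_checkups augments records and honours column mapping", {
  rec <- normal_record()
  rec2 <- rec
  names(rec2)[names(rec2) == "fpg"] <- "glucose"
  out <- classify_checkups(rec2, col_map = c(fpg = "glucose"))
  expect_identical(out$state, 1L)
  expect_identical(out$phenotype, "MHNW")
  expect_identical(out$weight_level, 0L)
  expect_true(all(c(mwt_covariates()) %in% names(out)))
  expect_error(classify_checkups(rec[, -5]), "missing columns")
})

test_that("mg/dL inputs can be converted on load", {
  rec <- normal_record()
  rec$fpg <- rec$fpg * 18.016
  rec$tg <- rec$tg * 88.57
  rec$hdl <- rec$hdl * 38.67
  path <- tempfile(fileext = ".csv")
  write_checkups(rec, path)
  back <- read_checkups(path, units_mgdl = TRUE)
  expect_equal(back$fpg, 5.18, tolerance = 1e-8)
  expect_equal(back$tg, 0.8, tolerance = 1e-8)
  expect_identical(classify_checkups(back)$state, 1L)
})
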