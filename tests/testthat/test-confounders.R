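test_that("covariate standardization uses the sample-SD convention and flags constants", {
  tab <- data.frame(x = c(1, 2, 3), const = c(5, 5, 5))
  z <- standardize_covariates(tab)
  expect_equal(z$x, c(-1, 0, 1))
  expect_null(z$const)
  expect_equal(attr(z, "dropped"), "const")
  z2 <- standardize_covariates(data.frame(x = z$x))
  expect_equal(z2$x, z$x, tolerance = 1e-12)
})

test_that("a noiseless single-covariate regression recovers beta = 1", {
  set.seed(20)
  covs <- data.frame(age = rnorm(50, 60, 7))
  dsc <- 0.5 + 0.2 * (covs$age - mean(covs$age)) / sd(covs$age)
  rep <- suppressWarnings(fit_dsc_regression(dsc, covs))
  expect_equal(rep$beta_std, 1, tolerance = 1e-8)
  expect_lt(rep$p_value, 1e-8)
})

test_that("injected orthogonal effects are recovered on the standardized scale", {
  set.seed(21)
  errs <- replicate(20, {
    z1 <- rnorm(200); z2 <- rnorm(200)
    # residual SD chosen so the outcome has unit variance
    y <- 0.5 * z1 - 0.3 * z2 + rnorm(200, 0, sqrt(1 - 0.25 - 0.09))
    rep <- fit_dsc_regression(y, data.frame(x1 = z1, x2 = z2))
    c(rep$beta_std[rep$covariate == "x1"] - 0.5,
      rep$beta_std[rep$covariate == "x2"] + 0.3)
  })
  # each estimate carries sampling error ~ sqrt((1-R^2)/n) ~ 0.057 at n=200,
  # so mean-level recovery is the meaningful check, with a 3.5-sigma bound on
  # any single replicate
  expect_lt(max(abs(rowMeans(errs))), 0.1)
  expect_lt(max(abs(errs)), 0.2)
})

test_that("under the null the regression keeps a nominal false-positive rate", {
  set.seed(22)
  fp <- 0; tot <- 0
  for (r in 1:20) {
    covs <- do.call(rbind, lapply(1:100, function(i)
      sample_covariates(if (i <= 50) "A" else "B", "M", id = sprintf("S%03d", i))))
    dsc <- 0.85 + rnorm(100, 0, 0.05)
    rep <- fit_dsc_regression(dsc, covs)
    fp <- fp + sum(rep$p_value < 0.05, na.rm = TRUE)
    tot <- tot + sum(!is.na(rep$p_value))
  }
  expect_gt(fp / tot, 0.01)
  expect_lt(fp / tot, 0.12)
})

test_that("univariate mode and zero-variance flagging work together", {
  set.seed(23)
  covs <- data.frame(x = rnorm(60), flat = rep(2, 60))
  y <- 0.3 * covs$x + rnorm(60, 0, 0.5)
  rep <- fit_dsc_regression(y, covs, mode = "univariate")
  expect_equal(nrow(rep), 1)
  expect_match(attr(rep, "notes"), "flat")
})

test_that("cohort characteristic tests mirror two-sample t-tests per covariate", {
  set.seed(24)
  base <- data.frame(subject_id = sprintf("S%02d", 1:20), group = "A",
                     sex = "M", bmi = rnorm(20, 27, 4))
  twin <- base; twin$group <- "B"; twin$subject_id <- sprintf("T%02d", 1:20)
  tab <- cohort_characteristic_tests(rbind(base, twin))
  expect_equal(tab$p_value[tab$covariate == "bmi"], 1)   # identical groups
  expect_false(tab$significant[tab$covariate == "bmi"])

  # group means/SDs reproduce the generator parameters at large n
  covs <- do.call(rbind, lapply(1:400, function(i)
    sample_covariates(if (i <= 200) "A" else "B", "M", id = sprintf("S%03d", i))))
  tab2 <- cohort_characteristic_tests(covs)
  bmi_row <- tab2[tab2$covariate == "bmi", ]
  expect_equal(bmi_row$mean_a, 26.9, tolerance = 0.05)
  expect_equal(bmi_row$mean_b, 28.6, tolerance = 0.05)
  expect_equal(bmi_row$sd_a, 4.6, tolerance = 0.2)
})

test_that("the published BMI group difference is detected in most replicates", {
  sig <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    covs <- do.call(rbind, lapply(1:436, function(i)
      sample_covariates(if (i <= 218) "A" else "B", "M", id = sprintf("S%04d", i))))
    tab <- cohort_characteristic_tests(covs)
    sig <- sig + tab$significant[tab$covariate == "bmi"]
  }
  expect_gte(sig, 18)
})

test_that("mechanism-simulated DSC outcomes stay in (0,1) and track the effects", {
  set.seed(25)
  covs <- do.call(rbind, lapply(1:150, function(i)
    sample_covariates(if (i <= 75) "A" else "B", "M", id = sprintf("S%03d", i))))
  dsc <- simulate_dsc_outcomes(covs, c(mri_year = -0.4), noise_sd = 0.03)
  expect_true(all(dsc > 0 & dsc < 1))
  expect_lt(cor(dsc, covs$mri_year), 0)
  expect_error(simulate_dsc_outcomes(covs, c(nonexistent = 1)))
})
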