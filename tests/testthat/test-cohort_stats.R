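test_that("ROI means average unflagged voxels per label", {
  maps <- std_maps()
  ph <- std_phantom()
  # uniform synthetic map: mean recovered exactly
  m2 <- maps
  m2$fa[] <- 0.3
  rm <- roi_means(m2, ph$labels)
  expect_true(all(abs(rm$FA - 0.3) < 1e-12))

  # half 0.2 / half 0.4 averages to 0.3; flagged voxels are excluded
  m3 <- list(fa = array(c(rep(0.2, 16), rep(0.4, 16), rep(0, 32)), c(4, 4, 4)),
             md = array(0.1, c(4, 4, 4)), d_ax = array(0.1, c(4, 4, 4)),
             d_rad = array(0.1, c(4, 4, 4)),
             flags = array(FALSE, c(4, 4, 4)), mask = array(TRUE, c(4, 4, 4)))
  lab2 <- array(0L, c(4, 4, 4)); lab2[, , 1:2] <- 1L
  rm3 <- roi_means(m3, lab2, roi_names = c(slab = 1L))
  expect_equal(rm3$FA, 0.3)
  m3f <- m3; m3f$flags[, , 1] <- TRUE  # drop the 0.2 half
  rm3f <- roi_means(m3f, lab2, roi_names = c(slab = 1L))
  expect_equal(rm3f$FA, 0.4)

  # empty ROI warns and yields NA
  expect_warning(rm4 <- roi_means(m3, lab2, roi_names = c(slab = 7L)),
                 "empty")
  expect_true(is.na(rm4$FA))

  # phantom CC-analog at SNR 20: mean MD within 2% of 0.074
  ph32 <- std_phantom()
  ser <- simulate_dwi(ph32, fixture("gt30", function()
    acquisition_scheme(30L, 3L, 4500, seed = 13L)))
  noisy <- add_rician_noise(ser, mean(ph32$s0[ph32$labels > 0]) / 20,
                            seed = 71)
  mm <- scalar_maps(fit_tensor(noisy))
  rm5 <- roi_means(mm, ph32$labels)
  expect_equal(rm5$MD[rm5$roi == "CC"], 0.074, tolerance = 0.02)
})

test_that("closed-form OLS matches lm and reports the printed df", {
  set.seed(31)
  x <- rnorm(20); y <- 2 + 3 * x
  f <- ols(y, cbind(x = x))
  expect_equal(f$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(f$df_residual, 18L)
  expect_equal(f$r_squared, 1)

  # 11 specimens on PMI + SI: residual df = 11 - 3 = 8
  co <- build_cohort(cohort_config(seed = 3))
  y11 <- rnorm(11)
  f11 <- ols(y11, cbind(PMI = co$pmi_hours, SI = co$si_months))
  expect_equal(f11$df_residual, 8L)

  # 5-point toy set against the independent lm oracle
  x5 <- c(0.1, 0.9, 1.7, 2.2, 3.3); z5 <- c(1, 0, 1, 0, 1)
  y5 <- c(2.2, 1.1, 4.0, 3.3, 5.1)
  mine <- ols(y5, cbind(a = x5, b = z5))
  ref <- stats::lm(y5 ~ x5 + z5)
  expect_equal(mine$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(mine$coefficients$se,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(mine$coefficients$p,
               unname(summary(ref)$coefficients[, 4]), tolerance = 1e-10)

  expect_error(ols(y5, cbind(a = x5, b = 2 * x5)), "collinear")
  expect_error(ols(y5[1:3], cbind(a = x5[1:3], b = z5[1:3])), "need n >")
})

test_that("cohort analysis recovers generated slopes and reporting rules", {
  co <- build_cohort(cohort_config(seed = 5))
  tab <- cohort_roi_table(co, noise_sd = 0)
  rep <- analyze_cohort(tab)

  # noiseless: Average-column MD slope equals the generator value exactly
  avg_md <- rep[rep$predictor == "PMI" & rep$index == "MD" &
                  rep$column == "Average", ]
  expect_equal(avg_md$slope_single, -0.0122, tolerance = 1e-6)
  expect_equal(avg_md$slope_multi, -0.0122, tolerance = 1e-6)
  expect_equal(avg_md$df_residual, 8L)
  expect_true(avg_md$significant)

  # D_ax slope likewise
  avg_dax <- rep[rep$predictor == "PMI" & rep$index == "D_ax" &
                   rep$column == "Average", ]
  expect_equal(avg_dax$slope_single, -0.0149, tolerance = 1e-6)

  # corrected p never below raw p; suppression rule produces NAs
  expect_true(all(rep$p_corrected >= rep$p_raw - 1e-15))
  noisy_rep <- analyze_cohort(cohort_roi_table(co, noise_sd = 0.5, seed = 2))
  expect_true(any(is.na(noisy_rep$reported)))

  # missing covariates are rejected with the specimen id
  tab_bad <- tab
  tab_bad$pmi_hours[3] <- NA
  expect_error(analyze_cohort(tab_bad), tab$specimen[3])
})

test_that("multiple regression equals single regressions for orthogonal predictors", {
  # construct exactly orthogonal centred predictors
  pmi <- c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2, 0)
  si <- c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1, 0)
  pmi <- pmi - mean(pmi); si <- si - mean(si)
  expect_equal(sum(pmi * si), 0)
  set.seed(41)
  y <- 1 + 0.5 * pmi - 0.2 * si + rnorm(11, 0, 0.1)
  multi <- ols(y, cbind(PMI = pmi, SI = si))
  s1 <- ols(y, cbind(PMI = pmi))
  s2 <- ols(y, cbind(SI = si))
  expect_equal(multi$coefficients$estimate[2], s1$coefficients$estimate[2],
               tolerance = 1e-10)
  expect_equal(multi$coefficients$estimate[3], s2$coefficients$estimate[2],
               tolerance = 1e-10)
})

test_that("corrected inference controls the family-wise false-positive rate", {
  # zero-slope cohorts: quick 100-replicate check (the 500-replicate run is
  # part of the acceptance suite)
  hits <- vapply(1:100, function(s) {
    co <- build_cohort(cohort_config(slope_md = 0, slope_dax = 0, seed = s))
    tab <- cohort_roi_table(co, noise_sd = 0.02, seed = s + 1000)
    rep <- analyze_cohort(tab)
    any(rep$significant[rep$predictor == "PMI"])
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
})
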