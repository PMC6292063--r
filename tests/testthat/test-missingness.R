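test_that("intercept calibration matches the closed-form logit when slopes are zero", {
  coh <- small_cohort(2000, seed = 21)
  targets <- data.frame(variable = "BMIz", wave = 1L, target = 0.25)
  slopes <- data.frame(variable = "BMIz", wave = 1L, slope1 = 0, slope2 = 0)
  m <- calibrate_intercepts(coh, mar_model(targets, slopes))
  expect_equal(m$intercept, log(0.25 / 0.75), tolerance = 1e-6)
})

test_that("a target of zero yields the never-missing sentinel", {
  coh <- small_cohort(200, seed = 22)
  targets <- data.frame(variable = "FamStruc", wave = 1:2,
                        target = c(0, 0))
  slopes <- data.frame(variable = "FamStruc", wave = 1:2,
                       slope1 = 0.5, slope2 = -0.4)
  m <- calibrate_intercepts(coh, mar_model(targets, slopes))
  expect_true(all(m$intercept == -Inf))
  out <- apply_mar(coh, m, seed = 1)
  expect_identical(out$data, coh$data)
})

test_that("intercept logit(0.5) with zero slopes masks half the cells", {
  n <- 100000
  coh <- generate_cohort(n, gen_params(), seed = 23)
  targets <- data.frame(variable = "BMIz", wave = 4L, target = 0.5)
  slopes <- data.frame(variable = "BMIz", wave = 4L, slope1 = 0, slope2 = 0)
  m <- calibrate_intercepts(coh, mar_model(targets, slopes))
  expect_equal(m$intercept, 0, tolerance = 1e-6)
  amp <- apply_mar(coh, m, seed = 24)
  frac <- mean(is.na(amp$data$BMIz_w4))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the calibrated default mechanism reproduces its target proportions on fresh data", {
  calib <- generate_cohort(10000, gen_params(), seed = 25)
  m <- calibrate_intercepts(calib, mar_model())
  fresh <- generate_cohort(5000, gen_params(), seed = 26)
  amp <- apply_mar(fresh, m, seed = 27)
  ms <- missingness_summary(amp)
  for (k in seq_len(nrow(m))) {
    tgt <- m$target[k]
    got <- ms$prop_missing[ms$variable == m$variable[k] & ms$wave == m$wave[k]]
    tol <- 3 * sqrt(max(tgt * (1 - tgt), 1e-12) / 5000) + 1e-9
    expect_lt(abs(got - tgt), tol + 0.01)  # calibration + binomial error
  }
  # outcome and baseline stay fully observed; wave-1 FamStruc never masked
  expect_false(anyNA(amp$data[c("sex", "language", "moedu", "SEP",
                                "FamStruc_w1",
                                paste0("QoLz_w", 1:6),
                                paste0("ageyr_w", 1:6))]))
})

test_that("analytic masking probabilities agree with the Monte-Carlo masked fraction", {
  coh <- small_cohort(5000, seed = 28)
  m <- calibrate_intercepts(coh, mar_model())
  amp <- apply_mar(coh, m, seed = 29)
  for (k in which(is.finite(m$intercept))[c(1, 5, 11)]) {
    p <- plogis(m$intercept[k] +
                  longmi:::mar_driver(coh, m$variable[k], m$wave[k],
                                      m$slope1[k], m$slope2[k]))
    col <- paste0(m$variable[k], "_w", m$wave[k])
    frac <- mean(is.na(amp$data[[col]]))
    expect_lt(abs(frac - mean(p)), 3 * sqrt(mean(p) * (1 - mean(p)) / 5000))
  }
})

test_that("increasing the QoL slope magnitude shifts masking toward low-QoL subjects", {
  coh <- small_cohort(4000, seed = 30)
  base_t <- data.frame(variable = "BMIz", wave = 6L, target = 0.3)
  weak <- calibrate_intercepts(coh, mar_model(base_t,
            data.frame(variable = "BMIz", wave = 6L, slope1 = 0, slope2 = 0)))
  strong <- calibrate_intercepts(coh, mar_model(base_t,
            data.frame(variable = "BMIz", wave = 6L, slope1 = 0, slope2 = -2)))
  low_qol <- coh$data$QoLz_w6 < median(coh$data$QoLz_w6)
  p_weak <- plogis(weak$intercept + 0 * coh$data$QoLz_w6)
  p_strong <- plogis(strong$intercept - 2 * coh$data$QoLz_w6)
  expect_gt(mean(p_strong[low_qol]), mean(p_weak[low_qol]))
  expect_lt(mean(p_strong[!low_qol]), mean(p_weak[!low_qol]))
})

test_that("missingness_summary counts exactly", {
  coh <- small_cohort(4, seed = 31)
  d <- coh$data
  d$BMIz_w3[2] <- NA
  amp <- cohort_table(d, 6)
  ms <- missingness_summary(amp)
  expect_equal(ms$prop_missing[ms$variable == "BMIz" & ms$wave == 3], 0.25)
  expect_equal(sum(ms$prop_missing), 0.25)
  full <- missingness_summary(coh)
  expect_true(all(full$prop_missing == 0))
})

test_that("state and parameter errors are raised", {
  coh <- small_cohort(100, seed = 32)
  m <- calibrate_intercepts(coh, mar_model())
  amp <- apply_mar(coh, m, seed = 33)
  expect_error(apply_mar(amp, m, seed = 34), "fully observed")
  expect_error(calibrate_intercepts(amp, mar_model()), "fully observed")
  expect_error(mar_model(data.frame(variable = "BMIz", wave = 1L, target = 1)),
               "\\[0, 1\\)")
  expect_error(mar_model(slopes = transform(default_mar_slopes(), slope1 = Inf)),
               "finite")
  expect_error(apply_mar(coh, mar_model(), seed = 1), "not calibrated")
})

test_that("monotone dropout masks all later waves once missing", {
  coh <- small_cohort(500, seed = 35)
  m <- calibrate_intercepts(coh, mar_model())
  amp <- apply_mar(coh, m, seed = 36, monotone_dropout = TRUE)
  bm <- is.na(as.matrix(amp$data[paste0("BMIz_w", 1:6)]))
  runs <- apply(bm, 1, function(z)
    identical(unname(as.logical(cummax(z))), unname(z)))
  expect_true(all(runs))
})

test_that("missingness model round-trips through its config file", {
  coh <- small_cohort(500, seed = 37)
  m <- calibrate_intercepts(coh, mar_model())
  f <- tempfile(fileext = ".yaml")
  write_mar_model(m, f)
  m2 <- read_mar_model(f)
  expect_equal(m$intercept, m2$intercept, tolerance = 1e-12)
  expect_equal(m$target, m2$target)
})
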