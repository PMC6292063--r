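test_that("cumulative-exposure categories count waves 1-5 correctly", {
  coh <- small_cohort(6, seed = 71)
  d <- coh$data
  # craft BMIz rows: 0, 1, 2, 3, 4, 5 waves above the cutoff
  for (i in 1:6)
    d[i, paste0("BMIz_w", 1:5)] <- c(rep(2, i - 1), rep(-2, 6 - i))
  cats <- derive_overwt_cat(cohort_table(d, 6), zcut = 1.04)
  expect_equal(as.character(cats), c("none", "1", "2", "3-4", "3-4", "5"))
  # family-structure variant
  d[1, paste0("FamStruc_w", 1:5)] <- c(1, 0, 0, 0, 1)
  d[2, paste0("FamStruc_w", 1:5)] <- 0
  fc <- derive_famst_cat(cohort_table(d, 6))
  expect_equal(as.character(fc[1:2]), c("2", "none"))
})

test_that("noiseless data yields exact coefficient recovery in model 1", {
  # QoLz collapses to its intercept when all slopes and variances vanish
  coh <- generate_cohort(80, noiseless_params(), seed = 72)
  est <- suppressWarnings(fit_model1(coh))
  expect_equal(est$estimate[est$term == "(Intercept)"], -0.04,
               tolerance = 1e-10)
})

test_that("model-1 OLS matches a normal-equations oracle on a small instance", {
  coh <- small_cohort(20, seed = 73)
  est <- suppressWarnings(fit_model1(coh))
  df <- longmi:::model1_frame(coh)
  for (v in c("OverWtCat", "FamStCat")) df[[v]] <- droplevels(df[[v]])
  X <- model.matrix(~ OverWtCat + ageyr_6 + sex + SEP + language + FamStCat,
                    data = df)
  beta <- solve(crossprod(X), crossprod(X, df$QoLz_6))
  expect_equal(unname(est$estimate), unname(drop(beta)), tolerance = 1e-8)
})

test_that("duplicating every subject leaves estimates fixed and shrinks SEs by ~sqrt(2)", {
  coh <- small_cohort(500, seed = 74)
  d2 <- rbind(coh$data, transform(coh$data, subject_id = subject_id + 1000))
  est1 <- suppressWarnings(fit_model1(coh))
  est2 <- suppressWarnings(fit_model1(cohort_table(d2, 6)))
  expect_equal(est1$estimate, est2$estimate, tolerance = 1e-10)
  expect_equal(est2$se / est1$se, rep(1 / sqrt(2), nrow(est1)),
               tolerance = 0.02)
})

test_that("the mixed model recovers the exposure effect and the ICC on complete data", {
  coh <- generate_cohort(5000, gen_params(), seed = 75)
  est <- fit_model2(coh)
  b <- est$estimate[est$term == "BMIz"]
  se <- est$se[est$term == "BMIz"]
  expect_lt(abs(b - (-0.12)), 3 * se)
  expect_lt(abs(attr(est, "icc") - 0.5), 0.05)
  expect_gt(attr(est, "ri_var"), 0)
})

test_that("zero random-intercept variance drives the REML estimate toward zero", {
  p <- gen_params(qolz_ri_var = 1e-12)
  coh <- generate_cohort(1500, p, seed = 76)
  est <- fit_model2(coh)
  expect_lt(attr(est, "ri_var"), 0.02)
})

test_that("Rubin pooling identities hold and match hand computation", {
  # three identical fits: B = 0, T = W, df capped at 1e9
  e <- data.frame(term = "x", estimate = 1.0, se = 0.2)
  p0 <- pool_rubin(list(e, e, e))
  expect_equal(p0$estimate, 1.0)
  expect_equal(p0$B, 0)
  expect_equal(p0$T, 0.04)
  expect_equal(p0$df, 1e9)
  expect_true(p0$ci_lo <= p0$estimate & p0$estimate <= p0$ci_hi)
  # m = 2 hand example
  e1 <- data.frame(term = "x", estimate = 1.0, se = 0.2)
  e2 <- data.frame(term = "x", estimate = 1.2, se = 0.2)
  p2 <- pool_rubin(list(e1, e2))
  expect_equal(p2$estimate, 1.1)
  expect_equal(p2$W, 0.04)
  expect_equal(p2$B, 0.02, tolerance = 1e-12)
  expect_equal(p2$T, 0.07, tolerance = 1e-12)
  expect_equal(p2$df, (1 + 0.04 / 0.03)^2, tolerance = 1e-10)
  expect_equal(p2$mcse, sqrt(0.02 / 2))
  # T >= W always on a fitted example
  amp <- small_amputed(200, seed = 77, mar_seed = 78)
  imp <- impute(amp, fast_config("FCS-Standard", m = 4), seed = 79)
  pr <- pool_rubin(fit_imputation_set(imp, model = 2))
  expect_true(all(pr$T >= pr$W))
  expect_true(all(pr$B >= 0))
  expect_true(all(pr$ci_lo <= pr$estimate & pr$estimate <= pr$ci_hi))
})

test_that("pooling errors on mismatched coefficient sets and m < 2", {
  e1 <- data.frame(term = "x", estimate = 1, se = 1)
  e2 <- data.frame(term = "y", estimate = 1, se = 1)
  expect_error(pool_rubin(list(e1, e2)), "mismatched")
  expect_error(pool_rubin(list(e1)), "at least 2")
})

test_that("Barnard-Rubin adjusted df never exceed the complete-data df", {
  e1 <- data.frame(term = "x", estimate = 1.0, se = 0.2)
  e2 <- data.frame(term = "x", estimate = 1.2, se = 0.2)
  pbr <- pool_rubin(list(e1, e2), dfcom = 100)
  expect_lt(pbr$df, 100)
  expect_lt(pbr$df, pool_rubin(list(e1, e2))$df)
})

test_that("available-data fits equal complete-data fits on fully observed cohorts", {
  coh <- small_cohort(800, seed = 80)
  expect_equal(available_data_fit(coh, 2)$estimate, fit_model2(coh)$estimate)
  expect_equal(suppressWarnings(available_data_fit(coh, 1))$estimate,
               suppressWarnings(fit_model1(coh))$estimate)
})

test_that("model 2 drops exactly the masked subject-wave rows", {
  coh <- small_cohort(50, seed = 81)
  d <- coh$data
  d$BMIz_w4[7] <- NA
  amp <- cohort_table(d, 6)
  long <- to_long(amp)
  kept <- complete.cases(long[c("QoLz", "BMIz", "ageyr", "FamStruc")])
  expect_equal(sum(!kept), 1)
  expect_silent(available_data_fit(amp, 2))
})

test_that("continuous imputed family structure is rounded before model-1 categories", {
  coh <- small_cohort(300, seed = 82)
  d <- coh$data
  d$FamStruc_w3 <- pmin(pmax(d$FamStruc_w3 +
                               withr::with_seed(83, rnorm(300, 0, 0.2)),
                             -0.4), 1.4)
  est <- suppressWarnings(fit_model1(cohort_table(d, 6)))
  expect_s3_class(est, "estimate_vector")
  rc <- longmi:::round_cohort_binaries(cohort_table(d, 6))
  expect_true(all(rc$data$FamStruc_w3 %in% 0:1))
})
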