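test_that("every engine preserves observed cells, fills all missing cells, and is seed-deterministic", {
  amp <- small_amputed(250, seed = 41, mar_seed = 42)
  obs <- !is.na(amp$data)
  for (method in all_methods) {
    imp <- impute(amp, fast_config(method), seed = 43)
    expect_s3_class(imp, "imputation_set")
    expect_equal(imp$m, 2)
    for (cc in imp$imputations) {
      expect_false(anyNA(cc$data))
      expect_identical(cc$data[obs], amp$data[obs])
    }
    # between-imputation variability exists where cells were imputed
    m1 <- as.matrix(imp$imputations[[1]]$data[-1])
    m2 <- as.matrix(imp$imputations[[2]]$data[-1])
    expect_gt(sum((m1 - m2)^2), 0)
    imp_b <- impute(amp, fast_config(method), seed = 43)
    expect_identical(imp$imputations[[2]]$data, imp_b$imputations[[2]]$data)
  }
})

test_that("a cohort with no missing cells is returned unchanged by any method", {
  coh <- small_cohort(120, seed = 44)
  for (method in c("JM-MVN", "FCS-Standard", "FCS-LMM")) {
    imp <- impute(coh, fast_config(method, m = 3), seed = 45)
    expect_equal(imp$m, 3)
    for (cc in imp$imputations) expect_identical(cc$data, coh$data)
  }
})

test_that("JM-MVN recovers cross-sectional correlation under 50% MCAR (conditional-normal oracle)", {
  coh <- generate_cohort(3000, gen_params(), seed = 46)
  d <- coh$data
  true_cor <- cor(d$BMIz_w6, d$QoLz_w6)
  hit <- withr::with_seed(47, runif(3000) < 0.5)
  d$BMIz_w6[hit] <- NA
  amp <- cohort_table(d, 6, shadow = coh$data)
  imp <- jm_mvn(amp, mi_config("JM-MVN", m = 10, burn_in = 50,
                               between_draws = 10), seed = 48)
  cors <- sapply(imp$imputations, function(cc)
    cor(cc$data$BMIz_w6, cc$data$QoLz_w6))
  expect_lt(abs(mean(cors) - true_cor), 0.05)
})

test_that("pooled means are unbiased under MCAR (pre-mask oracle)", {
  coh <- generate_cohort(2000, gen_params(), seed = 49)
  truth_mean <- mean(coh$data$BMIz_w6)
  d <- coh$data
  hit <- withr::with_seed(50, runif(2000) < 0.2)
  d$BMIz_w6[hit] <- NA
  amp <- cohort_table(d, 6, shadow = coh$data)
  for (method in c("JM-MVN", "FCS-Standard")) {
    imp <- impute(amp, mi_config(method, m = 10, burn_in = 50,
                                 between_draws = 10, fcs_cycles = 5),
                  seed = 51)
    ests <- lapply(imp$imputations, function(cc) {
      x <- cc$data$BMIz_w6
      data.frame(term = "mean", estimate = mean(x),
                 se = sd(x) / sqrt(length(x)))
    })
    pooled <- pool_rubin(ests)
    expect_lt(abs(pooled$estimate - truth_mean), 3 * pooled$se)
  }
})

test_that("chained-equations imputations of the binary indicator are 0/1", {
  amp <- small_amputed(300, seed = 52, mar_seed = 53)
  imp <- impute(amp, fast_config("FCS-Standard"), seed = 54)
  for (cc in imp$imputations)
    expect_true(all(as.matrix(cc$data[paste0("FamStruc_w", 1:6)]) %in% 0:1))
})

test_that("a full-width window reproduces the FCS-Standard predictor sets", {
  expect_identical(
    lapply(fcs_predictor_sets(6, window = 5), sort),
    lapply(fcs_predictor_sets(6, window = NULL), sort)
  )
  # window = 1 strictly restricts the wave-varying predictors
  w1 <- fcs_predictor_sets(6, window = 1)
  expect_true(all(c("BMIz_w3", "QoLz_w2", "sex") %in% w1[["BMIz_w2"]]))
  expect_false("BMIz_w5" %in% w1[["BMIz_w2"]])
  expect_false("QoLz_w6" %in% w1[["BMIz_w2"]])
})

test_that("PMM imputations are copied from observed donor values", {
  amp <- small_amputed(400, seed = 55, mar_seed = 56)
  imp <- impute(amp, fast_config("FCS-LMM-PMM"), seed = 57)
  for (v in c("BMIz", "FamStruc")) {
    cols <- paste0(v, "_w", 1:6)
    pool <- unlist(amp$data[cols]); pool <- pool[!is.na(pool)]
    got <- unlist(imp$imputations[[1]]$data[cols])[is.na(unlist(amp$data[cols]))]
    expect_true(all(got %in% pool))
  }
})

test_that("the univariate two-level Gibbs sampler recovers its own generating parameters", {
  # y_ij = 1 + 0.5 x_ij + b_i + e_ij with psi = 0.7, sigma2 = 0.5
  set.seed(58)
  n <- 400; J <- 6; N <- n * J
  sid <- rep(seq_len(n), each = J)
  x <- rnorm(N)
  b <- rnorm(n, 0, sqrt(0.7))
  y <- 1 + 0.5 * x + b[sid] + rnorm(N, 0, sqrt(0.5))
  mrows <- runif(N) < 0.2
  y_obs <- y; y_obs[mrows] <- mean(y[!mrows])
  X <- cbind(1, x)
  cfg <- mi_config("FCS-LMM", m = 2, gibbs_iters_per_visit = 1)
  state <- NULL
  draws <- matrix(NA_real_, 300, 3)
  for (it in 1:300) {
    state <- longmi:::lmm_gibbs_update(y_obs, X, sid, n, mrows, cfg,
                                       "homoscedastic", state)
    y_obs <- state$y
    draws[it, ] <- c(state$beta[2], state$psi[1, 1], state$sigma2)
  }
  post <- colMeans(draws[101:300, ])
  mcse <- apply(draws[101:300, ], 2, sd) / sqrt(50)  # conservative ESS
  expect_lt(abs(post[1] - 0.5), max(3 * mcse[1], 0.05))
  expect_lt(abs(post[2] - 0.7), max(3 * mcse[2], 0.10))
  expect_lt(abs(post[3] - 0.5), max(3 * mcse[3], 0.05))
})

test_that("the joint multilevel sampler recovers variances from self-generated responses", {
  base <- small_cohort(800, seed = 59)
  fr <- longmi:::mlmm_frame(base)
  set.seed(60)
  n <- 800; J <- 6
  Psi <- matrix(c(0.8, 0.3, 0.3, 0.6), 2)
  Sig <- matrix(c(0.5, 0.1, 0.1, 0.4), 2)
  b <- matrix(rnorm(n * 2), n) %*% chol(Psi)
  E <- matrix(rnorm(n * J * 2), n * J) %*% chol(Sig)
  Y <- b[fr$sid, ] + E          # fixed effects all zero
  d <- base$data
  d[paste0("BMIz_w", 1:6)] <- matrix(Y[, 1], n, J, byrow = TRUE)
  d[paste0("FamStruc_w", 1:6)] <- matrix(Y[, 2], n, J, byrow = TRUE)
  mask <- matrix(runif(n * J) < 0.2, n, J)
  d[paste0("BMIz_w", 1:6)][mask] <- NA
  amp <- cohort_table(d, 6)
  imp <- jm_mlmm(amp, mi_config("JM-MLMM", m = 2, burn_in = 150,
                                between_draws = 50), seed = 61)
  tr <- imp$diagnostics[101:250, ]
  expect_lt(abs(mean(tr$psi11) - 0.8), 0.15)
  expect_lt(abs(mean(tr$sig11) - 0.5), 0.05)
  expect_lt(abs(mean(tr$sig22) - 0.4), 0.05)
})

test_that("adaptive rounding follows its normal-approximation cutoff", {
  # symmetric case: cutoff exactly 0.5
  v <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(adaptive_round(v), c(0L, 0L, 1L, 1L))
  # construction: N(0.3, 0.3*0.7) rounds ~30% to 1
  x <- withr::with_seed(62, rnorm(2e5, 0.3, sqrt(0.3 * 0.7)))
  expect_lt(abs(mean(adaptive_round(x)) - 0.3), 0.01)
  expect_warning(out <- adaptive_round(rep(1.0, 5)), "all 1")
  expect_equal(out, rep(1L, 5))
  expect_error(adaptive_round(c(0.5, NA)), "finite")
})

test_that("configuration guards reject invalid settings", {
  expect_error(mi_config("NOPE"), "unknown method")
  expect_error(mi_config("JM-MVN", m = 1), "at least 2")
  expect_error(mi_config("FCS-MTW", window = 0), "window")
  amp <- small_amputed(150, seed = 63, mar_seed = 64)
  expect_error(jm_mlmm(amp, mi_config("JM-MLMM", m = 2, prior_df = 1)),
               "degrees of freedom")
})
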