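# Multilevel imputation engines operating on the long-format cohort.
#
# Shared model structure: subject-level random intercepts, inverse-Wishart
# priors (df = dimension, scale = identity by default) on random-effect and
# residual covariances, and binary variables treated as continuous.

# long-format design pieces shared by the multilevel engines
mlmm_frame <- function(cohort) {
  long <- to_long(cohort)
  J <- cohort$n_waves
  X <- cbind(1, cohort$data$ageyr_w1[match(long$subject_id,
                                           cohort$data$subject_id)],
             long$sex, long$SEP, long$language, long$QoLz)
  colnames(X) <- c("(Intercept)", "ageyr_w1", "sex", "SEP", "language", "QoLz")
  if (J > 1L) {
    wd <- outer(long$wave, 2:J, `==`) * 1
    colnames(wd) <- paste0("wave", 2:J)
    X <- cbind(X, wd)
  }
  sid <- match(long$subject_id, unique(long$subject_id))
  list(long = long, X = X, sid = sid, n = max(sid), J = J)
}

draw_scaled_invchisq <- function(df, scale_sum) scale_sum / stats::rchisq(1L, df)

#' Joint multivariate linear mixed-model imputation (JM-MLMM)
#'
#' Treats the bivariate subject-wave response (BMI z-score, family
#' structure) as jointly normal given fixed effects (baseline age, sex,
#' SEP, language, the QoL z-score, and wave indicators) and a subject-level
#' bivariate random intercept. A Gibbs sampler cycles through: the
#' fixed-effect matrix draw, per-subject random-effect draws, an
#' inverse-Wishart draw of the random-effect covariance, an inverse-Wishart
#' draw of the (constant across subjects) residual covariance, and draws of
#' the missing responses from their conditional normals. Binary family
#' structure is modelled as continuous.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @return an [imputation_set()].
#' @export
jm_mlmm <- function(cohort, config = mi_config("JM-MLMM"), seed = 1L) {
  fr <- mlmm_frame(cohort)
  X <- fr$X; sid <- fr$sid; n <- fr$n
  Y <- cbind(BMIz = fr$long$BMIz, FamStruc = fr$long$FamStruc)
  miss <- is.na(Y)
  N <- nrow(Y); p <- ncol(X); d <- 2L
  df0 <- if (is.null(config$prior_df)) d else config$prior_df
  if (df0 < d) stop("inverse-Wishart prior degrees of freedom below dimension")
  S0 <- diag(config$prior_scale, d)

  n_iter <- config$burn_in + config$m * config$between_draws
  keep_at <- config$burn_in + seq_len(config$m) * config$between_draws
  imps <- vector("list", config$m)
  trace <- matrix(NA_real_, n_iter, 4L,
                  dimnames = list(NULL, c("psi11", "psi22", "sig11", "sig22")))

  with_seed(seed, {
    # initialise missing responses from observed marginals
    for (k in 1:d) {
      mk <- miss[, k]
      if (any(mk)) Y[mk, k] <- sample(Y[!mk, k], sum(mk), replace = TRUE)
    }
    b <- matrix(0, n, d)
    Psi <- diag(d); Sigma <- diag(d)
    XtX <- crossprod(X)
    R <- chol(XtX)
    Rinv <- backsolve(R, diag(p))
    k_imp <- 0L
    for (it in seq_len(n_iter)) {
      # fixed effects (matrix-normal draw)
      ytil <- Y - b[sid, , drop = FALSE]
      Bhat <- backsolve(R, forwardsolve(t(R), crossprod(X, ytil)))
      B <- Bhat + Rinv %*% matrix(stats::rnorm(p * d), p, d) %*% chol(Sigma)
      resid_fix <- Y - X %*% B
      # random intercepts (balanced design: common conditional covariance)
      Siginv <- chol2inv(chol(Sigma))
      V <- chol2inv(chol(chol2inv(chol(Psi)) + fr$J * Siginv))
      S_i <- rowsum(resid_fix, sid)
      bmean <- S_i %*% Siginv %*% V
      b <- bmean + matrix(stats::rnorm(n * d), n, d) %*% chol(V)
      # covariance draws
      Psi <- rinvwishart(df0 + n, S0 + crossprod(b))
      E <- resid_fix - b[sid, , drop = FALSE]
      Sigma <- rinvwishart(df0 + N, S0 + crossprod(E))
      # missing-response draws from conditional normals
      mu <- X %*% B + b[sid, , drop = FALSE]
      both <- which(miss[, 1L] & miss[, 2L])
      if (length(both)) {
        Z <- matrix(stats::rnorm(2L * length(both)), length(both))
        Y[both, ] <- mu[both, , drop = FALSE] + Z %*% chol(Sigma)
      }
      for (k in 1:d) {
        o <- 3L - k
        only <- which(miss[, k] & !miss[, o])
        if (length(only)) {
          cmean <- mu[only, k] + Sigma[k, o] / Sigma[o, o] *
            (Y[only, o] - mu[only, o])
          cvar <- Sigma[k, k] - Sigma[k, o]^2 / Sigma[o, o]
          Y[only, k] <- cmean + sqrt(cvar) * stats::rnorm(length(only))
        }
      }
      trace[it, ] <- c(Psi[1L, 1L], Psi[2L, 2L], Sigma[1L, 1L], Sigma[2L, 2L])
      if (it %in% keep_at) {
        k_imp <- k_imp + 1L
        imps[[k_imp]] <- mlmm_rebuild(cohort, fr, Y)
      }
    }
  })
  imputation_set(imps, cohort, config, seed,
                 diagnostics = as.data.frame(trace))
}

# write completed long responses back into a wide cohort
mlmm_rebuild <- function(cohort, fr, Y) {
  long <- fr$long
  long$BMIz <- Y[, 1L]
  long$FamStruc <- Y[, 2L]
  out <- to_wide(long, cohort$n_waves)
  out$shadow <- cohort$shadow
  out
}

#' Chained-equations imputation with univariate two-level models (FCS-LMM)
#'
#' Imputes one incomplete variable at a time from a linear mixed model with
#' a subject random intercept, conditioning on the other time-varying
#' variables at the same wave (the other imputation target, the QoL z-score
#' and age) plus the baseline covariates. Variants:
#'
#' * `homoscedastic` — common residual variance (a univariate special case
#'   of the joint multilevel sampler);
#' * `heteroscedastic` — random slopes for every predictor and
#'   subject-specific residual variances drawn from scaled inverse-chi-square
#'   full conditionals (Kasim-Raudenbush scheme);
#' * `pmm` — predictive mean matching: predicted means from a drawn
#'   two-level model, each missing row copying the observed value of one of
#'   the `pmm_donors` donors with nearest predicted mean.
#'
#' Binary family structure is modelled as continuous in the first two
#' variants; PMM copies observed (hence binary) donor values.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @param variant one of `"homoscedastic"`, `"heteroscedastic"`, `"pmm"`.
#' @return an [imputation_set()].
#' @export
fcs_lmm <- function(cohort, config = mi_config("FCS-LMM"), seed = 1L,
                    variant = c("homoscedastic", "heteroscedastic", "pmm")) {
  variant <- match.arg(variant)
  fr0 <- mlmm_frame(cohort)
  long <- fr0$long
  sid <- fr0$sid; n <- fr0$n; J <- fr0$J; N <- nrow(long)
  base <- cbind(sex = long$sex, SEP = long$SEP, language = long$language)
  miss <- cbind(BMIz = is.na(long$BMIz), FamStruc = is.na(long$FamStruc))

  design_for <- function(target, cur) {
    other <- if (target == "BMIz") cur$FamStruc else cur$BMIz
    X <- cbind(1, other, long$QoLz, long$ageyr, base)
    colnames(X) <- c("(Intercept)", "other", "QoLz", "ageyr",
                     "sex", "SEP", "language")
    X
  }

  run_chain <- function() {
    cur <- list(BMIz = long$BMIz, FamStruc = long$FamStruc)
    for (v in c("BMIz", "FamStruc")) {
      mk <- miss[, v]
      if (any(mk)) cur[[v]][mk] <- sample(cur[[v]][!mk], sum(mk), TRUE)
    }
    state <- list()
    for (cyc in seq_len(config$fcs_cycles)) {
      for (v in c("BMIz", "FamStruc")) {
        if (!any(miss[, v])) next
        X <- design_for(v, cur)
        st <- lmm_gibbs_update(cur[[v]], X, sid, n, miss[, v],
                               config, variant, state[[v]])
        state[[v]] <- st
        cur[[v]] <- st$y
      }
    }
    cur
  }

  imps <- lapply(seq_len(config$m), function(i) {
    cur <- with_seed(derive_seed(seed, "fcslmm", variant, i), run_chain())
    out_long <- long
    out_long$BMIz <- cur$BMIz
    out_long$FamStruc <- cur$FamStruc
    out <- to_wide(out_long, cohort$n_waves)
    out$shadow <- cohort$shadow
    out
  })
  imputation_set(imps, cohort, config, seed)
}

# One block of Gibbs updates for a univariate two-level imputation model,
# followed by a redraw (or PMM match) of the missing responses.
lmm_gibbs_update <- function(y, X, sid, n, mrows, config, variant, state) {
  N <- length(y); p <- ncol(X)
  nu0 <- if (is.null(config$prior_df)) 1 else config$prior_df
  s0 <- config$prior_scale
  q <- if (variant == "heteroscedastic") p else 1L
  if (is.null(state)) {
    state <- list(beta = numeric(p), b = matrix(0, n, q),
                  psi = diag(1, q), sigma2 = stats::var(y[!mrows]),
                  sig2_i = rep(stats::var(y[!mrows]), n))
  }
  beta <- state$beta; b <- state$b; psi <- state$psi
  sigma2 <- state$sigma2; sig2_i <- state$sig2_i
  n_i <- tabulate(sid, n)

  for (it in seq_len(config$gibbs_iters_per_visit)) {
    if (variant %in% c("homoscedastic", "pmm")) {
      # fixed effects
      ytil <- y - b[sid, 1L]
      XtX <- crossprod(X); diag(XtX) <- diag(XtX) + config$ridge
      R <- chol(XtX)
      bhat <- backsolve(R, forwardsolve(t(R), crossprod(X, ytil)))
      beta <- drop(bhat + sqrt(sigma2) * backsolve(R, stats::rnorm(p)))
      # random intercepts
      r <- y - drop(X %*% beta)
      v <- 1 / (1 / psi[1L, 1L] + n_i / sigma2)
      bmean <- v * drop(rowsum(r, sid)) / sigma2
      b[, 1L] <- bmean + sqrt(v) * stats::rnorm(n)
      # variance components
      psi[1L, 1L] <- draw_scaled_invchisq(nu0 + n, s0 + sum(b[, 1L]^2))
      e <- r - b[sid, 1L]
      sigma2 <- draw_scaled_invchisq(nu0 + N, s0 + sum(e^2))
    } else {
      # heteroscedastic: random slopes for all predictors, subject-specific
      # residual variances (scaled inverse-chi-square full conditionals)
      w <- 1 / sig2_i[sid]
      ytil <- y - rowSums(X * b[sid, , drop = FALSE])
      XtWX <- crossprod(X * w, X); diag(XtWX) <- diag(XtWX) + config$ridge
      R <- chol(XtWX)
      bhat <- backsolve(R, forwardsolve(t(R), crossprod(X, w * ytil)))
      beta <- drop(bhat + backsolve(R, stats::rnorm(p)))
      r <- y - drop(X %*% beta)
      psi_inv <- chol2inv(chol(psi))
      for (i in seq_len(n)) {
        rows <- which(sid == i)
        Xi <- X[rows, , drop = FALSE]
        prec <- psi_inv + crossprod(Xi) / sig2_i[i]
        Vi <- chol2inv(chol(prec))
        mi <- Vi %*% crossprod(Xi, r[rows]) / sig2_i[i]
        b[i, ] <- drop(mi + t(chol(Vi)) %*% stats::rnorm(p))
      }
      e <- r - rowSums(X * b[sid, , drop = FALSE])
      sigma2 <- draw_scaled_invchisq(nu0 + N, s0 + sum(e^2))  # pooled anchor
      ss_i <- drop(rowsum(e^2, sid))
      few <- n_i < 2L
      sig2_i <- (nu0 * sigma2 + ss_i) / stats::rchisq(n, nu0 + n_i)
      if (any(few)) {
        message("fcs_lmm(het): ", sum(few),
                " subject(s) with <2 observations; pooled variance used")
        sig2_i[few] <- sigma2
      }
      psi <- rinvwishart((if (is.null(config$prior_df)) q else config$prior_df)
                         + n, diag(s0, q) + crossprod(b))
    }
  }

  # impute the missing rows
  if (variant == "pmm") {
    pred <- drop(X %*% beta) + b[sid, 1L]
    yobs <- y[!mrows]; pobs <- pred[!mrows]
    ord <- order(pobs)
    pobs_s <- pobs[ord]; yobs_s <- yobs[ord]
    k <- min(config$pmm_donors, length(yobs_s))
    for (row in which(mrows)) {
      pos <- findInterval(pred[row], pobs_s)
      lo <- max(1L, pos - k + 1L); hi <- min(length(pobs_s), pos + k)
      cand <- lo:hi
      cand <- cand[order(abs(pobs_s[cand] - pred[row]))][seq_len(k)]
      y[row] <- yobs_s[cand[sample.int(length(cand), 1L)]]
    }
  } else if (variant == "homoscedastic") {
    mu <- drop(X %*% beta) + b[sid, 1L]
    y[mrows] <- mu[mrows] + sqrt(sigma2) * stats::rnorm(sum(mrows))
  } else {
    mu <- drop(X %*% beta) + rowSums(X * b[sid, , drop = FALSE])
    y[mrows] <- mu[mrows] + sqrt(sig2_i[sid][mrows]) * stats::rnorm(sum(mrows))
  }
  list(y = y, beta = beta, b = b, psi = psi, sigma2 = sigma2, sig2_i = sig2_i)
}
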