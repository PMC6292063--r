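cat_levels <- c("none", "1", "2", "3-4", "5")

count_to_cat <- function(count) {
  lab <- ifelse(count == 0, "none",
         ifelse(count <= 2, as.character(count),
         ifelse(count <= 4, "3-4", "5")))
  factor(lab, levels = cat_levels)
}

#' Cumulative-exposure categories
#'
#' `derive_overwt_cat()` counts the waves 1-5 on which the child was
#' overweight (BMI z-score at or above `zcut`) and maps the count to the
#' categories none / 1 / 2 / 3-4 / 5. `derive_famst_cat()` does the same
#' with living with a single parent (`FamStruc = 1`) as the event. Subjects
#' with a missing input across waves 1-5 get `NA` (the available-data path
#' drops them; imputed cohorts have none).
#'
#' @param cohort a `cohort_table` (complete or amputed).
#' @param zcut BMI z-score threshold for overweight (default 1.04, roughly
#'   the 85th percentile of a standard normal).
#' @return a factor of length `n_subjects` with levels none, 1, 2, 3-4, 5.
#' @export
derive_overwt_cat <- function(cohort, zcut = 1.04) {
  waves <- seq_len(min(5L, cohort$n_waves))
  m <- as.matrix(cohort$data[wave_cols("BMIz", cohort$n_waves, waves)])
  count_to_cat(rowSums(m >= zcut))
}

#' @rdname derive_overwt_cat
#' @export
derive_famst_cat <- function(cohort) {
  waves <- seq_len(min(5L, cohort$n_waves))
  m <- as.matrix(cohort$data[wave_cols("FamStruc", cohort$n_waves, waves)])
  count_to_cat(rowSums(m == 1))
}

estimate_vector <- function(term, estimate, se, ri_var = NA_real_,
                            resid_var = NA_real_, icc = NA_real_) {
  out <- data.frame(term = term, estimate = estimate, se = se,
                    row.names = NULL)
  attr(out, "ri_var") <- ri_var
  attr(out, "resid_var") <- resid_var
  attr(out, "icc") <- icc
  class(out) <- c("estimate_vector", "data.frame")
  out
}

model1_frame <- function(cohort, zcut = 1.04) {
  cohort <- round_cohort_binaries(cohort)
  d <- cohort$data
  data.frame(
    QoLz_6 = d[[paste0("QoLz_w", cohort$n_waves)]],
    OverWtCat = derive_overwt_cat(cohort, zcut),
    FamStCat = derive_famst_cat(cohort),
    ageyr_6 = d[[paste0("ageyr_w", cohort$n_waves)]],
    sex = d$sex, SEP = d$SEP, language = d$language
  )
}

#' Analysis model 1: linear regression on cumulative exposure
#'
#' Ordinary least squares of the wave-6 QoL z-score on indicator contrasts
#' for the cumulative overweight and single-parent categories (reference
#' "none"), age at wave 6, sex, SEP and home language. Continuous imputed
#' family-structure values are adaptively rounded before the categories are
#' derived. An empty category level is dropped with a warning.
#'
#' @param cohort a completed `cohort_table` (no missing analysis inputs).
#' @param zcut overweight threshold passed to [derive_overwt_cat()].
#' @return an `estimate_vector` (term, estimate, model SE).
#' @export
fit_model1 <- function(cohort, zcut = 1.04) {
  df <- model1_frame(cohort, zcut)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (!nrow(df)) stop("no complete rows available for model 1")
  rhs <- c("OverWtCat", "ageyr_6", "sex", "SEP", "language", "FamStCat")
  for (v in c("OverWtCat", "FamStCat")) {
    if (any(table(df[[v]]) == 0)) {
      warning("empty ", v, " category level(s) dropped: ",
              paste(setdiff(levels(df[[v]]), unique(as.character(df[[v]]))),
                    collapse = ", "))
      df[[v]] <- droplevels(df[[v]])
    }
    if (nlevels(df[[v]]) < 2L) rhs <- setdiff(rhs, v)
  }
  fit <- stats::lm(stats::reformulate(rhs, response = "QoLz_6"), data = df)
  sm <- summary(fit)$coefficients
  estimate_vector(rownames(sm), sm[, 1L], sm[, 2L],
                  resid_var = summary(fit)$sigma^2)
}

#' Analysis model 2: random-intercept linear mixed model
#'
#' REML fit (via lme4) of the QoL z-score at all waves on the BMI z-score,
#' age, sex, SEP, language and family structure, with a subject-specific
#' random intercept. Unrounded imputed family-structure values are used on
#' this path.
#'
#' @param cohort a completed `cohort_table`.
#' @param reml use REML (default) or ML.
#' @return an `estimate_vector` carrying additionally the random-intercept
#'   variance, residual variance, and ICC as attributes.
#' @export
fit_model2 <- function(cohort, reml = TRUE) {
  long <- to_long(cohort)
  long <- long[stats::complete.cases(long[c("QoLz", "BMIz", "ageyr",
                                            "FamStruc")]), , drop = FALSE]
  if (!nrow(long)) stop("no complete subject-wave rows available for model 2")
  fit <- lme4::lmer(QoLz ~ BMIz + ageyr + sex + SEP + language + FamStruc +
                      (1 | subject_id), data = long, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  ri <- as.numeric(vc$subject_id[1L, 1L])
  rs <- attr(vc, "sc")^2
  estimate_vector(rownames(sm), sm[, 1L], sm[, 2L],
                  ri_var = ri, resid_var = rs, icc = ri / (ri + rs))
}

#' Random-intercept LMM for the exposure itself
#'
#' REML fit of the BMI z-score on its generating covariates (age, sex,
#' family structure) with a subject random intercept — used to check that
#' the generator's between-subject variance is recoverable from data.
#'
#' @param cohort a `cohort_table`.
#' @return an `estimate_vector` with random-intercept/residual variance
#'   attributes.
#' @export
fit_exposure_lmm <- function(cohort) {
  long <- to_long(cohort)
  long <- long[stats::complete.cases(long[c("BMIz", "ageyr", "FamStruc")]), ]
  fit <- lme4::lmer(BMIz ~ ageyr + sex + FamStruc + (1 | subject_id),
                    data = long, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  ri <- as.numeric(vc$subject_id[1L, 1L])
  rs <- attr(vc, "sc")^2
  estimate_vector(rownames(sm), sm[, 1L], sm[, 2L],
                  ri_var = ri, resid_var = rs, icc = ri / (ri + rs))
}

#' Available-data (complete-case) fits
#'
#' Model 1: subjects with any missing input to the derived category
#' variables are dropped (listwise deletion). Model 2: subject-wave rows
#' with missing BMI z-score or family structure are dropped; other rows of
#' the same subject are retained.
#'
#' @param cohort an amputed `cohort_table`.
#' @param model 1 or 2.
#' @param zcut overweight threshold (model 1).
#' @return an `estimate_vector`.
#' @export
available_data_fit <- function(cohort, model = 2L, zcut = 1.04) {
  if (model == 1L) fit_model1(cohort, zcut) else fit_model2(cohort)
}

#' Fit an analysis model to every completed copy of an imputation set
#'
#' @param imps an [imputation_set()].
#' @param model 1 or 2.
#' @param zcut overweight threshold (model 1).
#' @return list of `estimate_vector`s, one per imputation.
#' @export
fit_imputation_set <- function(imps, model = 2L, zcut = 1.04) {
  stopifnot(inherits(imps, "imputation_set"))
  lapply(imps$imputations, function(coh) {
    if (model == 1L) fit_model1(coh, zcut) else fit_model2(coh)
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' For each coefficient: pooled estimate Qbar (mean), within-imputation
#' variance W (mean squared SE), between-imputation variance B (sample
#' variance of estimates), total variance `T = W + (1 + 1/m) B`, reference-t
#' degrees of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2` (classic 1987
#' formula; the Barnard-Rubin small-sample adjustment is available via
#' `dfcom`), and a 95% t-interval. With `B = 0` the df are reported as
#' infinite, capped at 1e9.
#'
#' @param estimates list of `m >= 2` `estimate_vector`s with identical
#'   coefficient sets.
#' @param conf confidence level (default 0.95).
#' @param dfcom complete-data residual degrees of freedom; when supplied the
#'   Barnard-Rubin adjusted df are used instead of the classic formula.
#' @return a `pooled_result` data.frame: term, estimate, W, B, T, se, df,
#'   ci_lo, ci_hi, mcse (Monte-Carlo SE of the pooled estimate, sqrt(B/m)).
#' @export
#' @examples
#' e1 <- data.frame(term = "x", estimate = 1.0, se = 0.2)
#' e2 <- data.frame(term = "x", estimate = 1.2, se = 0.2)
#' pool_rubin(list(e1, e2))
pool_rubin <- function(estimates, conf = 0.95, dfcom = NULL) {
  m <- length(estimates)
  if (m < 2L) stop("pooling requires at least 2 imputations")
  terms <- estimates[[1L]]$term
  for (e in estimates)
    if (!identical(e$term, terms))
      stop("imputation fits have mismatched coefficient sets")
  Q <- sapply(estimates, function(e) e$estimate)
  U <- sapply(estimates, function(e) e$se^2)
  if (is.null(dim(Q))) { Q <- matrix(Q, nrow = 1L); U <- matrix(U, nrow = 1L) }
  qbar <- rowMeans(Q)
  W <- rowMeans(U)
  B <- apply(Q, 1L, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  if (!is.null(dfcom)) {
    # Barnard-Rubin: combine the classic df with the observed-data df
    lambda <- (1 + 1 / m) * B / Tv
    dfobs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- ifelse(B > 0, 1 / (1 / df + 1 / dfobs), dfobs)
  }
  df <- pmin(df, 1e9)
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  out <- data.frame(term = terms, estimate = qbar, W = W, B = B, T = Tv,
                    se = sqrt(Tv), df = df,
                    ci_lo = qbar - tq * sqrt(Tv),
                    ci_hi = qbar + tq * sqrt(Tv),
                    mcse = sqrt(B / m), row.names = NULL)
  attr(out, "m") <- m
  class(out) <- c("pooled_result", "data.frame")
  out
}

#' Confidence intervals for a single (unpooled) fit
#'
#' t-based intervals using the supplied residual degrees of freedom, or
#' normal-based when `df` is infinite.
#'
#' @param est an `estimate_vector`.
#' @param df reference degrees of freedom.
#' @param conf confidence level.
#' @return the estimate table with `ci_lo`, `ci_hi` columns added.
#' @export
estimate_ci <- function(est, df = Inf, conf = 0.95) {
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  est$ci_lo <- est$estimate - tq * est$se
  est$ci_hi <- est$estimate + tq * est$se
  est
}
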