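# Chained-equations engines on the wide data matrix.
#
# Each of the m imputations is an independent chain: missing cells are
# initialised by draws from the observed marginals, then the incomplete
# variables are visited in a fixed order (waves ascending, BMIz before
# FamStruc within a wave) for `fcs_cycles` cycles. Continuous targets are
# imputed by Bayesian linear regression draws; binary targets by logistic
# regression with an approximate normal posterior draw of the coefficients.

# one univariate visit: refit on originally observed rows, redraw missing
fcs_visit <- function(Y, miss, tc, preds, is_binary, ridge, warm) {
  obs <- !miss[, tc]
  X <- cbind(1, Y[, preds, drop = FALSE])
  mrows <- which(miss[, tc])
  if (is_binary) {
    fit <- bayes_logit_draw(X[obs, , drop = FALSE], Y[obs, tc],
                            ridge = ridge, start = warm)
    if (fit$separation)
      message("fcs: near-separation in logistic model for ", tc,
              "; ridge-penalised draw used")
    pm <- expit(drop(X[mrows, , drop = FALSE] %*% fit$beta))
    Y[mrows, tc] <- stats::rbinom(length(mrows), 1L, pm)
    attr(Y, "warm") <- fit$mle
  } else {
    fit <- bayes_lm_draw(X[obs, , drop = FALSE], Y[obs, tc], ridge = ridge)
    mu <- drop(X[mrows, , drop = FALSE] %*% fit$beta)
    Y[mrows, tc] <- mu + fit$sigma * stats::rnorm(length(mrows))
    attr(Y, "warm") <- NULL
  }
  Y
}

fcs_run_chain <- function(Y0, miss, sets, order_cols, cycles, ridge,
                          trace_env = NULL) {
  Y <- marginal_fill(Y0, miss)
  warm <- vector("list", length(order_cols))
  names(warm) <- order_cols
  for (cyc in seq_len(cycles)) {
    for (tc in order_cols) {
      if (!any(miss[, tc])) next
      Y <- fcs_visit(Y, miss, tc, sets[[tc]],
                     is_binary = startsWith(tc, "FamStruc"),
                     ridge = ridge, warm = warm[[tc]])
      warm[[tc]] <- attr(Y, "warm")
      attr(Y, "warm") <- NULL
    }
    if (!is.null(trace_env))
      trace_env$trace <- rbind(trace_env$trace,
                               c(cycle = cyc, mean_imputed = mean(Y[miss])))
  }
  Y
}

#' Standard chained-equations imputation (FCS-Standard)
#'
#' Univariate imputation models condition on all other imputation-model
#' columns, including every wave of the time-varying covariates.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @return an [imputation_set()].
#' @export
fcs_standard <- function(cohort, config = mi_config("FCS-Standard"),
                         seed = 1L) {
  em <- engine_matrix(cohort)
  sets <- fcs_predictor_sets(cohort$n_waves, window = NULL)
  tr <- new.env(); tr$trace <- NULL
  imps <- lapply(seq_len(config$m), function(i) {
    Y <- with_seed(derive_seed(seed, "fcs", i),
                   fcs_run_chain(em$Y, em$miss, sets, em$lay$targets,
                                 config$fcs_cycles, config$ridge, tr))
    rebuild_cohort(cohort, Y)
  })
  imputation_set(imps, cohort, config, seed,
                 diagnostics = as.data.frame(tr$trace))
}

#' Windowed chained-equations imputation (FCS-Twofold / FCS-MTW)
#'
#' Univariate models at wave t condition only on wave-varying measurements
#' within `window` waves of t, plus the baseline covariates. With
#' `twofold = TRUE`, each of `among_time_iters` outer sweeps runs
#' `within_time_iters` nested iterations over the incomplete variables of
#' each time block; with `twofold = FALSE` (the moving-time-window variant)
#' a single pass over the waves is made per sweep.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @param twofold run nested within-time iterations.
#' @return an [imputation_set()].
#' @export
fcs_windowed <- function(cohort, config = mi_config("FCS-MTW"), seed = 1L,
                         twofold = FALSE) {
  em <- engine_matrix(cohort)
  sets <- fcs_predictor_sets(cohort$n_waves, window = config$window)
  targets_by_wave <- split(em$lay$targets, target_wave(em$lay$targets))
  inner <- if (twofold) config$within_time_iters else 1L
  run_chain <- function(Y) {
    Y <- marginal_fill(Y, em$miss)
    warm <- list()
    for (sweep_i in seq_len(config$among_time_iters)) {
      for (wv in names(targets_by_wave)) {
        for (rep_i in seq_len(inner)) {
          for (tc in targets_by_wave[[wv]]) {
            if (!any(em$miss[, tc])) next
            Y <- fcs_visit(Y, em$miss, tc, sets[[tc]],
                           is_binary = startsWith(tc, "FamStruc"),
                           ridge = config$ridge, warm = warm[[tc]])
            warm[[tc]] <- attr(Y, "warm")
            attr(Y, "warm") <- NULL
          }
        }
      }
    }
    Y
  }
  imps <- lapply(seq_len(config$m), function(i) {
    Y <- with_seed(derive_seed(seed, "fcsw", i), run_chain(em$Y))
    rebuild_cohort(cohort, Y)
  })
  imputation_set(imps, cohort, config, seed)
}
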