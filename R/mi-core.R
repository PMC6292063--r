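#' Imputation configuration
#'
#' Method name plus iteration controls for the MI engines.
#'
#' Methods: `"JM-MVN"` (multivariate-normal data augmentation on the wide
#' matrix), `"FCS-Standard"` (chained equations conditioning on all waves),
#' `"FCS-Twofold"` and `"FCS-MTW"` (chained equations restricted to a moving
#' time window, with and without nested within-time iterations),
#' `"JM-MLMM"` (joint bivariate linear mixed-model Gibbs sampler),
#' `"FCS-LMM"`, `"FCS-LMM-het"`, `"FCS-LMM-PMM"` (univariate two-level
#' samplers: homoscedastic, subject-specific residual variances with random
#' slopes, and predictive mean matching).
#'
#' @param method one of the method names above.
#' @param m number of imputations (>= 2; 40 matches the headline study).
#' @param burn_in,between_draws data-augmentation/Gibbs chain controls for
#'   the JM engines: iterations discarded before the first imputation and
#'   spacing between retained imputations.
#' @param fcs_cycles chained-equation cycles per imputation chain.
#' @param within_time_iters,among_time_iters nested iteration controls for
#'   the twofold variant (inner per-time-block iterations; outer sweeps).
#' @param window half-width in waves of the moving time window.
#' @param gibbs_iters_per_visit Gibbs updates of a univariate two-level
#'   imputation model per chained-equations visit.
#' @param pmm_donors donor-pool size for predictive mean matching.
#' @param prior_df,prior_scale inverse-Wishart prior degrees of freedom
#'   (`NULL` = dimension) and scale multiplier (identity * scale) for the
#'   multilevel engines.
#' @param ridge ridge penalty guarding separation/collinearity.
#' @return an object of class `mi_config`.
#' @export
mi_config <- function(method = "FCS-Standard",
                      m = 40L,
                      burn_in = 200L,
                      between_draws = 100L,
                      fcs_cycles = 10L,
                      within_time_iters = 2L,
                      among_time_iters = 10L,
                      window = 1L,
                      gibbs_iters_per_visit = 10L,
                      pmm_donors = 5L,
                      prior_df = NULL,
                      prior_scale = 1,
                      ridge = 1e-4) {
  methods <- c("JM-MVN", "FCS-Standard", "FCS-Twofold", "FCS-MTW",
               "JM-MLMM", "FCS-LMM", "FCS-LMM-het", "FCS-LMM-PMM")
  if (!method %in% methods)
    stop("unknown method '", method, "'; available: ",
         paste(methods, collapse = ", "))
  if (m < 2L) stop("m must be at least 2")
  iters <- c(burn_in, between_draws, fcs_cycles, within_time_iters,
             among_time_iters, gibbs_iters_per_visit)
  if (any(iters < 1L)) stop("iteration controls must be >= 1")
  if (window < 1L) stop("window must be >= 1")
  structure(list(method = method, m = as.integer(m),
                 burn_in = as.integer(burn_in),
                 between_draws = as.integer(between_draws),
                 fcs_cycles = as.integer(fcs_cycles),
                 within_time_iters = as.integer(within_time_iters),
                 among_time_iters = as.integer(among_time_iters),
                 window = as.integer(window),
                 gibbs_iters_per_visit = as.integer(gibbs_iters_per_visit),
                 pmm_donors = as.integer(pmm_donors),
                 prior_df = prior_df, prior_scale = prior_scale,
                 ridge = ridge),
            class = "mi_config")
}

# Wide-format imputation-model layout shared by JM-MVN and the FCS-* wide
# engines. Targets are imputed; predictors are always observed. Mother's
# education is deliberately not part of the imputation model.
impute_layout <- function(n_waves) {
  targets <- character(0)
  for (j in seq_len(n_waves)) {
    targets <- c(targets, paste0("BMIz_w", j))
    if (j >= 2L) targets <- c(targets, paste0("FamStruc_w", j))
  }
  predictors <- c("ageyr_w1", "sex", "SEP", "language", "FamStruc_w1",
                  wave_cols("QoLz", n_waves))
  list(targets = targets, predictors = predictors,
       columns = c(targets, predictors))
}

target_wave <- function(cols) as.integer(sub("^.*_w", "", cols))
target_var <- function(cols) sub("_w[0-9]+$", "", cols)

#' Predictor sets used by the chained-equations engines
#'
#' For each imputation target, the columns its univariate model conditions
#' on. With `window = NULL` (FCS-Standard) every other imputation-model
#' column is used; with a finite window, wave-varying columns are restricted
#' to waves within `window` of the target's wave, while baseline columns are
#' always retained.
#'
#' @param n_waves number of waves.
#' @param window half-width in waves, or `NULL` for no restriction.
#' @return named list: target column -> character vector of predictors.
#' @export
fcs_predictor_sets <- function(n_waves, window = NULL) {
  lay <- impute_layout(n_waves)
  baseline <- c("ageyr_w1", "sex", "SEP", "language")
  sets <- lapply(lay$targets, function(tc) {
    others <- setdiff(lay$columns, tc)
    if (is.null(window)) return(others)
    tw <- target_wave(tc)
    keep <- vapply(others, function(cc) {
      if (cc %in% baseline) return(TRUE)
      abs(target_wave(cc) - tw) <= window
    }, logical(1))
    others[keep]
  })
  names(sets) <- lay$targets
  sets
}

#' Multiple-imputation result set
#'
#' Holds the `m` completed cohorts of one engine run plus method metadata
#' and chain diagnostics. Observed cells are identical across all copies and
#' to the input; every originally missing cell is filled in every copy.
#'
#' @param imputations list of completed `cohort_table`s.
#' @param cohort the amputed input cohort.
#' @param config the `mi_config` used.
#' @param seed the seed used.
#' @param diagnostics data.frame trace of imputation-model parameters.
#' @return an object of class `imputation_set`.
#' @export
imputation_set <- function(imputations, cohort, config, seed,
                           diagnostics = NULL) {
  structure(list(imputations = imputations, method = config$method,
                 m = length(imputations), config = config, seed = seed,
                 diagnostics = diagnostics,
                 mask = is.na(as.matrix(cohort$data))),
            class = "imputation_set")
}

#' @exportS3Method base::print
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: %s, m = %d, %d cells imputed per copy\n",
              x$method, x$m, sum(x$mask)))
  invisible(x)
}

#' Impute an incomplete cohort
#'
#' Dispatches to the engine named in `config`. Every engine returns `m`
#' completed copies of the cohort; observed cells are preserved bit-exactly
#' and the result is deterministic given `seed`. A cohort with no missing
#' cells is returned unchanged, replicated `m` times.
#'
#' Imputation targets are the BMI z-scores at all waves and the
#' family-structure indicator at waves 2 and later; the imputation model
#' further conditions on age at wave 1, sex, socio-economic position, home
#' language, wave-1 family structure and the QoL z-score at every wave.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @return an [imputation_set()].
#' @export
#' @examples
#' coh <- generate_cohort(300, gen_params(), seed = 1)
#' amp <- apply_mar(coh, calibrate_intercepts(coh), seed = 2)
#' imp <- impute(amp, mi_config("FCS-Standard", m = 3, fcs_cycles = 3), seed = 3)
#' imp
impute <- function(cohort, config = mi_config(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "mi_config"))
  if (!any(is.na(cohort$data))) {
    copies <- replicate(config$m, cohort, simplify = FALSE)
    return(imputation_set(copies, cohort, config, seed))
  }
  engine <- switch(config$method,
    "JM-MVN" = jm_mvn,
    "FCS-Standard" = fcs_standard,
    "FCS-Twofold" = function(coh, cfg, s) fcs_windowed(coh, cfg, s, twofold = TRUE),
    "FCS-MTW" = function(coh, cfg, s) fcs_windowed(coh, cfg, s, twofold = FALSE),
    "JM-MLMM" = jm_mlmm,
    "FCS-LMM" = function(coh, cfg, s) fcs_lmm(coh, cfg, s, variant = "homoscedastic"),
    "FCS-LMM-het" = function(coh, cfg, s) fcs_lmm(coh, cfg, s, variant = "heteroscedastic"),
    "FCS-LMM-PMM" = function(coh, cfg, s) fcs_lmm(coh, cfg, s, variant = "pmm"))
  engine(cohort, config, seed)
}

#' Adaptive rounding of continuous imputations of a binary variable
#'
#' Converts continuous imputed values of a 0/1 variable to binary using the
#' normal-approximation cutoff: with mean imputed value w, the cutoff is
#' `w - qnorm(w) * sqrt(w * (1 - w))`; values at or above the cutoff become
#' 1. Used on the cumulative-exposure (model 1) analysis path only; the
#' mixed-model path analyses the unrounded values.
#'
#' @param values numeric vector of imputed values.
#' @return integer 0/1 vector.
#' @export
#' @examples
#' adaptive_round(c(0.2, 0.5, 0.8))
adaptive_round <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  w <- mean(values)
  if (w <= 0) { warning("mean imputed value <= 0; returning all 0"); return(rep(0L, length(values))) }
  if (w >= 1) { warning("mean imputed value >= 1; returning all 1"); return(rep(1L, length(values))) }
  cutoff <- w - stats::qnorm(w) * sqrt(w * (1 - w))
  as.integer(values >= cutoff)
}

# Round any non-binary FamStruc columns of a completed cohort (model-1 path)
round_cohort_binaries <- function(cohort) {
  for (col in wave_cols("FamStruc", cohort$n_waves)) {
    v <- cohort$data[[col]]
    if (!all(v %in% c(0, 1))) cohort$data[[col]] <- adaptive_round(v)
  }
  cohort
}

# shared engine plumbing: wide numeric matrix of the imputation model
engine_matrix <- function(cohort) {
  lay <- impute_layout(cohort$n_waves)
  Y <- as.matrix(cohort$data[lay$columns])
  storage.mode(Y) <- "double"
  if (any(is.na(Y[, lay$predictors])))
    stop("imputation-model predictors must be fully observed")
  list(Y = Y, lay = lay, miss = is.na(Y))
}

# initial fill: draw each missing cell from the observed marginal
marginal_fill <- function(Y, miss) {
  for (k in which(colSums(miss) > 0)) {
    obs <- Y[!miss[, k], k]
    Y[miss[, k], k] <- sample(obs, sum(miss[, k]), replace = TRUE)
  }
  Y
}

# rebuild a completed cohort_table from an engine matrix
rebuild_cohort <- function(cohort, Y) {
  out <- cohort$data
  for (cc in colnames(Y)) out[[cc]] <- Y[, cc]
  cohort_table(out, cohort$n_waves, shadow = cohort$shadow)
}
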