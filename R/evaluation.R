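#' Model-2 truth vector
#'
#' The random-intercept analysis model coincides with the outcome-generating
#' model, so its true coefficients are read directly from the generative
#' parameters.
#'
#' @param params a [gen_params()] object.
#' @return data.frame with columns `term`, `truth`.
#' @export
truth_model2 <- function(params) {
  qc <- params$qolz_coefs
  data.frame(
    term = c("(Intercept)", "BMIz", "ageyr", "sex", "SEP", "language",
             "FamStruc"),
    truth = c(qc[["intercept"]], qc[["bmiz"]], qc[["ageyr"]], qc[["sex"]],
              qc[["sep"]], qc[["language"]], qc[["famstruc"]])
  )
}

#' Model-1 truth by large-population simulation
#'
#' The cumulative-exposure regression is not a sub-model of the generator,
#' so its true coefficients are defined as the large-sample fit: generate a
#' large complete population (in memory-bounded chunks), derive the
#' exposure categories, fit model 1, and return its coefficients.
#'
#' @param params a [gen_params()] object.
#' @param N population size (>= 1e5 recommended; smaller N warns).
#' @param zcut overweight threshold.
#' @param seed integer seed.
#' @param chunk subjects generated per chunk.
#' @return data.frame with columns `term`, `truth`.
#' @export
compute_truth_model1 <- function(params = gen_params(), N = 1e6,
                                 zcut = 1.04, seed = 1L, chunk = 2e5) {
  if (N < 1e5)
    warning("N below 1e5: model-1 truth will carry visible sampling error")
  n_chunks <- ceiling(N / chunk)
  frames <- vector("list", n_chunks)
  left <- N
  for (ci in seq_len(n_chunks)) {
    nc <- as.integer(min(chunk, left)); left <- left - nc
    coh <- generate_cohort(nc, params, seed = derive_seed(seed, "truth1", ci))
    frames[[ci]] <- model1_frame(coh, zcut)
  }
  df <- do.call(rbind, frames)
  fit <- stats::lm(QoLz_6 ~ OverWtCat + ageyr_6 + sex + SEP + language +
                     FamStCat, data = df)
  data.frame(term = names(stats::coef(fit)),
             truth = unname(stats::coef(fit)))
}

#' Performance metrics over simulation replicates
#'
#' Per method, model and coefficient: bias (mean estimate minus truth),
#' empirical SE (SD of estimates across replicates), average model-based SE,
#' coverage of the nominal 95% interval, the Monte-Carlo error of the
#' coverage estimate, replicate count, and failure count.
#'
#' @param estimates tidy estimate table (columns `method`, `model`,
#'   `replicate`, `term`, `estimate`, `se`, `ci_lo`, `ci_hi`).
#' @param truths data.frame with columns `model`, `term`, `truth`.
#' @return a `performance_summary` data.frame.
#' @export
performance <- function(estimates, truths) {
  key <- unique(estimates[c("method", "model", "term")])
  need <- unique(estimates[c("model", "term")])
  have <- merge(need, truths, by = c("model", "term"))
  if (nrow(have) < nrow(need)) {
    miss <- need[!paste(need$model, need$term) %in%
                   paste(have$model, have$term), ]
    stop("missing truth for: ",
         paste(miss$model, miss$term, collapse = "; "))
  }
  est <- merge(estimates, truths, by = c("model", "term"))
  sp <- split(est, list(est$method, est$model, est$term), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    K <- nrow(g)
    cov <- mean(g$ci_lo <= g$truth & g$truth <= g$ci_hi)
    data.frame(method = g$method[1L], model = g$model[1L], term = g$term[1L],
               truth = g$truth[1L], bias = mean(g$estimate) - g$truth[1L],
               emp_se = stats::sd(g$estimate), avg_model_se = mean(g$se),
               coverage = cov, coverage_mcse = sqrt(cov * (1 - cov) / K),
               bias_mcse = stats::sd(g$estimate) / sqrt(K), K = K,
               row.names = NULL)
  }))
  out <- out[order(out$model, out$method, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' Study configuration
#'
#' @param methods character vector of comparators: `"complete"`,
#'   `"available"`, and/or MI method names accepted by [mi_config()].
#' @param K number of replicates.
#' @param n subjects per replicate.
#' @param m imputations per MI method.
#' @param seed master seed; every stage derives its own substream.
#' @param params generative parameters.
#' @param mar missingness model (uncalibrated; targets and slopes).
#' @param models analysis models to fit (subset of `c(1, 2)`).
#' @param zcut overweight threshold.
#' @param mi_args named list of extra [mi_config()] arguments (iteration
#'   controls) applied to every MI method.
#' @param truth_N population size for the model-1 truth.
#' @param full_scale use the headline-study scale (K = 1000, n = 5000,
#'   m = 40, truth_N = 1e7) — a cluster-sized computation.
#' @return a `study_config` list.
#' @export
study_config <- function(methods = c("complete", "available", "FCS-Standard"),
                         K = 200L, n = 1000L, m = 10L, seed = 1L,
                         params = gen_params(), mar = mar_model(),
                         models = c(1L, 2L), zcut = 1.04,
                         mi_args = list(), truth_N = 1e6,
                         full_scale = FALSE) {
  if (full_scale) { K <- 1000L; n <- 5000L; m <- 40L; truth_N <- 1e7 }
  structure(list(methods = methods, K = as.integer(K), n = as.integer(n),
                 m = as.integer(m), seed = as.integer(seed), params = params,
                 mar = mar, models = as.integer(models), zcut = zcut,
                 mi_args = mi_args, truth_N = truth_N),
            class = "study_config")
}

# one replicate of the study -> tidy estimate rows
run_replicate <- function(cfg, mar_fit, r) {
  seed_r <- derive_seed(cfg$seed, "rep", r)
  cohort <- generate_cohort(cfg$n, cfg$params, seed = derive_seed(seed_r, "gen"))
  amputed <- apply_mar(cohort, mar_fit, seed = derive_seed(seed_r, "mar"))
  rows <- list()
  add <- function(method, model, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, model = model, replicate = r,
      term = est$term, estimate = est$estimate, se = est$se,
      ci_lo = est$ci_lo, ci_hi = est$ci_hi, row.names = NULL)
  }
  single_ci <- function(est, nrows) {
    estimate_ci(est, df = max(nrows - length(est$term), 1L))
  }
  for (method in cfg$methods) {
    for (model in cfg$models) {
      est <- tryCatch({
        if (method == "complete") {
          e <- if (model == 1L) fit_model1(cohort, cfg$zcut) else fit_model2(cohort)
          single_ci(e, if (model == 1L) cfg$n else cfg$n * cohort$n_waves)
        } else if (method == "available") {
          e <- available_data_fit(amputed, model, cfg$zcut)
          single_ci(e, if (model == 1L) cfg$n else cfg$n * cohort$n_waves)
        } else {
          mic <- do.call(mi_config, c(list(method = method, m = cfg$m),
                                      cfg$mi_args))
          imps <- impute(amputed, mic, seed = derive_seed(seed_r, method))
          pooled <- pool_rubin(fit_imputation_set(imps, model, cfg$zcut))
          data.frame(term = pooled$term, estimate = pooled$estimate,
                     se = pooled$se, ci_lo = pooled$ci_lo,
                     ci_hi = pooled$ci_hi)
        }
      }, error = function(e) {
        warning(sprintf("replicate %d, %s, model %d failed: %s",
                        r, method, model, conditionMessage(e)))
        NULL
      })
      if (!is.null(est)) add(method, model, est)
    }
  }
  do.call(rbind, rows)
}

#' Run the replicated simulation study
#'
#' Per replicate: generate a cohort, apply the calibrated MAR amputation,
#' run each requested comparator (complete-data fit, available-data fit,
#' and/or MI engines with Rubin pooling) on the requested analysis models,
#' and collect tidy estimates. The missingness intercepts are calibrated
#' once on a separate calibration cohort so the mechanism is fixed across
#' replicates. Engine failures are recorded and the study continues.
#'
#' @param cfg a [study_config()].
#' @param cache_dir optional directory for per-replicate artifact caching
#'   (resumable runs).
#' @param progress print a line every 25 replicates.
#' @return list with `estimates` (tidy table), `summary`
#'   (a [performance()] table), `truths`, `mar` (the calibrated model), and
#'   `config`.
#' @export
run_study <- function(cfg, cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  calib <- generate_cohort(max(cfg$n, 10000L), cfg$params,
                           seed = derive_seed(cfg$seed, "calibration"))
  mar_fit <- calibrate_intercepts(calib, cfg$mar)
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  reps <- lapply(seq_len(cfg$K), function(r) {
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, sprintf("replicate_%04d.rds", r))
      if (file.exists(f)) return(readRDS(f))
      res <- run_replicate(cfg, mar_fit, r)
      saveRDS(res, f)
      if (progress && r %% 25L == 0L) message("replicate ", r, "/", cfg$K)
      return(res)
    }
    if (progress && r %% 25L == 0L) message("replicate ", r, "/", cfg$K)
    run_replicate(cfg, mar_fit, r)
  })
  estimates <- do.call(rbind, reps)
  truths <- rbind(
    if (1L %in% cfg$models)
      cbind(model = 1L, compute_truth_model1(cfg$params, cfg$truth_N,
                                             cfg$zcut,
                                             seed = derive_seed(cfg$seed, "truth"))),
    if (2L %in% cfg$models) cbind(model = 2L, truth_model2(cfg$params))
  )
  list(estimates = estimates, summary = performance(estimates, truths),
       truths = truths, mar = mar_fit, config = cfg)
}
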