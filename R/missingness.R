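#' Missingness model for MAR amputation
#'
#' Per-wave logistic models for setting the BMI z-score (all waves) and the
#' family-structure indicator (waves 2 and later) to missing. For BMI the
#' linear predictor is `intercept + slope1 * ageyr_j + slope2 * QoLz_j`; for
#' family structure it is `intercept + slope1 * FamStruc_1 + slope2 *
#' QoLz_j`. Every driver is always observed, so the mechanism is missing at
#' random by construction. Family structure at wave 1 is never masked.
#'
#' `default_mar_targets()` returns the per-wave intended missingness
#' proportions the intercepts are calibrated to (BMI z-score
#' 0.01/0.06/0.10/0.15/0.19/0.28, family structure 0/0.06/0.08/0.10/0.15/0.24
#' across waves 1-6).
#'
#' @param targets data.frame with columns `variable` ("BMIz"/"FamStruc"),
#'   `wave`, `target` (intended proportions in `[0, 1)`).
#' @param slopes data.frame with columns `variable`, `wave`, `slope1`,
#'   `slope2`; defaults to `default_mar_slopes()` for every wave.
#' @return for `mar_model()`: an object of class `mar_model`, a data.frame
#'   with columns `variable, wave, intercept, slope1, slope2, target`
#'   (intercepts `NA` until calibrated; `-Inf` encodes "never missing").
#' @export
mar_model <- function(targets = default_mar_targets(),
                      slopes = default_mar_slopes(targets)) {
  m <- merge(targets, slopes, by = c("variable", "wave"), all.x = TRUE)
  if (any(!is.finite(m$slope1)) || any(!is.finite(m$slope2)))
    stop("missingness slopes must be finite")
  if (any(m$target < 0 | m$target >= 1))
    stop("target proportions must lie in [0, 1)")
  if (any(m$variable == "FamStruc" & m$wave == 1L & m$target > 0))
    stop("family structure at wave 1 is completely observed; target must be 0")
  m$intercept <- ifelse(m$target == 0, -Inf, NA_real_)
  m <- m[order(m$variable, m$wave),
         c("variable", "wave", "intercept", "slope1", "slope2", "target")]
  rownames(m) <- NULL
  class(m) <- c("mar_model", "data.frame")
  m
}

#' @rdname mar_model
#' @export
default_mar_targets <- function() {
  data.frame(
    variable = rep(c("BMIz", "FamStruc"), each = 6L),
    wave = rep(1:6, 2L),
    target = c(0.01, 0.06, 0.10, 0.15, 0.19, 0.28,
               0.00, 0.06, 0.08, 0.10, 0.15, 0.24)
  )
}

#' @rdname mar_model
#' @export
default_mar_slopes <- function(targets = default_mar_targets()) {
  data.frame(
    variable = targets$variable, wave = targets$wave,
    slope1 = ifelse(targets$variable == "BMIz", 0.1, 0.5),
    slope2 = -0.4
  )
}

# linear predictor, minus the intercept, for one model row on a cohort
mar_driver <- function(cohort, variable, wave, slope1, slope2) {
  d <- cohort$data
  qol <- d[[paste0("QoLz_w", wave)]]
  if (variable == "BMIz") {
    slope1 * d[[paste0("ageyr_w", wave)]] + slope2 * qol
  } else {
    slope1 * d[["FamStruc_w1"]] + slope2 * qol
  }
}

#' Calibrate missingness intercepts to target proportions
#'
#' For each wave and variable, solves for the intercept such that the mean
#' logistic probability over the calibration cohort equals the target
#' proportion, by monotone root-finding (tolerance 1e-6). A target of zero
#' yields the "never missing" sentinel (`-Inf`). The returned model
#' reproduces the targets in expectation on fresh cohorts from the same
#' generator.
#'
#' @param cohort a fully observed [cohort_table()] used for calibration.
#' @param model a [mar_model()] with targets and slopes set.
#' @return the model with calibrated intercepts.
#' @export
calibrate_intercepts <- function(cohort, model = mar_model()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (any(is.na(cohort$data))) stop("calibration cohort must be fully observed")
  for (k in seq_len(nrow(model))) {
    tgt <- model$target[k]
    if (tgt == 0) { model$intercept[k] <- -Inf; next }
    s <- mar_driver(cohort, model$variable[k], model$wave[k],
                    model$slope1[k], model$slope2[k])
    f <- function(a) mean(expit(a + s)) - tgt
    # mean(expit(a + s)) is strictly increasing in a, from 0 to 1
    root <- stats::uniroot(f, lower = -50, upper = 50, tol = 1e-9)
    if (abs(f(root$root)) > 1e-6)
      stop(sprintf("calibration failed for %s wave %d (target %.3f)",
                   model$variable[k], model$wave[k], tgt))
    model$intercept[k] <- root$root
  }
  model
}

#' Apply MAR amputation to a cohort
#'
#' Independently sets each maskable cell to missing with its model
#' probability. The pre-mask values are retained in the cohort's `shadow`
#' for oracle checks; the outcome (QoL z-score) and all baseline variables
#' are never masked. With `monotone_dropout = TRUE`, a subject masked at
#' wave j for a variable is additionally masked at all later waves of that
#' variable, emulating dropout.
#'
#' @param cohort a fully observed [cohort_table()].
#' @param model a calibrated [mar_model()].
#' @param seed integer seed.
#' @param monotone_dropout propagate masks to later waves.
#' @return the amputed `cohort_table` (with shadow).
#' @export
apply_mar <- function(cohort, model, seed = 1L, monotone_dropout = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(model, "mar_model"))
  if (any(is.na(cohort$data)))
    stop("apply_mar expects a fully observed cohort (already amputed?)")
  if (any(is.na(model$intercept)))
    stop("missingness model is not calibrated; run calibrate_intercepts()")
  n <- n_subjects(cohort)
  out <- cohort$data
  with_seed(seed, {
    for (k in seq_len(nrow(model))) {
      if (model$intercept[k] == -Inf) next
      pmiss <- expit(model$intercept[k] +
                       mar_driver(cohort, model$variable[k], model$wave[k],
                                  model$slope1[k], model$slope2[k]))
      hit <- stats::runif(n) < pmiss
      col <- paste0(model$variable[k], "_w", model$wave[k])
      out[[col]][hit] <- NA
    }
  })
  if (monotone_dropout) {
    for (v in c("BMIz", "FamStruc")) {
      cols <- wave_cols(v, cohort$n_waves)
      m <- as.matrix(out[cols])
      miss <- t(apply(is.na(m), 1L, cummax)) > 0
      m[miss] <- NA
      out[cols] <- as.data.frame(m)
    }
  }
  cohort_table(out, cohort$n_waves, shadow = cohort$data)
}

#' Per-wave, per-variable missing proportions
#'
#' @param cohort a `cohort_table`.
#' @return data.frame with columns `variable`, `wave`, `prop_missing`.
#' @export
missingness_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vars <- c("ageyr", "FamStruc", "BMIz", "QoLz")
  out <- expand.grid(variable = vars, wave = seq_len(cohort$n_waves),
                     stringsAsFactors = FALSE)
  out$prop_missing <- mapply(function(v, j) {
    mean(is.na(cohort$data[[paste0(v, "_w", j)]]))
  }, out$variable, out$wave)
  out[order(out$variable, out$wave), ]
}

#' Read/write a missingness model as a YAML config
#'
#' @param model a `mar_model`.
#' @param path file path.
#' @return `read_mar_model()` returns a `mar_model`.
#' @export
write_mar_model <- function(model, path) {
  rows <- lapply(seq_len(nrow(model)), function(k) {
    list(variable = model$variable[k], wave = model$wave[k],
         intercept = if (is.finite(model$intercept[k]))
           model$intercept[k] else "never",
         slope1 = model$slope1[k], slope2 = model$slope2[k],
         target = model$target[k])
  })
  yaml::write_yaml(list(missingness = rows), path, precision = 15L)
  invisible(path)
}

#' @rdname write_mar_model
#' @export
read_mar_model <- function(path) {
  rows <- yaml::read_yaml(path)$missingness
  m <- do.call(rbind, lapply(rows, function(r) {
    data.frame(variable = r$variable, wave = as.integer(r$wave),
               intercept = if (identical(r$intercept, "never")) -Inf
                           else as.numeric(r$intercept),
               slope1 = r$slope1, slope2 = r$slope2, target = r$target)
  }))
  class(m) <- c("mar_model", "data.frame")
  m
}
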