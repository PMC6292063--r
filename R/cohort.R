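#' Cohort tables
#'
#' A `cohort_table` is the package's central container: one row per subject in
#' wide format, with baseline columns (`subject_id`, `sex`, `language`,
#' `moedu`, `SEP`) and wave-indexed columns `ageyr_w1..ageyr_wJ`,
#' `FamStruc_w1..`, `BMIz_w1..`, `QoLz_w1..` (wave index 1-based). Missing
#' cells are `NA`; the missingness mask is therefore `is.na()` on the data.
#' When a cohort has been amputed, the pre-mask values are retained in a
#' `shadow` copy for oracle checks only — no estimation routine reads it.
#'
#' @param data wide-format data.frame following the column schema.
#' @param n_waves number of waves J.
#' @param shadow optional complete copy of `data` from before amputation.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(data, n_waves, shadow = NULL) {
  n_waves <- as.integer(n_waves)
  need <- c("subject_id", "sex", "language", "moedu", "SEP",
            wave_cols("ageyr", n_waves), wave_cols("FamStruc", n_waves),
            wave_cols("BMIz", n_waves), wave_cols("QoLz", n_waves))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("cohort data is missing columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), need)
  if (length(extra))
    stop("unknown cohort columns: ", paste(extra, collapse = ", "))
  structure(list(data = data[need], n_waves = n_waves, shadow = shadow),
            class = "cohort_table")
}

wave_cols <- function(prefix, n_waves, waves = seq_len(n_waves)) {
  paste0(prefix, "_w", waves)
}

#' @exportS3Method base::print
print.cohort_table <- function(x, ...) {
  n_miss <- sum(is.na(x$data))
  cat(sprintf("cohort_table: %d subjects x %d waves, %d missing cells%s\n",
              nrow(x$data), x$n_waves, n_miss,
              if (!is.null(x$shadow)) " (amputed; shadow retained)" else ""))
  invisible(x)
}

#' @exportS3Method base::dim
dim.cohort_table <- function(x) dim(x$data)

#' Number of subjects in a cohort
#' @param cohort a `cohort_table`.
#' @return integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$data)

#' Missingness mask of a cohort
#' @param cohort a `cohort_table`.
#' @return logical matrix, `TRUE` where a cell is missing.
#' @export
cohort_mask <- function(cohort) is.na(as.matrix(cohort$data[-1L]))

#' Reshape a cohort to long format
#'
#' One row per subject-wave with columns `subject_id`, `wave`, `ageyr`,
#' `FamStruc`, `BMIz`, `QoLz`, and the baseline columns repeated. Rows are
#' ordered by subject then wave.
#'
#' @param cohort a `cohort_table`.
#' @return a long-format data.frame with `n_subjects * n_waves` rows.
#' @export
to_long <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  J <- cohort$n_waves
  n <- nrow(d)
  idx <- rep(seq_len(n), each = J)
  long <- data.frame(
    subject_id = d$subject_id[idx],
    wave = rep(seq_len(J), times = n),
    sex = d$sex[idx], language = d$language[idx], moedu = d$moedu[idx],
    SEP = d$SEP[idx]
  )
  for (v in c("ageyr", "FamStruc", "BMIz", "QoLz")) {
    m <- as.matrix(d[wave_cols(v, J)])
    long[[v]] <- as.vector(t(m))
  }
  long
}

#' Reshape a long table back to a wide cohort
#'
#' Inverse of [to_long()]: `to_wide(to_long(x), x$n_waves)` reproduces the
#' values and the missingness mask of `x` exactly.
#'
#' @param long a long-format data.frame as produced by [to_long()].
#' @param n_waves number of waves.
#' @return a `cohort_table` (without shadow).
#' @export
to_wide <- function(long, n_waves) {
  n_waves <- as.integer(n_waves)
  need <- c("subject_id", "wave", "sex", "language", "moedu", "SEP",
            "ageyr", "FamStruc", "BMIz", "QoLz")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stop("long table is missing columns: ", paste(missing_cols, collapse = ", "))
  long <- long[order(long$subject_id, long$wave), , drop = FALSE]
  if (!all(long$wave %in% seq_len(n_waves)))
    stop("wave column contains values outside 1..n_waves")
  ids <- unique(long$subject_id)
  if (nrow(long) != length(ids) * n_waves)
    stop("long table must contain exactly one row per subject-wave")
  first <- long[!duplicated(long$subject_id), ]
  wide <- data.frame(subject_id = first$subject_id, sex = first$sex,
                     language = first$language, moedu = first$moedu,
                     SEP = first$SEP)
  for (v in c("ageyr", "FamStruc", "BMIz", "QoLz")) {
    m <- matrix(long[[v]], ncol = n_waves, byrow = TRUE)
    colnames(m) <- wave_cols(v, n_waves)
    wide <- cbind(wide, as.data.frame(m))
  }
  cohort_table(wide, n_waves)
}
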