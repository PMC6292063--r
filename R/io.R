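#' Read and write cohort tables as CSV
#'
#' Wide format: header `subject_id,sex,language,moedu,SEP,ageyr_w1..,
#' FamStruc_w1..,BMIz_w1..,QoLz_w1..` (wave suffix `_w{j}`, 1-based). Long
#' format: one row per subject-wave as produced by [to_long()]. Dialect:
#' comma-separated, UTF-8, "." decimal; an empty cell is a missing value and
#' round-trips to the missingness mask losslessly. Unknown columns raise an
#' error listing the offenders.
#'
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @param n_waves wave count; inferred from the header for wide files.
#' @return `read_cohort()` returns a `cohort_table`.
#' @export
read_cohort <- function(path, format = c("wide", "long"), n_waves = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    if (is.null(n_waves)) n_waves <- max(df$wave)
    return(to_wide(df, n_waves))
  }
  if (is.null(n_waves)) {
    ageyr_cols <- grep("^ageyr_w[0-9]+$", names(df), value = TRUE)
    if (!length(ageyr_cols)) stop("no ageyr_w* columns found in header")
    n_waves <- max(as.integer(sub("ageyr_w", "", ageyr_cols)))
  }
  cohort_table(df, n_waves)
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- if (format == "wide") cohort$data else to_long(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Persist an imputation set
#'
#' Writes one wide CSV per completed copy plus a JSON manifest holding the
#' method, seed, iteration controls and a diagnostics summary.
#'
#' @param imps an [imputation_set()].
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_imputation_set <- function(imps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(imps$imputations))
    write_cohort(imps$imputations[[i]],
                 file.path(dir, sprintf("imputation_%03d.csv", i)))
  cfg <- imps$config
  manifest <- list(
    method = imps$method, m = imps$m, seed = imps$seed,
    controls = cfg[setdiff(names(unclass(cfg)), "method")],
    diagnostics = if (!is.null(imps$diagnostics) && nrow(imps$diagnostics))
      lapply(as.data.frame(imps$diagnostics), function(x)
        c(first = x[1L], last = x[length(x)]))
    else NULL)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read and write a study configuration as YAML
#'
#' Round-trips the scalar fields, generator parameters and missingness
#' targets/slopes of a [study_config()] losslessly.
#'
#' @param cfg a `study_config`.
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  mar <- cfg$mar
  lst <- list(
    methods = cfg$methods, K = cfg$K, n = cfg$n, m = cfg$m, seed = cfg$seed,
    models = cfg$models, zcut = cfg$zcut, truth_N = cfg$truth_N,
    mi_args = cfg$mi_args,
    params = lapply(unclass(cfg$params), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    mar = lapply(seq_len(nrow(mar)), function(k)
      list(variable = mar$variable[k], wave = mar$wave[k],
           slope1 = mar$slope1[k], slope2 = mar$slope2[k],
           target = mar$target[k]))
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pl <- lapply(lst$params, function(x)
    if (is.list(x)) unlist(x) else x)
  pl$n_waves <- as.integer(pl$n_waves)
  params <- do.call(gen_params, pl)
  mar_df <- do.call(rbind, lapply(lst$mar, function(r)
    data.frame(variable = r$variable, wave = as.integer(r$wave),
               slope1 = r$slope1, slope2 = r$slope2, target = r$target)))
  mar <- mar_model(targets = mar_df[c("variable", "wave", "target")],
                   slopes = mar_df[c("variable", "wave", "slope1", "slope2")])
  study_config(methods = unlist(lst$methods), K = lst$K, n = lst$n,
               m = lst$m, seed = lst$seed, params = params, mar = mar,
               models = unlist(lst$models), zcut = lst$zcut,
               mi_args = lst$mi_args %||% list(), truth_N = lst$truth_N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
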