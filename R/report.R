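#' Write study figures and tables
#'
#' Produces the standard comparison graphics from a study result: per-method
#' bias distributions (boxplots over replicates, one panel per coefficient)
#' and per-method coverage dot-plots with a dashed reference line at the
#' nominal 0.95, plus the performance summary and tidy estimates as CSV.
#' No computation happens here beyond what the summary already holds.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @param device figure format, `"png"` or `"svg"`.
#' @return invisibly, the paths written.
#' @importFrom rlang .data
#' @export
report <- function(study, dir = "longmi-report", device = "png") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  est <- merge(study$estimates, study$truths, by = c("model", "term"))
  est$bias <- est$estimate - est$truth
  for (model in sort(unique(est$model))) {
    dm <- est[est$model == model & est$term != "(Intercept)", ]
    p_bias <- ggplot2::ggplot(dm, ggplot2::aes(x = .data$method,
                                               y = .data$bias)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "Bias",
                    title = sprintf("Bias distribution, analysis model %d", model)) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    f <- file.path(dir, sprintf("bias_model%d.%s", model, device))
    ggplot2::ggsave(f, p_bias, width = 9, height = 6, dpi = 150)
    paths <- c(paths, f)

    sm <- study$summary[study$summary$model == model &
                          study$summary$term != "(Intercept)", ]
    p_cov <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$method,
                                              y = .data$coverage)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
      ggplot2::facet_wrap(~term) +
      ggplot2::labs(x = NULL, y = "95% CI coverage",
                    title = sprintf("Coverage, analysis model %d", model)) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    f <- file.path(dir, sprintf("coverage_model%d.%s", model, device))
    ggplot2::ggsave(f, p_cov, width = 9, height = 6, dpi = 150)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "performance_summary.csv")
  utils::write.csv(study$summary, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "estimates.csv")
  utils::write.csv(study$estimates, f, row.names = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}
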