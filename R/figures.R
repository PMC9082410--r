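## Diagnostic figures written by the pipeline. Kept separate so the numeric
## pipeline works on headless systems without a graphics device.

#' Concentration-curve plot
#'
#' @param cres A [concentration_index()] result.
#' @return A ggplot object.
#' @export
plot_concentration_curve <- function(cres) {
  stopifnot(inherits(cres, "concentration_result"))
  ggplot2::ggplot(cres$curve, ggplot2::aes(x = p, y = L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2b6cb0", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative population share (ranked by living standard)",
      y = "Cumulative outcome share",
      title = sprintf("Concentration curve (CI = %.4f)", cres$ci)) +
    ggplot2::theme_minimal()
}

#' Lasso coefficient-path plot
#'
#' @param fit A [cv_select_lambda()] result.
#' @return A ggplot object.
#' @export
plot_lasso_path <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  p <- nrow(fit$std_path)
  df <- data.frame(
    lambda = rep(fit$lambda_grid, each = p),
    term = rep(rownames(fit$std_path), times = length(fit$lambda_grid)),
    coef = as.vector(fit$std_path)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = log10(lambda), y = coef, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(fit$selected_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10(lambda)", y = "Standardized coefficient",
                  title = "Lasso regularization path",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Decomposition contribution bar chart
#'
#' @param dec A [wagstaff_decomposition()] result.
#' @return A ggplot object.
#' @export
plot_contributions <- function(dec) {
  stopifnot(inherits(dec, "wagstaff_decomposition"))
  tab <- rbind(dec$table[c("factor", "pct_contribution")],
               data.frame(factor = "residual", pct_contribution = dec$residual_pct))
  tab$factor <- factor(tab$factor, levels = rev(tab$factor))
  ggplot2::ggplot(tab, ggplot2::aes(x = pct_contribution, y = factor)) +
    ggplot2::geom_col(fill = "#2b6cb0") +
    ggplot2::labs(x = "Contribution to total inequality (%)", y = NULL,
                  title = "Decomposition of the concentration index") +
    ggplot2::theme_minimal()
}

#' Outcome distribution by ranking-variable quartile
#'
#' @param outcome Numeric outcome vector.
#' @param ranking Numeric ranking vector.
#' @return A ggplot object.
#' @export
plot_outcome_by_quartile <- function(outcome, ranking) {
  qg <- quantile_group(ranking, 4)
  df <- data.frame(quartile = factor(qg, labels = paste0("Q", sort(unique(qg)))),
                   outcome = outcome)
  ggplot2::ggplot(df, ggplot2::aes(x = quartile, y = outcome)) +
    ggplot2::geom_boxplot(fill = "#bee3f8") +
    ggplot2::labs(x = "Consumption quartile", y = "Health-education score",
                  title = "Outcome by consumption quartile") +
    ggplot2::theme_minimal()
}

write_figures <- function(outdir, data, cres, dec, pds, outcome_col) {
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  save_one <- function(plot, name) {
    ggplot2::ggsave(file.path(figdir, name), plot, width = 6, height = 5,
                    dpi = 120)
  }
  save_one(plot_concentration_curve(cres), "concentration_curve.png")
  if (!is.null(pds$step_outcome)) {
    save_one(plot_lasso_path(pds$step_outcome), "lasso_path.png")
  }
  save_one(plot_contributions(dec), "contributions.png")
  save_one(plot_outcome_by_quartile(data[[outcome_col]], data$consumption),
           "outcome_by_quartile.png")
  invisible(figdir)
}
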