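#' Predicted versus actual age from a LOOCV run
#'
#' One point per held-out sample, coloured by dataset, with the identity
#' line. The vertical distance to the line is AA_diff.
#'
#' @param object A `loocv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loocv_result
#' @export
autoplot.loocv_result <- function(object, ...) {
  p <- object$predictions
  ggplot2::ggplot(p, ggplot2::aes(x = .data$actual_age,
                                  y = .data$predicted_age,
                                  colour = .data$dataset_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Actual age (years)", y = "Predicted age (years)",
                  colour = "Dataset") +
    ggplot2::theme_minimal()
}

#' Age acceleration as a function of age
#'
#' Shows AA_diff (or AA_resid) against actual age; AA_resid is uncorrelated
#' with age within each group by construction.
#'
#' @param table Tibble from [compute_aa()] or `loocv()$predictions`.
#' @param statistic `"aa_diff"` or `"aa_resid"`.
#' @return A ggplot.
#' @export
plot_age_acceleration <- function(table, statistic = c("aa_diff",
                                                       "aa_resid")) {
  statistic <- match.arg(statistic)
  grp <- if ("dataset_id" %in% names(table)) "dataset_id" else "group"
  ggplot2::ggplot(table, ggplot2::aes(x = .data$actual_age,
                                      y = .data[[statistic]],
                                      colour = .data[[grp]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Actual age (years)",
                  y = sprintf("%s (years)", toupper(statistic)),
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Volcano plot of an age EWAS
#'
#' Effect size (methylation change per year) against -log10 p, probes below
#' the FDR threshold highlighted.
#'
#' @param object An `ewas_table`.
#' @param fdr_cut Highlight threshold (default 0.005).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ewas_table
#' @export
autoplot.ewas_table <- function(object, fdr_cut = 0.005, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$fdr < fdr_cut
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Methylation change per year of age",
                  y = expression(-log[10](italic(p))),
                  colour = sprintf("FDR < %g", fdr_cut)) +
    ggplot2::theme_minimal()
}

#' Calibration map diagnostic plot
#'
#' The monotone source-to-gold transform over \[0, 1\] with the identity for
#' reference and the state boundaries marked.
#'
#' @param map A `calibration_map`.
#' @param n_grid Grid resolution.
#' @return A ggplot.
#' @export
plot_calibration_map <- function(map, n_grid = 512) {
  grid <- seq(0.001, 0.999, length.out = n_grid)
  df <- tibble::tibble(source = grid, calibrated = map$transform(grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source,
                                   y = .data$calibrated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = unname(map$boundaries), linetype = 3) +
    ggplot2::labs(x = "Source beta", y = "Calibrated beta") +
    ggplot2::theme_minimal()
}
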