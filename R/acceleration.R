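#' Age-acceleration statistics
#'
#' AA_diff is predicted minus actual age. AA_resid is the residual from an
#' ordinary least-squares regression of predicted on actual age, computed
#' separately within each evaluation group (typically the held-out dataset);
#' it is exactly uncorrelated with actual age within each group, hence
#' insensitive to the group's mean age. Groups with fewer than 3 samples get
#' `NA` AA_resid. Within a group of constant actual age the regression
#' reduces to the intercept, so AA_resid centres the predictions.
#'
#' @param predicted,actual Ages in years, equal length.
#' @param group_ids Evaluation group per sample; a single group when `NULL`.
#' @param pooled Regress over all samples at once instead of per group.
#' @return Tibble with `predicted_age`, `actual_age`, `group`, `aa_diff`,
#'   `aa_resid`.
#' @export
compute_aa <- function(predicted, actual, group_ids = NULL, pooled = FALSE) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (is.null(group_ids) || pooled) group_ids <- rep("all", length(predicted))
  if (length(group_ids) != length(predicted)) {
    stop("group_ids must match sample count", call. = FALSE)
  }
  out <- tibble::tibble(predicted_age = as.numeric(predicted),
                        actual_age = as.numeric(actual),
                        group = as.character(group_ids))
  out$aa_diff <- out$predicted_age - out$actual_age
  out$aa_resid <- NA_real_
  for (g in unique(out$group)) {
    idx <- which(out$group == g)
    ok <- idx[!is.na(out$actual_age[idx]) & !is.na(out$predicted_age[idx])]
    if (length(ok) < 3) next
    fit <- stats::lm(out$predicted_age[ok] ~ out$actual_age[ok])
    out$aa_resid[ok] <- stats::residuals(fit)
  }
  out
}

#' Per-group accuracy summary of an acceleration table
#'
#' Reports, per evaluation group: sample size, Pearson r between predicted
#' and actual age (NA, i.e. "not computed", when the group's age is constant
#' or n < 4), median |AA_diff|, mean AA_diff and median |AA_resid|.
#'
#' @param table Tibble from [compute_aa()] (or any tibble with
#'   `predicted_age`, `actual_age`, `aa_diff`, `aa_resid`).
#' @param group Group labels; defaults to the table's `group` column.
#' @return Tibble with columns `group`, `n`, `r`, `median_abs_aa_diff`,
#'   `mean_aa_diff`, `median_abs_aa_resid`.
#' @export
summarize_accuracy <- function(table, group = NULL) {
  if (is.null(group)) group <- table$group
  if (is.null(group)) group <- rep("all", nrow(table))
  table$..group <- as.character(group)
  table |>
    dplyr::group_by(.data$..group) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 4 &&
              stats::sd(.data$actual_age, na.rm = TRUE) > 0) {
        stats::cor(.data$predicted_age, .data$actual_age,
                   use = "complete.obs")
      } else NA_real_,
      median_abs_aa_diff = stats::median(abs(.data$aa_diff), na.rm = TRUE),
      mean_aa_diff = mean(.data$aa_diff, na.rm = TRUE),
      median_abs_aa_resid = stats::median(abs(.data$aa_resid), na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::rename(group = "..group")
}

#' Paired comparison of two clocks' absolute age acceleration
#'
#' Two-sided paired t-test on per-sample absolute age accelerations (AA_diff
#' or AA_resid). When every paired difference is exactly zero the clocks are
#' identical and `t = 0, p = 1` is reported; nonzero constant differences
#' (zero variance) are an error. Significance is flagged at p < 0.005.
#'
#' @param abs_aa_clock1,abs_aa_clock2 Equal-length vectors of absolute AA,
#'   paired by sample; n >= 3.
#' @param sig_level Significance threshold (default 0.005).
#' @return Tibble with `mean_difference`, `t`, `df`, `p`, `significant`.
#' @export
compare_clocks <- function(abs_aa_clock1, abs_aa_clock2, sig_level = 0.005) {
  if (length(abs_aa_clock1) != length(abs_aa_clock2)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(abs_aa_clock1) & !is.na(abs_aa_clock2)
  d <- abs_aa_clock1[ok] - abs_aa_clock2[ok]
  n <- length(d)
  if (n < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (all(d == 0)) {
    return(tibble::tibble(mean_difference = 0, t = 0, df = n - 1, p = 1,
                          significant = FALSE))
  }
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  tt <- stats::t.test(d)
  tibble::tibble(mean_difference = mean(d),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 significant = tt$p.value < sig_level)
}
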