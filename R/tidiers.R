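#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the weights of a fitted clock
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble with `probe_id`, `weight` (transformed-age units per beta
#'   unit) and `gold_beta` (the gold-standard mean at that probe).
#' @method tidy clock_model
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(probe_id = names(x$weights),
                 weight = unname(x$weights),
                 gold_beta = unname(x$gold_profile[names(x$weights)]))
}

#' @rdname tidy.clock_model
#' @return `glance()` returns a one-row tibble with the model's
#'   hyperparameters and weight count.
#' @method glance clock_model
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(n_weights = length(x$weights), intercept = x$intercept,
                 adult_age = x$adult_age, alpha = x$alpha, lambda = x$lambda,
                 gold_standard_id = x$gold_standard_id)
}

#' Tidy a leave-one-dataset-out evaluation
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-dataset accuracy summary; `glance()` a
#'   one-row tibble with the across-dataset averages (the "mean of
#'   per-dataset medians" convention) and the pooled correlation.
#' @export
tidy.loocv_result <- function(x, ...) x$summary

#' @rdname tidy.loocv_result
#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  p <- x$predictions
  tibble::tibble(
    n_datasets = nrow(x$summary),
    n_samples = nrow(p),
    mean_median_abs_aa_diff = mean(x$summary$median_abs_aa_diff),
    mean_r = mean(x$summary$r, na.rm = TRUE),
    pooled_r = stats::cor(p$predicted_age, p$actual_age,
                          use = "complete.obs"),
    median_abs_aa_resid = mean(x$summary$median_abs_aa_resid, na.rm = TRUE)
  )
}

#' Tidy a beta-mixture fit
#'
#' @param x A `beta_mixture_fit`.
#' @param ... Unused.
#' @return Tibble with one row per state: weight, shapes, implied mean.
#' @method tidy beta_mixture_fit
#' @export
tidy.beta_mixture_fit <- function(x, ...) {
  tibble::tibble(state = c("hypo", "hemi", "hyper"),
                 weight = x$weights, shape_a = x$shape_a,
                 shape_b = x$shape_b,
                 mean = x$shape_a / (x$shape_a + x$shape_b))
}
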