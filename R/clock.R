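#' Training configuration for an epigenetic clock
#'
#' @param alpha Elastic-net mixing weight in \[0, 1\] (default 0.5).
#' @param n_folds Cross-validation folds for selecting lambda (default 10).
#' @param lambda_rule `"min"` (CV-minimum, default) or `"1se"`.
#' @param adult_age Pivot (years) of the age transform (default 20).
#' @param standardize Standardize predictors inside the solver (default TRUE).
#' @param seed Integer seed controlling CV fold assignment.
#' @return A list of class `clock_train_config`.
#' @export
clock_train_config <- function(alpha = 0.5, n_folds = 10,
                               lambda_rule = c("min", "1se"), adult_age = 20,
                               standardize = TRUE, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (adult_age <= 0) stop("adult_age must be > 0", call. = FALSE)
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_rule = lambda_rule, adult_age = adult_age,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "clock_train_config")
}

#' Piecewise log-linear age transform
#'
#' Ages at or below the adult pivot are log-compressed,
#' `log((age + 1) / (adult_age + 1))`; adult ages are linear,
#' `(age - adult_age) / (adult_age + 1)`. The transform is continuous,
#' strictly increasing, zero at the pivot, and matches the convention used by
#' penalized-regression age clocks. `inverse_transform_age()` is its exact
#' inverse.
#'
#' @param age Ages in years (>= 0), vectorized.
#' @param adult_age Pivot in years (default 20).
#' @return Transformed ages (unitless).
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(age < 0, na.rm = TRUE)) stop("age must be >= 0", call. = FALSE)
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @param t Transformed ages.
#' @export
inverse_transform_age <- function(t, adult_age = 20) {
  ifelse(t <= 0,
         (adult_age + 1) * exp(t) - 1,
         adult_age + t * (adult_age + 1))
}

# stack a list of datasets (shared probe set) into samples x probes, plus
# aligned ages and dataset labels from the sheets
assemble_training <- function(datasets, sheets, require_age = TRUE) {
  probes <- probe_ids(datasets[[1]])
  for (ds in datasets) {
    if (!identical(probe_ids(ds), probes)) {
      stop("probe set mismatch between datasets; run intersect_probes() first",
           call. = FALSE)
    }
  }
  sheet <- sample_sheet(dplyr::bind_rows(lapply(sheets, tibble::as_tibble)))
  x <- t(do.call(cbind, lapply(datasets, function(d) d$beta)))
  idx <- match(rownames(x), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from sheets", call. = FALSE)
  sheet <- sheet[idx, ]
  if (require_age && anyNA(sheet$age)) {
    stop("all training samples must have age", call. = FALSE)
  }
  list(x = x, sheet = sheet, probes = probes)
}

# CV folds stratified by dataset id so no fold is a single dataset
stratified_folds <- function(dataset_id, n_folds, seed) {
  foldid <- integer(length(dataset_id))
  set.seed(seed)
  for (d in unique(dataset_id)) {
    idx <- which(dataset_id == d)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Train a transformed-age elastic-net clock
#'
#' Regresses the transformed age on all probes with an elastic-net penalty,
#' choosing lambda by k-fold cross-validation (folds stratified by dataset so
#' no fold coincides with one cohort). Only probes with nonzero weight are
#' stored in the returned model, together with the gold-standard mean profile
#' used as a fallback at prediction time.
#'
#' @param datasets List of calibrated `meth_dataset` sharing one probe set.
#' @param sheets List of sample sheets (or one combined sheet) covering every
#'   sample; every training sample must have age.
#' @param cfg A [clock_train_config()].
#' @param gold_profile Named per-probe mean betas of the gold standard;
#'   defaults to the mean profile of the pooled training data.
#' @param gold_standard_id Label stored in the model.
#' @param lambda Optional fixed penalty, skipping cross-validation (used for
#'   penalty-path studies; `lambda = 0` reduces to ordinary least squares on
#'   well-conditioned data).
#' @return A `clock_model`.
#' @export
train_clock <- function(datasets, sheets, cfg = clock_train_config(),
                        gold_profile = NULL, gold_standard_id = "gold",
                        lambda = NULL) {
  if (inherits(datasets, "meth_dataset")) datasets <- list(datasets)
  if (is.data.frame(sheets)) sheets <- list(sheets)
  tr <- assemble_training(datasets, sheets)
  if (stats::sd(tr$sheet$age) == 0) {
    stop("cannot fit clock on constant age", call. = FALSE)
  }
  y <- transform_age(tr$sheet$age, cfg$adult_age)
  if (is.null(lambda)) {
    foldid <- stratified_folds(tr$sheet$dataset_id, cfg$n_folds, cfg$seed)
    cv <- glmnet::cv.glmnet(tr$x, y, alpha = cfg$alpha, foldid = foldid,
                            standardize = cfg$standardize,
                            family = "gaussian")
    lambda <- if (cfg$lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    co <- as.matrix(stats::coef(cv, s = lambda))
  } else {
    # a decreasing path ending at the requested penalty keeps the
    # coordinate-descent warm starts accurate
    sx <- scale(tr$x)
    sx[!is.finite(sx)] <- 0 # constant probes carry no gradient
    lam_max <- max(abs(crossprod(sx, y - mean(y)))) /
      (nrow(tr$x) * max(cfg$alpha, 0.001))
    if (lambda >= lam_max) {
      path <- unique(c(lambda * 1.5, lambda))
    } else {
      path <- exp(seq(log(max(lam_max, 1e-10)),
                      log(max(lambda, lam_max * 1e-8)), length.out = 60))
      path <- sort(unique(c(path, lambda)), decreasing = TRUE)
    }
    fit <- glmnet::glmnet(tr$x, y, alpha = cfg$alpha, lambda = path,
                          standardize = cfg$standardize,
                          family = "gaussian", thresh = 1e-12)
    # the requested penalty sits on the fitted path: take it exactly
    idx <- which.min(abs(fit$lambda - lambda))
    co <- as.matrix(stats::coef(fit)[, idx, drop = FALSE])
  }
  w <- co[-1, 1]
  w <- w[w != 0]
  if (is.null(gold_profile)) {
    gold_profile <- rowMeans(t(tr$x))
  }
  clock_model(intercept = co[1, 1], weights = w, adult_age = cfg$adult_age,
              alpha = cfg$alpha, lambda = lambda,
              gold_standard_id = gold_standard_id,
              gold_profile = gold_profile[names(gold_profile) %in%
                                            tr$probes])
}

#' Predict age from methylation with a fitted clock
#'
#' Computes `inverse_transform(b0 + x'w)` per sample. Model probes missing
#' from the dataset are imputed from the model's gold-standard profile as
#' long as at least `min_probe_fraction` of them are present; below that the
#' call errors listing the absent probes. Predictions are clipped at 0 years.
#'
#' @param model A `clock_model`.
#' @param ds A `meth_dataset`.
#' @param min_probe_fraction Minimum fraction of model probes that must be
#'   present (default 0.95).
#' @return Tibble with `sample_id` and `predicted_age` (years).
#' @export
predict_age <- function(model, ds, min_probe_fraction = 0.95) {
  probes <- names(model$weights)
  if (length(probes) == 0) {
    pred <- rep(inverse_transform_age(model$intercept, model$adult_age),
                ncol(ds$beta))
    return(tibble::tibble(sample_id = sample_ids(ds),
                          predicted_age = pmax(pred, 0)))
  }
  present <- probes %in% probe_ids(ds)
  if (mean(present) < min_probe_fraction) {
    stop(sprintf("%d of %d model probes absent: %s", sum(!present),
                 length(probes),
                 paste(utils::head(probes[!present], 10), collapse = ", ")),
         call. = FALSE)
  }
  x <- matrix(NA_real_, nrow = length(probes), ncol = ncol(ds$beta),
              dimnames = list(probes, sample_ids(ds)))
  x[probes[present], ] <- ds$beta[probes[present], , drop = FALSE]
  if (any(!present)) {
    x[probes[!present], ] <- model$gold_profile[probes[!present]]
  }
  # per-sample missing calls also fall back to the gold profile
  if (anyNA(x)) {
    fill <- model$gold_profile[probes]
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- fill[nas]
    }
  }
  t_hat <- model$intercept + as.vector(crossprod(x, model$weights))
  tibble::tibble(sample_id = sample_ids(ds),
                 predicted_age = pmax(
                   inverse_transform_age(t_hat, model$adult_age), 0))
}

#' Leave-one-dataset-out cross-validation of the clock
#'
#' For each dataset, trains a clock on all other datasets, predicts the
#' held-out dataset, and computes the age-acceleration table. Per-dataset
#' accuracy (Pearson r when computable, median |AA_diff|, mean AA_diff,
#' median |AA_resid|) follows [summarize_accuracy()]; r is not computed for
#' held-out sets with constant age or fewer than 4 samples.
#'
#' @param datasets List of >= 3 calibrated `meth_dataset` sharing one probe
#'   set.
#' @param sheets List of sample sheets (or one combined sheet).
#' @param cfg A [clock_train_config()].
#' @param gold_profile Optional gold-standard profile passed to each
#'   training run.
#' @return List of class `loocv_result`: `predictions` (per-sample tibble
#'   with ages, AA_diff, AA_resid, held-out dataset id), `summary`
#'   (per-dataset tibble), `models` (list of per-fold `clock_model`).
#' @export
loocv <- function(datasets, sheets, cfg = clock_train_config(),
                  gold_profile = NULL) {
  if (length(datasets) < 3) stop("need >= 3 datasets for LOOCV", call. = FALSE)
  if (is.data.frame(sheets)) {
    sheet_all <- sample_sheet(sheets)
  } else {
    sheet_all <- sample_sheet(dplyr::bind_rows(lapply(sheets,
                                                      tibble::as_tibble)))
  }
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  preds <- vector("list", length(datasets))
  models <- vector("list", length(datasets))
  names(models) <- ids
  for (i in seq_along(datasets)) {
    train_ds <- datasets[-i]
    model <- train_clock(train_ds, sheet_all, cfg,
                         gold_profile = gold_profile,
                         gold_standard_id = if (is.null(gold_profile))
                           "pooled-training-mean" else "gold")
    models[[i]] <- model
    p <- predict_age(model, datasets[[i]])
    p$dataset_id <- ids[i]
    preds[[i]] <- p
  }
  pred <- dplyr::bind_rows(preds)
  pred$actual_age <- sheet_all$age[match(pred$sample_id, sheet_all$sample_id)]
  aa <- compute_aa(pred$predicted_age, pred$actual_age, pred$dataset_id)
  pred$aa_diff <- aa$aa_diff
  pred$aa_resid <- aa$aa_resid
  summ <- summarize_accuracy(pred, group = pred$dataset_id)
  structure(list(predictions = pred, summary = summ, models = models),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d datasets, %d samples\n",
              nrow(x$summary), nrow(x$predictions)))
  cat(sprintf("  mean of per-dataset median |AA_diff|: %.2f years\n",
              mean(x$summary$median_abs_aa_diff)))
  print(x$summary)
  invisible(x)
}
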