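#' Beta value from allele intensities
#'
#' Methylation fraction from methylated/unmethylated signal intensities with
#' the standard +100 offset in the denominator: `M / (U + M + 100)`. Always
#' in \[0, 1).
#'
#' @param methylated,unmethylated Non-negative intensities (vectorized).
#' @return Numeric vector of methylation fractions.
#' @export
beta_from_intensities <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  methylated / (unmethylated + methylated + 100)
}

#' Beta / M-value conversion
#'
#' `beta_to_m()` is the logit2 transform `log2(beta / (1 - beta))`, applied
#' after clipping beta into `[eps, 1 - eps]` to avoid infinities;
#' `m_to_beta()` is its exact inverse on the clipped range.
#'
#' @param beta Methylation fractions (vector or matrix).
#' @param m M values.
#' @param eps Clipping bound (default 1e-6).
#' @return Same shape as the input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  out <- 2^m / (1 + 2^m)
  out[is.infinite(m) & m > 0] <- 1
  if (is.matrix(m)) {
    dim(out) <- dim(m)
    dimnames(out) <- dimnames(m)
  }
  out
}

#' Detection information aligned to a beta matrix
#'
#' @param detection_p Numeric matrix of per-call detection p-values in
#'   \[0, 1\], same dimnames layout as the beta matrix.
#' @param bead_count Optional integer matrix of bead counts (>= 0).
#' @return A list of class `detection_info`.
#' @export
detection_info <- function(detection_p, bead_count = NULL) {
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(bead_count) && any(bead_count < 0, na.rm = TRUE)) {
    stop("bead counts must be >= 0", call. = FALSE)
  }
  structure(list(detection_p = detection_p, bead_count = bead_count),
            class = "detection_info")
}

new_qc_report <- function(samples_removed = tibble::tibble(
                            sample_id = character(), reason = character()),
                          probes_removed = tibble::tibble(
                            probe_id = character(), reason = character()),
                          mean_intercorrelation = NA_real_,
                          max_beta = NA_real_, pass = NA) {
  structure(list(samples_removed = samples_removed,
                 probes_removed = probes_removed,
                 mean_intercorrelation = mean_intercorrelation,
                 max_beta = max_beta, pass = pass),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  samples removed: %d\n", nrow(x$samples_removed)))
  cat(sprintf("  probes removed:  %d\n", nrow(x$probes_removed)))
  if (!is.na(x$mean_intercorrelation)) {
    cat(sprintf("  mean inter-correlation: %.4f\n", x$mean_intercorrelation))
  }
  if (!is.na(x$max_beta)) cat(sprintf("  max beta: %.4f\n", x$max_beta))
  if (!is.na(x$pass)) cat(sprintf("  pass: %s\n", x$pass))
  invisible(x)
}

align_detection <- function(ds, det) {
  dp <- det$detection_p
  if (!identical(dim(dp), dim(ds$beta))) {
    stop("detection matrix not aligned to dataset", call. = FALSE)
  }
  det
}

#' Remove samples with too many failed detection calls
#'
#' A sample is removed when strictly more than `max_fail_fraction` of its
#' probes have detection p-value > `p_cut` (boundary retained: a sample with
#' exactly the threshold fraction failing is kept).
#'
#' @param ds A `meth_dataset`.
#' @param det A `detection_info` aligned to `ds`.
#' @param max_fail_fraction Removal threshold on the failing fraction
#'   (default 0.10).
#' @param p_cut Detection p-value call threshold (default 0.01).
#' @return List with elements `dataset` (filtered `meth_dataset`) and
#'   `report` (`qc_report`).
#' @export
filter_samples <- function(ds, det, max_fail_fraction = 0.10, p_cut = 0.01) {
  det <- align_detection(ds, det)
  fail_frac <- colMeans(det$detection_p > p_cut, na.rm = TRUE)
  drop <- fail_frac > max_fail_fraction
  if (all(drop)) stop("all samples removed by detection filter", call. = FALSE)
  removed <- tibble::tibble(
    sample_id = colnames(ds$beta)[drop],
    reason = sprintf("detection failure fraction %.3f > %.3f",
                     fail_frac[drop], max_fail_fraction)
  )
  keep <- colnames(ds$beta)[!drop]
  list(dataset = subset_dataset(ds, samples = keep),
       report = new_qc_report(samples_removed = removed))
}

#' Remove low-quality and ambiguous probes
#'
#' Drops probes with any missing beta; any detection p-value > `p_cut`;
#' bead count < 3 in at least `bead_sample_fraction` of samples; non-CpG
#' probes; multimapping probes; SNP-associated probes; probes without
#' annotation; and, when `drop_sex_chrom`, probes on chrX/chrY. Thresholds
#' follow the usual array-QC wording literally: the bead rule is inclusive
#' ("at least 5%"), the bead cut strict ("< 3").
#'
#' @param ds A `meth_dataset`.
#' @param det A `detection_info` aligned to `ds` (bead counts optional).
#' @param ann Probe annotation tibble (see [probe_annotation()]).
#' @param drop_sex_chrom Drop chrX/chrY probes (use for mixed-sex datasets).
#' @param p_cut Detection p-value call threshold (default 0.01).
#' @param bead_sample_fraction Fraction-of-samples threshold for the bead
#'   rule (default 0.05, inclusive).
#' @return List with `dataset` and `report` as in [filter_samples()].
#' @export
filter_probes <- function(ds, det = NULL, ann, drop_sex_chrom = FALSE,
                          p_cut = 0.01, bead_sample_fraction = 0.05) {
  b <- ds$beta
  pid <- rownames(b)
  reasons <- list()
  flag <- function(mask, why) {
    if (any(mask)) reasons[[length(reasons) + 1]] <<-
        tibble::tibble(probe_id = pid[mask], reason = why)
    mask
  }
  drop <- flag(rowSums(is.na(b)) > 0, "missing beta")
  if (!is.null(det)) {
    det <- align_detection(ds, det)
    drop <- drop | flag(rowSums(det$detection_p > p_cut, na.rm = TRUE) > 0,
                        sprintf("detection p > %g", p_cut))
    if (!is.null(det$bead_count)) {
      low_frac <- rowMeans(det$bead_count < 3, na.rm = TRUE)
      drop <- drop | flag(low_frac >= bead_sample_fraction,
                          "bead count < 3 in >= 5% of samples")
    }
  }
  ann <- probe_annotation(ann)
  idx <- match(pid, ann$probe_id)
  drop <- drop | flag(is.na(idx), "unannotated")
  known <- !is.na(idx)
  mk <- function(col) {
    v <- rep(FALSE, length(pid))
    v[known] <- ann[[col]][idx[known]]
    v
  }
  drop <- drop | flag(known & !mk("is_cg"), "non-CG probe")
  drop <- drop | flag(mk("is_multimapping"), "multimapping probe")
  drop <- drop | flag(mk("is_snp_associated"), "SNP-associated probe")
  if (drop_sex_chrom) {
    sexchr <- rep(FALSE, length(pid))
    sexchr[known] <- ann$chrom[idx[known]] %in% c("chrX", "chrY", "X", "Y")
    drop <- drop | flag(sexchr, "sex chromosome")
  }
  removed <- if (length(reasons) > 0) {
    dplyr::distinct(dplyr::bind_rows(reasons), .data$probe_id,
                    .keep_all = TRUE)
  } else {
    tibble::tibble(probe_id = character(), reason = character())
  }
  keep <- pid[!drop]
  if (length(keep) == 0) stop("all probes removed", call. = FALSE)
  list(dataset = subset_dataset(ds, probes = keep),
       report = new_qc_report(probes_removed = removed))
}

#' Impute missing beta values by k-nearest neighbours over samples
#'
#' For each sample with missing calls, the `k` nearest samples (Euclidean
#' distance on the probes both samples observe, scaled to a per-probe mean
#' distance) supply the imputed value as their mean at the missing probe,
#' restricted to neighbours that observe it. Probes observed in fewer than
#' `k` samples are dropped with a warning.
#'
#' @param ds A `meth_dataset`.
#' @param k Number of neighbours (default 5).
#' @return A `meth_dataset` without missing values.
#' @export
impute_missing <- function(ds, k = 5) {
  b <- ds$beta
  if (all(is.na(b))) stop("dataset fully missing", call. = FALSE)
  if (!anyNA(b)) return(ds)
  n_obs <- rowSums(!is.na(b))
  if (any(n_obs < k)) {
    warning(sprintf("dropping %d probe(s) with fewer than %d observed samples",
                    sum(n_obs < k), k))
    b <- b[n_obs >= k, , drop = FALSE]
  }
  if (ncol(b) <= k) {
    stop(sprintf("need more than k = %d samples for kNN imputation", k),
         call. = FALSE)
  }
  obs <- !is.na(b)
  # mean squared difference over shared observed probes, per sample pair
  n <- ncol(b)
  d2 <- matrix(Inf, n, n)
  for (j in seq_len(n)) {
    shared <- obs & obs[, j]
    diffs <- (b - b[, j])^2
    diffs[!shared] <- NA
    cnt <- colSums(shared)
    d2[, j] <- ifelse(cnt > 0, colSums(diffs, na.rm = TRUE) / cnt, Inf)
  }
  diag(d2) <- Inf
  for (j in which(colSums(!obs) > 0)) {
    ord <- order(d2[, j])
    for (i in which(!obs[, j])) {
      donors <- ord[obs[i, ord]]
      donors <- donors[seq_len(min(k, length(donors)))]
      b[i, j] <- mean(b[i, donors])
    }
  }
  meth_dataset(b, ds$platform, ds$dataset_id)
}

# Newton inversion of trigamma, used by the batch-variance prior.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Location-scale empirical-Bayes batch adjustment of M values
#'
#' Per-probe standardization, per-batch location/scale estimates shrunk
#' toward method-of-moments priors pooled across probes (normal prior for the
#' location, inverse-gamma for the scale; the standard parametric
#' empirical-Bayes batch model), recentring/rescaling, then
#' de-standardization. `method = "direct"` skips the shrinkage
#' (batch effects removed exactly, appropriate when probes are few or batch
#' effects homogeneous); `method = "eb"` is the default. A second batch
#' variable (e.g. array position) is adjusted in a sequential second pass.
#'
#' @param m Numeric matrix of M values, probes x samples.
#' @param batch Batch label per sample (length `ncol(m)`).
#' @param position Optional second technical label per sample.
#' @param method `"eb"` (empirical Bayes, default) or `"direct"`.
#' @return Adjusted M-value matrix of the same shape.
#' @export
adjust_batch <- function(m, batch, position = NULL, method = c("eb", "direct")) {
  method <- match.arg(method)
  batch <- as.character(batch)
  if (length(batch) != ncol(m)) {
    stop("batch labels must match sample count", call. = FALSE)
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stop(sprintf("singleton batch: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  out <- if (length(tab) < 2) m else adjust_batch_one(m, batch, method)
  if (!is.null(position)) {
    out <- adjust_batch(out, position, NULL, method)
  }
  out
}

adjust_batch_one <- function(m, batch, method) {
  batches <- unique(batch)
  n <- ncol(m)
  n_b <- vapply(batches, function(g) sum(batch == g), numeric(1))
  # per-probe batch means and the sample-size-weighted grand mean
  bmeans <- vapply(batches, function(g)
    rowMeans(m[, batch == g, drop = FALSE]), numeric(nrow(m)))
  grand <- as.vector(bmeans %*% (n_b / n))
  resid <- m - bmeans[, match(batch, batches), drop = FALSE]
  pooled_var <- rowSums(resid^2) / n
  pooled_sd <- sqrt(pmax(pooled_var, 1e-12))
  z <- (m - grand) / pooled_sd
  gamma_hat <- vapply(batches, function(g)
    rowMeans(z[, batch == g, drop = FALSE]), numeric(nrow(m)))
  delta_hat <- vapply(batches, function(g) {
    zb <- z[, batch == g, drop = FALSE]
    rowSums((zb - rowMeans(zb))^2) / (ncol(zb) - 1)
  }, numeric(nrow(m)))
  delta_hat <- pmax(delta_hat, 1e-12)

  if (method == "direct") {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (gi in seq_along(batches)) {
      g_bar <- mean(gamma_hat[, gi])
      tau2 <- stats::var(gamma_hat[, gi])
      # inverse-gamma prior on delta^2 by moment matching
      v_bar <- mean(delta_hat[, gi])
      s2_v <- stats::var(delta_hat[, gi])
      a_prior <- if (s2_v > 0) (2 * s2_v + v_bar^2) / s2_v else Inf
      b_prior <- if (is.finite(a_prior)) (v_bar * s2_v + v_bar^3) / s2_v
                 else v_bar
      nb <- n_b[gi]
      g_new <- gamma_hat[, gi]
      d_new <- delta_hat[, gi]
      # iterate the coupled EB updates to convergence
      for (it in 1:100) {
        if (tau2 > 0) {
          g_upd <- (nb * tau2 * gamma_hat[, gi] + d_new * g_bar) /
            (nb * tau2 + d_new)
        } else {
          g_upd <- rep(g_bar, nrow(m))
        }
        ss <- rowSums((z[, batch == batches[gi], drop = FALSE] - g_upd)^2)
        if (is.finite(a_prior)) {
          d_upd <- (0.5 * ss + b_prior) / (nb / 2 + a_prior - 1)
        } else {
          d_upd <- rep(v_bar, nrow(m))
        }
        if (max(abs(g_upd - g_new), abs(d_upd - d_new)) < 1e-8) {
          g_new <- g_upd; d_new <- d_upd
          break
        }
        g_new <- g_upd; d_new <- d_upd
      }
      gamma_star[, gi] <- g_new
      delta_star[, gi] <- pmax(d_new, 1e-12)
    }
  }
  bi <- match(batch, batches)
  z_adj <- (z - gamma_star[, bi, drop = FALSE]) /
    sqrt(delta_star[, bi, drop = FALSE])
  # recentre so the per-probe grand mean is preserved exactly
  z_adj <- z_adj - rowMeans(z_adj)
  z_adj * pooled_sd + grand
}

#' Restrict datasets to their common probe set
#'
#' @param datasets List of `meth_dataset` (>= 2).
#' @return List of `meth_dataset`, each restricted to the ordered
#'   intersection of probe ids (order taken from the first dataset).
#' @export
intersect_probes <- function(datasets) {
  if (length(datasets) < 2) stop("need at least 2 datasets", call. = FALSE)
  common <- Reduce(intersect, lapply(datasets, probe_ids))
  if (length(common) == 0) stop("empty probe intersection", call. = FALSE)
  common <- probe_ids(datasets[[1]])[probe_ids(datasets[[1]]) %in% common]
  message(sprintf("intersect_probes: %d probes in common across %d datasets",
                  length(common), length(datasets)))
  lapply(datasets, subset_dataset, probes = common)
}

#' Dataset-level quality control
#'
#' Computes the mean pairwise Pearson correlation between samples and the
#' matrix maximum beta; a dataset passes when the mean inter-correlation
#' exceeds `min_correlation` and the maximum beta exceeds `min_max_beta`.
#' Failure is flagged (with a warning), not a hard stop: the thresholds are
#' an inclusion screen for external datasets.
#'
#' @param ds A `meth_dataset` with >= 2 samples.
#' @param min_correlation Threshold on the mean inter-correlation
#'   (default 0.97, strict).
#' @param min_max_beta Threshold on the maximum beta (default 0.99, strict).
#' @return A `qc_report`.
#' @export
qc_dataset <- function(ds, min_correlation = 0.97, min_max_beta = 0.99) {
  if (ncol(ds$beta) < 2) stop("need >= 2 samples for QC", call. = FALSE)
  cc <- stats::cor(ds$beta, use = "pairwise.complete.obs")
  mean_cor <- mean(cc[upper.tri(cc)])
  mx <- max(ds$beta, na.rm = TRUE)
  pass <- (mean_cor > min_correlation) && (mx > min_max_beta)
  if (!pass) {
    warning(sprintf(
      "dataset '%s' fails QC: mean inter-correlation %.4f, max beta %.4f",
      ds$dataset_id, mean_cor, mx))
  }
  new_qc_report(mean_intercorrelation = mean_cor, max_beta = mx, pass = pass)
}
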