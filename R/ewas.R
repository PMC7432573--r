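#' Estimate the moderated-variance prior from per-probe variances
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to residual
#' variances, matching the mean and variance of `log(s^2)` via digamma /
#' trigamma inversion. When the spread of the log-variances does not exceed
#' what a common variance would produce, the prior degrees of freedom are
#' infinite and the prior variance is the common value.
#'
#' @param s_sq Per-probe residual variances (>= 100 values, all > 0).
#' @param d Residual degrees of freedom of each variance.
#' @return List of class `variance_prior` with `d0` (prior df, possibly
#'   `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(s_sq, d) {
  s_sq <- s_sq[!is.na(s_sq)]
  if (length(s_sq) < 100) stop("need >= 100 variances", call. = FALSE)
  if (any(s_sq <= 0)) stop("variances must be positive", call. = FALSE)
  z <- log(s_sq)
  e <- z - digamma(d / 2) + log(d / 2)
  e_bar <- mean(e)
  e_var <- stats::var(e)
  excess <- e_var - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_bar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %s, s0^2 = %.6g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone-enforced), as implemented in base R's
#' `p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of adjusted values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# consensus exchangeable intra-block correlation: pooled correlation of
# within-block residual pairs over a probe subsample
estimate_block_correlation <- function(resid, blocks, max_probes = 500) {
  blocks <- as.character(blocks)
  tab <- table(blocks)
  multi <- names(tab)[tab >= 2]
  if (length(multi) == 0) return(0)
  probes <- seq_len(nrow(resid))
  if (length(probes) > max_probes) {
    probes <- round(seq(1, nrow(resid), length.out = max_probes))
  }
  num <- 0
  den <- 0
  scale2 <- rowMeans(resid[probes, , drop = FALSE]^2)
  for (b in multi) {
    idx <- which(blocks == b)
    rb <- resid[probes, idx, drop = FALSE]
    pairs <- utils::combn(seq_along(idx), 2)
    for (k in seq_len(ncol(pairs))) {
      num <- num + sum(rb[, pairs[1, k]] * rb[, pairs[2, k]] / scale2)
      den <- den + length(probes)
    }
  }
  rho <- num / den
  min(max(rho, 0), 0.95)
}

# blockwise whitening transform for an exchangeable correlation rho:
# V = (1 - rho) I + rho J within each block; T = V^{-1/2}
whiten_blocks <- function(blocks, rho) {
  blocks <- as.character(blocks)
  n <- length(blocks)
  tmat <- matrix(0, n, n)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    if (k == 1 || rho == 0) {
      tmat[idx, idx] <- diag(1, k)
    } else {
      lam1 <- 1 + (k - 1) * rho # eigenvalue of the all-ones direction
      lam2 <- 1 - rho
      pmat <- matrix(1 / k, k, k)
      tmat[idx, idx] <- pmat / sqrt(lam1) + (diag(1, k) - pmat) / sqrt(lam2)
    }
  }
  tmat
}

#' Epigenome-wide association of methylation with age
#'
#' Per-probe linear model of methylation (beta or M values) on age plus
#' covariates (sex, dataset id by default), fitted by least squares
#' simultaneously for all probes. With a `block` column (subject id for
#' paired designs), a single consensus intra-block correlation is estimated
#' from residual pairs over a probe subsample and the model is refitted by
#' generalized least squares under an exchangeable within-block correlation
#' (`block_method = "gls"`), or with fixed subject effects
#' (`block_method = "fixed"`). Residual variances are then moderated with an
#' empirical-Bayes scaled inverse-chi-square prior: the moderated variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t has `d0 + d` degrees of
#' freedom.
#'
#' @param mat Numeric matrix, probes x samples (beta by default; pass M
#'   values and note it in reporting if preferred for modelling).
#' @param sheet Sample sheet aligned to `colnames(mat)`.
#' @param covariates Covariate columns besides age (default
#'   `c("sex", "dataset_id")`; constant columns must be removed by the
#'   caller - a rank-deficient design is an error naming aliased columns).
#' @param block Optional column name holding the block (subject) id.
#' @param block_method `"gls"` (default) or `"fixed"`.
#' @param prior Optional `variance_prior` overriding the estimated one
#'   (use `list(d0 = 0)` for unmoderated t-statistics).
#' @return Tibble of class `ewas_table` (one row per probe): `probe_id`,
#'   `slope` (methylation change per year of age), `se`, `t_ordinary`,
#'   `t_moderated`, `p`, `fdr`, `direction`; the fitted prior and the block
#'   correlation are attached as attributes `prior` and `block_rho`.
#' @export
ewas_fit <- function(mat, sheet, covariates = c("sex", "dataset_id"),
                     block = NULL, block_method = c("gls", "fixed"),
                     prior = NULL) {
  block_method <- match.arg(block_method)
  sheet <- sample_sheet(sheet)
  idx <- match(colnames(mat), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from sheet", call. = FALSE)
  sheet <- sheet[idx, ]
  if (anyNA(sheet$age)) stop("EWAS requires age for every sample",
                             call. = FALSE)

  df <- data.frame(age = sheet$age)
  for (cv in covariates) {
    v <- sheet[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv, call. = FALSE)
    fv <- if (is.numeric(v)) v else factor(v)
    if (is.factor(fv) && nlevels(fv) < 2) {
      stop("rank-deficient design; aliased columns: ", cv, call. = FALSE)
    }
    df[[cv]] <- fv
  }
  blocks <- if (!is.null(block)) sheet[[block]] else NULL
  if (!is.null(blocks) && all(is.na(blocks))) blocks <- NULL

  if (!is.null(blocks) && block_method == "fixed") {
    df$..block <- factor(as.character(blocks))
    blocks <- NULL
  }
  x <- stats::model.matrix(~ ., data = df)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  fit_ols <- function(xm, ym) {
    q <- qr(xm)
    coefs <- qr.coef(q, t(ym))           # p x probes
    resid <- t(ym) - xm %*% coefs        # n x probes
    list(coefs = coefs, resid = resid, xm = xm)
  }
  fit <- fit_ols(x, mat)
  rho <- 0
  if (!is.null(blocks)) {
    rho <- estimate_block_correlation(t(fit$resid), blocks)
    if (rho > 0) {
      tm <- whiten_blocks(blocks, rho)
      fit <- fit_ols(tm %*% x, mat %*% t(tm))
    }
  }
  n <- ncol(mat)
  d <- n - ncol(x)
  if (d <= 0) stop("no residual degrees of freedom", call. = FALSE)
  s_sq <- colSums(fit$resid^2) / d
  xtxi <- chol2inv(qr.R(qr(fit$xm)))
  v_age <- xtxi[2, 2] # "age" is the first model term after the intercept
  slope <- fit$coefs["age", ]
  se_ord <- sqrt(pmax(s_sq, 1e-300) * v_age)
  t_ord <- slope / se_ord

  if (is.null(prior)) {
    prior <- estimate_prior(s_sq, d)
  } else if (!inherits(prior, "variance_prior")) {
    prior <- structure(list(d0 = prior$d0,
                            s0_sq = if (is.null(prior$s0_sq)) mean(s_sq)
                                    else prior$s0_sq),
                       class = "variance_prior")
  }
  if (is.infinite(prior$d0)) {
    s_mod <- rep(prior$s0_sq, length(s_sq))
    df_mod <- Inf
  } else if (prior$d0 == 0) {
    s_mod <- s_sq
    df_mod <- d
  } else {
    s_mod <- (prior$d0 * prior$s0_sq + d * s_sq) / (prior$d0 + d)
    df_mod <- prior$d0 + d
  }
  t_mod <- slope / sqrt(pmax(s_mod, 1e-300) * v_age)
  p <- 2 * stats::pt(-abs(t_mod), df = df_mod)

  out <- tibble::tibble(
    probe_id = rownames(mat),
    slope = unname(slope),
    se = unname(sqrt(s_mod * v_age)),
    t_ordinary = unname(t_ord),
    t_moderated = unname(t_mod),
    p = unname(p),
    fdr = fdr_bh(unname(p)),
    direction = ifelse(slope >= 0, "hyper", "hypo")
  )
  attr(out, "prior") <- prior
  attr(out, "block_rho") <- rho
  attr(out, "df_residual") <- d
  class(out) <- c("ewas_table", class(out))
  out
}

#' Effect sizes per decade of age
#'
#' Convenience conversion of per-year slopes to the per-decade reporting
#' convention (multiply by 10; on the beta scale, times 100 gives percent
#' methylation change per decade).
#'
#' @param ewas An `ewas_table`.
#' @return The table with an added `slope_per_decade` column.
#' @export
slope_per_decade <- function(ewas) {
  ewas$slope_per_decade <- ewas$slope * 10
  ewas
}

#' Call differentially methylated regions
#'
#' Significant probes (FDR below `fdr_cut`) are sorted by chromosome and
#' position; consecutive probes are merged into a cluster while the gap stays
#' at or below `max_gap` base pairs AND the direction of change with age is
#' the same. Clusters with at least `min_probes` probes are emitted as DMRs.
#'
#' @param ewas An `ewas_table`.
#' @param ann Probe annotation (positions needed for all significant probes).
#' @param max_gap Maximum within-cluster gap in bp (default 1000).
#' @param fdr_cut Significance threshold (default 0.005).
#' @param min_probes Minimum probes per DMR (default 2).
#' @return Tibble, one row per DMR: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_probes`, `probe_ids` (list column), `direction`,
#'   `min_fdr`, `mean_slope`.
#' @export
call_dmrs <- function(ewas, ann, max_gap = 1000, fdr_cut = 0.005,
                      min_probes = 2) {
  ann <- probe_annotation(ann)
  sig <- ewas[ewas$fdr < fdr_cut, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_ids = list(), direction = character(),
                          min_fdr = numeric(), mean_slope = numeric()))
  }
  idx <- match(sig$probe_id, ann$probe_id)
  if (anyNA(idx)) {
    stop("significant probes missing from annotation: ",
         paste(utils::head(sig$probe_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  sig$chrom <- ann$chrom[idx]
  sig$pos <- ann$pos[idx]
  sig <- sig[order(sig$chrom, sig$pos), ]
  new_cluster <- c(TRUE, diff(sig$pos) > max_gap |
                     sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                     sig$direction[-1] != sig$direction[-nrow(sig)])
  sig$cluster <- cumsum(new_cluster)
  keep <- as.integer(names(which(table(sig$cluster) >= min_probes)))
  sig <- sig[sig$cluster %in% keep, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_ids = list(), direction = character(),
                          min_fdr = numeric(), mean_slope = numeric()))
  }
  sig |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      n_probes = dplyr::n(),
      probe_ids = list(.data$probe_id),
      direction = .data$direction[1],
      min_fdr = min(.data$fdr),
      mean_slope = mean(.data$slope),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# two-sided Fisher exact p and sample odds ratio for one 2x2 table
# (a = foreground in level, b = foreground out, c = background-only in level,
#  d = background-only out)
fisher_2x2 <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- (a * d) / (b * c_)
  c(or = or, p = min(p, 1))
}

#' Fisher-exact enrichment of a probe panel in annotation categories
#'
#' For each level of the chosen category, tests the 2x2 table of
#' (in/out of level) x (in/out of foreground, within the background) with a
#' two-sided Fisher exact test. The odds ratio reported is the sample odds
#' ratio. BH adjustment is applied across the levels of the category (the 4
#' island-context levels and the 15 chromatin states are corrected
#' separately).
#'
#' @param foreground Probe ids of the panel (must be a subset of
#'   `background`).
#' @param background Probe ids forming the universe.
#' @param ann Probe annotation.
#' @param category `"island_context"` or `"chromatin_state"`.
#' @return Tibble per level: `level`, `n_foreground`, `n_background`,
#'   `odds_ratio`, `p`, `fdr`.
#' @export
enrichment_fisher <- function(foreground, background, ann,
                              category = c("island_context",
                                           "chromatin_state")) {
  category <- match.arg(category)
  if (length(foreground) == 0) stop("empty foreground", call. = FALSE)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background", call. = FALSE)
  }
  ann <- probe_annotation(ann)
  levels_all <- if (category == "island_context") island_context_levels()
                else chromatin_state_levels()
  lab <- ann[[category]][match(background, ann$probe_id)]
  if (anyNA(lab)) stop("background probes missing from annotation",
                       call. = FALSE)
  in_fg <- background %in% foreground
  res <- lapply(levels_all, function(lv) {
    in_lv <- lab == lv
    a <- sum(in_fg & in_lv)
    b <- sum(in_fg & !in_lv)
    c_ <- sum(!in_fg & in_lv)
    d <- sum(!in_fg & !in_lv)
    ft <- fisher_2x2(a, b, c_, d)
    tibble::tibble(level = lv, n_foreground = a, n_background = a + c_,
                   odds_ratio = unname(ft["or"]), p = unname(ft["p"]))
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- fdr_bh(out$p)
  out
}

#' Monte-Carlo null for the overlap between two probe panels
#'
#' Draws `n_draws` uniform subsets of `draw_size` probes without replacement
#' from the background and records their overlap with `panel_b` (first
#' intersected with the background). Reports the null distribution, its
#' maximum, and the Monte-Carlo tail probability of an overlap at least as
#' large as `panel_a`'s observed overlap (with the +1 continuity correction).
#'
#' @param panel_a Probe ids whose observed overlap is evaluated.
#' @param panel_b Reference panel.
#' @param background Universe to draw from.
#' @param draw_size Size of each random panel (defaults to
#'   `length(panel_a)`).
#' @param n_draws Number of draws (default 1e6).
#' @param seed Integer seed.
#' @return List of class `overlap_null`: `observed`, `max_null`,
#'   `p_tail`, `null_mean`, `null_var`, `null_counts` (table of the null
#'   distribution).
#' @export
random_overlap_test <- function(panel_a, panel_b, background,
                                draw_size = NULL, n_draws = 1e6, seed = 1L) {
  if (is.null(draw_size)) draw_size <- length(panel_a)
  n_bg <- length(background)
  if (draw_size > n_bg) stop("draw_size exceeds background size",
                             call. = FALSE)
  in_b <- background %in% panel_b
  observed <- length(intersect(intersect(panel_a, background), panel_b))
  set.seed(seed)
  overlaps <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    overlaps[i] <- sum(in_b[sample.int(n_bg, draw_size)])
  }
  structure(
    list(observed = observed,
         max_null = max(overlaps),
         p_tail = (sum(overlaps >= observed) + 1) / (n_draws + 1),
         null_mean = mean(overlaps),
         null_var = stats::var(overlaps),
         null_counts = table(overlaps),
         draw_size = draw_size, n_draws = n_draws,
         n_background = n_bg, n_panel_b = sum(in_b)),
    class = "overlap_null"
  )
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(paste0("<overlap_null> observed %d; null max %d over %d draws ",
                     "(mean %.3f); tail p = %.3g\n"),
              x$observed, x$max_null, x$n_draws, x$null_mean, x$p_tail))
  invisible(x)
}

# Wallenius noncentral hypergeometric pmf; omega is the odds of drawing an
# in-set gene relative to an out-of-set gene. The standard integral
# representation P(x) = C(m1,x) C(m2,n-x) Int_0^1 (1-t^(w/D))^x
# (1-t^(1/D))^(n-x) dt with D = w(m1-x) + (m2-n+x) is evaluated after the
# substitution u = t^(1/D), which turns the sharply peaked integrand into a
# Beta(D, n-x+1) expectation of the smooth factor (1-u^w)^x; at w = 1 the
# expression collapses analytically to the central hypergeometric pmf.
dwallenius <- function(x, m1, m2, n, omega) {
  # reduce to omega <= 1 via the complement identity so the ratio factor
  # below stays bounded in (0, 1]
  if (omega > 1) return(dwallenius(n - x, m2, m1, n, 1 / omega))
  vapply(x, function(xi) {
    if (xi < max(0, n - m2) || xi > min(n, m1)) return(0)
    dd <- omega * (m1 - xi) + (m2 - (n - xi))
    if (dd <= 0) dd <- 1e-9
    logk <- lchoose(m1, xi) + lchoose(m2, n - xi) + log(dd) +
      lbeta(dd, n + 1)
    if (xi == 0) return(exp(logk))
    # expectation of ((1 - u^w) / (1 - u))^x under Beta(dd, n + 1); the
    # ratio is smooth and tends to w as u -> 1, and is identically 1 at
    # w = 1, where the pmf collapses to the central hypergeometric exactly
    h <- function(s) {
      u <- stats::qbeta(s, dd, n + 1)
      lr <- ifelse(1 - u < 1e-12, log(omega),
                   log1p(-u^omega) - log1p(-u))
      exp(xi * lr)
    }
    ev <- stats::integrate(h, 0, 1, rel.tol = 1e-11, abs.tol = 1e-14,
                           subdivisions = 1000L)$value
    exp(logk) * ev
  }, numeric(1))
}

# upper tail P(X >= x_obs), normalized over the support
pwallenius_upper <- function(x_obs, m1, m2, n, omega) {
  supp <- max(0, n - m2):min(n, m1)
  pmf <- dwallenius(supp, m1, m2, n, omega)
  tot <- sum(pmf)
  if (tot <= 0) return(1)
  sum(pmf[supp >= x_obs]) / tot
}

#' Bias-aware gene-set enrichment of significant probes
#'
#' A gene is scored significant when at least one significant probe maps to
#' it. Because genes with more probes are more likely to contain a
#' significant probe by chance, the null for the number of significant genes
#' inside a set is modelled as a Wallenius noncentral hypergeometric
#' distribution. Each gene's sampling weight is its null probability of
#' containing a significant probe, `1 - (1 - p)^k` for a gene with `k`
#' probes when a fraction `p` of background probes is significant - in the
#' sparse regime this is proportional to the probe count, and it remains
#' calibrated when large genes saturate. The odds parameter is the ratio of
#' the mean weight of in-set genes to that of out-of-set genes.
#' `method = "hypergeometric"` gives the naive unweighted test for
#' comparison; with equal probe counts the two coincide.
#'
#' @param significant_probes Probe ids called significant.
#' @param background_probes Universe of tested probes.
#' @param ann Probe annotation providing the probe -> genes map; the gene
#'   universe is every gene with at least one background probe.
#' @param gene_sets Named list of character vectors of gene symbols.
#' @param method `"wallenius"` (default) or `"hypergeometric"`.
#' @return Tibble per set: `set`, `n_genes`, `n_sig_genes`, `expected`,
#'   `p`, `fdr`.
#' @export
gene_set_test <- function(significant_probes, background_probes, ann,
                          gene_sets, method = c("wallenius",
                                                "hypergeometric")) {
  method <- match.arg(method)
  ann <- probe_annotation(ann)
  idx <- match(background_probes, ann$probe_id)
  if (anyNA(idx)) stop("background probes missing from annotation",
                       call. = FALSE)
  genes_per_probe <- ann$genes[idx]
  probe_gene <- tibble::tibble(
    probe_id = rep(background_probes, lengths(genes_per_probe)),
    gene = unlist(genes_per_probe)
  )
  if (nrow(probe_gene) == 0) stop("no annotated genes in background",
                                  call. = FALSE)
  counts <- probe_gene |>
    dplyr::count(.data$gene, name = "n_probes")
  sig_genes <- unique(probe_gene$gene[probe_gene$probe_id %in%
                                        significant_probes])
  counts$significant <- counts$gene %in% sig_genes
  n_sig <- sum(counts$significant)
  p_hat <- mean(unique(probe_gene$probe_id) %in% significant_probes)
  counts$weight <- if (p_hat > 0 && p_hat < 1) {
    1 - (1 - p_hat)^counts$n_probes
  } else {
    counts$n_probes
  }
  res <- lapply(names(gene_sets), function(nm) {
    in_set <- counts$gene %in% gene_sets[[nm]]
    m1 <- sum(in_set)
    if (m1 == 0) {
      stop(sprintf("gene set '%s' empty after intersection with the universe",
                   nm), call. = FALSE)
    }
    m2 <- sum(!in_set)
    x_obs <- sum(in_set & counts$significant)
    p <- if (n_sig == 0) {
      1
    } else if (m2 == 0) {
      1 # the set contains every gene in the universe
    } else if (method == "hypergeometric") {
      stats::phyper(x_obs - 1, m1, m2, n_sig, lower.tail = FALSE)
    } else {
      w_in <- mean(counts$weight[in_set])
      w_out <- mean(counts$weight[!in_set])
      pwallenius_upper(x_obs, m1, m2, n_sig, omega = w_in / w_out)
    }
    tibble::tibble(set = nm, n_genes = m1, n_sig_genes = x_obs,
                   expected = m1 * n_sig / nrow(counts), p = p)
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- fdr_bh(out$p)
  out
}
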