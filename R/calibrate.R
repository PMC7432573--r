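#' Fit a three-component beta mixture by EM
#'
#' Models a vector of methylation fractions as a mixture of three beta
#' distributions corresponding to hypo-, hemi- and hypermethylated states.
#' The E step computes posterior state responsibilities; the M step maximizes
#' the weighted beta log-likelihood of each component via its sufficient
#' statistics (a quasi-Newton step started at the current parameters, so the
#' observed-data log-likelihood never decreases). Initialization is
#' deterministic, from fixed cut points on the beta scale, so repeated fits
#' are identical.
#'
#' @param values Numeric vector of fractions; needs >= 50 values in (0, 1)
#'   after clipping.
#' @param max_iter Maximum EM iterations (default 100). Warm-started
#'   per-sample fits that stop at this cap are mildly regularized toward
#'   their starting fit, which stabilizes the resulting calibration maps;
#'   raising the cap buys full convergence at the cost of noisier maps.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @param eps Clipping bound applied before fitting (default 1e-6).
#' @param init Optional warm start: a previous `beta_mixture_fit` whose
#'   weights and shapes seed the EM.
#' @return An object of class `beta_mixture_fit` with elements `weights`
#'   (3 mixing proportions), `shape_a`, `shape_b` (component shapes, ordered
#'   by increasing mean), `loglik`, `loglik_trace`, `n_iter`.
#' @export
fit_beta_mixture <- function(values, max_iter = 100, tol = 1e-6, eps = 1e-6,
                             init = NULL) {
  x <- values[!is.na(values)]
  x <- pmin(pmax(x, eps), 1 - eps)
  if (length(x) < 50) stop("need >= 50 values to fit a beta mixture",
                           call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("degenerate input: all values equal",
                                 call. = FALSE)
  lx <- log(x)
  l1x <- log1p(-x)

  moment_shapes <- function(xs) {
    mu <- mean(xs)
    v <- max(stats::var(xs), 1e-6)
    v <- min(v, mu * (1 - mu) * 0.95)
    nu <- mu * (1 - mu) / v - 1
    c(max(mu * nu, 0.05), max((1 - mu) * nu, 0.05))
  }

  if (!is.null(init)) {
    w <- init$weights
    a <- init$shape_a
    b <- init$shape_b
  } else {
    # fixed cut points on the beta scale (hypo < 0.2, hyper > 0.75)
    grp <- cut(x, c(-Inf, 0.2, 0.75, Inf), labels = FALSE)
    if (min(table(factor(grp, levels = 1:3))) < 10) {
      qs <- stats::quantile(x, c(1 / 3, 2 / 3))
      grp <- cut(x, c(-Inf, qs, Inf), labels = FALSE)
    }
    a <- b <- w <- numeric(3)
    for (cidx in 1:3) {
      xs <- x[grp == cidx]
      if (length(xs) < 2) xs <- stats::quantile(x, c(0.1, 0.5, 0.9))
      sh <- moment_shapes(xs)
      a[cidx] <- sh[1]
      b[cidx] <- sh[2]
      w[cidx] <- max(mean(grp == cidx), 1e-3)
    }
    w <- w / sum(w)
  }

  comp_loglik <- function(par, sw, s1, s2) {
    aa <- exp(par[1]); bb <- exp(par[2])
    -(sw * (lgamma(aa + bb) - lgamma(aa) - lgamma(bb)) +
        (aa - 1) * s1 + (bb - 1) * s2)
  }
  comp_grad <- function(par, sw, s1, s2) {
    aa <- exp(par[1]); bb <- exp(par[2])
    dab <- digamma(aa + bb)
    ga <- sw * (dab - digamma(aa)) + s1
    gb <- sw * (dab - digamma(bb)) + s2
    -c(ga * aa, gb * bb)
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  n_iter <- 0
  dens <- matrix(0, length(x), 3)
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    for (cidx in 1:3) {
      dens[, cidx] <- w[cidx] * stats::dbeta(x, a[cidx], b[cidx])
    }
    rowsum_d <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    r <- dens / rowsum_d
    for (cidx in 1:3) {
      sw <- sum(r[, cidx])
      if (sw < 1e-8) next
      s1 <- sum(r[, cidx] * lx)
      s2 <- sum(r[, cidx] * l1x)
      opt <- stats::optim(log(c(a[cidx], b[cidx])), comp_loglik, comp_grad,
                          sw = sw, s1 = s1, s2 = s2, method = "BFGS",
                          control = list(maxit = 25))
      # keep the update only if it does not decrease the component objective
      if (opt$value <= comp_loglik(log(c(a[cidx], b[cidx])), sw, s1, s2)) {
        a[cidx] <- exp(opt$par[1])
        b[cidx] <- exp(opt$par[2])
      }
      w[cidx] <- sw / length(x)
    }
    w <- w / sum(w)
  }
  ord <- order(a / (a + b))
  fit <- structure(
    list(weights = w[ord], shape_a = a[ord], shape_b = b[ord],
         loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
         n_iter = n_iter, eps = eps),
    class = "beta_mixture_fit"
  )
  fit
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  mu <- x$shape_a / (x$shape_a + x$shape_b)
  cat("<beta_mixture_fit>\n")
  cat(sprintf("  state  weight  mean\n"))
  st <- c("hypo", "hemi", "hyper")
  for (i in 1:3) {
    cat(sprintf("  %-5s  %.3f   %.3f\n", st[i], x$weights[i], mu[i]))
  }
  cat(sprintf("  loglik %.2f after %d iteration(s)\n", x$loglik, x$n_iter))
  invisible(x)
}

#' Posterior state assignment under a beta-mixture fit
#'
#' Assigns each value to the state with the highest posterior responsibility;
#' ties break toward the lower-mean state.
#'
#' @param fit A `beta_mixture_fit`.
#' @param values Numeric vector of fractions.
#' @return Character vector in `c("hypo", "hemi", "hyper")`.
#' @export
state_of_value <- function(fit, values) {
  x <- pmin(pmax(values, fit$eps), 1 - fit$eps)
  post <- vapply(1:3, function(cidx)
    fit$weights[cidx] * stats::dbeta(x, fit$shape_a[cidx], fit$shape_b[cidx]),
    numeric(length(x)))
  if (length(x) == 1) post <- matrix(post, nrow = 1)
  # max.col with ties.method "first" favours the lower-mean (first) state
  c("hypo", "hemi", "hyper")[max.col(post, ties.method = "first")]
}

# state boundaries of a fit: largest grid value assigned hypo and smallest
# assigned hyper, on a fixed dense grid (deterministic)
mixture_boundaries <- function(fit, n_grid = 4001) {
  grid <- seq(fit$eps, 1 - fit$eps, length.out = n_grid)
  st <- state_of_value(fit, grid)
  b_lo <- if (any(st == "hypo")) max(grid[st == "hypo"]) else fit$eps
  b_hi <- if (any(st == "hyper")) min(grid[st == "hyper"]) else 1 - fit$eps
  if (b_hi <= b_lo) {
    b_lo <- stats::quantile(grid, 0.35)
    b_hi <- stats::quantile(grid, 0.65)
  }
  c(lower = unname(b_lo), upper = unname(b_hi))
}

#' Build a quantile-matching calibration map between two beta distributions
#'
#' Fits three-state beta mixtures to the source and target (gold) values and
#' returns a monotone map \[0,1\] -> \[0,1\]. Hypo-state values map through
#' beta-CDF quantile matching between the hypo components,
#' `F_gold^{-1}(F_source(v))`; hyper-state values likewise through the hyper
#' components; hemi-state values map through the hemi components and are then
#' rescaled affinely so the hemi segment is anchored exactly at the images of
#' the two state boundaries under the hypo and hyper maps - an interpolation
#' between the boundary transforms that keeps the overall map continuous and
#' monotone even where the hemi components of source and target disagree.
#'
#' @param sample_values Source values (one sample, or a profile).
#' @param gold_values Target values over the same probe set.
#' @param gold_fit Optional pre-computed `beta_mixture_fit` of the gold
#'   values (saves refitting when calibrating many samples).
#' @param sample_init Optional warm start for the source fit.
#' @param ... Passed to [fit_beta_mixture()].
#' @return An object of class `calibration_map`: list with `source_fit`,
#'   `target_fit`, and `transform` (a vectorized monotone function).
#' @export
build_calibration <- function(sample_values, gold_values = NULL,
                              gold_fit = NULL, sample_init = NULL, ...) {
  if (is.null(gold_fit)) {
    if (is.null(gold_values)) stop("need gold_values or gold_fit",
                                   call. = FALSE)
    gold_fit <- fit_beta_mixture(gold_values, ...)
  }
  src_fit <- fit_beta_mixture(sample_values, init = sample_init, ...)
  eps <- src_fit$eps
  sb <- mixture_boundaries(src_fit)
  map_state <- function(v, cidx) {
    p <- stats::pbeta(pmin(pmax(v, eps), 1 - eps),
                      src_fit$shape_a[cidx], src_fit$shape_b[cidx])
    stats::qbeta(p, gold_fit$shape_a[cidx], gold_fit$shape_b[cidx])
  }
  t_lo <- map_state(sb["lower"], 1)
  t_hi <- map_state(sb["upper"], 3)
  if (t_hi <= t_lo) { # pathological fits: fall back to identity in the middle
    t_lo <- sb["lower"]
    t_hi <- sb["upper"]
  }
  transform <- function(v) {
    v <- pmin(pmax(v, 0), 1)
    out <- numeric(length(v))
    lo <- v <= sb["lower"]
    hi <- v >= sb["upper"]
    mid <- !lo & !hi
    if (any(lo)) out[lo] <- pmin(map_state(v[lo], 1), t_lo)
    if (any(hi)) out[hi] <- pmax(map_state(v[hi], 3), t_hi)
    if (any(mid)) {
      t_a <- map_state(sb["lower"], 2)
      t_b <- map_state(sb["upper"], 2)
      if (t_b - t_a > 1e-8) {
        frac <- (map_state(v[mid], 2) - t_a) / (t_b - t_a)
      } else {
        frac <- (v[mid] - sb["lower"]) / (sb["upper"] - sb["lower"])
      }
      out[mid] <- t_lo + frac * (t_hi - t_lo)
    }
    pmin(pmax(out, eps), 1 - eps)
  }
  structure(list(source_fit = src_fit, target_fit = gold_fit,
                 boundaries = sb, boundary_images = c(t_lo, t_hi),
                 transform = transform),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(paste0("<calibration_map> state boundaries %.3f / %.3f -> ",
                     "%.3f / %.3f\n"),
              x$boundaries[1], x$boundaries[2],
              x$boundary_images[1], x$boundary_images[2]))
  invisible(x)
}

#' Diagnostics of a calibration map as a JSON-ready list
#'
#' @param map A `calibration_map`.
#' @return List with component parameters and log-likelihood traces.
#' @export
calibration_diagnostics <- function(map) {
  dump_fit <- function(f) {
    list(weights = f$weights, shape_a = f$shape_a, shape_b = f$shape_b,
         loglik_trace = f$loglik_trace, n_iter = f$n_iter)
  }
  list(source = dump_fit(map$source_fit), target = dump_fit(map$target_fit),
       boundaries = unname(map$boundaries),
       boundary_images = unname(map$boundary_images))
}

#' Calibrate every sample of a dataset to a gold-standard profile
#'
#' Fits the gold mixture once to the reference profile, then maps each sample
#' through its own [build_calibration()] transform (the sample fit is
#' warm-started at the gold fit). The output is rank-preserving per sample
#' and bounded in \[0, 1\].
#'
#' @param ds A `meth_dataset`.
#' @param gold_profile Named numeric vector: probe id -> gold-standard mean
#'   beta. `ds` is restricted to the probes present here; fewer than 50
#'   shared probes is an error.
#' @param ... Passed to [fit_beta_mixture()].
#' @return A calibrated `meth_dataset`.
#' @export
calibrate_dataset <- function(ds, gold_profile, ...) {
  shared <- intersect(probe_ids(ds), names(gold_profile))
  if (length(shared) < 50) {
    stop("fewer than 50 probes shared with the gold profile", call. = FALSE)
  }
  ds <- subset_dataset(ds, probes = shared)
  gold <- gold_profile[shared]
  gold_fit <- fit_beta_mixture(gold, ...)
  out <- ds$beta
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    ok <- !is.na(v)
    map <- build_calibration(v[ok], gold_fit = gold_fit,
                             sample_init = gold_fit, ...)
    out[ok, j] <- map$transform(v[ok])
  }
  meth_dataset(out, ds$platform, ds$dataset_id)
}

#' Gold-standard mean profile of a dataset
#'
#' @param ds A `meth_dataset` (the gold-standard dataset).
#' @return Named numeric vector of per-probe mean betas.
#' @export
gold_profile_of <- function(ds) {
  rowMeans(ds$beta, na.rm = TRUE)
}
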