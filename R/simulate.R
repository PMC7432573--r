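#' Configuration for the synthetic multi-dataset methylation simulator
#'
#' Describes a collection of array datasets with heterogeneous age
#' distributions, platform-specific probe subsets intersecting in a common
#' core, paired designs, per-dataset batch shifts and probe-level noise.
#' Effects are linear on the M (logit2) scale, matching array practice;
#' age-probe effect sizes are parameterized on the beta-per-year scale and
#' converted at each probe's baseline by the delta method.
#'
#' @param datasets Tibble with one row per dataset: `dataset_id`, `platform`,
#'   integer stratum quotas `n_18_30`, `n_30_50`, `n_50_70`, `n_70_90`,
#'   `constant_age` (NA, or a fixed age in years overriding the strata
#'   draws), `paired` (logical), `frac_female`.
#' @param n_probes_total Total probes across all platforms.
#' @param common_core_size Probes shared by every platform.
#' @param n_age_probes Number of core probes whose methylation drifts with
#'   age.
#' @param slope_sd_beta SD of the age slope on the beta-per-year scale
#'   (normal, truncated to `slope_range`).
#' @param slope_range Truncation bounds on |slope| (beta per year).
#' @param baseline_weights,baseline_shape_a,baseline_shape_b Three-component
#'   beta mixture for per-probe baseline methylation.
#' @param noise_sd_m Probe-level noise SD on the M scale.
#' @param batch_shift_sd SD of the per-dataset scalar shift on the M scale.
#' @param batch_scale_sd SD of the log of the per-dataset scale factor on
#'   the M scale. Together the shift and scale form an affine per-dataset
#'   distortion of the logit-methylation distribution - the
#'   compression/dilation artefact that separates labs and that
#'   gold-standard quantile calibration is designed to remove.
#' @param platform_scale Named fixed M-scale dilation per platform,
#'   multiplying the per-dataset factor. Array generations differ
#'   systematically in how compressed their beta distributions are (the
#'   Infinium design-type effect): the all-Type-I HM27 runs wider, the
#'   Type-II-dominated HMEPIC more compressed, with HM450 as reference.
#' @param subject_sd_m SD of the per-subject random effect on the M scale
#'   (shared by paired samples; controls the within-pair correlation).
#' @param n_sex_probes,sex_effect_m Number of probes shifted between sexes
#'   and the M-scale shift.
#' @param age_center Age (years) at which baselines are anchored.
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(datasets,
                              n_probes_total = 21000,
                              common_core_size = 19401,
                              n_age_probes = 1000,
                              slope_sd_beta = 0.0015,
                              slope_range = c(5e-4, 5e-3),
                              baseline_weights = c(0.35, 0.25, 0.40),
                              baseline_shape_a = c(2, 5, 20),
                              baseline_shape_b = c(20, 5, 2),
                              noise_sd_m = 0.15,
                              batch_shift_sd = 0.2,
                              batch_scale_sd = 0.1,
                              platform_scale = c(HM27 = 1.15, HM450 = 1,
                                                 HMEPIC = 0.92,
                                                 SYNTH = 1),
                              subject_sd_m = 0.10,
                              n_sex_probes = 50,
                              sex_effect_m = 0.5,
                              age_center = 45,
                              seed = 1L) {
  datasets <- tibble::as_tibble(datasets)
  needed <- c("dataset_id", "platform", "n_18_30", "n_30_50", "n_50_70",
              "n_70_90", "constant_age", "paired", "frac_female")
  miss <- setdiff(needed, names(datasets))
  if (length(miss) > 0) {
    stop("dataset table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (n_age_probes > common_core_size || common_core_size > n_probes_total) {
    stop("need n_age_probes <= common_core_size <= n_probes_total",
         call. = FALSE)
  }
  if (noise_sd_m < 0 || batch_shift_sd < 0 || batch_scale_sd < 0 ||
      subject_sd_m < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (n_sex_probes > common_core_size) {
    stop("n_sex_probes exceeds the common core", call. = FALSE)
  }
  structure(list(datasets = datasets, n_probes_total = n_probes_total,
                 common_core_size = common_core_size,
                 n_age_probes = n_age_probes,
                 slope_sd_beta = slope_sd_beta, slope_range = slope_range,
                 baseline_weights = baseline_weights / sum(baseline_weights),
                 baseline_shape_a = baseline_shape_a,
                 baseline_shape_b = baseline_shape_b,
                 noise_sd_m = noise_sd_m, batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd,
                 platform_scale = platform_scale,
                 subject_sd_m = subject_sd_m, n_sex_probes = n_sex_probes,
                 sex_effect_m = sex_effect_m, age_center = age_center,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default simulator configuration mirroring a 12-dataset muscle compendium
#'
#' Twelve datasets over three platforms with a fixed per-dataset age-stratum
#' quota matrix. At `scale = 1` the pooled sample total is exactly 682 with
#' stratum counts 242 (18-30), 105 (30-50), 275 (50-70) and 60 (70-90) - a
#' bimodal pooled age distribution with a trough at 30-50. The collection
#' includes one broad-age-range "gold" dataset (n = 48, young and old but no
#' middle-aged), one large middle/old dataset (n = 282), two age-constant
#' young datasets, one n = 3 dataset, and eight paired designs.
#'
#' @param scale Multiplies every stratum quota (rounded; each dataset is kept
#'   at >= 2 samples).
#' @param ... Overrides passed to [simulation_config()] (e.g.
#'   `n_probes_total`, `common_core_size`, `n_age_probes`, `noise_sd_m`).
#' @return A `simulation_config`.
#' @export
default_paper_like_config <- function(scale = 1, ...) {
  q <- tibble::tribble(
    ~dataset_id, ~platform, ~n_18_30, ~n_30_50, ~n_50_70, ~n_70_90,
    ~constant_age, ~paired, ~frac_female,
    "ds01_gold", "HM450",  24,  0,  12, 12, NA, TRUE,  0.0,
    "ds02",      "HM450",   0, 60, 192, 30, NA, TRUE,  0.4,
    "ds03",      "HMEPIC",  0, 15,  25, 10, NA, FALSE, 0.5,
    "ds04",      "HM27",    0,  0,  16,  6, NA, TRUE,  0.0,
    "ds05",      "HM27",   42,  0,   0,  0, 24, TRUE,  0.0,
    "ds06",      "HM27",   24,  0,   0,  0, 25, TRUE,  0.0,
    "ds07",      "HM450",   0,  0,   3,  0, NA, FALSE, 0.0,
    "ds08",      "HM450",  46,  0,   0,  0, NA, TRUE,  0.0,
    "ds09",      "HMEPIC", 30, 10,   0,  0, NA, TRUE,  0.0,
    "ds10",      "HMEPIC", 28, 10,  12,  0, NA, TRUE,  0.3,
    "ds11",      "HM450",  20,  5,   5,  2, NA, FALSE, 0.0,
    "ds12",      "HM450",  28,  5,  10,  0, NA, FALSE, 0.0
  )
  strata <- c("n_18_30", "n_30_50", "n_50_70", "n_70_90")
  if (scale != 1) {
    for (s in strata) q[[s]] <- round(q[[s]] * scale)
    tot <- rowSums(as.matrix(q[, strata]))
    for (i in which(tot < 2)) {
      biggest <- strata[which.max(unlist(q[i, strata]))]
      q[[biggest]][i] <- q[[biggest]][i] + (2 - tot[i])
    }
  }
  simulation_config(datasets = q, ...)
}

# integer ages for one dataset, honouring the stratum quotas
draw_ages <- function(row) {
  bounds <- list(c(18, 30), c(30, 50), c(50, 70), c(70, 89))
  counts <- c(row$n_18_30, row$n_30_50, row$n_50_70, row$n_70_90)
  if (!is.na(row$constant_age)) {
    return(list(age = rep(row$constant_age, sum(counts)),
                stratum = rep(which.max(counts), sum(counts))))
  }
  age <- integer(0)
  stratum <- integer(0)
  for (s in 1:4) {
    if (counts[s] == 0) next
    # strata are [18,30), [30,50), [50,70), [70,90): sample below the bound
    hi <- if (s < 4) bounds[[s]][2] - 1 else bounds[[s]][2]
    age <- c(age, sample(seq(bounds[[s]][1], hi), counts[s], replace = TRUE))
    stratum <- c(stratum, rep(s, counts[s]))
  }
  list(age = age, stratum = stratum)
}

#' Simulate a multi-dataset methylation compendium
#'
#' Draws per-probe baselines from a three-component beta mixture, adds
#' age, sex, batch and subject effects on the M scale, adds probe-level
#' noise, and back-transforms to beta (so all values are strictly inside
#' (0, 1)). Platform probe sets share exactly the configured common core.
#' Probes are laid out on two synthetic chromosomes with island-like spacing,
#' and genes receive long-tailed probe counts to exercise bias-aware
#' gene-set testing.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `simulation` with `datasets` (list of
#'   `meth_dataset`), `sheets` (list of sample-sheet tibbles), `annotation`
#'   (probe annotation tibble), `truth` (list: `age_probes` tibble with true
#'   slopes on both scales, `batch_shifts`, `sex_probes`, `ages`, pair
#'   assignments are in the sheets' `subject_id`), and `config`.
#' @export
simulate_multidataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  np <- cfg$n_probes_total
  core <- cfg$common_core_size
  probes <- sprintf("cg%07d", seq_len(np))
  core_probes <- probes[seq_len(core)]
  extras <- setdiff(probes, core_probes)
  # three extra groups; each platform misses at least one, so the
  # intersection across platforms is exactly the core
  grp <- if (length(extras) > 0) {
    split(extras, rep_len(1:3, length(extras)))
  } else {
    list(character(0), character(0), character(0))
  }
  platform_probes <- list(
    HM27 = c(core_probes, grp[[1]]),
    HM450 = c(core_probes, grp[[1]], grp[[2]]),
    HMEPIC = c(core_probes, grp[[2]], grp[[3]]),
    SYNTH = probes
  )

  ann <- simulate_annotation(probes, cfg)

  mu_comp <- sample.int(3, np, replace = TRUE, prob = cfg$baseline_weights)
  mu <- stats::rbeta(np, cfg$baseline_shape_a[mu_comp],
                     cfg$baseline_shape_b[mu_comp])
  mu <- pmin(pmax(mu, 0.02), 0.98)
  mu_m <- beta_to_m(mu)
  names(mu) <- names(mu_m) <- probes

  age_probes <- sample(core_probes, cfg$n_age_probes)
  slope_beta <- numeric(cfg$n_age_probes)
  todo <- seq_len(cfg$n_age_probes)
  while (length(todo) > 0) {
    s <- stats::rnorm(length(todo), 0, cfg$slope_sd_beta)
    ok <- abs(s) >= cfg$slope_range[1] & abs(s) <= cfg$slope_range[2]
    slope_beta[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  # delta method at the baseline: dM/dbeta = 1 / (ln 2 * beta (1 - beta))
  slope_m <- slope_beta / (log(2) * mu[age_probes] * (1 - mu[age_probes]))
  slope_all_m <- stats::setNames(numeric(np), probes)
  slope_all_m[age_probes] <- slope_m

  sex_probes <- if (cfg$n_sex_probes > 0) {
    pool <- setdiff(core_probes, age_probes)
    sample(pool, min(cfg$n_sex_probes, length(pool)))
  } else character(0)
  sex_eff <- stats::setNames(numeric(np), probes)
  sex_eff[sex_probes] <- cfg$sex_effect_m * sample(c(-1, 1),
                                                   length(sex_probes),
                                                   replace = TRUE)

  batch_shift <- stats::rnorm(nrow(cfg$datasets), 0, cfg$batch_shift_sd)
  names(batch_shift) <- cfg$datasets$dataset_id
  batch_scale <- exp(stats::rnorm(nrow(cfg$datasets), 0, cfg$batch_scale_sd))
  names(batch_scale) <- cfg$datasets$dataset_id
  total_scale <- batch_scale *
    unlist(cfg$platform_scale[cfg$datasets$platform])
  names(total_scale) <- cfg$datasets$dataset_id

  datasets <- list()
  sheets <- list()
  for (di in seq_len(nrow(cfg$datasets))) {
    row <- cfg$datasets[di, ]
    aa <- draw_ages(row)
    n_d <- length(aa$age)
    if (n_d == 0) next
    sid <- sprintf("%s_s%03d", row$dataset_id, seq_len(n_d))

    # subjects: paired designs pair samples within the same age stratum
    if (isTRUE(row$paired)) {
      ord <- order(aa$stratum, aa$age)
      subj_of <- integer(n_d)
      subj_of[ord] <- (seq_len(n_d) + 1L) %/% 2L
      # keep pair members at the same age
      for (s in unique(subj_of)) {
        members <- which(subj_of == s)
        aa$age[members] <- aa$age[members[1]]
      }
      condition <- rep("baseline", n_d)
      for (s in unique(subj_of)) {
        members <- which(subj_of == s)
        if (length(members) == 2) condition[members[2]] <- "followup"
      }
      subject <- sprintf("%s_subj%03d", row$dataset_id, subj_of)
    } else {
      subj_of <- seq_len(n_d)
      subject <- sprintf("%s_subj%03d", row$dataset_id, subj_of)
      condition <- rep("baseline", n_d)
    }
    n_subjects <- max(subj_of)

    n_female <- round(row$frac_female * n_subjects)
    subj_sex <- sample(c(rep("F", n_female),
                         rep("M", n_subjects - n_female)))
    sex <- subj_sex[subj_of]

    pp <- platform_probes[[row$platform]]
    npd <- length(pp)
    m <- matrix(mu_m[pp], nrow = npd, ncol = n_d)
    m <- m + outer(slope_all_m[pp], aa$age - cfg$age_center)
    m <- m + outer(sex_eff[pp], as.numeric(sex == "F"))
    if (cfg$subject_sd_m > 0) {
      subj_fx <- matrix(stats::rnorm(npd * n_subjects, 0, cfg$subject_sd_m),
                        nrow = npd)
      m <- m + subj_fx[, subj_of, drop = FALSE]
    }
    if (cfg$noise_sd_m > 0) {
      m <- m + matrix(stats::rnorm(npd * n_d, 0, cfg$noise_sd_m), nrow = npd)
    }
    # affine distortion of the logit-methylation distribution: a fixed
    # platform compression/dilation times a per-dataset lab factor, plus a
    # per-dataset shift
    scale_d <- batch_scale[di] * cfg$platform_scale[[row$platform]]
    m <- scale_d * m + batch_shift[di]
    b <- m_to_beta(m)
    dimnames(b) <- list(pp, sid)
    datasets[[row$dataset_id]] <- meth_dataset(b, row$platform,
                                               row$dataset_id)
    sheets[[row$dataset_id]] <- tibble::tibble(
      sample_id = sid, age = as.numeric(aa$age), sex = sex,
      dataset_id = row$dataset_id, subject_id = subject,
      condition = condition)
  }

  truth <- list(
    age_probes = tibble::tibble(probe_id = age_probes,
                                slope_beta_per_year = slope_beta,
                                slope_m_per_year = slope_m,
                                baseline_beta = unname(mu[age_probes])),
    batch_shifts = batch_shift,
    batch_scales = total_scale,
    sex_probes = sex_probes,
    baseline_beta = mu,
    ages = dplyr::bind_rows(sheets)[, c("sample_id", "age", "dataset_id")]
  )
  structure(list(datasets = datasets, sheets = sheets, annotation = ann,
                 truth = truth, config = cfg),
            class = "simulation")
}

# synthetic probe annotation: two chromosomes, island-like spacing,
# closed-vocabulary contexts/states, long-tailed gene probe counts
simulate_annotation <- function(probes, cfg) {
  np <- length(probes)
  half <- ceiling(np / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(half, np - half))
  gap <- ifelse(stats::runif(np) < 0.2,
                sample(50:500, np, replace = TRUE),
                100 + round(stats::rexp(np, rate = 1 / 3000)))
  pos <- integer(np)
  pos[chrom == "chr1"] <- cumsum(gap[chrom == "chr1"]) + 10000L
  pos[chrom == "chr2"] <- cumsum(gap[chrom == "chr2"]) + 10000L
  ctx <- sample(island_context_levels(), np, replace = TRUE,
                prob = c(0.30, 0.23, 0.12, 0.35))
  state_prob <- c(0.07, 0.07, 0.02, 0.10, 0.15, 0.03, 0.08, 0.02, 0.04,
                  0.02, 0.02, 0.02, 0.04, 0.07, 0.25)
  cst <- sample(chromatin_state_levels(), np, replace = TRUE,
                prob = state_prob)
  n_genes <- max(50L, round(np / 12))
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  gene_wt <- pmax(1, round(stats::rlnorm(n_genes, meanlog = log(4),
                                         sdlog = 1)))
  has_gene <- stats::runif(np) < 0.8
  gene_of <- rep(NA_character_, np)
  gene_of[has_gene] <- sample(gene_ids, sum(has_gene), replace = TRUE,
                              prob = gene_wt)
  genes <- lapply(gene_of, function(g) if (is.na(g)) character(0) else g)
  probe_annotation(tibble::tibble(
    probe_id = probes, chrom = chrom, pos = pos,
    design_type = sample(c("I", "II"), np, replace = TRUE,
                         prob = c(0.3, 0.7)),
    island_context = ctx, chromatin_state = cst, genes = genes,
    is_cg = stats::runif(np) > 0.005,
    is_snp_associated = stats::runif(np) < 0.01,
    is_multimapping = stats::runif(np) < 0.01
  ))
}

#' @export
print.simulation <- function(x, ...) {
  n <- sum(vapply(x$sheets, nrow, integer(1)))
  cat(sprintf(paste0("<simulation> %d datasets, %d samples, %d probes ",
                     "(core %d), %d age probes\n"),
              length(x$datasets), n, x$config$n_probes_total,
              x$config$common_core_size, x$config$n_age_probes))
  invisible(x)
}
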