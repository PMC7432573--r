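make_ewas_data <- function(n_probes = 120, n = 60, seed = 1,
                           slope_sd = 0.002, frac_age = 0.25) {
  set.seed(seed)
  age <- stats::runif(n, 20, 80)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dsid <- sample(c("d1", "d2"), n, replace = TRUE)
  base <- stats::runif(n_probes, 0.2, 0.8)
  slope <- numeric(n_probes)
  n_age <- round(frac_age * n_probes)
  slope[seq_len(n_age)] <- stats::rnorm(n_age, 0, slope_sd)
  b <- outer(base, rep(1, n)) + outer(slope, age - 50) +
    matrix(stats::rnorm(n_probes * n, 0, 0.02), n_probes, n)
  b <- pmin(pmax(b, 0.01), 0.99)
  dimnames(b) <- list(sprintf("cg%04d", seq_len(n_probes)),
                      sprintf("s%03d", seq_len(n)))
  sheet <- tibble::tibble(sample_id = colnames(b), age = age, sex = sex,
                          dataset_id = dsid)
  list(b = b, sheet = sheet, slope = slope)
}

test_that("unmoderated EWAS matches a per-probe OLS oracle", {
  dat <- make_ewas_data()
  et <- ewas_fit(dat$b, dat$sheet, prior = list(d0 = 0))
  expect_equal(et$t_moderated, et$t_ordinary, tolerance = 1e-12)
  for (i in c(1, 7, 50, 120)) {
    fit <- stats::lm(dat$b[i, ] ~ dat$sheet$age + factor(dat$sheet$sex) +
                       factor(dat$sheet$dataset_id))
    co <- summary(fit)$coefficients
    expect_equal(et$slope[i], co[2, 1], tolerance = 1e-10)
    expect_equal(et$t_ordinary[i], co[2, 3], tolerance = 1e-8)
    expect_equal(et$p[i], co[2, 4], tolerance = 1e-8)
  }
  expect_identical(et$direction, ifelse(et$slope >= 0, "hyper", "hypo"))
})

test_that("infinite prior df pools every probe to the prior variance", {
  dat <- make_ewas_data(seed = 2)
  et <- ewas_fit(dat$b, dat$sheet, prior = list(d0 = Inf, s0_sq = 4e-4))
  # all moderated variances equal: se identical across probes
  expect_lt(stats::sd(et$se), 1e-12)
})

test_that("moderated statistics agree with the established reference", {
  dat <- make_ewas_data(n_probes = 400, n = 50, seed = 3)
  et <- ewas_fit(dat$b, dat$sheet)
  design <- stats::model.matrix(~ age + factor(sex) + factor(dataset_id),
                                data = dat$sheet)
  lf <- limma::eBayes(limma::lmFit(dat$b, design))
  expect_equal(attr(et, "prior")$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(et, "prior")$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(et$t_moderated, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(et$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the aliased columns", {
  dat <- make_ewas_data(seed = 4)
  dat$sheet$sex <- "M" # constant covariate aliases with the intercept
  expect_error(ewas_fit(dat$b, dat$sheet), "aliased")
})

test_that("block designs estimate a consensus correlation and keep inference valid", {
  set.seed(5)
  n_subj <- 40
  age <- stats::runif(n_subj, 20, 80)
  n_probes <- 300
  subj_fx <- matrix(stats::rnorm(n_probes * n_subj, 0, 0.03), n_probes)
  make_rep <- function() {
    pmin(pmax(0.5 + subj_fx +
                matrix(stats::rnorm(n_probes * n_subj, 0, 0.03), n_probes),
              0.01), 0.99)
  }
  b <- cbind(make_rep(), make_rep())
  dimnames(b) <- list(sprintf("cg%04d", 1:n_probes),
                      sprintf("s%03d", 1:(2 * n_subj)))
  sheet <- tibble::tibble(sample_id = colnames(b), age = rep(age, 2),
                          sex = "M", dataset_id = "d1",
                          subject_id = rep(sprintf("subj%02d", 1:n_subj), 2))
  et <- ewas_fit(b, sheet, covariates = character(0), block = "subject_id")
  rho <- attr(et, "block_rho")
  expect_gt(rho, 0.3) # true intraclass correlation is 0.5
  expect_lt(rho, 0.7)
  # fixed-effects fallback needs within-subject age variation (longitudinal
  # design), otherwise age is aliased with the subject effects
  sheet_long <- sheet
  sheet_long$age[seq_len(n_subj) + n_subj] <- age + 8
  et2 <- ewas_fit(b, sheet_long, covariates = character(0),
                  block = "subject_id", block_method = "fixed")
  expect_equal(nrow(et2), n_probes)
  expect_error(ewas_fit(b, sheet, covariates = character(0),
                        block = "subject_id", block_method = "fixed"),
               "aliased")
})

test_that("variance prior recovery matches the generating parameters", {
  set.seed(6)
  d0 <- 4; s0 <- 0.04; d <- 50
  s_sq <- s0 * d0 / stats::rchisq(5000, d0) *
    stats::rchisq(5000, d) / d
  pri <- estimate_prior(s_sq, d)
  expect_gt(pri$d0, 2); expect_lt(pri$d0, 8)
  expect_lt(abs(pri$s0_sq - s0) / s0, 0.25)
  # identical variances: infinite prior df
  expect_equal(estimate_prior(rep(0.02, 200), 10)$d0, Inf)
  # order invariance
  pri2 <- estimate_prior(rev(s_sq), d)
  expect_equal(pri2$d0, pri$d0)
  expect_equal(pri2$s0_sq, pri$s0_sq)
  expect_error(estimate_prior(c(-1, s_sq), d), "positive")
  expect_error(estimate_prior(s_sq[1:50], d), ">= 100")
})

bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

test_that("BH adjustment matches the brute-force step-up oracle", {
  p <- c(0.001, 0.01, 0.03, 0.9)
  expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-15)
  set.seed(7)
  for (i in 1:50) {
    p <- stats::runif(sample(5:200, 1))
    expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-15)
  }
  # permutation equivariance
  p <- stats::runif(30)
  perm <- sample(30)
  expect_equal(fdr_bh(p)[perm], fdr_bh(p[perm]))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMR calling merges direction-consistent significant neighbours", {
  ann <- make_ann(sprintf("cg%02d", 1:6),
                  pos = c(1000L, 1500L, 9000L, 14000L, 20000L, 20400L))
  # two significant hyper probes 500 bp apart: one DMR
  et <- make_ewas_table(sprintf("cg%02d", 1:6),
                        slope = c(0.001, 0.002, 0.001, 0.001, 0.001, 0.001),
                        fdr = c(1e-4, 1e-4, 0.5, 0.5, 0.5, 0.5))
  dmrs <- call_dmrs(et, ann)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 1000L)
  expect_equal(dmrs$end, 1500L)
  expect_equal(dmrs$n_probes, 2L)

  # 5000 bp apart: no DMR
  et2 <- make_ewas_table(sprintf("cg%02d", 1:6),
                         slope = rep(0.001, 6),
                         fdr = c(0.5, 0.5, 1e-4, 1e-4, 0.5, 0.5))
  expect_equal(nrow(call_dmrs(et2, ann)), 0)

  # adjacent but opposite directions: no DMR
  et3 <- make_ewas_table(sprintf("cg%02d", 1:6),
                         slope = c(0.001, -0.002, 0.001, 0.001, 0.001, 0.001),
                         fdr = c(1e-4, 1e-4, 0.5, 0.5, 0.5, 0.5))
  expect_equal(nrow(call_dmrs(et3, ann)), 0)

  # probe order invariance
  shuf <- sample(6)
  d1 <- call_dmrs(et[shuf, ], ann)
  expect_equal(d1$start, dmrs$start)
  expect_equal(d1$probe_ids[[1]], dmrs$probe_ids[[1]])
})

fisher_oracle <- function(a, b, c_, d) {
  # two-sided exact p: sum of hypergeometric probabilities <= observed
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  supp <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(supp, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher enrichment matches the hypergeometric-sum oracle", {
  set.seed(8)
  for (i in 1:50) {
    tab <- sample(0:15, 4, replace = TRUE)
    if (sum(tab[c(1, 2)]) == 0 || sum(tab[c(3, 4)]) == 0 ||
        sum(tab[c(1, 3)]) == 0 || sum(tab[c(2, 4)]) == 0) next
    p_pkg <- muscleclock:::fisher_2x2(tab[1], tab[2], tab[3], tab[4])["p"]
    expect_equal(unname(p_pkg), fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("enrichment over annotation categories returns one row per level", {
  probes <- sprintf("cg%03d", 1:200)
  ann <- make_ann(probes,
                  island_context = rep(island_context_levels(), each = 50))
  # foreground proportions equal to background: OR 1, p 1 everywhere
  fg <- probes[c(1:10, 51:60, 101:110, 151:160)]
  res <- enrichment_fisher(fg, probes, ann, "island_context")
  expect_equal(nrow(res), 4)
  expect_equal(res$odds_ratio, rep(1, 4))
  expect_equal(res$p, rep(1, 4))
  expect_length(res$fdr, 4)

  # a concentrated foreground is enriched in its level
  res2 <- enrichment_fisher(probes[1:25], probes, ann, "island_context")
  expect_lt(res2$p[res2$level == "island"], 1e-6)
  expect_gt(res2$odds_ratio[res2$level == "island"], 1)
  expect_error(enrichment_fisher(character(0), probes, ann), "empty")
  expect_error(enrichment_fisher("nope", probes, ann), "subset")
})

test_that("the Monte-Carlo overlap null behaves at its edges and centre", {
  bg <- sprintf("cg%04d", 1:500)
  pa <- bg[1:20]
  # panel_b disjoint from the background: every draw overlaps 0
  r0 <- random_overlap_test(pa, c("x1", "x2"), bg, n_draws = 200, seed = 1)
  expect_equal(r0$max_null, 0)
  expect_equal(r0$observed, 0)
  # panel_b equal to the background: every draw overlaps draw_size
  r1 <- random_overlap_test(pa, bg, bg, n_draws = 200, seed = 1)
  expect_equal(as.integer(r1$null_counts), 200L)
  expect_identical(names(r1$null_counts), "20")
  expect_equal(r1$max_null, 20)
  expect_error(random_overlap_test(pa, bg, bg, draw_size = 501), "exceeds")
})

test_that("the overlap null matches hypergeometric moments", {
  set.seed(9)
  bg <- sprintf("cg%05d", 1:2000)
  pb <- sample(bg, 150)
  r <- random_overlap_test(bg[1:80], pb, bg, draw_size = 80,
                           n_draws = 20000, seed = 2)
  m1 <- 150; n_bg <- 2000; k <- 80
  mu <- k * m1 / n_bg
  v <- k * (m1 / n_bg) * (1 - m1 / n_bg) * (n_bg - k) / (n_bg - 1)
  expect_lt(abs(r$null_mean - mu), 3 * sqrt(v / 20000))
  expect_lt(abs(r$null_var - v), 4 * v * sqrt(2 / (20000 - 1)))
})

test_that("gene-set test reduces to the hypergeometric with equal probe counts", {
  genes <- sprintf("G%03d", 1:80)
  probes <- sprintf("cg%03d", 1:160)
  ann <- make_ann(probes, genes = as.list(rep(genes, each = 2)))
  set.seed(10)
  sig <- sample(probes, 30)
  sets <- list(s1 = genes[1:20], s2 = genes[21:60], all = genes)
  rw <- gene_set_test(sig, probes, ann, sets, method = "wallenius")
  rn <- gene_set_test(sig, probes, ann, sets, method = "hypergeometric")
  expect_equal(rw$p[1:2], rn$p[1:2], tolerance = 1e-6)
  # a set containing every gene cannot be enriched
  expect_equal(rw$p[rw$set == "all"], 1)
  expect_error(gene_set_test(sig, probes, ann, list(bad = "NOPE")), "empty")
})

test_that("Wallenius tail agrees with a weighted-sampling Monte-Carlo oracle", {
  set.seed(11)
  m1 <- 30; m2 <- 120; n <- 25; omega <- 3
  wts <- c(rep(omega, m1), rep(1, m2))
  draws <- vapply(1:20000, function(i) {
    sum(sample.int(m1 + m2, n, prob = wts) <= m1)
  }, numeric(1))
  for (x_obs in c(5, 8, 11)) {
    p_mc <- mean(draws >= x_obs)
    p_an <- muscleclock:::pwallenius_upper(x_obs, m1, m2, n, omega)
    expect_lt(abs(p_an - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 20000) + 0.002)
  }
})

test_that("per-decade effect reporting multiplies the yearly slope by ten", {
  et <- make_ewas_table(c("a", "b"), slope = c(0.0028, -0.001),
                        fdr = c(0.001, 0.5))
  out <- slope_per_decade(et)
  expect_equal(out$slope_per_decade, c(0.028, -0.01))
})
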