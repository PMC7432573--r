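# small deterministic builders shared across test files

make_beta <- function(n_probes, n_samples, seed = 1, prefix = "cg") {
  set.seed(seed)
  b <- matrix(stats::runif(n_probes * n_samples, 0.05, 0.95),
              nrow = n_probes,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  b
}

make_ann <- function(probe_ids, chrom = "chr1",
                     pos = seq_along(probe_ids) * 1000L,
                     design_type = "II", island_context = "open_sea",
                     chromatin_state = "Quies", genes = NULL,
                     is_cg = TRUE, is_snp_associated = FALSE,
                     is_multimapping = FALSE) {
  n <- length(probe_ids)
  if (is.null(genes)) genes <- replicate(n, character(0), simplify = FALSE)
  probe_annotation(tibble::tibble(
    probe_id = probe_ids,
    chrom = rep_len(chrom, n),
    pos = rep_len(pos, n),
    design_type = rep_len(design_type, n),
    island_context = rep_len(island_context, n),
    chromatin_state = rep_len(chromatin_state, n),
    genes = genes,
    is_cg = rep_len(is_cg, n),
    is_snp_associated = rep_len(is_snp_associated, n),
    is_multimapping = rep_len(is_multimapping, n)
  ))
}

make_ewas_table <- function(probe_id, slope, fdr, p = fdr / 2) {
  tibble::tibble(probe_id = probe_id, slope = slope,
                 se = abs(slope) / 5, t_ordinary = slope / (abs(slope) / 5),
                 t_moderated = slope / (abs(slope) / 5), p = p, fdr = fdr,
                 direction = ifelse(slope >= 0, "hyper", "hypo"))
}

# small paper-like simulation for integration-style tests
tiny_sim <- function(seed = 1, scale = 0.15, n_probes_total = 360,
                     common_core_size = 300, n_age_probes = 40, ...) {
  simulate_multidataset(default_paper_like_config(
    scale = scale, n_probes_total = n_probes_total,
    common_core_size = common_core_size, n_age_probes = n_age_probes,
    seed = seed, ...))
}
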