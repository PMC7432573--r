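pipeline_known_keys <- c("seed", "out_dir", "stages", "simulate", "inputs",
                         "clock", "ewas", "calibrate")

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "muscleclock_run",
    stages = list(simulate = TRUE, qc = TRUE, calibrate = TRUE,
                  loocv = TRUE, train = TRUE, ewas = TRUE, enrich = FALSE),
    simulate = list(scale = 0.1, n_probes_total = 1200,
                    common_core_size = 1000, n_age_probes = 100),
    inputs = NULL,
    clock = list(alpha = 0.5, n_folds = 10, lambda_rule = "min",
                 adult_age = 20),
    ewas = list(covariates = c("sex", "dataset_id"), block = "subject_id",
                fdr_cut = 0.005, max_gap = 1000),
    calibrate = list(gold_dataset = NULL)
  )
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON; unknown top-level keys are rejected, and
#' omitted keys take package defaults.
#'
#' @param path File path, or a list already in memory.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), pipeline_known_keys)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- default_run_config()
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && is.list(out[[k]])) {
      for (k2 in names(cfg[[k]])) out[[k]][[k2]] <- cfg[[k]][[k2]]
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  out
}

#' Run the end-to-end clock pipeline
#'
#' Executes the toggled stages in order: simulate (or load inputs) ->
#' dataset QC -> probe intersection -> gold-standard calibration ->
#' leave-one-dataset-out evaluation -> final clock training -> age EWAS with
#' DMR calling -> enrichment. All artifacts are written to a staging
#' directory and moved into `out_dir` only on success, together with a
#' `manifest.json` recording the seed, package and R versions, and an md5
#' hash of every artifact, so a rerun with the same seed is verifiably
#' identical.
#'
#' @param config Path to a YAML/JSON config, or a config list (see
#'   [read_run_config()]).
#' @return Invisibly, a list with the manifest and the in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir
  set.seed(cfg$seed)

  if (isTRUE(cfg$stages$simulate)) {
    sim_args <- cfg$simulate
    scale <- sim_args$scale %||% 1
    sim_args$scale <- NULL
    sim_args$seed <- cfg$seed
    sim <- simulate_multidataset(
      do.call(default_paper_like_config, c(list(scale = scale), sim_args)))
    datasets <- sim$datasets
    sheets <- sim$sheets
    ann <- sim$annotation
  } else {
    if (is.null(cfg$inputs)) stop("no inputs and simulate stage off",
                                  call. = FALSE)
    paths <- unlist(cfg$inputs[c("beta_matrices", "sample_sheet",
                                 "annotation")])
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("missing input path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    datasets <- lapply(names(cfg$inputs$beta_matrices), function(id) {
      read_beta_matrix(cfg$inputs$beta_matrices[[id]], dataset_id = id)
    })
    names(datasets) <- names(cfg$inputs$beta_matrices)
    sheet_all <- sample_sheet(utils::read.csv(cfg$inputs$sample_sheet))
    sheets <- split(sheet_all, sheet_all$dataset_id)
    ann <- if (!is.null(cfg$inputs$annotation)) {
      probe_annotation(utils::read.delim(cfg$inputs$annotation))
    } else NULL
  }

  stage_dir <- tempfile("muscleclock_stage_")
  dir.create(stage_dir, recursive = TRUE)
  artifacts <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(stage_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
  }

  sheet_all <- dplyr::bind_rows(sheets)
  emit_csv(sheet_all, "sample_sheet.csv")
  results <- list()

  if (isTRUE(cfg$stages$qc)) {
    qc <- lapply(datasets, function(d) {
      r <- suppressWarnings(qc_dataset(d))
      tibble::tibble(dataset_id = d$dataset_id,
                     mean_intercorrelation = r$mean_intercorrelation,
                     max_beta = r$max_beta, pass = r$pass)
    })
    results$qc <- dplyr::bind_rows(qc)
    emit_csv(results$qc, "qc_report.csv")
  }

  datasets <- intersect_probes(datasets)

  gold_id <- cfg$calibrate$gold_dataset %||% names(datasets)[1]
  gold <- gold_profile_of(datasets[[gold_id]])
  if (isTRUE(cfg$stages$calibrate)) {
    datasets <- lapply(datasets, calibrate_dataset, gold_profile = gold)
  }

  clock_cfg <- clock_train_config(alpha = cfg$clock$alpha,
                                  n_folds = cfg$clock$n_folds,
                                  lambda_rule = cfg$clock$lambda_rule,
                                  adult_age = cfg$clock$adult_age,
                                  seed = cfg$seed)

  if (isTRUE(cfg$stages$loocv)) {
    results$loocv <- loocv(datasets, sheets, clock_cfg, gold_profile = gold)
    emit_csv(results$loocv$summary, "loocv_summary.csv")
    emit_csv(results$loocv$predictions, "loocv_predictions.csv")
  }

  if (isTRUE(cfg$stages$train)) {
    results$model <- train_clock(datasets, sheets, clock_cfg,
                                 gold_profile = gold,
                                 gold_standard_id = gold_id)
    p <- file.path(stage_dir, "clock_model.json")
    write_model(results$model, p)
    artifacts <- c(artifacts, p)
  }

  if (isTRUE(cfg$stages$ewas)) {
    beta_all <- do.call(cbind, lapply(datasets, function(d) d$beta))
    covs <- cfg$ewas$covariates
    # drop covariates that are constant across the pooled samples
    covs <- covs[vapply(covs, function(cv)
      length(unique(sheet_all[[cv]])) > 1, logical(1))]
    block <- cfg$ewas$block
    if (!is.null(block) && all(is.na(sheet_all[[block]]))) block <- NULL
    results$ewas <- ewas_fit(beta_all, sheet_all, covariates = covs,
                             block = block)
    emit_csv(results$ewas[, c("probe_id", "slope", "t_moderated", "p",
                              "fdr", "direction")], "ewas.csv")
    if (!is.null(ann)) {
      results$dmrs <- call_dmrs(results$ewas, ann,
                                max_gap = cfg$ewas$max_gap,
                                fdr_cut = cfg$ewas$fdr_cut)
      emit_csv(results$dmrs[, setdiff(names(results$dmrs), "probe_ids")],
               "dmrs.csv")
      p <- file.path(stage_dir, "dmrs.bed")
      write_dmrs_bed(results$dmrs, p)
      artifacts <- c(artifacts, p)
    }
  }

  if (isTRUE(cfg$stages$enrich) && !is.null(ann) &&
      !is.null(results$model) && length(results$model$weights) > 0) {
    results$enrichment <- enrichment_fisher(
      names(results$model$weights), probe_ids(datasets[[1]]), ann,
      category = "island_context")
    emit_csv(results$enrichment, "enrichment_island_context.csv")
  }

  manifest <- list(
    package = "muscleclock",
    package_version = as.character(utils::packageVersion("muscleclock")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    stages = cfg$stages,
    artifact_md5 = as.list(tools::md5sum(artifacts))
  )
  names(manifest$artifact_md5) <- basename(artifacts)
  mp <- file.path(stage_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  artifacts <- c(artifacts, mp)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(artifacts, out_dir, overwrite = TRUE)
  if (!all(ok)) stop("failed to move artifacts into out_dir", call. = FALSE)
  unlink(stage_dir, recursive = TRUE)
  invisible(list(manifest = manifest, results = results,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
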