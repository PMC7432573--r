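#' Construct a methylation dataset
#'
#' A `meth_dataset` holds a probes-by-samples matrix of beta values
#' (methylation fractions in \[0, 1\], `NA` for missing calls), the platform
#' the array was run on, and a dataset label. Invariants (unique probe and
#' sample identifiers, values in range, matching dimensions) are enforced at
#' construction so downstream code never has to re-check them.
#'
#' @param beta Numeric matrix, probes in rows and samples in columns, with
#'   `rownames` giving probe ids and `colnames` giving sample ids. Values
#'   must lie in \[0, 1\] or be `NA`.
#' @param platform One of `"HM27"`, `"HM450"`, `"HMEPIC"`, `"SYNTH"`.
#' @param dataset_id Single string labelling the dataset.
#'
#' @return An object of class `meth_dataset`.
#' @export
meth_dataset <- function(beta, platform = "SYNTH", dataset_id = "dataset") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("`beta` must have probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  platform <- match.arg(platform, c("HM27", "HM450", "HMEPIC", "SYNTH"))
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids", call. = FALSE)
  rng <- suppressWarnings(range(beta, na.rm = TRUE))
  if (!all(is.finite(rng))) {
    if (!all(is.na(beta))) stop("non-finite beta values", call. = FALSE)
  } else if (rng[1] < 0 || rng[2] > 1) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("beta out of range at probe '%s', sample '%s'",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]), call. = FALSE)
  }
  structure(
    list(beta = beta, platform = platform,
         dataset_id = as.character(dataset_id)[1]),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  n_na <- sum(is.na(x$beta))
  cat(sprintf("<meth_dataset '%s'> %d probes x %d samples [%s]%s\n",
              x$dataset_id, nrow(x$beta), ncol(x$beta), x$platform,
              if (n_na > 0) sprintf(", %d missing", n_na) else ""))
  invisible(x)
}

#' @export
dim.meth_dataset <- function(x) dim(x$beta)

#' Probe and sample identifiers of a methylation dataset
#'
#' @param ds A `meth_dataset`.
#' @return Character vector of ids, in matrix order.
#' @export
probe_ids <- function(ds) rownames(ds$beta)

#' @rdname probe_ids
#' @export
sample_ids <- function(ds) colnames(ds$beta)

#' Subset a methylation dataset by probes and/or samples
#'
#' @param ds A `meth_dataset`.
#' @param probes,samples Character vectors of ids to keep (order respected);
#'   `NULL` keeps everything.
#' @return A `meth_dataset`.
#' @export
subset_dataset <- function(ds, probes = NULL, samples = NULL) {
  b <- ds$beta
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(b))
    if (length(missing) > 0) {
      stop(sprintf("unknown probe ids: %s", paste(utils::head(missing, 5),
                                                  collapse = ", ")),
           call. = FALSE)
    }
    b <- b[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(b))
    if (length(missing) > 0) {
      stop(sprintf("unknown sample ids: %s", paste(utils::head(missing, 5),
                                                   collapse = ", ")),
           call. = FALSE)
    }
    b <- b[, samples, drop = FALSE]
  }
  meth_dataset(b, ds$platform, ds$dataset_id)
}

#' Validate a sample sheet
#'
#' A sample sheet is a tibble with one row per sample: `sample_id`, `age`
#' (years, `NA` allowed for prediction-only samples), `sex` (`"F"`, `"M"` or
#' `"unknown"`), `dataset_id`, optional `subject_id` (identifies paired or
#' repeated samples) and optional `condition`.
#'
#' @param sheet A data frame.
#' @return The sheet as a tibble with canonical column types.
#' @export
sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  needed <- c("sample_id", "age", "sex", "dataset_id")
  miss <- setdiff(needed, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (any(!is.na(sheet$age) & sheet$age < 0)) {
    stop("negative age in sample sheet", call. = FALSE)
  }
  bad_sex <- setdiff(unique(as.character(sheet$sex)), c("F", "M", "unknown"))
  if (length(bad_sex) > 0) {
    stop("sex must be one of F, M, unknown; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  if (!"subject_id" %in% names(sheet)) sheet$subject_id <- NA_character_
  if (!"condition" %in% names(sheet)) sheet$condition <- NA_character_
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$dataset_id <- as.character(sheet$dataset_id)
  sheet$sex <- as.character(sheet$sex)
  sheet$age <- as.numeric(sheet$age)
  sheet
}

#' Closed vocabularies for probe annotation
#'
#' @return Character vector of allowed levels.
#' @export
island_context_levels <- function() c("island", "shore", "shelf", "open_sea")

#' @rdname island_context_levels
#' @export
chromatin_state_levels <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF_Rpts",
    "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' Validate a probe annotation table
#'
#' One row per probe: genomic position (1-based), Infinium design type,
#' CpG-island context, 15-state chromatin-state label, gene list
#' (comma-separated string or list column), and flags used by probe filters.
#'
#' @param ann A data frame with columns `probe_id`, `chrom`, `pos`,
#'   `design_type` ("I"/"II"), `island_context`, `chromatin_state`, `genes`,
#'   `is_cg`, `is_snp_associated`, `is_multimapping`.
#' @return A tibble with `genes` as a list column of character vectors.
#' @export
probe_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("probe_id", "chrom", "pos", "design_type", "island_context",
              "chromatin_state", "genes", "is_cg", "is_snp_associated",
              "is_multimapping")
  miss <- setdiff(needed, names(ann))
  if (length(miss) > 0) {
    stop("probe annotation missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in annotation",
                                        call. = FALSE)
  if (any(ann$pos < 1)) stop("annotation positions must be >= 1", call. = FALSE)
  if (!all(ann$design_type %in% c("I", "II"))) {
    stop("design_type must be 'I' or 'II'", call. = FALSE)
  }
  if (!all(ann$island_context %in% island_context_levels())) {
    stop("island_context outside closed vocabulary", call. = FALSE)
  }
  if (!all(ann$chromatin_state %in% chromatin_state_levels())) {
    stop("chromatin_state outside closed vocabulary", call. = FALSE)
  }
  if (!is.list(ann$genes)) {
    ann$genes <- lapply(strsplit(as.character(ann$genes), ";|,"), function(g) {
      g <- trimws(g)
      g[nzchar(g) & !is.na(g)]
    })
  }
  ann$probe_id <- as.character(ann$probe_id)
  ann
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row, a first column named `probe_id`, and one column per
#' sample. Empty cells and `NA` become missing values (a count is messaged).
#' Values outside \[0, 1\] are an error naming the offending cell.
#'
#' @param path File path (CSV or TSV; delimiter sniffed from the header).
#' @param platform,dataset_id Passed to [meth_dataset()].
#' @return A `meth_dataset`.
#' @export
read_beta_matrix <- function(path, platform = "SYNTH",
                             dataset_id = "dataset") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (names(df)[1] != "probe_id") {
    stop("first column must be named 'probe_id'", call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids", call. = FALSE)
  b <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(b) <- "double"
  rownames(b) <- as.character(df$probe_id)
  n_na <- sum(is.na(b))
  if (n_na > 0) message(sprintf("read_beta_matrix: %d missing value(s)", n_na))
  meth_dataset(b, platform, dataset_id)
}

#' Write a beta matrix as delimited text
#'
#' @param ds A `meth_dataset`.
#' @param path Output path; `.tsv` extension selects tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(ds, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(probe_id = rownames(ds$beta), ds$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a clock model object
#'
#' A fitted epigenetic clock: an intercept and sparse probe weights on the
#' transformed-age scale, the adult-age pivot of the age transform, the
#' elastic-net hyperparameters used, and the gold-standard mean profile used
#' both for calibration and as a fallback for probes missing at prediction
#' time.
#'
#' @param intercept Intercept in transformed-age units.
#' @param weights Named numeric vector: probe id -> coefficient
#'   (transformed-age units per beta unit). May be empty.
#' @param adult_age Pivot (years) of the age transform; must be > 0.
#' @param alpha,lambda Elastic-net mixing weight and selected penalty.
#' @param gold_standard_id Label of the gold-standard dataset.
#' @param gold_profile Named numeric vector: probe id -> mean beta in the
#'   gold standard. Must cover every weight.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(intercept, weights, adult_age = 20, alpha = 0.5,
                        lambda = NA_real_, gold_standard_id = "gold",
                        gold_profile = numeric()) {
  weights <- unlist(weights)
  if (length(weights) > 0 && is.null(names(weights))) {
    stop("weights must be named by probe id", call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  if (adult_age <= 0) stop("adult_age must be > 0", call. = FALSE)
  extra <- setdiff(names(weights), names(gold_profile))
  if (length(extra) > 0) {
    stop("gold_profile must cover every weighted probe; missing: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept), weights = weights,
         adult_age = as.numeric(adult_age), alpha = as.numeric(alpha),
         lambda = as.numeric(lambda),
         gold_standard_id = as.character(gold_standard_id),
         gold_profile = unlist(gold_profile)),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(paste0("<clock_model> %d CpG weight(s), intercept %.4f ",
                     "(transformed-age units), adult_age %g, alpha %g, ",
                     "lambda %s\n"),
              length(x$weights), x$intercept, x$adult_age, x$alpha,
              format(x$lambda, digits = 4)))
  invisible(x)
}

clock_model_format_version <- 1L

#' Serialize / deserialize a clock model
#'
#' Models are stored as versioned, human-inspectable JSON. Round trips are
#' lossless for all fields; an unknown `format_version` is an error.
#'
#' @param model A `clock_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the `clock_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  payload <- list(
    format_version = clock_model_format_version,
    intercept = model$intercept,
    adult_age = model$adult_age,
    alpha = model$alpha,
    lambda = model$lambda,
    gold_standard_id = model$gold_standard_id,
    weights = as.list(model$weights),
    gold_profile = as.list(model$gold_profile)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path)
  ver <- payload$format_version
  if (is.null(ver) || ver != clock_model_format_version) {
    stop(sprintf("unknown model format version: %s",
                 if (is.null(ver)) "<none>" else ver), call. = FALSE)
  }
  as_named <- function(x) {
    out <- vapply(x, function(v) {
      if (is.character(v)) as.numeric(v) else as.numeric(v)
    }, numeric(1))
    names(out) <- names(x)
    out
  }
  clock_model(
    intercept = as.numeric(payload$intercept),
    weights = if (length(payload$weights) > 0) as_named(payload$weights)
              else numeric(),
    adult_age = as.numeric(payload$adult_age),
    alpha = as.numeric(payload$alpha),
    lambda = if (is.character(payload$lambda)) NA_real_
             else as.numeric(payload$lambda),
    gold_standard_id = payload$gold_standard_id,
    gold_profile = if (length(payload$gold_profile) > 0)
      as_named(payload$gold_profile) else numeric()
  )
}

#' Export DMRs to BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is shifted down by one.
#'
#' @param dmrs Tibble from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = dmrs$chrom,
                    start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("DMR_%d_%s", seq_len(nrow(dmrs)),
                                   dmrs$direction),
                    score = round(-10 * log10(pmax(dmrs$min_fdr, 1e-300))),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
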