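#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of unique
#' feature ids; remaining cells numeric.  Values are taken as log2 scale
#' unless `log2_transform = TRUE`, in which case raw intensities are
#' floored at `floor` and log2-transformed.
#'
#' @param path TSV/CSV path (delimiter auto-detected from the extension;
#'   tab otherwise).
#' @param class_labels Per-sample labels (see [expression_dataset()]), or
#'   path to a two-column TSV (`sample_id`, `class`) matched by sample id.
#' @param log2_transform Apply `log2(pmax(I, floor))` to raw intensities.
#' @param floor Intensity floor used before the log (default 1).
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, class_labels, log2_transform = FALSE,
                                floor = 1) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("expression table needs a feature-id column and >= 2 samples: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  raw <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at data row %d (feature '%s'), column '%s'",
                 path, bad[1L], ids[bad[1L]], colnames(raw)[bad[2L]]))
  }
  m <- matrix(num, nrow = nrow(raw),
              dimnames = list(ids, colnames(raw)))
  if (log2_transform) m <- log2(pmax(m, floor))

  if (is.character(class_labels) && length(class_labels) == 1L &&
      file.exists(class_labels)) {
    lab_df <- utils::read.delim(class_labels, stringsAsFactors = FALSE,
                                colClasses = "character")
    if (ncol(lab_df) < 2L) stop("label file needs two columns (sample_id, class)")
    miss <- setdiff(colnames(m), lab_df[[1L]])
    if (length(miss))
      stop("samples missing from label file: ", paste(miss, collapse = ", "))
    class_labels <- lab_df[[2L]][match(colnames(m), lab_df[[1L]])]
  }
  expression_dataset(m, class_labels)
}

#' Write an expression dataset as TSV
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset plus its truth sidecar
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default "sim").
#' @return Paths of the expression TSV, truth TSV and label TSV.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, paste0(prefix, "_expression.tsv"))
  p_truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  p_lab <- file.path(dir, paste0(prefix, "_labels.tsv"))
  write_expression_tsv(sim$dataset, p_expr)
  utils::write.table(sim$truth, p_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(sim$dataset$values),
               class = sim$dataset$class_labels),
    p_lab, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = p_expr, truth = p_truth, labels = p_lab))
}

#' Run the full DFC pipeline on a dataset and write its artifacts
#'
#' Summarizes features, estimates the null model, applies the selection
#' and ranking, and writes three artifacts to `output_dir`:
#' `dfc_results.tsv` (ranked per-feature table with a `#`-comment header
#' describing every column), `null_model.tsv` (the (mu, LV, d) cloud with
#' fitted curves) and `run_metadata.json` (parameters and versions).
#' Partial outputs are removed if any stage fails.
#'
#' @param dataset An [expression_dataset()], or a path to an expression
#'   TSV (then `class_labels` is required).
#' @param output_dir Directory for the artifacts (created if absent).
#' @param params A [dfc_parameters()].
#' @param bins A [bin_spec()].
#' @param estimate_d0 Center the null logFC on per-bin medians.
#' @param class_labels,log2_transform Passed to [read_expression_tsv()]
#'   when `dataset` is a path.
#' @return Invisibly, a list with `result`, `model` and the artifact
#'   paths.
#' @export
run_dfc <- function(dataset, output_dir, params = dfc_parameters(),
                    bins = bin_spec(), estimate_d0 = FALSE,
                    class_labels = NULL, log2_transform = FALSE) {
  if (is.character(dataset)) {
    if (is.null(class_labels))
      stop("stage input: class_labels required when reading from file")
    dataset <- read_expression_tsv(dataset, class_labels,
                                   log2_transform = log2_transform)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(output_dir,
                     c("dfc_results.tsv", "null_model.tsv", "run_metadata.json"))
  wrote <- character()
  on.exit(if (length(wrote)) unlink(wrote), add = TRUE)

  sm <- with_stage("summarize", summarize_features(dataset))
  model <- with_stage("null_model", estimate_null_model(sm, bins, estimate_d0))
  res <- with_stage("selection", select_and_rank(sm, model, params))

  with_stage("write", {
    write_results_tsv(res, paths[1L], params)
    wrote <- paths[1L]
    diag <- null_model_diagnostics(sm, model)
    utils::write.table(diag, paths[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    wrote <- paths[1:2]
    meta <- list(
      package = "dfctest",
      version = as.character(utils::packageVersion("dfctest")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      n_features = nrow(res), n1 = dataset$n1, n2 = dataset$n2,
      alpha = params$alpha, beta_th = params$beta_th,
      variance_filter = params$variance_filter,
      estimate_d0 = estimate_d0,
      n_bins_used = model$n_bins_used,
      n_selected = sum(res$passes_selection)
    )
    jsonlite::write_json(meta, paths[3L], auto_unbox = TRUE, pretty = TRUE)
    wrote <- paths
  })
  on.exit()    # success: keep artifacts
  invisible(list(result = res, model = model, paths = paths))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# ranked results with a self-describing comment header
write_results_tsv <- function(res, path, params) {
  res <- res[order(res$rank), ]
  hdr <- c(
    "# DFC ranked results",
    sprintf("# alpha=%g beta_th=%g variance_filter=%s",
            params$alpha, params$beta_th, params$variance_filter),
    "# feature_id: feature identifier",
    "# mu: mean log2 expression (mu1+mu2)/2;  d: logFC mu1-mu2;  fc: 2^d",
    "# vT: total variance about the grand mean;  LV: log2(vT);  lv_th: null-variance threshold at mu",
    "# sigma0: null logFC sd at mu;  s: sd of d (stabilized);  df: Welch degrees of freedom",
    "# z_score: DFC score;  p_value: two-sided normal p on z_score",
    "# delta1/delta2: significance/power logFC thresholds;  type2_error: conditional Type II error (NA if |d| <= delta1)",
    "# p_th: implied stabilized t-test p bound;  t_p_stab: stabilized t-test p",
    "# is_null: LV < lv_th;  passes_selection: |d| > delta1+delta2 (and variance filter);  rank: by |z_score| desc"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
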