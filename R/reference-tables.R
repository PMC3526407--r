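#' Packaged benchmark reference tables
#'
#' Two small reference tables ship with the package for regression tests
#' of the AUC-comparison machinery:
#' * `geo_benchmark_datasets()` -- 11 public human microarray datasets
#'   with RT-PCR-verified DEG counts (`n_pc`; 284 verified DEGs in
#'   total across the compendium);
#' * `geo_benchmark_auc()` -- the per-dataset AUC of the Welch t-test,
#'   shrinkage t-test and DFC rankers under MAS5 and RMA preprocessing.
#'
#' @return A data.frame (see the column comments in the shipped TSVs).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
geo_benchmark_datasets <- function() {
  read_extdata("geo_benchmark_datasets.tsv")
}

#' @rdname reference_tables
#' @export
geo_benchmark_auc <- function() {
  read_extdata("geo_benchmark_auc.tsv")
}

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "dfctest")
  if (path == "") stop("packaged reference table not found: ", name)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
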