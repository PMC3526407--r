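#' Two-class log2 expression dataset
#'
#' Container for a features x samples matrix of log2-scale intensities
#' together with a two-class sample assignment.  All downstream statistics
#' (log fold change, variances, the DFC score) operate on this object.
#'
#' @param values Numeric matrix, features in rows, samples in columns,
#'   log2 scale.  No missing or non-finite values are allowed.
#' @param class_labels Vector of per-sample class labels with exactly two
#'   distinct values; levels are mapped to classes 1 and 2 in sorted
#'   order, as `factor()` would.  Each class needs at least 2 samples.
#' @param feature_ids Character vector of unique feature identifiers; by
#'   default taken from `rownames(values)` or generated as `f1, f2, ...`.
#'
#' @return An object of class `expression_dataset` with elements `values`
#'   (matrix with feature ids as rownames), `class_labels` (integer vector
#'   of 1/2), `n1`, `n2`.
#' @examples
#' x <- matrix(rnorm(40, mean = 8), nrow = 4)
#' ds <- expression_dataset(x, rep(c(1, 2), each = 5))
#' ds$n1
#' @export
expression_dataset <- function(values, class_labels, feature_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (anyNA(values) || !all(is.finite(values)))
    stop("`values` contains missing or non-finite entries; impute or filter upstream")
  if (length(class_labels) != ncol(values))
    stop(sprintf("length of `class_labels` (%d) != number of samples (%d)",
                 length(class_labels), ncol(values)))
  labs <- normalize_class_labels(class_labels)
  n1 <- sum(labs == 1L); n2 <- sum(labs == 2L)
  if (n1 < 2L || n2 < 2L)
    stop(sprintf("each class needs >= 2 samples (got n1=%d, n2=%d)", n1, n2))
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(values))
    stop("`feature_ids` length must equal the number of feature rows")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(utils::head(unique(feature_ids[duplicated(feature_ids)]), 5),
               collapse = ", "))
  rownames(values) <- feature_ids
  structure(
    list(values = values, class_labels = labs, n1 = n1, n2 = n2),
    class = "expression_dataset"
  )
}

# Map arbitrary two-level labels onto integers 1/2 by sorted level order
# (factor semantics), so relabelling 1<->2 genuinely swaps the classes.
normalize_class_labels <- function(class_labels) {
  if (anyNA(class_labels)) stop("missing class labels")
  u <- sort(unique(as.character(class_labels)))
  if (length(u) != 2L)
    stop(sprintf("exactly 2 classes required, found %d (%s)",
                 length(u), paste(utils::head(u, 5), collapse = ", ")))
  out <- match(as.character(class_labels), u)
  storage.mode(out) <- "integer"
  out
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples (n1=%d, n2=%d)\n",
              nrow(x$values), ncol(x$values), x$n1, x$n2))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)
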