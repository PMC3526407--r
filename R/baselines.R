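#' Per-feature Welch t-test
#'
#' Classical two-sample t-test with unequal variances on every feature,
#' the basic reference ranker.  Optionally uses stabilized variances
#' (shrunk toward a null model's `v_bar_ee(mu)`), which is the variant
#' entering the p-value-bound equivalence of the DFC selection.
#'
#' @param dataset An [expression_dataset()].
#' @param model Optional `dfc_null_model`; when supplied, per-class
#'   variances are stabilized toward `2^{lv_th(mu)}` before forming the
#'   statistic.
#' @return Data frame with `feature_id, t, df, p`.  Features with zero
#'   variance in both classes (and no stabilization) get `t = 0`,
#'   `p = NA` and are flagged in `degenerate`.
#' @export
welch_t_test <- function(dataset, model = NULL) {
  sm <- summarize_features(dataset)
  v1 <- sm$var1; v2 <- sm$var2
  if (!is.null(model)) {
    ev <- evaluate_null_model(model, sm$mu)
    v1 <- stabilized_variance(v1, sm$n1, ev$v_bar_ee)
    v2 <- stabilized_variance(v2, sm$n2, ev$v_bar_ee)
  }
  degen <- v1 == 0 & v2 == 0
  t_stat <- df <- rep(NA_real_, nrow(sm))
  if (any(!degen)) {
    vd <- variance_of_d(v1[!degen], v2[!degen], sm$n1[!degen], sm$n2[!degen])
    t_stat[!degen] <- sm$d[!degen] / vd$s
    df[!degen] <- vd$df
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  t_stat[degen] <- 0
  data.frame(feature_id = sm$feature_id, t = t_stat, df = df, p = p,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Plain fold-change ranker
#'
#' Scores each feature by `|d|`, the naive fold-change criterion with no
#' associated confidence level; performs well only when feature variances
#' are fairly similar.
#'
#' @param summaries Data frame from [summarize_features()].
#' @return Numeric score vector `|d|`, named by feature id.
#' @export
fold_change_ranker <- function(summaries) {
  stats::setNames(abs(summaries$d), summaries$feature_id)
}

#' Import an externally computed score vector
#'
#' Reads a two-column delimited file (`feature_id`, `score`) so that
#' third-party rankers can enter the evaluation harness without being
#' re-implemented.
#'
#' @param path Path to a TSV with header columns `feature_id` and `score`.
#' @return Named numeric vector of scores.
#' @export
read_score_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "score") %in% names(df)))
    stop("score file must have columns 'feature_id' and 'score': ", path)
  if (!is.numeric(df$score)) stop("non-numeric scores in ", path)
  if (anyDuplicated(df$feature_id)) stop("duplicate feature ids in ", path)
  stats::setNames(df$score, df$feature_id)
}
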