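#' Per-feature summary statistics
#'
#' Computes, for every feature of a two-class dataset, the class means
#' (log2 units), the log fold change `d = mu1 - mu2` (so that the fold
#' change is `FC = 2^d`), the mean expression `mu = (mu1 + mu2)/2`, the
#' unbiased within-class variances, the total variance `vT` taken about
#' the pooled grand mean of all samples, its log `LV = log2(vT)`, and the
#' pooled ("internal") within-class variance kept for diagnostics.
#'
#' The total variance about the grand mean absorbs the between-class
#' signal: an unregulated feature (d ~ 0) has `vT` close to its internal
#' variance while a regulated one is inflated by `d^2`, which is what the
#' expression-dependent variance filter exploits.
#'
#' @param dataset An [expression_dataset()].
#' @return A data.frame with one row per feature (input order preserved)
#'   and columns `feature_id, mu1, mu2, mu, d, fc, var1, var2, vT, LV,
#'   v_internal, n1, n2`.  `LV` is `NA` when `vT == 0`.
#' @examples
#' ds <- expression_dataset(rbind(a = c(2, 4, 1, 3)), rep(c(1, 2), each = 2))
#' summarize_features(ds)
#' @export
summarize_features <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  x <- dataset$values
  i1 <- dataset$class_labels == 1L
  i2 <- dataset$class_labels == 2L
  n1 <- dataset$n1; n2 <- dataset$n2
  x1 <- x[, i1, drop = FALSE]
  x2 <- x[, i2, drop = FALSE]

  mu1 <- rowMeans(x1)
  mu2 <- rowMeans(x2)
  var1 <- row_var(x1)
  var2 <- row_var(x2)
  d <- mu1 - mu2
  mu <- (mu1 + mu2) / 2

  # unbiased variance of all n1+n2 values about the pooled grand mean
  vT <- row_var(x)
  # pooled within-class variance (signal removed)
  v_int <- ((n1 - 1) * var1 + (n2 - 1) * var2) / (n1 + n2 - 2)

  lv <- ifelse(vT > 0, log2(vT), NA_real_)
  data.frame(
    feature_id = rownames(x), mu1 = mu1, mu2 = mu2, mu = mu,
    d = d, fc = 2^d, var1 = var1, var2 = var2,
    vT = vT, LV = lv, v_internal = v_int,
    n1 = n1, n2 = n2,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# rowwise unbiased variance without apply() overhead
row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  pmax(rowSums((m - mu)^2) / (n - 1), 0)
}

#' Stabilized within-class variance
#'
#' Minimal-correction variance stabilization: shrink the unbiased sample
#' variance toward the local average variance of unregulated features
#' `v_bar_ee(mu)`,
#' \deqn{v_s = \frac{n-1}{n} v + \frac{1}{n} \bar v_{EE}(\mu).}
#' When `sample_var == v_bar_ee` this reproduces the unbiased estimate;
#' when `sample_var >> v_bar_ee` it approaches the maximum-likelihood
#' variance.
#'
#' @param sample_var Unbiased sample variance(s), >= 0.
#' @param n Class sample size, >= 2.
#' @param v_bar_ee Local null-feature average variance(s), >= 0.
#' @return Stabilized variance, same length as the longest argument.
#' @export
stabilized_variance <- function(sample_var, n, v_bar_ee) {
  if (any(n < 2)) stop("sample size n must be >= 2")
  if (any(sample_var < 0) || any(v_bar_ee < 0))
    stop("variances must be non-negative")
  (n - 1) / n * sample_var + v_bar_ee / n
}

#' Variance, standard deviation and Welch degrees of freedom of the logFC
#'
#' The variance of `d = mu1 - mu2` is `vsd = vs1/n1 + vs2/n2`; the
#' degrees of freedom follow the Welch–Satterthwaite approximation of the
#' Behrens–Fisher problem, evaluated on the (possibly stabilized)
#' per-class variances.
#'
#' @param vs1,vs2 Per-class variances (stabilized or raw), >= 0, not both 0.
#' @param n1,n2 Class sample sizes, >= 2.
#' @return List with vectors `vsd`, `s = sqrt(vsd)`, `df`.
#' @export
variance_of_d <- function(vs1, vs2, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("class sizes must be >= 2")
  if (any(vs1 < 0) || any(vs2 < 0)) stop("variances must be non-negative")
  if (any(vs1 == 0 & vs2 == 0))
    stop("degenerate variances: vs1 and vs2 both zero")
  a1 <- vs1 / n1
  a2 <- vs2 / n2
  vsd <- a1 + a2
  df <- vsd^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  list(vsd = vsd, s = sqrt(vsd), df = df)
}

#' DFC score
#'
#' Signal-to-noise statistic
#' \deqn{Z_d = \frac{d - \bar d_0(\mu)}{\sqrt{v_s(d|\mu) + v_0(\mu)}},}
#' intermediate between a normal Z and a t statistic: the denominator
#' combines the sampling variance of the feature's own logFC with the
#' population variance of the null features' logFC distribution at the
#' same expression level, which does not shrink with sample size.
#'
#' @param d Observed logFC.
#' @param d0_center Center of the local null logFC distribution
#'   (normally 0).
#' @param vsd Sampling variance of `d` (see [variance_of_d()]).
#' @param v0 Local null logFC variance `sigma0(mu)^2`.
#' @return The score(s) `Z_d`.
#' @export
dfc_score <- function(d, d0_center, vsd, v0) {
  tot <- vsd + v0
  if (any(tot <= 0))
    stop("degenerate variance: vsd + v0 must be positive")
  (d - d0_center) / sqrt(tot)
}
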