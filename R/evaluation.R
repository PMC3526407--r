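#' ROC curve with explicit tie handling
#'
#' Builds the stepwise ROC curve of a ranking score against binary truth.
#' Thresholds sweep the distinct score values from high to low; all
#' features sharing a score enter together, producing a diagonal segment,
#' so the trapezoidal area equals the Mann-Whitney pairwise probability
#' with ties counted 1/2.  The curve always includes (0,0) and (1,1).
#'
#' Alongside the FPR `eta` and TPR `tau`, each point carries the selected
#' fraction `nu = eta (1 - N_T/N_p) + tau N_T/N_p` -- the fraction of all
#' features called DE at that threshold.
#'
#' @param scores Numeric ranking scores, higher = more likely DE.
#' @param truth Logical vector, `TRUE` for true DEGs.  Needs at least one
#'   positive and one negative.
#' @return A `roc_curve`: data.frame with columns `eta`, `tau`, `nu` and
#'   attributes `n_pos`, `n_neg`, `degenerate` (all scores tied).
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  if (anyNA(scores) || anyNA(truth)) stop("missing scores or truth values")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos < 1L || n_pos >= length(truth))
    stop("need at least one positive and one negative feature")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t_ <- truth[ord]
  grp_end <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  tp <- cumsum(t_)[grp_end]
  fp <- grp_end - tp
  eta <- c(0, fp / n_neg)
  tau <- c(0, tp / n_pos)
  np <- length(scores)
  nu <- eta * (1 - n_pos / np) + tau * (n_pos / np)

  out <- data.frame(eta = eta, tau = tau, nu = nu)
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "degenerate") <- length(grp_end) == 1L
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal integral of `tau` over `eta`; equal, including ties, to the
#' probability that a random positive outranks a random negative.
#'
#' @param curve A [roc_curve()].
#' @return AUC in [0, 1].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  trapezoid(curve$eta, curve$tau)
}

trapezoid <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Standardized partial AUC
#'
#' \eqn{SPA(\eta) = \frac{1}{\eta}\int_0^{\eta} \tau(\eta')\,d\eta'}: the
#' partial area up to FPR `eta_max`, standardized by the ideal receiver's
#' partial area (which is `eta_max`).  Equivalently the average TPR over
#' FPR in `[0, eta_max]`.  `spa(curve, 1)` equals the AUC.
#'
#' @param curve A [roc_curve()].
#' @param eta_max Upper FPR bound in (0, 1].
#' @return SPA in [0, 1].
#' @export
spa <- function(curve, eta_max) {
  stopifnot(inherits(curve, "roc_curve"))
  if (eta_max <= 0 || eta_max > 1) stop("eta_max must be in (0, 1]")
  eta <- curve$eta; tau <- curve$tau
  # segment-wise trapezoids clipped to [0, eta_max]; vertical jumps (tie
  # groups, perfect-separation steps) contribute nothing to the integral
  total <- 0
  for (i in seq_len(length(eta) - 1L)) {
    x0 <- eta[i]; x1 <- eta[i + 1L]
    if (x0 >= eta_max) break
    if (x1 <= x0) next
    x1c <- min(x1, eta_max)
    t0 <- tau[i]
    t1 <- tau[i] + (tau[i + 1L] - tau[i]) * (x1c - x0) / (x1 - x0)
    total <- total + (x1c - x0) * (t0 + t1) / 2
  }
  total / eta_max
}

#' Youden index of a ROC curve
#'
#' `YI = max(tau - eta)` over curve points; 0 for a random ranking, 1 for
#' an ideal one.  Also returns `nu_max`, the selected fraction at which
#' the maximum is first attained -- often taken as the optimal cut.
#'
#' @param curve A [roc_curve()].
#' @return List with `yi` and `nu_max`.
#' @export
youden_index <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tau - curve$eta
  k <- which.max(j)
  list(yi = j[k], nu_max = curve$nu[k])
}

#' Logit transform of AUC values
#'
#' `LTA = 0.5 * ln(AUC / (1 - AUC))`: maps (0, 1) onto the real line so
#' that near-1 AUCs become approximately normal for paired t-testing.
#'
#' @param auc_values AUCs strictly inside (0, 1).
#' @return Transformed values.
#' @export
logit_auc <- function(auc_values) {
  if (any(auc_values <= 0 | auc_values >= 1))
    stop("logit transform requires AUC strictly inside (0, 1)")
  0.5 * log(auc_values / (1 - auc_values))
}

#' Paired comparison of two methods' AUCs across datasets
#'
#' Tests whether method A outranks method B over a collection of paired
#' per-dataset AUCs, with two complementary tests: a one-sided paired
#' Wilcoxon signed-rank test on the raw AUCs (distribution-free; AUCs
#' near 1 are far from normal) and a one-sided paired t-test on the
#' logit-transformed AUCs.
#'
#' @param auc_a,auc_b Paired AUC vectors (same datasets, same order),
#'   at least 5 pairs.
#' @param alternative Passed to the tests; default `"greater"` (A > B).
#' @return List with `wilcoxon_p` (raw AUCs), `t_p` (logit AUCs),
#'   `mean_lta_diff`, `n`.
#' @export
compare_aucs <- function(auc_a, auc_b, alternative = "greater") {
  if (length(auc_a) != length(auc_b)) stop("paired vectors differ in length")
  if (length(auc_a) < 5L) stop("need >= 5 paired AUC values")
  lta <- logit_auc(auc_a) - logit_auc(auc_b)
  w <- suppressWarnings(
    stats::wilcox.test(auc_a, auc_b, paired = TRUE, alternative = alternative)
  )
  tt <- stats::t.test(logit_auc(auc_a), logit_auc(auc_b), paired = TRUE,
                      alternative = alternative)
  list(wilcoxon_p = w$p.value, t_p = tt$p.value,
       mean_lta_diff = mean(lta), n = length(auc_a))
}

#' Correlation of logit AUCs between two conditions
#'
#' Measures the stability of a method across conditions (e.g. two
#' preprocessing pipelines) as the correlation of its logit-transformed
#' per-dataset AUCs.
#'
#' @param auc_cond1,auc_cond2 Paired AUC vectors for the same datasets
#'   under two conditions.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
lta_correlation <- function(auc_cond1, auc_cond2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(auc_cond1) != length(auc_cond2))
    stop("paired vectors differ in length")
  stats::cor(logit_auc(auc_cond1), logit_auc(auc_cond2), method = method)
}

#' Average ROC/SPA curves across datasets at fixed selected fraction
#'
#' Interpolates each dataset's curve onto a common grid of the selected
#' fraction `nu` and averages `tau` (and `eta`) pointwise, with standard
#' errors -- the averaging convention for comparing rankers across
#' heterogeneous datasets under a fixed fraction of top features.
#'
#' @param curves List of [roc_curve()] objects.
#' @param nu_grid Grid of selected fractions; default 200 log-spaced
#'   points spanning the curves' common `nu` range.
#' @return Data frame with `nu`, `tau_mean`, `tau_se`, `eta_mean`,
#'   `eta_se`.
#' @export
average_roc_curves <- function(curves, nu_grid = NULL) {
  stopifnot(length(curves) >= 2L)
  if (is.null(nu_grid)) {
    lo <- max(vapply(curves, function(cv) min(cv$nu[cv$nu > 0]), 0))
    nu_grid <- exp(seq(log(lo), log(1), length.out = 200L))
  }
  tau_m <- vapply(curves, function(cv)
    stats::approx(cv$nu, cv$tau, xout = nu_grid, rule = 2, ties = max)$y,
    numeric(length(nu_grid)))
  eta_m <- vapply(curves, function(cv)
    stats::approx(cv$nu, cv$eta, xout = nu_grid, rule = 2, ties = max)$y,
    numeric(length(nu_grid)))
  se <- function(m) apply(m, 1L, stats::sd) / sqrt(ncol(m))
  data.frame(nu = nu_grid,
             tau_mean = rowMeans(tau_m), tau_se = se(tau_m),
             eta_mean = rowMeans(eta_m), eta_se = se(eta_m))
}
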