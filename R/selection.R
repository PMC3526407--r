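#' DFC test parameters
#'
#' @param alpha Significance level in (0, 1] for the expression-dependent
#'   logFC threshold; `alpha = 1` disables it.
#' @param beta_th Type II error bound in (0, 0.5]; `beta_th = 0.5`
#'   disables the power requirement.
#' @param variance_filter Require `LV > lv_th(mu)` for selection
#'   (recommended for stringent selection; switch off for full-list
#'   ranking / ROC construction).
#' @return A `dfc_parameters` list.
#' @export
dfc_parameters <- function(alpha = 0.05, beta_th = 0.2,
                           variance_filter = TRUE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (beta_th <= 0 || beta_th > 0.5) stop("beta_th must be in (0, 0.5]")
  structure(list(alpha = alpha, beta_th = beta_th,
                 variance_filter = isTRUE(variance_filter)),
            class = "dfc_parameters")
}

#' Expression-dependent significance threshold on |logFC|
#'
#' \eqn{\Delta_{1}(\alpha,\mu) = \sigma_0(\mu)\,\Phi^{-1}(1-\alpha/2)}.
#' Below this threshold a feature carries insufficient evidence at level
#' `alpha` against the local null logFC distribution.  At `alpha = 1` the
#' threshold is exactly 0.
#'
#' @param alpha Significance level in (0, 1].
#' @param sigma0 Null logFC standard deviation(s) at the feature's `mu`.
#' @return Threshold(s), log2 fold-change units.
#' @export
delta1_threshold <- function(alpha, sigma0) {
  if (any(alpha <= 0)) stop("alpha = 0 gives an infinite threshold")
  if (any(alpha > 1)) stop("alpha must be in (0, 1]")
  if (any(sigma0 <= 0)) stop("sigma0 must be positive")
  sigma0 * stats::qnorm(1 - alpha / 2)
}

#' Expression-dependent power threshold on |logFC|
#'
#' \eqn{\Delta_{2}(\beta,\mu) = s(\mu)\,T^{-1}(1-\beta_{Th}, DF)} with the
#' central t quantile: the extra logFC needed for power `1 - beta_th`.
#' At `beta_th = 0.5` the threshold is 0.
#'
#' @param beta_th Type II error bound in (0, 0.5].
#' @param s Standard deviation of `d` (stabilized).
#' @param df Welch degrees of freedom.
#' @return Threshold(s), log2 fold-change units.
#' @export
delta2_threshold <- function(beta_th, s, df) {
  if (beta_th <= 0 || beta_th > 0.5) stop("beta_th must be in (0, 0.5]")
  if (any(s < 0)) stop("s must be non-negative")
  s * stats::qt(1 - beta_th, df)
}

#' Conditional Type II error of calling a feature DE
#'
#' For features already past the significance threshold
#' (`|d| > delta1`), the probability of missing the effect:
#' \eqn{\beta(d\,|\,\alpha) = 1 - T\!\big((|d|-\Delta_1)/s,\ DF\big)}.
#' Power is `1 - beta`.
#'
#' @param d Observed logFC (sign ignored).
#' @param delta1 Significance threshold from [delta1_threshold()].
#' @param s Standard deviation of `d`.
#' @param df Welch degrees of freedom.
#' @return Type II error probability in (0, 1).
#' @export
conditional_type2_error <- function(d, delta1, s, df) {
  if (any(s <= 0)) stop("s must be positive")
  if (any(abs(d) <= delta1))
    stop("conditional Type II error is defined only for |d| > delta1")
  1 - stats::pt((abs(d) - delta1) / s, df)
}

#' Expression-dependent p-value threshold implied by the DFC selection
#'
#' Every feature passing the DFC selection at `(alpha, beta_th)` has a
#' (stabilized-variance) t-test p-value at or below
#' \deqn{p_{Th} = 2\Big(1 - T\big(\tfrac{\sigma_0}{s}\Phi^{-1}(1-\alpha/2)
#'   + T^{-1}(1-\beta_{Th},DF),\ DF\big)\Big).}
#' At `alpha = 1` this reduces to `2 * beta_th` (plain t-test selection).
#'
#' @inheritParams delta1_threshold
#' @inheritParams delta2_threshold
#' @return p-value bound(s).
#' @export
p_threshold <- function(alpha, beta_th, sigma0, s, df) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (beta_th <= 0 || beta_th > 0.5) stop("beta_th must be in (0, 0.5]")
  2 * (1 - stats::pt(sigma0 / s * stats::qnorm(1 - alpha / 2) +
                       stats::qt(1 - beta_th, df), df))
}

#' Run the DFC selection and ranking on summarized features
#'
#' Computes the DFC score, its two-sided normal p-value, the
#' expression-dependent thresholds `delta1` (significance) and `delta2`
#' (power), the conditional Type II error, the implied t-test p-value
#' bound, the null/non-null classification, the combined selection flag
#' \eqn{|d| > \Delta_1 + \Delta_2} (intersected with the variance filter
#' `LV > lv_th(mu)` when enabled), and the rank of every feature by
#' descending `|Z_d|` (ties broken by input order).
#'
#' `use_v_bar_ee` and `use_v0` exist for diagnostic reductions: with both
#' off, `Z_d` is exactly the Welch t statistic and, at `alpha = 1` with
#' the variance filter off, the selection set is exactly
#' `{t-test p <= 2 beta_th}`.
#'
#' @param summaries Data frame from [summarize_features()].
#' @param model A `dfc_null_model` from [estimate_null_model()].
#' @param params A [dfc_parameters()] object.
#' @param use_v_bar_ee Apply the variance stabilization toward
#'   `v_bar_ee(mu) = 2^{lv_th(mu)}` (default TRUE).
#' @param use_v0 Include the null logFC variance `sigma0(mu)^2` in the
#'   score denominator (default TRUE).
#' @return A `dfc_result` data.frame, one row per input feature, columns:
#'   `feature_id, mu, d, fc, vT, LV, sigma0, s, df, z_score, p_value,
#'   delta1, delta2, type2_error, p_th, t_p_stab, is_null,
#'   passes_selection, rank`.
#' @export
select_and_rank <- function(summaries, model, params = dfc_parameters(),
                            use_v_bar_ee = TRUE, use_v0 = TRUE) {
  stopifnot(inherits(params, "dfc_parameters"))
  ev <- evaluate_null_model(model, summaries$mu)
  n1 <- summaries$n1; n2 <- summaries$n2
  if (use_v_bar_ee) {
    vs1 <- stabilized_variance(summaries$var1, n1, ev$v_bar_ee)
    vs2 <- stabilized_variance(summaries$var2, n2, ev$v_bar_ee)
  } else {
    # stabilization off: plain unbiased variances (Welch-t reduction path)
    vs1 <- summaries$var1
    vs2 <- summaries$var2
  }
  degen <- vs1 == 0 & vs2 == 0       # flat feature in a zero-v_bar_ee region

  vsd <- s <- df <- rep(NA_real_, nrow(summaries))
  if (any(!degen)) {
    vd <- variance_of_d(vs1[!degen], vs2[!degen], n1[!degen], n2[!degen])
    vsd[!degen] <- vd$vsd; s[!degen] <- vd$s; df[!degen] <- vd$df
  }

  v0 <- if (use_v0) ev$sigma0^2 else rep(0, nrow(summaries))
  z <- p <- numeric(nrow(summaries))
  ok <- !degen & (vsd + v0) > 0
  z[ok] <- (summaries$d[ok] - ev$d0_center[ok]) / sqrt(vsd[ok] + v0[ok])
  z[!ok] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  p[!ok] <- 1

  delta1 <- delta1_threshold(params$alpha, ev$sigma0)
  delta2 <- rep(0, nrow(summaries))
  delta2[!degen] <- delta2_threshold(params$beta_th, s[!degen], df[!degen])
  absd <- abs(summaries$d)
  type2 <- rep(NA_real_, nrow(summaries))
  in_dom <- !degen & absd > delta1
  type2[in_dom] <- 1 - stats::pt((absd[in_dom] - delta1[in_dom]) / s[in_dom],
                                 df[in_dom])

  p_th <- rep(NA_real_, nrow(summaries))
  p_th[!degen] <- p_threshold(params$alpha, params$beta_th,
                              ev$sigma0[!degen], s[!degen], df[!degen])
  t_p_stab <- rep(1, nrow(summaries))
  t_p_stab[!degen] <- 2 * stats::pt(-absd[!degen] / s[!degen], df[!degen])

  is_null <- classify_null_features(summaries, model)
  passes <- absd > delta1 + delta2
  if (params$variance_filter) {
    var_ok <- !is.na(summaries$LV) & summaries$LV > ev$lv_th
    passes <- passes & var_ok
  }
  passes[degen] <- FALSE

  ord <- order(-abs(z))               # stable: ties keep input order
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)

  out <- data.frame(
    feature_id = summaries$feature_id,
    mu = summaries$mu, d = summaries$d, fc = summaries$fc,
    vT = summaries$vT, LV = summaries$LV, lv_th = ev$lv_th,
    sigma0 = ev$sigma0, s = s, df = df,
    z_score = z, p_value = p,
    delta1 = delta1, delta2 = delta2,
    type2_error = type2, p_th = p_th, t_p_stab = t_p_stab,
    is_null = is_null, passes_selection = passes, rank = rk,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  class(out) <- c("dfc_result", "data.frame")
  out
}

#' Selection via the conditional-power formulation
#'
#' Recomputes the selection set from the power side --
#' `beta(d|alpha) < beta_th` and `|d| > delta1` (and the variance filter
#' when enabled) -- which is algebraically equivalent to the threshold
#' form `|d| > delta1 + delta2`.  Exposed for verification.
#'
#' @param result A `dfc_result` from [select_and_rank()].
#' @param params The same [dfc_parameters()] used to build `result`.
#' @return Logical selection vector.
#' @export
passes_by_power <- function(result, params = attr(result, "params")) {
  sel <- !is.na(result$type2_error) & result$type2_error < params$beta_th &
    abs(result$d) > result$delta1
  if (params$variance_filter) {
    var_ok <- !is.na(result$LV) & result$LV > result$lv_th
    sel <- sel & var_ok
  }
  sel
}
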