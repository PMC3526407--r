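#' Binning specification for null-model estimation
#'
#' @param strategy `"equal-count"` (default; quantile bins of `mu`, uniform
#'   estimator variance) or `"equal-width"`.
#' @param n_bins Number of expression bins; `NULL` picks
#'   `clamp(floor(N/200), 10, 50)` from the data at fit time.
#' @param min_per_bin Minimum features per usable bin (default 100).
#' @return A `bin_spec` list.
#' @export
bin_spec <- function(strategy = c("equal-count", "equal-width"),
                     n_bins = NULL, min_per_bin = 100L) {
  strategy <- match.arg(strategy)
  if (!is.null(n_bins) && n_bins < 3L) stop("n_bins must be >= 3")
  if (min_per_bin < 20L) stop("min_per_bin must be >= 20")
  structure(list(strategy = strategy, n_bins = n_bins,
                 min_per_bin = as.integer(min_per_bin)),
            class = "bin_spec")
}

#' Estimate the expression-dependent null-feature model
#'
#' From the whole feature population, estimates as a function of mean
#' expression `mu`:
#' * `lv_th(mu)` -- the expected log2 total variance of unregulated
#'   features, `E[LV | d = 0, mu]`, which doubles as the variance-filter
#'   threshold separating the null feature set `{LV < lv_th(mu)}`;
#' * `sigma0(mu)` -- the standard deviation of the null features' logFC
#'   distribution, fitted as the Gaussian-scaled median absolute
#'   deviation of all the bin's d values about `d0_center`.  Because the
#'   DE prior is assumed << 1, the bin's d distribution is dominated by
#'   null features and the MAD (50% breakdown) is insensitive to the DE
#'   tail; estimating on the full bin rather than the variance-filtered
#'   null subset avoids the downward truncation bias that conditioning
#'   on low total variance induces on |d|;
#' * optionally `d0_center(mu)` -- the per-bin median null logFC
#'   (default 0, the nominal centering assumption).
#'
#' Within a bin, `E[LV | d = 0]` is taken as the intercept of a quadratic
#' regression of `LV` on `d` when the bin has >= 200 features; smaller
#' bins fall back to the mean `LV` over features with `|d|` at or below
#' the bin's 40th percentile of `|d|`.  Curves are smoothed with a 3-bin
#' moving average before interpolation.
#'
#' Features with `vT == 0` are excluded from estimation.
#'
#' @param summaries Data frame from [summarize_features()].
#' @param bins A [bin_spec()].
#' @param estimate_d0 If `TRUE`, center the null logFC distribution on the
#'   per-bin median of the null set instead of 0 (for data with
#'   normalization drift).
#' @return A `dfc_null_model`: list with `bin_centers`, `lv_th`, `sigma0`,
#'   `d0_center`, per-bin `n` and `n_null`, and the `bin_spec` used.
#' @export
estimate_null_model <- function(summaries, bins = bin_spec(),
                                estimate_d0 = FALSE) {
  stopifnot(inherits(bins, "bin_spec"))
  usable <- summaries[summaries$vT > 0, , drop = FALSE]
  n <- nrow(usable)
  if (n < 3L * bins$min_per_bin)
    stop(sprintf("too few features with positive variance (%d) for null-model estimation (need >= %d)",
                 n, 3L * bins$min_per_bin))
  n_bins <- bins$n_bins
  if (is.null(n_bins)) n_bins <- max(10L, min(50L, n %/% 200L))
  n_bins <- min(n_bins, n %/% bins$min_per_bin)

  idx <- bin_assign(usable$mu, n_bins, bins$strategy)
  keep <- tabulate(idx, n_bins) >= bins$min_per_bin
  bin_ids <- which(keep)
  if (length(bin_ids) < 3L)
    stop(sprintf("fewer than 3 usable bins (%d) after enforcing min_per_bin=%d",
                 length(bin_ids), bins$min_per_bin))

  centers <- lv_th <- sigma0 <- d0c <- numeric(length(bin_ids))
  nb <- nnull <- integer(length(bin_ids))
  for (k in seq_along(bin_ids)) {
    b <- bin_ids[k]
    sub <- usable[idx == b, , drop = FALSE]
    centers[k] <- mean(sub$mu)
    nb[k] <- nrow(sub)
    lv_th[k] <- bin_lv_at_d0(sub$LV, sub$d)
    null_d <- sub$d[sub$LV < lv_th[k]]
    nnull[k] <- length(null_d)
    if (nnull[k] < 10L)
      stop(sprintf("null set of bin %d (mu ~ %.2f) has only %d features (< 10)",
                   b, centers[k], nnull[k]))
    d0c[k] <- if (estimate_d0) stats::median(sub$d) else 0
    sigma0[k] <- robust_gaussian_scale(sub$d, d0c[k])
    if (sigma0[k] <= 0)
      stop(sprintf("degenerate null logFC scale in bin %d (mu ~ %.2f)",
                   b, centers[k]))
  }

  ord <- order(centers)
  model <- list(
    bin_centers = centers[ord],
    lv_th = moving_average3(lv_th[ord]),
    sigma0 = moving_average3(sigma0[ord]),
    d0_center = if (estimate_d0) moving_average3(d0c[ord]) else rep(0, length(ord)),
    n = nb[ord], n_null = nnull[ord],
    bins = bins, n_bins_used = length(bin_ids),
    estimate_d0 = estimate_d0
  )
  class(model) <- "dfc_null_model"
  model
}

# conditional mean of LV at d = 0 within one expression slice
bin_lv_at_d0 <- function(lv, d) {
  if (length(lv) >= 200L) {
    fit <- stats::lm.fit(cbind(1, d, d * d), lv)
    unname(fit$coefficients[1L])
  } else {
    q40 <- stats::quantile(abs(d), 0.40, names = FALSE)
    mean(lv[abs(d) <= q40])
  }
}

# MAD scaled by 1/0.6745 (Gaussian-consistent); sd fallback if MAD collapses
robust_gaussian_scale <- function(x, center) {
  s <- stats::median(abs(x - center)) / 0.6745
  if (s <= 0) s <- stats::sd(x)
  s
}

moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[1L] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1L):n])
  if (n > 2L) out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out
}

bin_assign <- function(mu, n_bins, strategy) {
  if (strategy == "equal-count") {
    brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE))
  } else {
    brk <- seq(min(mu), max(mu), length.out = n_bins + 1L)
  }
  if (length(brk) < 4L) stop("degenerate mu distribution: cannot form >= 3 bins")
  findInterval(mu, brk, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Evaluate the null model at arbitrary expression levels
#'
#' Piecewise-linear interpolation of the binned curves between bin
#' centers, clamped to the first/last bin outside the grid.
#'
#' @param model A `dfc_null_model`.
#' @param mu Expression levels (log2 units).
#' @return List of vectors `lv_th`, `sigma0`, `d0_center`, and
#'   `v_bar_ee = 2^lv_th`.
#' @export
evaluate_null_model <- function(model, mu) {
  stopifnot(inherits(model, "dfc_null_model"))
  interp <- function(y)
    stats::approx(model$bin_centers, y, xout = mu, rule = 2)$y
  lv_th <- interp(model$lv_th)
  list(
    lv_th = lv_th,
    sigma0 = interp(model$sigma0),
    d0_center = interp(model$d0_center),
    v_bar_ee = 2^lv_th
  )
}

#' Classify features as null (unregulated) or non-null
#'
#' A feature is null iff its log2 total variance falls strictly below the
#' expression-dependent threshold, `LV < lv_th(mu)`; equality is
#' non-null.  Zero-variance features are null by convention.
#'
#' @param summaries Data frame from [summarize_features()].
#' @param model A `dfc_null_model`.
#' @return Logical vector, `TRUE` for null features.
#' @export
classify_null_features <- function(summaries, model) {
  ev <- evaluate_null_model(model, summaries$mu)
  out <- summaries$LV < ev$lv_th
  out[summaries$vT == 0] <- TRUE
  out
}

#' Diagnostic table of the (mu, LV, d) cloud and fitted curves
#'
#' Per-feature view of the quantities the null model is estimated from,
#' plus the interpolated curves at each feature's `mu`; suitable for
#' plotting a variance-vs-expression cloud with its threshold.
#'
#' @inheritParams classify_null_features
#' @return Data frame with columns `feature_id, mu, d, LV, lv_th, sigma0,
#'   d0_center, is_null`.
#' @export
null_model_diagnostics <- function(summaries, model) {
  ev <- evaluate_null_model(model, summaries$mu)
  data.frame(
    feature_id = summaries$feature_id,
    mu = summaries$mu, d = summaries$d, LV = summaries$LV,
    lv_th = ev$lv_th, sigma0 = ev$sigma0, d0_center = ev$d0_center,
    is_null = classify_null_features(summaries, model),
    stringsAsFactors = FALSE
  )
}

#' @export
print.dfc_null_model <- function(x, ...) {
  cat(sprintf("dfc_null_model: %d bins over mu in [%.2f, %.2f]\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers)))
  cat(sprintf("  sigma0 range [%.4f, %.4f]; lv_th range [%.2f, %.2f]\n",
              min(x$sigma0), max(x$sigma0), min(x$lv_th), max(x$lv_th)))
  invisible(x)
}
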