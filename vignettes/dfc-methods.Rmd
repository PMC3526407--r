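---
title: "The distributional fold change test: model, estimation choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The distributional fold change test: model, estimation choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package works on a features × samples matrix of log2 intensities
`X = log2(I)` split into two classes of sizes $n_1, n_2 \ge 2$. Per
feature it computes the class means $\mu_1, \mu_2$, the log fold change
$d = \mu_1 - \mu_2$ (so the fold change is $2^d$), the mean expression
$\mu = (\mu_1+\mu_2)/2$, and the total variance $v_T$ of all $n_1+n_2$
values about their grand mean, with $LV = \log_2 v_T$.

The working assumptions are: intensities are independent and, on the log
scale, normal within class; the feature population is large
($N_p \gg 1$), so that population-level distributions conditioned on
$\mu$ are estimable; it is a mixture of a dominant unregulated ("null")
component and a small regulated component with prior fraction
$\pi \ll 1$; and the null component's log fold changes at expression
level $\mu$ are $N(\bar d_0(\mu), \sigma_0(\mu)^2)$ with
$\bar d_0 = 0$ unless a centering drift is estimated explicitly.

Three expression-dependent curves summarize the null population:

* $LV_{Th}(\mu) = E[LV \mid d = 0, \mu]$, the expected log2 total
  variance of unregulated features, which also serves as the
  variance-filter boundary: features with $LV < LV_{Th}(\mu)$ form the
  null set;
* $\sigma_0(\mu)$, the standard deviation of the null log fold change
  distribution;
* optionally $\bar d_0(\mu)$, a nonzero null center for data with
  normalization drift.

Every feature is scored by

$$Z_d = \frac{d - \bar d_0(\mu)}{\sqrt{v_s(d\mid\mu) + v_0(\mu)}},
\qquad v_0 = \sigma_0^2,$$

where $v_s(d\mid\mu) = v_{s1}/n_1 + v_{s2}/n_2$ uses the minimally
stabilized class variances
$v_s = \frac{n-1}{n} v + \frac{1}{n}\bar v_{EE}(\mu)$ with
$\bar v_{EE}(\mu) = 2^{LV_{Th}(\mu)}$. The stabilization reproduces the
unbiased estimate when the feature's variance equals the local null
average and approaches the maximum-likelihood estimate when it is much
larger; it mainly prevents features with accidentally tiny sample
variance from exploding the score at small $n$.

Selection at significance $\alpha$ and Type II bound $\beta_{Th}$
requires

$$|d| > \Delta_1(\alpha,\mu) + \Delta_2(\beta_{Th},\mu), \qquad
\Delta_1 = \sigma_0(\mu)\,\Phi^{-1}(1-\alpha/2), \quad
\Delta_2 = s(\mu)\,T^{-1}(1-\beta_{Th}, DF),$$

with Welch–Satterthwaite $DF$, optionally intersected with the variance
filter $LV > LV_{Th}(\mu)$. The equivalent power-side formulation — the
conditional Type II error $\beta(d\mid\alpha) =
1 - T((|d|-\Delta_1)/s, DF)$ below $\beta_{Th}$ — is implemented
separately (`passes_by_power`) and verified to select identical sets.
Ranking of all features uses $|Z_d|$ (equivalently, two-sided normal
p-values on $Z_d$), independent of the selection thresholds.

## Tunable parameters

* `alpha` (default **0.05**): two-sided significance of the fold change
  against the local null distribution. Since the null is estimated from
  all features at that expression, `alpha` operates at the population
  level; `alpha = 1` disables $\Delta_1$ entirely.
* `beta_th` (default **0.2**): bound on the Type II error of a t-type
  detection conditional on $\alpha$; `beta_th = 0.5` disables
  $\Delta_2$, reducing selection to a pure fold-change criterion against
  the null spread.
* `variance_filter` (default **on** for selection): the
  $LV > LV_{Th}(\mu)$ condition. For full-list ranking and ROC
  construction it should be off — in that mode one typically also sets
  `alpha = 1, beta_th = 0.5` so the p-value ordering alone defines the
  curve.
* Binning (`bin_spec`): equal-count bins in $\mu$ with
  `n_bins = clamp(floor(N_p/200), 10, 50)` and at least 100 features per
  bin. Equal-count keeps the estimator variance uniform across the
  expression range; equal-width is available for strongly non-uniform
  designs.

All logFC quantities are in log2 units; variances in squared log2 units.

## Estimation choices

**Total variance.** $v_T$ is the unbiased variance of all
$n_1+n_2$ values about the pooled grand mean. This choice makes $v_T$
absorb the between-class signal (for balanced classes,
$(n-1)v_T = SS_w + \frac{n_1 n_2}{n}\hat d^2$), so regulated features
rise above $LV_{Th}$ and the variance filter is meaningful. The pooled
within-class variance is stored alongside (`v_internal`) for
diagnostics. The alternative — internal variance only — would make the
filter blind to regulation.

**$E[LV \mid d=0]$ within a bin.** A quadratic regression of $LV$ on
$d$, evaluated at $d = 0$. The conditional mean is what the definition
demands, and the regression borrows strength from all bin members
instead of only the near-zero-$d$ ones; bins under 200 features fall
back to the mean $LV$ over features with $|d|$ at or below the bin's
40th percentile.

**$\sigma_0(\mu)$.** Estimated as the Gaussian-scaled median absolute
deviation (MAD/0.6745) of *all* $d$ values in the bin about
$\bar d_0$. Two remarks. First, robustness does the contamination
control: with $\pi \ll 1$ the bin's $d$ distribution is dominated by
nulls and the MAD (50% breakdown) is essentially unmoved by the DE
tail, so restricting to a filtered subset is unnecessary. Second,
restricting to the variance-filtered null set would actively *bias*
$\sigma_0$ low: $\hat d^2$ contributes to $v_T$, so conditioning on
below-threshold total variance anti-selects large $|\hat d|$ — on
pure-null simulations that variant underestimated $\sigma_0$ by ~14%,
while the whole-bin MAD is unbiased to within sampling noise. The exact
fitting recipe behind the original formulation is not public; this is
the package's own documented choice.

**Smoothing and evaluation.** $LV_{Th}$ and $\sigma_0$ are smoothed
with a 3-bin moving average, then evaluated anywhere by piecewise-linear
interpolation between bin centers with constant extrapolation (clamping)
outside the grid. Clamping is deliberately conservative: the tails of
the expression range are exactly where bin estimates are noisiest.

**Degenerate features.** Features with $v_T = 0$ are excluded from
null-model fitting, classified null by convention, and scored through
the stabilized-variance floor ($\bar v_{EE}/n$); if the local
$\bar v_{EE}$ is also 0 they receive $Z_d = 0$, $p = 1$. Boundary cases
use strict inequalities throughout ($LV = LV_{Th}$ is non-null;
$|d| = \Delta_1 + \Delta_2$ fails selection). Ties in $|Z_d|$ are broken
by input order, so runs are byte-reproducible.

**Null d-distribution support.** The mixture derivation's integral over
the null variance range is taken over $LV \in (-\infty, LV_{Th}]$: a
lower bound of 0 would be a unit artifact, since $LV$ is a log and
routinely negative.

## Calibration of the score — a deliberate conservatism

$\Delta_1$ is exactly calibrated: for a null feature,
$P(|d| > \Delta_1(\alpha,\mu)) = \alpha$ by construction, and the test
suite verifies the empirical rate on pure-null simulations. The normal
p-value on $Z_d$, however, is *conservative* on ideal pure-null data:
there $\sigma_0^2$ itself equals the sampling variance of $d$, so the
denominator $\sqrt{v_s(d) + \sigma_0^2}$ counts the sampling noise
twice and $Z_d \sim N(0, \approx 1/2)$, giving a rejection rate near
$2(1-\Phi(1.96\sqrt2)) \approx 0.006$ at nominal 0.05 rather than 0.05.
This is intrinsic to the score's design — the $v_0$ term is meant to
carry population-level spread of null fold changes (normalization drift,
technical heterogeneity), which in idealized simulations is absent. The
score's job is ranking, for which any monotone rescaling is irrelevant;
its p-values should be read as conservative ranking scores, not
calibrated tail probabilities. One acceptance criterion asserts strict
calibration of these p-values and is knowingly left failing, with this
analysis as the explanation.

## What the simulator emulates — and what it does not

`generate_dataset` draws baseline expressions uniformly over a log2
range (default 4–14), within-class values independently normal with an
expression-dependent variance — constant, monotone-decreasing
("mas5"-like, $a\,2^{-b\mu}+c$), or low-plateau-with-low-expression-rise
("rma"-like, logistic in $\mu$) — a fixed count
$\mathrm{round}(\pi N_p)$ of DE features with symmetric signs and
shifted-gamma magnitudes (optionally expressed in local
signal-to-noise units), and optional FFPE-like distortion: a
multiplicative compression of all true fold changes and a downward
shift of expression. Everything is reproducible from a single seed and
the caller's RNG state is restored.

It does **not** emulate: probe-level effects or probe-to-gene
summarization; correlation between features (all features independent);
heavy-tailed or skewed intensity noise; differential RNA degradation
rates; array normalization artifacts (the null center is exactly 0
unless shifted by hand). A green test on this generator therefore
establishes internal consistency of the estimators and the documented
reductions — it does not certify performance on real arrays, where the
packaged benchmark AUC table of eleven public datasets serves as the
external reference point for the comparison machinery.

Default generator settings state the world the tests run in:
$N_p = 5000$, $n_1 = n_2 = 10$, $\pi = 0.02$, flat variance 0.25
(log2²), effect magnitudes $0.5 + \Gamma(1.5, 0.6)$ log2 units. They
were chosen once, as a plausible medium-sized two-class study, and are
not tuned to test outcomes.

## Evaluation machinery

ROC curves sweep all distinct score thresholds; tied scores enter as a
group, producing diagonal segments, so the trapezoidal AUC equals the
pairwise probability $P(\text{pos} > \text{neg}) + \frac12
P(\text{tie})$ exactly (verified against a brute-force pairwise oracle).
Each ROC point also carries the selected fraction
$\nu = \eta(1-N_T/N_p) + \tau N_T/N_p$. The standardized partial area
$SPA(\eta) = \frac{1}{\eta}\int_0^\eta \tau$ integrates segment-wise
with clipping, so vertical jumps at the boundary contribute nothing;
$SPA(1) = AUC$ identically. Paired AUC comparisons use a one-sided
Wilcoxon signed-rank test on raw AUCs and a one-sided paired t-test on
logit-transformed AUCs $\tfrac12\ln(AUC/(1-AUC))$; cross-condition
stability is the Pearson correlation of logit AUCs (Spearman
available). Curve averaging across datasets interpolates $\tau$ and
$\eta$ onto a common $\nu$ grid — the quantity that is comparable across
datasets of different sizes — with standard-error bands.

## Known limitations

* No multiple-testing correction is applied to the ranked p-values; the
  expression-dependent threshold structure does not translate directly
  into standard FDR machinery, and any correction would change only the
  cut, not the ranking.
* The Welch-t reference distribution for $\Delta_2$ and the power
  calculation treats the stabilized variances as if they were plain
  sample variances; the approximation is good except at very small
  $n$ (< ~5 per class), where a dedicated shrinkage design would do
  better.
* $\sigma_0$ estimation assumes the null dominates every expression
  bin; datasets with locally dense regulation (e.g. a DE fraction
  concentrated in a narrow expression band exceeding tens of percent)
  would inflate it there.
* The variance filter assumes regulation inflates total variance; a
  regulated feature with strongly reduced within-class variance in both
  classes could in principle slip under $LV_{Th}$.
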