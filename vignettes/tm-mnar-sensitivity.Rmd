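---
title: "Trimmed means under MNAR dropout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimmed means under MNAR dropout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbias)
```

## The problem

In a two-arm randomized trial with a single continuous outcome, dropout that
depends on the unobserved outcome itself (missing not at random, MNAR) biases
a complete-case analysis (CCA) and any analysis that assumes missing at
random, including multiple imputation. A canonical example: comparator-arm
patients who experience no benefit — and would have recorded the worst
outcome values — leave the study.

The trimmed-means (TM) estimator targets exactly this situation. Within each
arm, missing outcomes are assigned the most extreme rank on the assumed
dropout side, the same fraction $p$ of each arm's (missing-padded)
distribution is trimmed away from that side, and the treatment effect is
estimated by least squares of the outcome on the arm indicator over the
retained rows. `tmbias` implements the estimator, the closed-form calculus of
its biases when its assumptions fail, a variance-rescaled adjusted estimator,
permutation inference, an MNAR dropout simulator, and a replication harness.

## Model and assumptions

Let $y_{ij}$ be the outcome of participant $i$ in arm $j \in \{0, 1\}$, with
population means $\mu_j$, treatment effect $\beta = \mu_1 - \mu_0$, and
missingness indicator $m_{ij}$. The TM estimand with lower-value trimming at
fraction $p$ is
$$\mu_{tj} = E[Y \mid R = j,\; Y > F_j^{-1}(p)], \qquad
  \beta_t = \mu_{t1} - \mu_{t0},$$
estimated by the mean of the retained $\lceil n_j (1 - p) \rceil$
observations per arm. $\hat\beta_t$ is unbiased for $\beta$ under two
assumptions:

* **Strong MNAR**: all missing outcomes lie inside the trimmed-away fraction,
  so the retained fraction is fully observed. This requires
  $p \ge p_\min$, the largest observed per-arm dropout proportion
  (*adaptive* trimming sets $p = p_\min$).
* **Location shift**: the arm outcome distributions are identical in shape
  and differ only by a mean shift (under normality: equal SDs).

For normal arms with SD $\sigma_j$, all bias formulae below are expressed
through truncated-normal means parameterized on the quantile scale:
$\mu_{u,v} = \mu - \sigma Q_{u,v}$ with
$Q_{u,v} = [\phi(\Phi^{-1}(v)) - \phi(\Phi^{-1}(u))]/(v - u)$
(`q_factor()`, `truncated_mean()`), with $\phi(\Phi^{-1}(x))$ defined as 0 at
$x \in \{0, 1\}$ so tail terms vanish rather than blow up. Working on
probability masses keeps every formula arm-interchangeable; conversion to
outcome units happens only through $(\mu_j, \sigma_j)$.

## The bias calculus

**Location-shift violation.** With unequal SDs and strong MNAR intact,
$$B_t^{LS} = (\sigma_1 - \sigma_0)\,\frac{\phi(\Phi^{-1}(p))}{1 - p},$$
which is $(\sigma_1 - \sigma_0)\sqrt{2/\pi}$ at $p = 0.5$
(`location_shift_bias()`). The sign flips for higher-value trimming.

**Strong-MNAR violation.** Dropout is modelled as *homogeneous* within a
region: a proportion $p_d$ of the arm is deleted uniformly from the lowest
fraction $c$ of the distribution (`dropout_scenario()`). When $c > p$ some
dropout sits in the retained fraction, the retained mass must reach down to a
shift quantile $b = c - c(c - p)/(c - p_d)$ (`strong_mnar_shift()`), and the
per-arm bias magnitude is
$$B_t^{SM} = -\frac{c - p}{1 - p}\,\sigma\,(Q_{p,c} - Q_{b,c})$$
(`strong_mnar_bias()`), zero when $c \le p$ and maximal at $c = 1$ (MCAR).
`combine_biases()` signs the per-arm components: under lower-value trimming a
comparator-arm violation pushes the estimate up, a treatment-arm violation
down, and both flip under higher-value trimming. The total
$B_t = B_t^{LS} + B_t^{SM,0} + B_t^{SM,1}$ yields the bias-adjusted estimate
$\hat\beta_t^{BA} = \hat\beta_t - B_t$ and the ordered pair
$\{\hat\beta_t, \hat\beta_t^{BA}\}$ brackets the plausible effect.

**CCA bias.** Under the same mechanism the complete-case mean is the thinned
mixture $[(c - p_d)\mu_{0,c} + (1 - c)\mu_{c,1}]/(1 - p_d)$, giving
`cca_bias()`; it vanishes at $p_d = 0$ and at $c = 1$. Its maximum over all
mechanisms with fixed $p_d$ is the Copas–Jackson bound
$\sigma\,\phi(\Phi^{-1}(p_d))/(1 - p_d)$ (`cca_max_bias()`), attained by a
threshold selection model that deletes exactly the most extreme $p_d$
fraction. `tm_max_bias()` gives the analogous worst case for the TM
estimator, reached when dropout sits in the *opposite* tail to the one
trimmed.

Three of these printed formulae lost their fraction bars in the source
rendering; the implementations are re-derivations validated against the
published numeric values (0.19, 0.06, 0.29, 0.15, −0.40, and the ≈10-unit
screening bound) and against million-draw deletion oracles in the test suite.

**SDs from thinned samples.** The bias formulae need full-sample SDs, but an
analyst observes post-dropout SDs. Homogeneous thinning scales a normal's SD
by a known factor (the thinned distribution is a two-component truncated
mixture), so `infer_full_sd()` inverts the relation in closed form — the
factor is free of $\mu$ and $\sigma$, so no root-finding is needed.

## The adjusted estimator

At $p = 0.5$ the retained fraction of a normal arm is half-normal.
`adjusted_tm_fit()` relaxes the location-shift assumption by *mirroring* the
rescaled arm's retained half about its trim boundary $m$ — producing an
artificial full normal with mean $m$ and SD
$\hat\sigma_g = \sqrt{\tfrac{1}{n}\sum (y - m)^2}$ — and rescaling it to the
other arm's full-sample SD:
$$\hat\mu_{at,g} = m + (\bar y_{tg} - m)\,\hat\sigma_{o}/\hat\sigma_g.$$
The other arm's SD $\hat\sigma_o$ is read directly off its observed outcomes
when it has no dropout, and otherwise extrapolated from its trimmed-fraction
SD via $\sqrt{\pi/(\pi - 2)}$ (`half_normal_sd_factor()`). Under no violation
the two routes coincide ($m \to \mu$, mirrored SD $\to \sigma$), and the
estimator is exactly unbiased under unequal SDs whenever dropout stays inside
the trimmed fraction. Under violation they differ, and the mirror
construction is the one that reproduces the published simulation results for
the comparator-rescaled estimator; SD-factor extrapolation of the rescaled
arm itself would understate the adjustment (it predicts 0.90 where the
reference simulations give 0.96 in the MCAR unequal-SD design). The
adjustment is defined for fixed 50% trimming only and is strongly reliant on
normality — both are hard errors, not warnings, elsewhere.

## Permutation inference

The reference approach for TM intervals is permutation-based but its exact
construction is not spelled out; `permutation_ci()` therefore documents its
own: arm labels are permuted across participants (missingness travels with
its row), the complete trim-and-fit pipeline is re-run per permutation, and a
basic (reflection) interval shifts the observed estimate by the permutation
null quantiles, with the SE reported as the SD of the null distribution.
Defaults: 1000 permutations, 95% level. For fixed trimming, a permutation in
which one arm's dropout exceeds $p$ is trimmed at that permutation's minimum
feasible fraction, keeping the pipeline total rather than discarding draws.

## The synthetic-trial generator

`generate_trial()` draws $y = \mu_j + \gamma u + \varepsilon$ with
$u \sim N(0,1)$ and residual SD $\sqrt{\sigma_j^2 - \gamma^2}$, so the
*total* arm SD equals the design's $\sigma_j$. Dropout mechanisms
(`apply_dropout()`):

* `mech_restricted()` — exactly `round(pd * n)` deletions drawn uniformly
  from the rows whose pre-deletion outcome lies in the lowest (highest)
  `round(c * n)` values of the arm. Exact-count deletion is used instead of
  per-row Bernoulli thinning to cut Monte-Carlo variance and match designs
  stated as "20% dropout"; region membership uses the pre-deletion empirical
  quantiles because the spread bound is defined on the full outcome
  distribution.
* `mech_mcar()` — the `c = 1` special case.
* `mech_logit()` — per-row Bernoulli missingness with probability
  `plogis(intercept + slope_u * u + arm_offset)`, for covariate-dependent
  (MAR) dropout.
* `mech_threshold()` — deterministic deletion of the most extreme values,
  the mechanism attaining the maximum-bias bounds.

The shipped study configurations (`study_config()`, `run_study()`) replicate
the reference simulation designs at $n = 500$ per arm, $S = 1000$
replicates, with closed-form predictions attached where the scenario is
homogeneous-normal. Two generator choices were open and are fixed here once:

* **Logit coefficients.** The covariate-dependent designs report realized
  dropout proportions (≈18% treatment / 36% comparator; ≈30%
  treatment-dependent covariate missingness) but not coefficients. The
  defaults (`intercept = -1.76, slope_u = 1` on the outcome;
  `intercept = -1.73`, treatment offset `1.40` on the covariate) were
  calibrated once against those marginal rates and are asserted, with
  tolerance, in the test suite.
* **Log-normal parameterization.** Where the outcome family is log-normal,
  the latent normal (including the covariate contribution) is scaled so that
  the *outcome-scale* SD equals $\sigma_j$, exponentiated, centred, and
  shifted by $\mu_j$, so the stated effect and SDs live on the outcome
  scale. The reference tables state outcome-scale parameters but not the
  generation recipe; with this parameterization the TM estimator is
  unbiased when its assumptions hold (asserted in tests), but complete-case
  and adjusted-estimator summaries under skewness depend on the recipe and
  are not comparable cell-by-cell with the reference values.

What the generator does *not* emulate: repeated measures and longitudinal
dropout processes, more than two arms, non-normal families beyond the
log-normal above, floor/ceiling effects and integer-valued scores of real
instruments. Passing tests therefore demonstrate correctness of the
estimators and formulae under the stated generating mechanisms, not
robustness to everything real trial data can do.

## Covariate imputation

`impute_covariate()` is deliberately simple: normal-linear stochastic
regression of the covariate on arm and outcome among observed rows *after*
trimming, with 5 imputations by default (estimates are pooled by averaging,
SEs by Rubin's rules in `tm_fit_pooled()`). Five suffices here because only
the point estimate feeds the replication summaries; analysts wanting full MI
inference on real data should use a dedicated MI package and feed the
completed datasets through `tm_fit()`.

## Numerical choices and degenerate inputs

* Quantile-interval validity is checked to tolerance `1e-12`; degenerate
  intervals ($u = v$), single-arm data, all-missing arms and empty post-trim
  arms are hard errors, never silent `NaN`.
* The retained count applies the ceiling rule with an epsilon guard
  (`ceiling(n * (1 - p) - 1e-9)`) because adaptive $p$ is an exact ratio
  $k/n$ and floating point can otherwise inflate the count by one.
* Ties at the trim boundary are broken by input row order, retaining exactly
  the ceiling-rule count; missing values are ranked as a block at the
  trimmed extreme with stable input order, and their numeric value is never
  materialized.
* Adaptive $p$ uses the observed dropout proportions exactly, with no
  rounding to a grid.
* All biases are reported on the $\hat\beta - \beta$ scale of the fitted
  regression, so overestimation of a beneficial negative effect appears as
  negative bias; direction handling is centralized in `combine_biases()`
  rather than duplicated per formula.

## Problem sizes

The test suite runs the full Table-replication studies at $S = 1000$
replicates of $n = 1000$ participants and checks closed-form oracles with
$10^6$-draw Monte-Carlo simulations; property-style checks use smaller
configurations ($n = 40$–$500$, $S = 120$–$500$) sized so that three
Monte-Carlo standard errors separate signal from noise. The acceptance
script re-runs the headline designs at the reference scale
($S = 1000$, $n = 500$/arm).

## Known limitations

* Bias formulae assume normal outcomes; for skewed data they establish bias
  *direction* and relative magnitude across scenarios, not exact size.
* Covariate-dependent (non-homogeneous) dropout has no closed-form bias
  here; the homogeneous formula with a widened spread serves as an upper
  bound within the homogeneous family.
* The sensitivity workflow reproduces the published bias-decomposition
  *arithmetic* exactly, but intermediate strong-MNAR components for the
  motivating trial depended on an unpublished full-sample SD inference and
  are not reproduced number-for-number; `infer_full_sd()` is this package's
  own, documented, inversion.
* The adjusted estimator is defined only for $p = 0.5$ and degrades under
  non-normality; prefer the unadjusted TM estimator plus the bias calculus
  when normality is doubtful.
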