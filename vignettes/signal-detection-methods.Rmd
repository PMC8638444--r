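---
title: "Signal detection in spontaneous reports: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection in spontaneous reports: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The statistical problem

Spontaneous reporting systems collect case reports of suspected adverse drug
reactions. Each report lists the drugs the patient was exposed to; for a
given adverse event (AE) of interest, a report either mentions that event or
not. Classical disproportionality analysis reduces this to one 2x2 table per
drug, which ignores co-prescription and suffers from masking: a heavily
reported drug can hide a weaker but real association of a co-reported drug.

`pvsignal` instead treats detection as variable selection in one multiple
logistic regression over all drugs simultaneously:

$$\operatorname{logit} \Pr(y_i = 1 \mid x_i) = \beta_0 + \sum_{p=1}^P \beta_p x_{ip},$$

where $x_{ip} \in \{0,1\}$ indicates exposure of report $i$ to drug $p$ and
$y_i$ indicates the AE. The exposure matrix is large, binary and extremely
sparse, and cases are typically rare. A drug is *declared a signal* when its
fitted coefficient is strictly positive (harmful direction); L1 solvers
return exact zeros for inactive drugs, so no epsilon is involved.

All penalized fits minimize the per-observation objective

$$-\tfrac{1}{N}\,\ell(\beta_0, \beta) + \lambda \sum_p w_p\,|\beta_p|,$$

with an unpenalized intercept and per-drug penalty multipliers $w_p \in
(0, \infty]$ ($w_p = \infty$ excludes a drug). Under this scaling the
smallest penalty with an empty model is
$\lambda_{\max} = \max_p |x_p^\top(y - \bar y)| / (N\,w_p)$, which the
package exposes as `lambda_max()` and verifies against the fitted path.
`glmnet` performs the path computation; the wrapper undoes glmnet's internal
renormalization of penalty factors so user-facing $\lambda$ values are
exactly on this scale.

## The detector families

**Lasso selectors.** `lasso-cv` picks $\lambda$ minimizing 5-fold
cross-validated binomial deviance (folds stratified on the outcome; with
case fractions as low as $\operatorname{expit}(-6) \approx 0.25\%$,
unstratified folds can lack cases entirely). `lasso-bic` enumerates the
distinct supports visited along the path, refits each by unpenalized maximum
likelihood, and minimizes $\mathrm{BIC} = -2\ell + \mathrm{df}\,\ln N$;
because equal supports give equal refits, the criterion selects a support
rather than a particular $\lambda$, and ties break toward the smaller
support. `lasso-perm` regresses $K = 20$ permutations of the outcome on the
unpermuted design, records each permuted problem's $\lambda_{\max}$, and
fits the original data at the median (midpoint of the central order
statistics for even $K$); permutations are uniform and may include the
identity.

**CISL.** The class-imbalanced subsampling lasso draws $B = 100$ bootstrap
subsamples of size $N/2$ with cases over-weighted so the expected subsample
case fraction is $\min(0.5, \text{observed})$ — the weight is
$\max(1, n_0/n_1)$, never down-weighting cases. On each subsample a lasso
path is fitted and, for each drug, the fraction of model sizes
$\eta = 1..E$ at which its coefficient is positive,
$\hat\pi^b_p = \tfrac1E \sum_\eta \mathbf 1[\hat\beta^{\eta,b}_p > 0]$,
is recorded, where $E$ is the largest final active-set size over all
subsample paths. "The model with $\eta$ covariates" is resolved by
first-crossing on the path's df sequence, carrying forward when df skips a
value and truncating at the path end. A drug is declared when the lower
(type-1) empirical 10%-quantile of $\{\hat\pi^b_p\}_b$ is positive —
equivalently when fewer than $\lceil 0.1B \rceil$ of the $B$ values are
zero.

*Model-size cap.* The subsample paths are truncated at `dfmax = 50` active
drugs. This matters: on small panels the default grid (down to
$10^{-2}\lambda_{\max}$) reaches the nearly saturated model, and "positive
at some model size" then degenerates to the sign of the full-model
coefficient, which is stable across subsamples of the same parent data —
the quantile rule loses its protection and noise drugs are declared. With
the cap, and a drug panel substantially larger than $E$ (the regime the
method is designed for), the null declared set is empty. Users analysing
panels with $P$ close to 50 should raise `dfmax` consciously or interpret
CISL output with care; the package's own evaluation uses $P \geq 100$.

**Adaptive lasso.** Five two-stage detectors differ in how the first stage
builds the weights $w_p$ and how the second stage selects (Table):

| method | weights from | adaptive-stage selection |
|---|---|---|
| `adapt-cv` | cross-validated lasso, $w = 1/|\hat\beta^{lcv}|$, $\infty$ off-support | cross-validation |
| `adapt-univ` | univariate coefficients, $w = 1/|\hat\beta^{univ}|$ | cross-validation |
| `adapt-univ-bic` | univariate coefficients | BIC |
| `adapt-bic` | BIC-selected lasso, weights from the *unpenalized refit*, $\infty$ off-support | BIC |
| `adapt-cisl` | CISL's non-zero selection proportions $\hat\tau^b_p$ | BIC |

The CISL-based weights are $1/B$ when $\hat\tau^b_p > 0$ in every
subsample, $\infty$ when in none, and $1 - \tfrac1B\sum_b
\mathbf 1[\hat\tau^b_p > 0]$ otherwise. For the univariate weights there is
no exclusion branch; a univariate coefficient that is exactly zero (a drug
with sample odds ratio 1) maps to a large finite cap `w_max = 1e10` rather
than $\infty$, a choice this package makes explicit and configurable. For a
binary exposure the univariate logistic MLE is the log odds-ratio of the
2x2 table, so these weights are computed in closed form, with a ridge
($10^{-8}$)-stabilized fit when a table cell is empty.

For the CV-selected variants the adaptive-stage $\lambda$ is chosen by
nested cross-validation: weights are re-derived on each training fold
(directly for univariate weights, by an embedded CV lasso otherwise), the
per-fold weighted path is evaluated on a common full-data grid at the
grid's own points (no interpolation), and the winning $\lambda$ is applied
to the full data with full-data weights. A fold whose weights exclude
everything contributes the null-model deviance at every grid point.

The BIC variants judge positivity on the unpenalized refit coefficients;
CV variants on the penalized fit at $\lambda^*$. Only weight exponent
$\gamma = 1$ is implemented; other values raise an error rather than
silently changing the estimator. By construction every `adapt-bic` signal
lies inside the `lasso-bic` selected support — the harness asserts this on
every simulated replication.

**Propensity-score detectors.** For each drug with more than three reports
in common with the AE (`coreport_filter()`, strict inequality; filtered
drugs keep p-value 1), the drug column becomes the exposure and a
propensity score is estimated: confounders are selected among all other
drugs by `lasso-bic` and the exposure model is refitted unpenalized. Four
analyses follow: adjustment (outcome ~ exposure + PS, linear on the logit
scale), IPTW ($1/\mathrm{ps}$ or $1/(1-\mathrm{ps})$), IPTW with weights
clamped to the pooled 2.5%/97.5% empirical percentiles
(linear-interpolation quantiles, both arms pooled), and matching weights
$\min(\mathrm{ps}, 1-\mathrm{ps})$ divided by the observed arm's
probability. Each drug gets a one-sided Wald p-value for a harmful effect —
model-based variance for adjustment, a robust sandwich variance for the
weighted fits, the standard practice for weighted PS analyses. The
Benjamini-Yekutieli step-up at FDR level 5% (valid under arbitrary
dependence) determines the declared set.

**RFET.** The reporting Fisher's exact test is the disproportionality
baseline: the one-sided hypergeometric tail $P[A \ge a]$ of the 2x2 table
with margins fixed, the same `>3` co-report filter, and the same BY
correction. A mid-p variant (subtracting half the point mass at the
observed count) is available behind a flag; the default is the standard
conservative tail.

## The synthetic-data engine

The real spontaneous-report exposure matrix this methodology targets is not
distributable, so `sample_exposure()` generates a stand-in with its two
salient features: extreme sparsity and heavy-tailed drug reporting
frequencies. Per report, $k \sim 1 + \mathrm{Poisson}(1.5)$ drug mentions
are drawn with replacement from a log-uniform weight law on
$[2\times10^{-4}, 0.05]$ and deduplicated (the matrix is binary). This
gives the exact inclusion probability
$1 - (1-q_j)e^{-1.5 q_j}$, $q_j = w_j / \sum w$, which the generator
reports and the tests verify against realized column means. The weight
range was set so every drug's implied marginal exceeds 11 reports per
100 000 at $P = 500$ and both reporting classes are populated: *frequent*
drugs (at least 100 reports per 100 000) and *rare* drugs (20 to 100 per
100 000, the boundary count classed as frequent). The thresholds are rates,
scaled by $N$, so reduced-size runs keep their meaning. An optional cluster
tilt (per report, one drug cluster's weights are multiplied by a
configurable odds factor) induces co-reporting correlation; multiplier 1 is
exactly the independent model. What the generator does *not* emulate is the
correlation structure of real prescribing — polypharmacy by indication,
age- and sex-linked exposure patterns — so passing tests demonstrate
correctness of the machinery and qualitative behaviour of the detectors,
not real-data operating characteristics.

Outcomes follow the logistic model above, with intercepts
$\beta_0 \in \{-2, -4, -6\}$ spanning common to very rare events, true
predictor counts $\{0, 5, 20\}$, effects $\beta_{TP} \in \{1, 2\}$ and
predictor frequency class frequent/rare: the 27-cell grid of
`scenario_grid()`, with the exposure matrix, the predictor set (drawn
uniformly within the class by realized counts) and the outcome all
regenerated every replication.

## Evaluation conventions

Replications are scored by confusion counts against the planted truth (or a
reference set, where drugs of unknown status are excluded from everything
but the raw signal count). FDR is `FP / declared-with-known-status` with
$0/0 = 0$ — necessary for averaging over replications where conservative
methods declare nothing — and sensitivity is `TP / n_TP`, undefined when no
predictors were planted. Aggregates use the sample (n-1) standard
deviation. All methods in a replication see identical data. Per-task seeds
are pre-drawn from the master seed, so the result table is reproducible and
independent of execution order.

## Numerical choices

* Path fitting: `glmnet`, `standardize = FALSE`, convergence threshold
  $10^{-8}$ (tightened to $10^{-12}$ where fits are compared against
  independent solvers), warm starts along the decreasing grid; default grid
  100 points down to $10^{-2}\lambda_{\max}$. Grid points glmnet does not
  reach (saturation, `dfmax`) carry the last converged solution forward and
  are flagged.
* Unpenalized refits: sparse Newton-Raphson with step-halving, warm-started
  from the penalized solution that produced the support. Collinear supports
  are repaired deterministically (scanning in column order on the Gram
  matrix, lowest index kept). Separation — frequent when refitting
  rare-outcome supports — is detected by divergence (any coefficient beyond
  15 in absolute value, odds ratios above $3\times10^6$) or boundary fitted
  values, and resolved by a $10^{-8}$ ridge, flagged, rather than by
  failure.
* BIC ties break toward the smaller support; `df` counts drugs only, never
  the intercept.
* The empirical quantile in the CISL rule is the lower (type-1) quantile,
  which gives the clean counting interpretation above; weight truncation
  uses type-7 (linear interpolation) quantiles, matching standard practice
  for continuous weights.
* Reports with no drug exposures are retained in all regressions — they
  carry information about the intercept.

## Problem sizes used in the package's own checks

The test-suite replication study runs at $N = 20\,000$, $P = 100$, 50
replications per scenario cell, and the acceptance script at the same size
with 20 replications; the intercept-only case-count check runs at the full
$N = 100\,000$ with 500 replications, and the PS size check uses 400
replicates of a 1 500-report confounded null. These sizes were chosen so
the full suite runs on a single CPU in well under half an hour while
keeping Monte-Carlo error small relative to the tolerances tested.

## Known limitations

* CISL's quantile rule presumes a drug panel much larger than the capped
  model size; see the discussion of `dfmax` above.
* The BIC carries no finite-sample FDR guarantee; its error control here is
  empirical, as the simulation results show.
* The univariate-weight cap (`w_max`) and the CISL subsampling defaults
  (`B`, subsample size, case weight) are reasoned defaults, not values with
  a theoretical optimum; all are exposed as arguments.
* PS detectors inherit the instability of inverse-probability weights when
  propensity scores approach 0 or 1; truncation mitigates but does not
  remove it, and matching weights are the conservative alternative.
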