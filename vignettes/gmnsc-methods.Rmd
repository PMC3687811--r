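---
title: "Shrunken centroid classification under class imbalance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrunken centroid classification under class imbalance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gmnsc)
```

## The problem

Nearest shrunken centroid (NSC) classifiers are a workhorse for
high-dimensional class prediction — typically gene-expression data with
tens of thousands of variables and at most a few hundred samples. They
assign a new sample to the class whose *shrunken* centroid is nearest in a
variance-standardized distance, and the shrinkage doubles as variable
selection. The amount of shrinkage is conventionally tuned by minimizing
the cross-validated overall error rate.

That convention fails quietly when the classes are imbalanced. The overall
error gives the minority class little weight, and with many variables the
minority centroid is the noisier estimate, so error-minimizing tuning
prefers small thresholds, keeps thousands of noise variables active and
drives almost every new sample into the majority class. This package
implements the NSC family together with a tuning rule designed for that
regime: select the threshold maximizing the cross-validated *geometric
mean* of the class-specific predictive accuracies (g-means). The
resulting classifiers are called GM-PAM, GM-ALP and GM-AHP.

## The model

Let $x_{ij}$ be variable $j$ on sample $i$, with classes $k = 1,\dots,K$
of sizes $n_k$, class centroids $\bar x_{kj}$, overall centroid
$\bar x_j$ (mean over all $n$ samples), pooled within-class standard
deviation $s_j$ and $s_0$ the median of the $s_j$. The standardized
difference between the class and overall centroid is

$$d_{kj} = \frac{\bar x_{kj} - \bar x_j}{m_k (s_j + s_0)},
\qquad m_k = \sqrt{1/n_k - 1/n},$$

and the shrunken centroid reconstructs as
$\bar x'_{kj} = \bar x_j + \hat d_{kj}\, m_k (s_j + s_0)$, where
$\hat d_{kj}$ is a penalized version of $d_{kj}$. The three penalties are:

* **PAM** — uniform soft-thresholding,
  $\hat d_{kj} = \mathrm{sgn}(d_{kj})(|d_{kj}| - \lambda)_+$: every
  variable is shrunken by the same amount.
* **ALP** — an adaptive $L_\infty$ penalty
  $\lambda \sum_j w_j \max_k |\tilde d_{kj}|$: per variable, components
  above a common cap are clipped to it, smaller components are untouched,
  and the variable drops out entirely iff
  $\sum_k |d_{kj}| \le \lambda w_j$.
* **AHP** — a hierarchical penalty on the factorization
  $\tilde d_{kj} = \gamma_j \theta_{kj}$ ($\gamma_j \ge 0$):
  $\lambda_\gamma \sum_j w^\gamma_j \gamma_j +
  \lambda_\theta \sum_{j,k} w^\theta_{kj} |\theta_{kj}|$, combining
  variable-level and class-level shrinkage.

A new sample $x^*$ receives discriminant scores

$$\delta_k(x^*) = \sum_j \frac{(x^*_j - \bar x'_{kj})^2}{(s_j + s_0)^2}
  - 2 \log \pi_k$$

and is assigned to $\arg\min_k \delta_k$. At $\lambda = 0$ the rule is
essentially diagonal linear discriminant analysis (up to the $s_0$
stabilizer); variables with $\hat d_{kj} = 0$ in every class contribute
the same amount to every score and are *inactive*.

Two conventions matter under imbalance and are the package defaults:

* **Equal priors.** With empirical priors $\pi_k = n_k/n$, the
  $-2\log\pi_k$ term dominates whenever most variables are inactive and
  pushes everything into the majority class; we use $\pi_k = 1/K$.
  Empirical and user priors remain available for comparison.
* **Random tie-breaking.** Under complete shrinkage all scores tie
  exactly; ties (relative tolerance $10^{-12}$) are resolved uniformly at
  random, with an optional seed for reproducibility. The tolerance is
  deliberately tiny: genuine ties arise only through complete shrinkage,
  but near-ties produced by floating-point summation order must not flip
  classes irreproducibly.

## Threshold tuning

`nsc_fit()` evaluates a grid of `T = 30` thresholds, equally spaced from 0
to $\lambda_{\max}$ — the smallest threshold at which every centroid
collapses onto the overall centroid — by stratified `folds = 10` fold
cross-validation, pools the held-out predictions over folds
(micro-averaging, matching the indicator-sum estimator of the per-class
accuracies $PA_k$) and selects

* `criterion = "min_error"`: the threshold minimizing the pooled CV
  error (the conventional rule; classifiers PAM/ALP/AHP), or
* `criterion = "max_gmeans"`: the threshold maximizing
  $GM = (\prod_k PA_k)^{1/K}$ (classifiers GM-PAM/GM-ALP/GM-AHP).

The final model is refit on the complete training data at the selected
threshold. Ties in the selection criterion go to the *largest* threshold:
the criterion values are identical, so we prefer the sparser model.
Stratification is not optional decoration — with a 90/10 class split and
10 folds, unstratified folds routinely leave the minority class absent
from a training fold. `folds = n` requests leave-one-out CV. A
logarithmic grid (`spacing = "log"`, zero prepended to a geometric
sequence from $\lambda_{\max}/1000$) is available for problems where many
variables carry signal and interesting thresholds crowd near zero.

$\lambda_{\max}$ is exact for all three methods: $\max_{kj} |d_{kj}|$ for
PAM and $\max_j \sum_k |d_{kj}|/w_j$ for ALP. For AHP, profiling
$\theta$ out of the per-variable objective and substituting
$t = \gamma/\lambda$ reduces the all-zero condition to a one-dimensional
maximization whose piecewise stationary points are roots of a quadratic,
solved exactly piece by piece (`lambda_max()`).

## Numerical choices

* **Pooled SD divisor.** $s_j$ uses the standard pooled within-class
  estimator with divisor $n - K$; $s_0$ is the median over all $p$
  variables, zero-variance variables included. Every class must have at
  least two samples; an all-constant matrix (so $s_j \equiv 0$ and
  $s_0 = 0$) is an error rather than a silent division by zero.
* **Adaptive weights.** The ALP/AHP weights default to the adaptive-LASSO
  convention: $w_j = w^\gamma_j = 1/\max_k |d_{kj}|$ and
  $w^\theta_{kj} = 1/|d_{kj}|$, clamped at $10^{8}$ for near-zero
  denominators. They are exposed as arguments; the oracle tests are
  weight-agnostic.
* **AHP solver.** A single user-facing threshold is tuned with
  $\lambda_\gamma = \lambda_\theta$ by default (`lambda_ratio`
  configures the link). The per-variable problem is biconvex, solved by
  alternating closed-form updates (soft-threshold $\theta$-step,
  non-negative least-squares $\gamma$-step) with tolerance $10^{-8}$ on
  the objective decrease and at most 500 iterations, vectorized across
  variables. Because a single start can land in the wrong basin, the
  solver runs from three $\gamma$ initializations
  ($\{1, 1/4, 4\} \times \max_k |d_{kj}|$) and compares against the
  all-zero solution; the best objective wins. Only the product
  $\gamma_j \theta_{kj}$ is returned, so the scale ambiguity of the
  factorization is immaterial. The test suite holds the returned
  solutions to within $10^{-6}$ of a brute-force multi-start minimizer
  (`pergene_numeric_oracle()`) on more than a thousand random columns.
* **AUC.** For two classes the ranking statistic is
  $\delta_1 - \delta_2$ and the AUC is the Mann–Whitney rank statistic
  with half credit for ties, implemented directly so the test-side
  $O(n^2)$ pairwise oracle is an independent route.
* **FDR convention.** With zero active variables the variable-selection
  FDR is defined as 0.

## The simulation engine

`nsc_scenario()` parameterizes the Monte-Carlo designs used throughout:
multivariate Gaussian samples with unit variances and block-exchangeable
correlation — pairwise correlation $\rho$ within consecutive blocks of
`block_size` variables, independence across blocks — generated exactly as
$\sqrt{\rho}\, z_{\text{block}} + \sqrt{1-\rho}\, z_{\text{indep}}$.
Class $k$ adds its mean to the first `n_informative` variables, which
therefore share correlation blocks (the generator takes the contiguous
placement; whether informative variables should instead be scattered
across blocks is a design freedom the engine leaves to the caller via
`p`/`block_size`).

The two stock designs mirror the simulation study this package is built
around:

* `scenario_two_class()`: $n = 100$ training samples split $k_1$/$1-k_1$,
  $p = 10000$ variables in blocks of 100 with $\rho = 0.8$, class-2 mean
  $\mu_2$ on 100 informative variables, balanced test set of 1000.
* `scenario_three_class()`: $p = 5000$, $n = (100, 20, 100)$, class
  means $(+1, 0, -1)$ on 100 informative variables — the minority class
  nested between the outer classes — balanced test set of 1500.

Replicate $r$ draws under seed `base_seed + r`, so replicates are
independent and individually re-runnable; fold seeds derive from the same
base with a fixed offset. `run_experiment()` runs one CV path per method
per replicate and derives the fits for *both* selection criteria from it
— the two rules share grid and folds by construction, so this is exact
and halves the cost. `oversample_minority()` balances a two-class
training set by replicating randomly chosen minority samples, the
case-weighting surrogate whose failure mode (cross-validated minority
accuracy degenerating into a resubstitution estimate) the experiments
reproduce.

The package's own reproduction runs use 50 replicates of each design —
replicate means then carry standard errors around 0.01–0.03, comfortably
inside the reporting precision of the original 500-replicate study —
and `experiment_table()` reports SDs alongside every mean so smaller or
larger runs remain interpretable.

## What the generator does and does not emulate

The simulated data are exactly Gaussian with known, homogeneous
covariance, exactly unit variances and a clean informative/noise split.
Real expression data have heavy tails, batch structure, variance-mean
dependence and correlation that does not respect tidy blocks. Passing
the simulation checks therefore demonstrates that the estimators,
tuning rules and bias mechanisms behave as designed under the stated
model — not that any particular accuracy will transfer to a given real
data set. On real data the same interface applies
(`read_expression()` + `nsc_fit()`), typically with 5-fold CV.

## Known limitations

* Per-class thresholds, elastic-net/fused penalties, posterior class
  probabilities and bias-corrected discriminant scores are out of scope.
* The alternative overall-centroid definition
  $\bar x_j = \sum_k \bar x_{kj}/K$ (an unweighted class average) is not
  implemented: it trades the minority-shift bias for a worse
  majority-class bias under strong imbalance, and the available account
  of its modified $m_k$ is ambiguous.
* Multi-class AUC is not computed; the AUC column applies to two-class
  problems only.
* The AHP objective is biconvex; the multi-start alternating solver has
  matched a brute-force oracle on every random instance we have tested,
  but a global optimum certificate is not available in general.
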