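# gmnsc

Nearest shrunken centroid (NSC) classifiers for high-dimensional,
class-imbalanced data — PAM, ALP and AHP, plus their **GM** variants that
tune the shrinkage threshold by maximizing the cross-validated geometric
mean of the class-specific predictive accuracies (g-means) instead of
minimizing the overall error rate.

## Who this is for

Anyone building class predictors on variables-by-samples data where
p >> n and the classes are unequal — the typical gene-expression setting
(say 10,000 probes, 100 patients, a 90/10 class split). In that regime the
conventional NSC pipeline quietly assigns nearly every new sample to the
majority class: the overall CV error barely sees the minority class, so
error-minimizing tuning picks tiny thresholds, keeps thousands of noise
variables and inherits the majority-class bias of unshrunken
high-dimensional centroids.

## The method

All NSC classifiers shrink the standardized centroid differences

$$d_{kj} = \frac{\bar x_{kj} - \bar x_j}{m_k\,(s_j + s_0)}, \qquad
m_k = \sqrt{1/n_k - 1/n},$$

reconstruct shrunken centroids
$\bar x'_{kj} = \bar x_j + \hat d_{kj}\, m_k (s_j + s_0)$, and assign a
new sample to the class minimizing
$\delta_k(x^*) = \sum_j (x^*_j - \bar x'_{kj})^2/(s_j+s_0)^2 - 2\log\pi_k$
(equal priors by default; exact ties broken uniformly at random). The
penalties: **PAM** soft-thresholds every $d_{kj}$ uniformly; **ALP**
applies an adaptive $L_\infty$ penalty that clips each variable's
components at a common cap; **AHP** factorizes
$\tilde d_{kj} = \gamma_j\theta_{kj}$ and penalizes variable- and
class-level factors hierarchically.

The threshold is tuned on a grid of `T = 30` values from 0 to
$\lambda_{max}$ (complete shrinkage) by stratified 10-fold CV, either by

- `criterion = "min_error"` — the conventional rule (PAM / ALP / AHP), or
- `criterion = "max_gmeans"` — maximize
  $GM = (\prod_k PA_k)^{1/K}$ (GM-PAM / GM-ALP / GM-AHP),

then refit on the full training data. g-means weights every class
equally, so the GM rule resists the majority-class bias and, as a side
effect, selects far fewer noise variables. The package also ships the
block-exchangeable Gaussian simulation engine, evaluation metrics
(per-class accuracy, g-means, AUC, variable-selection FDR/FNR), minority
over-sampling, delimited-text I/O, a versioned model container and a CLI.

## Worked example

Simulate an imbalanced two-class training set (90/10 split, 2,000
block-correlated variables of which 100 carry a mean shift of 1), tune
PAM both ways, and evaluate on the independent balanced test set:

```r
library(gmnsc)

sc <- scenario_two_class(k1 = 0.9, mu2 = 1, p = 2000, n_informative = 100,
                         base_seed = 7)
gen <- generate(sc, 1)

fit_err <- nsc_fit(gen$train, method = "pam", criterion = "min_error",
                   fold_seed = 42)
fit_gm  <- nsc_fit(gen$train, method = "pam", criterion = "max_gmeans",
                   fold_seed = 42)
dplyr::bind_rows(glance(fit_err), glance(fit_gm))
#> # A tibble: 2 × 9
#>   classifier method criterion  lambda n_active cv_error cv_gmeans folds     T
#>   <chr>      <chr>  <chr>       <dbl>    <int>    <dbl>     <dbl> <int> <int>
#> 1 PAM        pam    min_error   0         2000     0.19     0.650    10    30
#> 2 GM-PAM     pam    max_gmeans  0.585      580     0.3      0.742    10    30

dplyr::bind_rows(
  nsc_evaluate(fit_err$model, gen$test, gen$truth_informative, rng_seed = 1),
  nsc_evaluate(fit_gm$model,  gen$test, gen$truth_informative, rng_seed = 1))
#> # A tibble: 2 × 10
#>    pa_1  pa_2 overall_pa gmeans   auc n_active n_active_informative
#>   <dbl> <dbl>      <dbl>  <dbl> <dbl>    <int>                <int>
#> 1 0.872 0.366      0.619  0.565 0.715     2000                  100
#> 2 0.726 0.694      0.71   0.710 0.770      580                  100
```

Error-rate tuning selects no shrinkage at all (λ\* = 0, all 2,000
variables active) and reads 87% accuracy on the majority class against
37% on the minority class. g-means tuning pays 11 points of overall CV
error for a threshold that drops 71% of the variables and nearly
equalizes the two classes (0.73 / 0.69), lifting test g-means from 0.57
to 0.71 and AUC from 0.72 to 0.77. `autoplot(fit_gm)` draws the CV
tuning path; `tidy(fit_gm)` returns it as a tibble.

Monte-Carlo experiments over many replicates are one call:

```r
ex <- run_experiment(scenario_two_class(k1 = 0.9, mu2 = 1, base_seed = 1),
                     methods = "pam", n_replicates = 50)
experiment_table(ex)       # means and SDs per classifier
write_experiment_tsv(ex, "results.tsv")
```

A command-line interface with `train` / `predict` / `evaluate` /
`simulate` subcommands lives at
`system.file("cli", "gmnsc.R", package = "gmnsc")`.

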