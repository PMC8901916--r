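# suddency

Suddency-domain analysis of positive-valued signals: the **Lehmer
transform**, a two-parameter **action potential distribution** with
maximum-likelihood fitting, a five-statistic **EEG channel featurizer**,
and replicated cross-validated **classification** — testable end to end on
a built-in synthetic cohort generator.

## The problem and the model

Frequency-domain EEG pipelines need artifact filtering, stationarity
assumptions and large storage. An alternative is to work in a domain of
*statistical moments*: for a strictly positive sample
`x = (x_1, …, x_n)` the Lehmer transform

    L(s) = Σ x_i^s / Σ x_i^(s-1)

is strictly increasing from `min(x)` (at `s = −∞`) to `max(x)` (at
`s = +∞`) and acts as a statistic-generating function — `s = 0, 1/2, 1, 2`
give the harmonic, geometric (n = 2), arithmetic and contra-harmonic means.
Inverting it maps every sample to its own *suddency moment* `s`, a
representation in which extreme events sit at large `|s|`.

On a signal rescaled so `L(−∞) = 1` and
`L(∞) = exp{W₀(αβ)/(αβ)}` (with `W₀` the principal Lambert-W branch), the
suddency moment is modelled by the action potential distribution

    f(s) = (C/α) (1 + αβ L(s)) e^{β L(s)} L(s)^{1/α − 1} L'(s),
    F(s) = A + B L(s)^{1/α} e^{β L(s)},   α ∈ (0,1], β > 0,

with Lambert-W-based normalization constants `A = −C e^β`, `B = C`.
Each EEG channel is fitted by maximum likelihood and summarised by five
statistics — three segment integrals of `f log f` split at the constrained
modes `m₁ ≤ 1 ≤ m₂`, plus the tails `F(m₁)` and `1 − F(m₂)` — giving
`5 × experiments × channels` (285) features per subject, which feed bagged
decision trees or Gaussian naive Bayes under stratified 10-fold
cross-validation repeated over seeded reshuffles.

## Worked example

```r
library(suddency)

lehmer_transform(c(1, 2, 3), c(0, 1, 2, Inf))
#> [1] 1.636364 2.000000 2.333333 3.000000

## fit the distribution to moments drawn from a known law
x <- apd_carrier_signal()
d <- apd_distribution(x, alpha = 0.6, beta = 2)
s <- apd_sample(d, 2000, seed = 1)
fit <- fit_apd(s, x)
print(fit)
#> Action potential distribution fit (maximum likelihood)
#>   alpha = 0.6268, beta = 1.9401
#>   log-likelihood -8325.7690 on 2000 observations
```

The fitted `(alpha, beta)` land near the generating values `(0.6, 2)`;
`summary(fit)` additionally reports the carrier's transform range and the
differential entropy of the fitted density.

```r
## a synthetic cohort, features, and cross-validated classification
coh <- generate_cohort(synthetic_config(n_per_class = 2, duration_s = 2,
                                        missing = 0, seed = 5))
cf <- channel_features(coh$subjects$MDD01$experiments$EC[, "Fp1"])
print(cf)
#> Channel features
#>   alpha = 0.4245, beta = 0.8739 (logLik -2008.9909)
#>   modes m1 = -0.8066, m2 = 1.0000
#>   segment integrals of f log f: -1.1813 | -0.3054 | -2.6971
#>   tails F(m1) = 0.3264, 1 - F(m2) = 0.5649
#>   differential entropy 4.1839 nats

ft <- assemble_features(coh, n_support = 64, max_obs = 256, maxit = 150)
r <- evaluate_cv("badt", ft$features, ft$labels, folds = 4, reps = 10, seed = 1)
print(r)
#> Bagged decision trees, 4-fold cross-validation over 10 replications (positive class: MDD)
#>   accuracy     1.000 (+/- 0.000)
#>   sensitivity  1.000 (+/- 0.000)
#>   specificity  1.000 (+/- 0.000)
```

The five statistics are the printed integrals `∫ f log f` (not negated);
`differential_entropy()` and the `entropy_heatmap()` scalp summaries apply
the conventional minus sign. The two planted classes — controls at
`(α, β) = (0.7, 1.0)`, depressed at `(0.5, 2.0)` — separate cleanly even in
this toy four-subject cohort.

See `vignettes/suddency-methods.Rmd` for the model's assumptions, the
numerical choices (log-space power sums, quadrature bounds from the
closed-form CDF, the inversion noise plateau), and what passing tests on
synthetic cohorts do and do not demonstrate about clinical recordings.

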