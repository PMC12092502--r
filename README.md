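# momentbf

Bayes factors for the workhorse tests of experimental research — one- and
two-sample t tests, multiple regression and ANOVA model comparisons, and
chi-squared / likelihood-ratio tests — under priors that are *focused on an
effect size the analyst names in advance*, instead of the default
scaled-Cauchy (JZS) prior whose single most likely value is the null effect.

Two prior families are implemented, alongside the Cauchy default:

- **Effect-size priors**: an equal-weight mixture of two scaled, shifted t
  distributions centered at −d_e and +d_e (prespecified Cohen's d), with
  recommended degrees of freedom ν = 3 and scale r = √((ν−2)/ν)·d_e, so the
  between-mode spread and within-component spread contribute equally to the
  prior variance ν/(ν−2)·r² + d_e².
- **Moment priors**: nonlocal priors proportional to d² times a scaled t
  density — exactly zero density at d = 0, modes exactly at ±d_e —
  with recommended ν = 5 (t tests) and ν = 5 + (q−1) when q coefficients
  are tested jointly.

Every Bayes factor here is a one-dimensional integral of a noncentral /
central density ratio against the prior on the standardized effect,

    B10 = ∫ f(t | ncp(ξ)) f(ξ) dξ / f(t | 0),

with noncentrality √N·d (one-sample t), √M·d with M = N₁N₂/N (two-sample
t), (N−p)·λ² (regression/ANOVA on q tested coefficients; the induced prior
on λ² involves the Gauss hypergeometric function ₂F₁), and N·w² (chi-squared
tests with a Gamma prior on Cohen's w²). The same identity powers a generic
test-statistic engine (`bf_teststat()`) for any test whose noncentral
sampling distribution is known, which is also how a significance test's
binary outcome converts to a Bayes factor of (1−β)/α.

These Bayes factors depend on the data only through the test statistic, are
scale invariant, satisfy predictive matching, are framing invariant (the
same hypothesis tested as a t test, ANOVA or regression comparison gives
the same number), and are consistent in information once N reaches a small
prior-dependent threshold (`consistency_threshold()`).

## Worked example

A memory experiment reports t(79) = 2.03 for one contrast. Under the wide
default prior the data favor the null; a researcher expecting a small
effect (d_e = 0.2) reaches the opposite conclusion:

```r
library(momentbf)
bf_ttest(2.03, one_sample(80), cauchy_prior(1))
#> Bayes factor (ttest)
#>   B10       = 0.642076
#>   B01       = 1.55745
#>   log10 B10 = -0.192413
#>   abs. error estimate = 7.53e-12
bf_ttest(2.03, one_sample(80), es_prior(0.2))$b10       # 2.523161
bf_ttest(2.03, one_sample(80), moment_prior(0.8))$b10   # 0.19222
```

A regression model comparison from partial R² (N = 175 skulls, full model
vs the reduced model keeping 3 of 5 coefficients, q = 2 tested), focused on
a large effect (f² = 0.35): `b01` is the preference for the reduced model.

```r
bf_linear(linear_layout(175, p = 3, q = 2),
          lambda2_es_prior(2, effect_size = sqrt(0.35)),
          r2p = 0.0136)$b01                             # 41.24762
```

A likelihood-ratio test G² = 12.72 on 5 df from N = 100 observations, with
the Gamma prior on w² focused on a medium effect w_e = 0.3:

```r
fam <- stat_family("chisq", df = 5, effect_map = function(w2) 100 * w2)
bf_teststat(12.72, fam, wsq_gamma_prior(0.3))$b10       # 5.13966
```

The same analyses from a shell:

```sh
exec/momentbf ttest --t 2.03 --n 80 --prior es --effect-size 0.2
exec/momentbf linear --r2p 0.0136 --n 175 --p 3 --q 2 --prior es --cohen-f2 0.35 --json
exec/momentbf chisq --stat 12.72 --df 5 --n 100 --we 0.3
```

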