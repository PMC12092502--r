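---
title: "Effect-size and moment priors for Bayes factors: models, defaults, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size and moment priors for Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentbf)
```

## The model

All tests covered here share one structure. Data are normal with a vague
Jeffreys prior on the variance (and flat priors on any nuisance location
parameters), the null model pins the standardized effect at zero, and the
alternative model places a proper prior on the standardized effect. Under
these assumptions the Bayes factor collapses to a one-dimensional integral
that depends on the data only through the test statistic:

$$B_{10} \;=\; \frac{\int f(t \mid \mathrm{ncp}(\xi))\, f(\xi)\, d\xi}
                    {f(t \mid 0)},$$

where $f(t \mid \cdot)$ is the noncentral sampling density of the statistic
and $\mathrm{ncp}(\xi)$ maps the standardized effect to the noncentrality
parameter: $\sqrt{N}d$ for a one-sample t test, $\sqrt{M}d$ with
$M = N_1N_2/N$ for a two-sample t test, $(N-p)\lambda^2$ for a
regression/ANOVA comparison testing $q$ coefficients against a reduced
model with $p$ retained coefficients, and $Nw^2$ for chi-squared tests.
`bf_ttest()`, `bf_linear()` and the generic `bf_teststat()` all evaluate
exactly this integral; the t-family special case of `bf_teststat()` is
bit-for-bit the same computation as `bf_ttest()`.

Three priors on the standardized effect are provided.

* `cauchy_prior(r)` — the scaled-Cauchy (JZS) default. Its mode is the
  null value and its tails are heavy: with $r = 1$, 10.5% of the prior mass
  lies on absolute effects larger than 6.
* `es_prior(d_e, nu, r)` — an equal-weight mixture of two scaled t
  distributions centered at $\pm d_e$. Symmetric, bimodal, integrates to 1,
  and with $\nu > 2$ has total variance
  $\frac{\nu}{\nu-2}r^2 + d_e^2$: the first term is within-component
  spread, the second the spread between the two modes. Setting
  $d_e = 0$, $\nu = 1$ recovers the Cauchy default exactly, which the test
  suite asserts pointwise to 1e-12 and through the Bayes-factor path to
  1e-10.
* `moment_prior(d_e, nu)` — a nonlocal prior: the scaled t density
  multiplied by $d^2$ and renormalized. Its density is exactly zero at the
  null and its modes sit exactly at $\pm d_e$ once the component scale is
  fixed at $c = \sqrt{(\nu-1)d_e^2/(2\nu)}$. (With scale $c$ the mode of
  $d^2 f_t(d \mid \nu, 0, c)$ satisfies $d^2 = 2\nu c^2/(\nu-1)$, which
  equals $d_e^2$; the same identity normalizes the density, since the
  second moment of the t kernel is $\frac{\nu}{\nu-2}c^2$.)

For regression/ANOVA the multivariate analogues induce priors on the
squared multivariate effect $\lambda^2$ (`lambda2_es_prior()`,
`lambda2_moment_prior()`). The effect-size variant's density involves the
Gauss hypergeometric function
$_2F_1\!\big(\frac{\nu+q}{4}, \frac{2+\nu+q}{4}; \frac{q}{2}; z\big)$ with
$z = 4f^2\lambda^2/(\lambda^2+f^2+\nu r^2)^2 \in [0,1)$; the moment
variant reduces, after rescaling, to a beta-prime (scaled F) distribution
that normalizes exactly — the suite checks the quadrature against 1 to
1e-8.

## Tunable parameters and their defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `d_e`, `f`, `w_e` | targeted effect size (Cohen's d / f / w, unitless) | user-chosen; labels small/medium/large map to d: 0.2/0.5/0.8, f: 0.10/0.25/0.40, f²: 0.02/0.15/0.35, w: 0.10/0.30/0.50 | the conventional benchmarks for each statistic family |
| `nu` (effect-size) | t-component degrees of freedom | 3 | tames the Cauchy tails while keeping rare large effects possible; ν = 4 changes results marginally |
| `r` (effect-size) | component scale | $\sqrt{(\nu-2)/\nu}\,d_e$; $\sqrt{(\nu-2)/(\nu q)}\,f$ for linear comparisons | equalizes the two variance contributions, so prior resolution tracks the targeted effect |
| `nu` (moment) | t-kernel degrees of freedom | 5; `5 + (q - 1)` for q tested coefficients | the quadratic weight thickens tails as q grows; raising ν with q keeps tail mass low. Beyond q = 20 a warning suggests raising ν further |
| `shape`, `rate` (w² Gamma) | Gamma prior on w² | shape 6.6, rate $(2\cdot\mathrm{shape}-1)/(2w_e^2)$ | the induced density of w is then unimodal with mode exactly $w_e$ (squared mode $=(2s-1)/(2\,\mathrm{rate})$) and, at shape 6.6, standard deviation ≈ 0.2 w_e |

On the w² rate: a shape–rate Gamma with rate $(2s-1)/w_e^2$ — i.e. without
the factor 2 — puts the induced mode of $w$ at $w_e/\sqrt 2$ and its
standard deviation near $0.14\,w_e$, so it is *not* focused on $w_e$; the
factor-2 calibration is the one that reproduces both the intended focus and
the reference worked example ($G^2 = 12.72$, df 5, $N = 100$,
$w_e = 0.3 \Rightarrow B_{10} = 5.14$). Any other calibration can be
supplied through the `rate` argument.

A caveat on two often-quoted masses of the recommended effect-size prior:
with $\nu = 3$ and $r = \sqrt{1/3}\,d_e$ the exact t-mixture places 48.0%
of its mass in $[-d_e, d_e]$ and 90.2% in $[-2d_e, 2d_e]$. The rounder
figures of 50% and 96% sometimes associated with this calibration are the
values of the *normal* ($\nu \to \infty$) limit of the mixture at the same
scale; the heavy t(3) tails shave several points off the central mass.
`interval_mass()` reports the exact values.

## Numerical strategy

The integrand — density ratio times prior — is evaluated in log space
(`log_density_ratio()`), so ratios for extreme statistics neither overflow
nor underflow. Before adaptive quadrature the log integrand is probed on a
grid; the integration range is truncated where it falls 45 log-units below
its peak, and the integrand is rescaled by the peak so relative tolerances
stay meaningful whether $B_{10}$ is $10^{-2}$ or $10^{80}$. The truncated
range is split at the prior modes ($\pm d_e$, or the $\lambda^2$ mode) and
at the effect size implied by the observed statistic, so each panel is
unimodal; panels run through `stats::integrate` (adaptive Gauss–Kronrod) at
relative tolerance 1e-9, with recursive bisection when a steeply decaying
panel defeats the extrapolation. R's noncentral t density is numerically
noisy many tens of log-units below the mode; panels that remain
unconvergeable at depth 8 contribute their estimate and their error bound
to the reported `abs_error_estimate`, which in default configurations stays
below 1e-6 relative to $B_{10}$.

The $\lambda^2$ prior on $(0,\infty)$ keeps its integrable
$\lambda^{q-2}$ singularity at the origin inside the quadrature (the lower
truncation point is pinned at 0). ₂F₁ is evaluated by the power series for
$z \le 0.8$ and by the Euler transformation
$(1-z)^{c-a-b}\,{}_2F_1(c-a, c-b; c; z)$ beyond — for this family
$a+b-c = (\nu+1)/2 > 0$, so the transformed series converges even at
$z = 1$; reference values frozen from an arbitrary-precision evaluation
pin the implementation to 1e-12. With the recommended scale,
$z \le q/(q+\nu-2)$, comfortably inside the stable regime for any
realistic q.

Degenerate inputs are rejected up front: non-finite t, $N$ below
estimability, $N \le p + q$ (uninformative F), partial $R^2 = 1$. $t = 0$
is valid. A sample size below the consistency-in-information threshold
(`consistency_threshold()`: $1+\nu$ / $2+\nu$ / $p+q+\nu$ for effect-size
priors, $\nu-1$ / $\nu$ / $p+q+\nu-2$ for moment priors) attaches a note to
the result rather than failing — the Bayes factor is well defined there,
it just stays bounded as the statistic grows.

## Design evaluation and the synthetic-data generator

`significance_outcome_bf()` converts the bare outcome of a Neyman–Pearson
test into a Bayes factor ($(1-\beta)/\alpha$ for a significant result —
16 at $\alpha = .05$, power .80 — and $\beta/(1-\alpha)$ otherwise, or the
prior-averaged power when a power function and an effect prior are given).
`t_for_target_bf()` inverts the Bayes-factor curve on $t \ge 0$ by
bracketing and root refinement. `expected_bf_ratio()` computes
$E[\mathrm{BF}_a/\mathrm{BF}_b]$ against the noncentral-t sampling
distribution of the statistic at a chosen true effect; the expectation of
the ratio (arithmetic convention) is the default and a geometric-mean
variant (`average = "geometric"`) is exposed, since either convention is
defensible for summarizing ratio curves.

`simulate_fixture()` generates raw normal data for one-sample, two-sample
and general linear designs, computes t or F (plus partial $R^2$ and partial
$\eta^2$) by ordinary least squares, and records the true effect on the
relevant scale — for linear designs
$f^2 = \mu^t \Omega \mu$ with $\mu = \beta_2/\sigma$ and
$\Omega = X_2^t(I - X_1(X_1^tX_1)^{-1}X_1^t)X_2/(N-p)$. It emulates
exactly the sampling model the Bayes factors assume: independent
homoscedastic normal errors and fixed design matrices. Real data violate
these assumptions in ways the generator does not represent (skew, outliers,
heteroscedasticity, dependent observations), so passing tests certify the
computation of the Bayes factors, not their robustness to model
misspecification. Sampling uses a single root seed with deterministic
reproduction, so every stochastic test and the command-line `fixture`
subcommand are exactly repeatable.

Tests exercise the suite at deliberately modest problem sizes — Monte-Carlo
oracles with $10^6$ prior draws for each Bayes-factor path, a
2,000-replicate simulation oracle for the expected-ratio curves, and a
$10^4$-replicate uniformity check of null p values — chosen so the full
suite completes in a few minutes while leaving the 3-standard-error
acceptance bands narrow enough to catch real defects.

## Design choices made here

* **Direction of reporting.** All functions return $B_{10}$ (alternative
  over null) together with $B_{01} = 1/B_{10}$; published tables sometimes
  print the preference for the *reduced* model, so the print method and the
  CLI always show both.
* **Conversions as first-class operations.** `F_from_r2p()`,
  `eta2p_from_F()` and friends implement the one-to-one maps between F,
  partial $R^2$ and partial $\eta^2$; `convert_effect_size()` implements
  $f = d$ (one-sample framings) and $d = \sqrt{(N-1)/M}\,f$ (two-sample vs
  linear framings), which is what makes the framing-invariance identities
  testable to 1e-6.
* **Closed-form prior CDFs.** The t-mixture CDF is a sum of two shifted
  `pt()` calls; the moment-prior CDF uses the exact representation of the
  $d^2$-weighted t kernel as a scaled $F(3, \nu-2)$ variable, and the
  $\lambda^2$ moment prior a scaled $F(q+2, \nu-2)$. Quadrature of the
  densities is kept in the tests as an independent cross-check.
* **Construction-based sampler for the $\lambda^2$ effect-size prior.**
  Draws come from the defining construction (multivariate t noise around a
  uniform point on the Cohen's-f sphere, squared norm taken), not from the
  hypergeometric density — so sampler and density check each other.

## Known limitations

* Random-factor and mixed ANOVA designs are out of scope; comparisons are
  fixed-design full-vs-reduced model contrasts.
* The chi-squared path relies on the asymptotic noncentral chi-squared
  distribution of $G^2$/$\chi^2$; no small-sample correction is applied.
* Priors here are symmetric and focused; asymmetric or otherwise custom
  priors can be used through `bf_teststat()`'s plain-function interface,
  which checks their normalization but not their tail behaviour.
* Posterior model probabilities, prior odds bookkeeping and raw-data
  posterior sampling are not provided — the package computes Bayes
  factors.
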