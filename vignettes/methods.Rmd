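---
title: "Multilevel multivariate normative comparisons: model, estimation and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel multivariate normative comparisons: model, estimation and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnormcomp)
```

## The problem

A normative comparison asks whether one person's profile of
neuropsychological test scores deviates from healthy norms. Comparing
the whole profile at once — a multivariate comparison — is more
sensitive than testing each score separately and needs no multiplicity
correction, but it requires *multivariate* normative data: the
covariance among all tests in healthy controls. Single studies rarely
administer enough tests to many enough participants, so the natural
source is an aggregated database pooling the healthy control groups of
many published studies. Pooling creates three problems this package
addresses jointly: scores are nested in studies that differ
systematically; every study administers only a subset of the tests; and
patients must be compared to controls of similar age, gender and
education.

## The model

Let $y_{msi}$ be the score of participant $i$ in study $s$ on test
$m = 1, \dots, p$. The three-level model is

$$
y_{msi} = \gamma_{0m}
  + \gamma_{1m}\,\mathrm{age}_{si}
  + \gamma_{2m}\,\mathrm{gender}_{si}
  + \gamma_{3m}\,\mathrm{education}_{si}
  + \nu_{ms} + \epsilon_{msi},
$$

with, independently,

* $\boldsymbol\epsilon_{si} \sim N_p(\mathbf 0, \boldsymbol\Sigma_w)$:
  participant-level residual vectors with an **unstructured** $p \times p$
  within-study covariance — the object the multivariate comparison needs;
* $\nu_{ms} \sim N(0, \sigma^2_{b,m})$: a study-level intercept deviation
  per test, independent across tests (**diagonal** between-study
  covariance) and across studies.

Covariates are centered at participant-level norm-group means
(`center_covariates()`); gender is a ±1 contrast. Because $\nu_{ms}$ is
shared by all of study $s$'s scores on test $m$, any two scores on the
same test in the same study covary by $\sigma^2_{b,m}$, and two scores
of the same participant covary by the corresponding element of
$\boldsymbol\Sigma_w$.

## Estimation: FIML with missingness by design

Studies choose which tests to administer before seeing any scores, so
the missingness does not depend on unobserved values and is ignorable:
maximizing the likelihood of the observed scores alone is valid. Each
study contributes the multivariate normal density of its stacked score
vector restricted to its administered test set $S$. The within-study
covariance between tests $m$ and $m'$ is estimable iff some study
administered both; `pair_coverage()` checks this and `fit_fiml()`
refuses unidentified data, naming the uncovered pairs.

Computationally, when all participants of a study share one test set
(the rule under planned missingness), the study's density factorizes
into $n - 1$ independent contrast vectors with covariance
$\mathbf W_S = \boldsymbol\Sigma_w[S, S]$ and one mean vector with
covariance $\mathbf W_S + n \operatorname{diag}(\sigma^2_b)[S]$. This
reduces a $1500 \times 1500$-dimensional density to a handful of
$|S| \times |S|$ factorizations per study and makes one fit at the
reference scale (10 tests, 30 studies of 50) take ~20 ms — which is
what makes 1000-replicate Monte Carlo studies routine. The fixed
effects are profiled out exactly by generalized least squares at every
covariance evaluation, and the covariance parameters are optimized by
L-BFGS-B with analytic gradients on an unconstrained scale:
log-Cholesky for $\boldsymbol\Sigma_w$, log for $\sigma^2_b$. The
likelihood and gradient are implemented in C++ (RcppArmadillo) from
per-study sufficient statistics; a slower dense-assembly path handles
participants with heterogeneous test sets. Convergence uses a relative
log-likelihood tolerance ($10^{-8}$) with up to three jittered restarts;
starting values are per-test least squares, the pooled within-study
centered residual covariance (eigenvalue-repaired to positive definite),
and the between-study variance of study mean residuals.

The evaluator was verified against an independent brute-force dense
multivariate-normal oracle (tolerance $10^{-8}$) and, on a
representative model, reproduces `nlme::lme`'s maximum-likelihood
log-likelihood and parameters exactly; `nlme` is used only as a
cross-check in the test suite, never as the implementation.

## The normative comparison

A new patient with scores $\mathbf x$ and (centered) covariates is
compared against the covariate-matched prediction
$\hat{\mathbf y} = \boldsymbol\Gamma (1, \text{age}, \text{gender},
\text{educ})'$ in the metric of the **combined** covariance
$\mathbf C = \boldsymbol\Sigma_w + \operatorname{diag}(\sigma^2_b)$ —
a patient is not a member of any norm study, so the study-level
variability is part of their reference variance. The adapted Hotelling
statistic is

$$
T^2 = \frac{n}{n+1} \cdot \frac{n-p}{(n-1)\,p}\,
      (\hat{\mathbf y} - \mathbf x)' \mathbf C^{-1}
      (\hat{\mathbf y} - \mathbf x)
      \;\sim\; F(p,\ \mathrm{df}_2),
$$

with $n$ the number of norm participants and, instead of the classical
$n - p$ denominator (inappropriate under nesting and missingness),

$$
\mathrm{df}_2 = N_{\text{obs}} - (K + q + 1),
$$

where $N_{\text{obs}}$ counts scores, $K$ studies and $q = 4p$ estimated
fixed effects. At the reference scale this is
$15000 - 71 = 14929$ (complete data) or $8929$ (40% missing) — so large
that the F is effectively a scaled $\chi^2$, but the convention is kept
throughout, including for the univariate t comparisons below.

Clinicians care only about *worse-than-normal* profiles, so the decision
is one-sided with two criteria: declare a deviation iff the sum of
standardized deviations $\sum_m (x_m - \hat y_m)/\sqrt{C_{mm}}$ is
negative **and** the two-sided p-value is at most $0.10$. Under the
null the two criteria are nearly independent, giving an effective level
of $0.05$. Per-test univariate comparisons use the normative t
$t_m = (x_m - \hat y_m)/\sqrt{C_{mm}(n+1)/n}$ with the same
$\mathrm{df}_2$, one-sided at $\alpha = 0.05$ uncorrected and at
$\alpha/p$ Bonferroni-corrected.

## The simulation engine

`sim_config()` defaults encode the reference condition: $p = 10$ tests,
$K = 30$ studies of $n = 50$, intercepts 20, effects $-0.125$ (age),
$0.5$ (gender), $1.25$ (education), within variance 25 with
equicorrelation 0.4, between variance 5 (intraclass correlation
$5/30 \approx 0.167$). Missingness is a deterministic greedy
pair-covering design: every study administers exactly
$p(1-\text{fraction})$ tests, chosen to cover all pairs and then to
balance test usage, so the missing fraction is exact and
$\boldsymbol\Sigma_w$ stays estimable up to 70% missingness (and 60% at
$p = 5$). Each Monte Carlo replicate simulates a database, fits it by
FIML, simulates one patient from the same population and applies all
decision rules; replicate seeds derive deterministically from the master
seed, so results are reproducible and independent of the number of
worker processes. A simulated "deviating" patient has
$2\sqrt{\sigma^2_w + \sigma^2_b} = 2\sqrt{30} \approx 10.95$ points
subtracted from the first `n_deviations` test scores.

## Conventions on points the method leaves open

Several details are not fixed by the general theory; the package's
choices, used consistently in code, tests and simulations:

* **Numerator df and dimension.** $\mathrm{df}_1 = p$, the number of
  tests, regardless of missingness in the norm data (the patient is
  complete on the modeled tests; patients with fewer tests should be
  compared under a model refit to that subset).
* **$n$ in the small-sample factors** is the total number of norm
  participants across studies.
* **Standardization of the summed deviation** uses the combined
  standard deviations $\sqrt{C_{mm}}$ without the $(n+1)/n$ inflation;
  the inflation factor enters the univariate t denominators.
* **Neglected between-study variance** (`estimate_between = FALSE`,
  used to quantify the cost of ignoring nesting) fixes $\sigma^2_b = 0$
  both in fitting and in $\mathbf C$, and keeps the same
  $\mathrm{df}_2$ formula; at $\mathrm{df}_2 \approx 15000$ the
  alternative (not subtracting $K$) is numerically indistinguishable.
* **Patient covariates in simulations** are drawn from the norm
  population (age $\sim N(0, 15^2)$, gender ±1, education
  $\sim N(0, 1.5^2)$), so covariate-prediction error is part of the
  simulated error rates; `patient_covariates = "average"` fixes them at
  the centered means instead.

## Calibration and two measured properties

Two honest measurement notes, established with the verified evaluator
(see the test suite) and *not* adjusted for:

* **Finite-sample behavior of the FPR.** At the reference condition the
  one-sided multivariate false-positive rate measures ≈ 0.06 over 1000
  replicates against the nominal 0.05: with only $K = 30$ studies the
  estimated $\mathbf C$ is noisy and fixed-effect uncertainty is not
  captured by the $(n+1)/n$ factor. Missingness adds to this
  (≈ 0.06 at 40%, ≈ 0.10–0.12 at 70%), which is the method's own
  documented behavior, not an implementation artifact.
* **ML bias of the between-study variance.** Maximum likelihood
  underestimates $\sigma^2_b$ by $O(1/K)$ — about $-0.2$ on a true
  value of 5 at $K = 30$. All other generating parameters are recovered
  without measurable bias.
* **Sensitivity is not monotone to the end.** Sensitivity rises with
  the number of truly deviating tests up to 5 of 10 (≈ 0.05, 0.24,
  0.52, 0.91 for 0, 1, 2, 5 deviations of 2 SD) but dips at 9
  (≈ 0.80): under equicorrelation a deviation on almost all tests
  approaches a uniform profile shift, which lies in the high-variance
  common direction of $\mathbf C$. With
  $\mathbf C = 20\mathbf I + 10\mathbf J$ the Mahalanobis noncentrality
  of a uniform shift of size $s$ on $k$ tests is
  $(s^2/20)(k - k^2/12)$: 17.5 at $k = 5$ but 13.5 at $k = 9$. This is
  a real property of profile-shape statistics, worth knowing when a
  patient is globally, uniformly impaired — the summed-deviation
  criterion and univariate comparisons remain sensitive in that case.

## Problem sizes

The blocked FIML path is comfortable up to tens of tests and hundreds
of studies (cost per evaluation is roughly
$K\,|S|^3 + (pc)^3$ for $c = 4$ covariate columns; at $p = 20$,
$K = 30$ a fit takes well under a second). The dense path for
heterogeneous test sets scales with the cube of scores per study and is
intended for small databases. `adjusted_df()` errors when
$\mathrm{df}_2 \le p$, which bounds how little data the comparison
tolerates.
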