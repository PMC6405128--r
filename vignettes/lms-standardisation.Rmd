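---
title: "Age-conditional norms with the weighted LMS method"
author: "lmsnorms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-conditional norms with the weighted LMS method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmsnorms)
```

## The model

Many developmental test scores are bounded, skewed, and strongly
age-dependent: the raw score of a five-year-old cannot be read against the
distribution of an eight-year-old. The LMS model summarises the
age-conditional distribution of a positive score $y$ at age $t$ by three
smooth curves: a Box-Cox power $L(t)$ capturing skewness, the median
$M(t)$, and the generalised coefficient of variation $S(t)$. The
standardised score is

$$
z = \frac{(y/M(t))^{L(t)} - 1}{L(t)\,S(t)}, \qquad
z = \frac{\log(y/M(t))}{S(t)} \;\; \text{when } L(t) = 0,
$$

and is assumed standard normal at every age. Inverting the transform gives
the centile curve at lower tail area $a$:

$$
C_a(t) = M(t)\bigl(1 + L(t) S(t) z_a\bigr)^{1/L(t)},
$$

with $z_a$ the normal quantile at $a$. Because all centiles are monotone
functions of the same three curves, they can never cross at any age. The
model corrects skewness but not kurtosis; heavily leptokurtic measures
will get unreliable extreme centiles and need a different family.

Instruments whose range includes zero (a screening checklist where most
children have no reported difficulties) violate the positivity requirement
of the power transform; a constant offset — conventionally $+1$ — is added
before transformation and recorded in every fitted object and serialized
calculator, so charts and z-scores are always reported back on the
instrument's own scale.

## Estimation

`fit_lms()` maximises the penalized (optionally weighted) log-likelihood

$$
\sum_i \omega_i \,\ell_i \;-\; \tfrac12 \sum_{c \in \{L,M,S\}} \lambda_c
\int c''(t)^2 \, dt ,
\qquad
\ell_i = L_i \log (y_i/M_i) - \log S_i - z_i^2/2 ,
$$

by cyclic Fisher-scoring updates of the three curves (the backfitting
scheme introduced for this model by Cole and Green, in the
diagonal-information form later popularised by the GAMLSS RS algorithm).
Each cycle smooths a working response for one curve with a weighted cubic
smoothing spline whose penalty $\lambda_c$ is solved — on the trace of the
smoother matrix — so that the realised equivalent degrees of freedom (EDF)
match the request. The expected-information weights are
$(1 + 2L^2S^2)/S^2$ for $\log M$, $2$ for $\log S$ and $7S^2/4$ for $L$.

EDF semantics follow the standard convention: for $M$ and $S$, 1 fits a
constant, 2 a linear trend, above 2 a cubic smoothing spline (non-integer
requests are honoured); for $L$, 0 fixes $L \equiv 1$ (no skewness
correction) and 1 estimates a single constant power. $M$ and $S$ are
modelled on the log scale, so positivity is structural and an "EDF 2"
median is linear in $\log M$ — over realistic score ranges the difference
from a natural-scale line is a fraction of a percent, far below the
recovery tolerances we test. $L$ is kept on the natural scale, bounded to
$[-5, 5]$.

Numerical choices, all fixed in `lms_control()` or module constants:

* the $L \approx 0$ branch switch sits at $|L| \le 10^{-8}$, where the
  continuity error of the log branch, of order $L \log^2(y/M)$, is
  negligible;
* outer convergence is declared when the penalized deviance changes by
  less than $10^{-4}$ between full cycles (at most 200 cycles);
  the stopping rule is evaluated with weights normalised to mean one, so
  fitted curves are *exactly* invariant to rescaling all sampling weights,
  while the reported deviance keeps the raw weights and scales with them;
* spline knots sit at the distinct observed ages up to a cap of 50,
  quantile-thinned beyond it;
* non-convergence is an explicit flag on the returned fit, never an error
  and never a silent success — more complex models are best warm-started
  from a simpler converged fit (`start =`), which is also what the
  sequential search does;
* repeated assessments of one child are treated as independent
  cross-sectional records; the child identifier is bookkeeping only.

The criteria reported are global deviance $-2\sum \omega_i \ell_i$,
AIC $= \text{dev} + 2k$, SBC $= \text{dev} + k\log n$ and GAIC(3)
$= \text{dev} + 3k$, with $k$ the *requested* EDF sum and $n$ the number
of observations (not the sum of weights — weights here are calibration
devices, and criterion *differences*, which drive selection, are
unaffected by this bookkeeping choice up to an additive constant).

## Choosing the EDFs

`sequential_search()` starts at $a_L = 0, a_M = 1, a_S = 1$ and increments
one curve at a time, by default median first, then variation, then
skewness. A step is accepted only if the criterion (SBC by default, the
most stringent together with GAIC(3)) improves by more than 2. A rejected
curve is frozen; a non-converged candidate is skipped and retried after
another curve has moved, which reproduces the practical experience that
some models only converge once a neighbouring curve has been freed. Caps
default to 2 per curve for single-wave data over a short age span and
should be raised to 4 for pooled two-wave data; the caps exist to keep
out-of-sample behaviour sensible, not to optimise in-sample fit. The full
trace — accepted, rejected and failed steps — is kept and printable as the
usual sequential-optimisation table.

## Weights for two-phase designs

In a two-phase survey everyone is screened cheaply and a stratified
subsample — deliberately enriched for high-risk children — is assessed
intensively. Unweighted curves fitted to such a subsample describe the
wrong population. `two_step_weights()` reconstructs the reference
population by inverse probability weighting:

1. a logistic model for *invitation* on the design covariates (risk
   stratum, school screening count), fitted to the whole screened sample;
2. a logistic model for *complete data* among the invited, with backward
   elimination over candidate covariates (drop the least significant while
   its Wald p-value exceeds 0.05, refitting after each drop; an empty
   retained set is valid);
3. the final weight is $1/(p_1 p_2)$.

Probability products below $10^{-4}$ trigger a warning (optional
truncation, off by default, because truncation trades variance for bias).
Perfect separation falls back to a lightly ridged ($10^{-6}$) IRLS refit
and, failing that, errors with an instruction to collapse strata. Children
included with certainty by design (e.g. those with no phrase speech) are a
stratum with $p_1 = 1$.

## The synthetic cohort

The generator provides ground truth for every stage. `screen_truth()`
emulates a 0–39 teacher screen (higher = worse) on ages 57–70 months:
median falling from about 11 to about 4 while the 97th centile falls only
from about 40 to about 36 — so the skewness power falls and the
coefficient of variation rises roughly linearly with age — with 15% floor
mass producing the characteristic mode at zero, and the $+1$ shift.
`vocab_truth()` emulates a 0–190 vocabulary test across two assessment
waves (ages 61–82 and 85–111 months) with linearly rising median
(74.5 to 91.3 at the wave midpoints), falling coefficient of variation
(0.212 to 0.171) and constant mild skew; second-wave retention defaults
to 95%. `design_config()` defaults encode the two-phase design: sampling
fractions 0.405/0.375 (high-risk boys/girls) and 0.043/0.042 (low-risk),
48 forced inclusions, and a logistic complete-data response on deprivation
and free-school-meals status tuned to about 83% completeness among the
selected. The risk threshold (screen score $\ge 20$) was calibrated once
against the generator's own score distribution so that a screened
population of 6,459 yields about 636 selected children in expectation,
matching the design the defaults emulate.

Mechanics worth knowing: standard-normal draws are truncated to the
support of the local Box-Cox transform (the model family is a truncated
Box-Cox normal; the clipped tail lands on the instrument floor or
ceiling); scores are rounded to integers and clamped to the instrument
bounds by default, with `round = FALSE` available for transform-level
checks; floor mass is injected by remapping the lowest quantile of the
latent z to the minimum score. One integer seed drives a named substream
per operation, so stages can be regenerated independently.

What the generator does *not* emulate: item-level responses or
discontinuation rules, clustering of outcomes within schools, or
demographically realistic covariate distributions (covariates are simple
Bernoulli/Gaussian draws — their role is to carry statistical structure
for the response model and the elimination procedure). Passing tests
therefore demonstrate correctness of the machinery under the stated
distributional conditions, not robustness to every pathology of real
cohort data; in particular a large floor mode is, by construction,
impossible to normalise fully, and the Q-test will say so.

## Charts, calculator, diagnostics

`build_centile_table()` tabulates $C_a(t)$ at the seven conventional
levels (3, 10, 25, 50, 75, 90, 97); cells outside the transform's support
become `NA` with an attached error table, never silent `NaN`.
`as_lms_model()` freezes a fit onto a dense monthly grid at 15 significant
digits — the precision its JSON serialization carries — so a reloaded
calculator scores bit-identically; scoring interpolates the grid linearly,
a difference from direct spline evaluation far below reporting precision.
The calculator refuses ages outside the normed domain rather than
extrapolating or clamping: out-of-support and out-of-domain requests are
errors by design, because silently clamped extreme centiles are wrong
centiles. Percent-style level inputs are accepted at the command-line
layer only; everywhere else levels are lower tail areas in $(0,1)$.
z-scores print to 3 decimals and centiles to 1 at the CLI; machine outputs
keep full precision.

`q_test()` checks standard-normality of the model's z-scores within age
bins: per bin, standardized statistics for mean 0 (exact), variance 1
(Wilson–Hilferty transform of the chi-square) and zero skewness
(moment-ratio with its exact small-sample standard error), combined as a
chi-square on $3 \times \text{bins}$ degrees of freedom. The combination
is a convention choice — the diagnostic is usually presented as a plot —
and its null calibration is itself tested. Weighted variants use weighted
moments with the effective sample size $(\sum w)^2 / \sum w^2$.

`compare_weighted_unweighted()` runs the design demonstration: z-scores of
a shared evaluation set under a full-population fit, a weighted subsample
fit and an unweighted subsample fit, with Kolmogorov–Smirnov and
1-Wasserstein distances of the two subsample fits from the population fit
plus a density grid for plotting.

## Problem sizes and verification

The test-suite checks run at sizes chosen to make Monte-Carlo noise small
relative to the tolerances they assert: transform inversion over 1,000
random parameter draws (relative error $10^{-10}$); centile non-crossing
over 100 random curve sets; coverage of the 3rd/50th/97th centile curves
from 100,000 draws within three binomial standard errors; median-curve
recovery within 5% from 5,000 records at the generating EDFs; complexity
recovery over 50 seeded selection replicates; the weighting demonstration
over 25 replicates of a 6,459-child screened population; Q-test null
calibration over 200 replicates. `scripts/acceptance.R` recomputes the
same quantities from scratch at a single command-line seed.

## Known limitations

* No kurtosis adjustment; measures with heavy tails after the power
  transform need a four-parameter family.
* The penalized-deviance bookkeeping (the penalty term added to the
  reported deviance) follows this package's internal scaling; it can
  differ from other LMS software by an additive constant, which cancels in
  the criterion differences used for selection.
* Group-specific norms (e.g. by sex) are obtained by filtering upstream
  and fitting per group; there is no simultaneous multi-group fit.
* Weight estimation assumes the response model is correctly specified up
  to its candidate set; no calibration/raking or imputation is provided.
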