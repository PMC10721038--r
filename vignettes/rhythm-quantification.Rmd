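---
title: "Quantifying rhythmicity by effect size: models and methods"
author: "rhythmeb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rhythmicity by effect size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmeb)
```

## Why effect sizes

Most genome-scale rhythmicity methods test the null hypothesis that a feature
is arrhythmic and rank features by p-value. A p-value confounds the size of a
rhythm with the precision of its estimate: a tiny but well-measured
oscillation can out-rank a large, biologically consequential one. rhythmeb
instead estimates the rhythm itself — the fitted periodic curve and summary
statistics such as peak-to-trough amplitude — together with the uncertainty of
those estimates, so that features can be prioritised by how strongly they
cycle rather than by how confidently one can reject a null that is rarely
true anyway.

## The model

For feature $g$ measured in sample $i$ at time $t_i$ (hours), the expected
log-scale measurement is

$$\mathrm{E}(y_{g,i}) = \beta_{g,0} + \sum_{j=1}^{n} \beta_{g,j}
B_j(\theta_i), \qquad \theta_i = 2\pi t_i/\tau,$$

where the $B_j$ are periodic cubic B-spline basis functions with period
$\tau$ (default 24 h) and $n$ is the number of spline knots (default 3).
Optional covariates (e.g. batch) enter additively. A cosinor basis
($\cos\theta_i$, $\sin\theta_i$) is available for strictly sinusoidal
modelling.

The $n$-knot periodic spline has $n + 1$ uniformly spaced knots on the
circle, at $j\,\tau/(n+1)$, $j = 0, \dots, n$. The full periodic basis of
dimension $n+1$ partitions unity; one column is dropped so that the retained
$n$ columns plus the intercept span exactly the same space, keeping
$\beta_{g,0}$ interpretable as a level.

**Knot shifts.** Spline fits can depend noticeably on where the knots sit,
especially for strongly rhythmic features. The model is therefore fitted $m$
times (default 3) with all knots shifted by

$$d_k = (k-1)\,\frac{\tau}{m\,(n+1)}, \qquad k = 1, \dots, m,$$

so that the $m$ shift offsets tile one inter-knot spacing evenly (for the
defaults: 0, 2, 4 h). The overall fitted curve is the pointwise average of
the $m$ per-shift fits. A useful consequence of this lattice: translating all
sample times by a multiple of $\tau/(m(n+1))$ maps each shifted model space
onto another one exactly, so phases rotate and amplitudes are preserved to
machine precision; for arbitrary translations the equivariance is only
approximate (amplitude changes of order $10^{-3}$ at the defaults), because
the finite-dimensional spline spaces themselves move. For the same reason a
pure sinusoid is not represented exactly: the single-shift projection error
is about 1.2% in relative $L_2$ norm at $n = 3$, and the 3-shift average
reduces the amplitude error of a noiseless sinusoid to below $10^{-3}$.

**Estimation.** Each per-shift model is fitted to every feature by (weighted)
least squares via limma. Three backends control how residual variance enters
the standard errors: `plain` uses each feature's own residual variance;
`trend` (default for log-scale data) squeezes residual variances toward a
mean-expression trend before forming standard errors; `voom` (default for
counts) first estimates per-observation precision weights from the count
mean-variance trend and shares one weight matrix across all shifts (the
weights are estimated once, from the unshifted design). Variance moderation
has little practical effect at the sample sizes typical of circadian designs;
it is retained for fidelity at smaller $n$.

The exported `moderate_variances()` implements the squeeze directly: lowess
trend of log variances against mean expression, prior degrees of freedom
$d_0$ by trigamma method-of-moments on the residual spread, posterior
variance $(d_0 s^2_{\mathrm{trend}} + d\,s^2)/(d_0 + d)$. The trend is the
plain exponentiated smooth without a log-scale bias correction — a deliberate
simplification that makes the no-spread case an exact fixed point (identical
input variances come back unchanged) at the cost of a small ($\approx 10\%$
at $d = 10$) downward bias in the trend level.

## Multivariate adaptive shrinkage

Raw per-feature fits are noisy, and their noise level varies across features;
ranking by raw amplitude rewards noise. The time coefficients of all shifted
models are therefore moderated jointly across features with an
empirical-Bayes mixture prior (the multivariate adaptive shrinkage approach).
Writing $\hat\beta_g$ for the concatenated $R = m \times n$ time coefficients
of feature $g$ and $V_g = \mathrm{diag}(\hat{s}_g^2)$ for their squared
standard errors,

$$\hat\beta_g \mid \beta_g \sim N(\beta_g, V_g), \qquad
\beta_g \sim \sum_c \pi_c\, N(0, \Sigma_c),$$

with component covariances $\Sigma_c = w_\ell^2 U_k$ built from:

* **data-driven covariances** $U_k$: features are ranked by maximum
  $|\hat\beta/\hat{s}|$; those exceeding $z_{\min} = 4$ (capped at 2000) are
  the *strong signals*. From the (uncentered) SVD of their coefficient
  matrix, one rank-1 component per top principal axis plus the rank-$p$
  reconstruction are emitted ($p$ = number of knots), each scaled to unit
  spectral norm;
* **scales** $w_\ell$: a geometric grid with ratio $\sqrt2$ spanning
  $[\min(\hat{s})/10,\ 2\max|\hat\beta|]$ (at most 40 values, keeping the
  largest), plus an exact null scale $w = 0$.

The mixture weights $\pi$ maximise the marginal likelihood by EM
(deterministic uniform initialisation, relative tolerance $10^{-6}$, at most
500 iterations; the log-likelihood is non-decreasing at every step — this is
checked in the tests). Posterior moments follow in closed form per component,
and the overall posterior mean and SD combine components by the
responsibilities and the law of total variance. Intercepts and covariate
coefficients bypass shrinkage: with typical circadian sample sizes their
standard errors are small, and moderating them would mostly distort levels.

Error covariances are taken diagonal across coefficients. The design-induced
correlation between spline coefficients is real but modest for near-balanced
circadian designs; the diagonal approximation matches common practice and
keeps the likelihood evaluations cheap. This is the main known approximation
in the shrinkage step.

Posterior draws sample a mixture component per feature and draw from that
component's Gaussian posterior, using R's RNG stream so `set.seed()` makes
entire analyses reproducible.

## Rhythm statistics and credible intervals

Fitted curves (raw, posterior-mean, or per-draw) are evaluated on a uniform
$G$-point grid over $[0, \tau)$, $G = 512$ by default — a phase resolution of
$\tau/512 \approx 2.8$ min at $\tau = 24$, far below the sampling interval of
any realistic design. Seven statistics summarise each curve: mesor (grid
mean), peak and trough values, peak and trough phases (first-occurrence grid
argmax/argmin; ties — in practice only constant curves — resolve to phase 0
and set a degeneracy flag), peak-to-trough amplitude, and RMS amplitude
$\sqrt{\tfrac1\tau\int_0^\tau (f(t) - \bar f)^2\,dt}$ computed as the Riemann
mean on the grid.

Credible intervals come from the rhythm statistics of 200 posterior draws
(default), as 90% equal-tailed quantile intervals (type-7) or as the
narrowest window containing $\lceil 0.9\,n\rceil$ sorted draws (HDI).
Amplitudes are non-negative, so their naive intervals could never span zero.
Draws whose peak phase lies more than $\tau/4$ (circular distance) from the
amplitude-weighted circular mean peak phase have their amplitudes negated
before interval construction; an arrhythmic feature's phases scatter around
the circle, about half its draws flip, and the signed-amplitude interval
straddles zero. The circular mean is weighted by the peak-to-trough
amplitudes for both the peak-to-trough and the RMS interval, so both
amplitudes flip coherently for the same draws. Phase credible intervals are
deliberately not reported: phases are circular and interval endpoints on a
circle are not well defined for weak rhythms.

## The synthetic-data generator

`simulate_rhythm_data()` produces log-scale expression with known per-gene
mesor, amplitude, peak phase, waveform and noise SD — the ground truth every
test and acceptance experiment compares against. Choices and rationale:

* **Design**: 24 samples at 2-h intervals over 48 h (two replicates per
  unique time mod 24), mirroring the densest common circadian RNA-seq
  layout. Sparser designs are a parameter away.
* **Waveforms**: sinusoid, a von-Mises-shaped bump (non-sinusoidal, peaked),
  and a clipped sinusoid (square-ish), all normalised to range exactly
  $[-1, 1]$ so a gene's true peak-to-trough amplitude is exactly its
  amplitude parameter $A$.
* **Amplitudes**: log-normal across genes (median 1 log2 unit, sdlog 0.7),
  giving the long right tail seen in real data and enough dynamic range for
  ranking tests.
* **Mesors**: normal (mean 6, SD 2, log2-CPM-like units).
* **Noise**: Gaussian, baseline SD 0.3 log2 units, with per-gene SD
  inflated for dim genes
  ($\sigma_g = \sigma_0 (1 + e^{-(\text{mesor}_g - \min \text{mesor})/2})$)
  to mimic the log-scale mean-variance relation of RNA-seq.
* **Count mode**: expected log2-CPM is renormalised per sample (CPM is
  compositional) and mapped to negative-binomial counts at library size
  $10^7$ with dispersion 0.05, so mesors are recovered as log2-CPM up to a
  small common offset.

What the generator deliberately does not emulate: outlier samples,
batch-by-time confounding, amplitude decay over the course, shared
correlation structure between genes beyond what shrinkage discovers, and
count over-dispersion heterogeneity. Passing tests therefore demonstrate the
estimator's behaviour under its own assumptions, not robustness to every
pathology of real experiments.

## Numerical and design choices

* **Grid tolerance vs basis error.** A pure sinusoid is outside the 3-knot
  periodic spline space; the honest recovery floor for its amplitude is the
  basis-approximation error ($\sim 6\times10^{-4}$ for the 3-shift average at
  a 2-h design), not the grid resolution. Tests assert amplitude recovery at
  0.01.
* **Monotone shrinkage in noise.** With a shared mixture prior, a feature
  with the same raw coefficients but larger standard errors receives a
  smaller posterior amplitude — for real rhythms. At the numerical-null floor
  (posterior amplitudes of order 0.01) responsibilities need not be strictly
  ordered in the noise level, so the monotonicity checks are run on rhythmic
  features.
* **Interval calibration.** Shrinkage credible intervals are not exact
  frequentist confidence intervals. On sinusoidal simulations their 90%
  peak-to-trough intervals cover the truth for roughly 80–97% of genes. With
  strongly non-sinusoidal (peaked) waveforms coverage drops further because
  the 3-knot spline cannot reach the waveform's extremes — a model-bias
  statement rather than an interval defect.
* **Degenerate inputs.** All-zero count rows cannot be zero-imputed and are
  an error; zero library sizes name the offending sample; rank-deficient
  designs name the collinear columns; fewer than coefficient-count + 1
  usable samples is an error; fewer than 10 features skips variance
  moderation with a warning; an empty strong-signal set falls back to
  top-ranked features with a warning.
* **Problem sizes.** The test-and-acceptance experiments run at 300–5000
  features and 12–24 samples with 100–200 posterior draws — sizes at which
  every behaviour being asserted is already stable, as the multi-seed
  acceptance runs confirm.

## Limitations

The method assumes one shared, user-specified period; it quantifies
rhythmicity within a single condition (no differential-rhythmicity
statistics); it does not model amplitude decay; and the DESeq2-style count
likelihood backend is not implemented — counts are handled through precision
weights on log2-CPM. Phase estimates for features whose amplitude interval
spans zero should not be interpreted.
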