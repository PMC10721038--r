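# rhythmeb

Effect-size quantification of rhythmicity in genomic time series.

## The problem

Circadian transcriptome experiments measure thousands of genes over one or
more daily cycles and ask which genes cycle, how strongly, and when. Most
tools answer with p-values against the null "this gene is arrhythmic" — a
null that is rarely exactly true, and a ranking that confounds rhythm size
with measurement precision: a shallow but precisely measured oscillation can
out-rank a high-amplitude rhythm of real biological consequence. rhythmeb is
for analysts who want the opposite emphasis: estimates of the rhythm itself
(amplitude, phase, mesor) with honest uncertainty, so genes can be
prioritised by effect size.

## The method

For each feature g, the expected log-scale measurement is modelled as

    E(y_gi) = beta_g0 + sum_{j=1..n} beta_gj B_j(theta_i),   theta_i = 2 pi t_i / tau

with periodic cubic B-spline bases B_j (n = 3 knots, period tau = 24 h by
default; a cosinor basis is available). Because spline fits depend on knot
placement, the model is fitted m = 3 times with knots shifted by
d_k = (k-1) tau / (m (n+1)) and the fitted curves averaged. Fits use
(weighted) least squares via limma, with optional residual-variance
moderation ("trend") or count precision weights ("voom").

The time coefficients of all shifted models are then moderated jointly
across features by empirical-Bayes multivariate adaptive shrinkage: a
mixture-of-multivariate-normals prior with data-driven covariances (PCA of
strong signals), a geometric scale grid plus an exact null, and mixture
weights fitted by EM on the marginal likelihood. Posterior fitted curves
yield seven rhythm statistics — mesor, peak, peak phase, trough, trough
phase, peak-to-trough amplitude, RMS amplitude — and 90% credible intervals
from 200 posterior draws. Amplitude draws whose peak phase is more than
tau/4 from the amplitude-weighted circular mean phase are sign-flipped, so
the amplitude interval of an uncertain rhythm can span zero.

See `vignettes/rhythm-quantification.Rmd` for the full model description,
parameter defaults and numerical choices.

## Worked example

```r
library(rhythmeb)

sim <- simulate_rhythm_data(n_genes = 500, seed = 42)  # known ground truth
fit <- rhythmfit(sim$experiment)                       # fit + shrinkage
summary(fit)
```

```
Rhythmicity fit (spline basis)
  features: 500; samples: 24; period: 24 h
  knots: 3; shifted models: 3 (shifts 0, 2, 4 h)
  backend: trend
  shrinkage: 85 mixture components, null weight 5.95e-05

Top features by posterior peak-to-trough amplitude:
 feature_id mesor ptr_amp rms_amp peak_phase trough_phase
  gene_0025 9.651  11.662   4.123     19.266        7.266
  gene_0015 5.642   5.990   2.117     23.812       11.906
  gene_0113 4.972   5.267   1.862     16.500        4.547
  gene_0016 7.404   4.937   1.745     19.500        7.219
  gene_0077 7.498   4.605   1.627      2.297       14.016
```

The table reads: `gene_0025` oscillates around a mesor of 9.65 log2 units
with a posterior peak-to-trough amplitude of 11.7, peaking at 19.3 h — the
simulation's truth for this gene is amplitude 9.6 peaking at 19.4 h
(non-sinusoidal waveforms fit by a 3-knot spline can overshoot at the
extremes). Credible intervals and the signed-amplitude behaviour:

```r
iv <- rhythm_intervals(fit, n_draws = 200, seed = 42)
iv[order(-iv$ptr_amp_mean)[1:3], c("feature_id", "ptr_amp_lower", "ptr_amp_upper")]
#>     feature_id ptr_amp_lower ptr_amp_upper
#> 25   gene_0025         11.02         12.36
#> 15   gene_0015          5.64          6.33
#> 113  gene_0113          4.99          5.62
```

For arrhythmic genes the signed-amplitude intervals typically straddle zero,
which is the method's way of saying "this rhythm is not distinguishable from
none". File-based runs (`run_pipeline()`, or
`inst/scripts/run_rhythm.R` from a shell) write `rhythm_stats.tsv`,
`rhythm_intervals.tsv` and a reproducibility manifest.

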