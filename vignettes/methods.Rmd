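---
title: "Methods: crossover EEG exposure analysis with Bayesian model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover EEG exposure analysis with Bayesian model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and the estimand

The package analyzes double-blind, counterbalanced crossover EEG studies of
radiofrequency (RF) exposure. Each subject is recorded in two sessions (A
then B) of alternating eyes-open (EO) and eyes-closed (EC) blocks; half the
subjects (group 1) receive RF in session A and sham in session B, the other
half (group 2) the reverse. The datum is the **PSD contrast**
$d_{s,r}$: the session-B minus session-A alpha-band (6--10 Hz) power
spectral density of subject $s$ in scalp region $r$, in $\mu V^2/Hz$, in
the EO condition. With the B$-$A sign convention, an exposure that raises
alpha power makes group-2 contrasts positive, while group-1 contrasts are
negative (no carryover) or near zero (exposure effect persisting into the
following sham session). The packaged study table (`load_table1()`)
contains 192 such contrasts: 32 subjects $\times$ 6 regions.

## Spectral pipeline

`preprocess()` downsamples to 250 Hz (8th-order zero-phase Butterworth
anti-alias low-pass at 0.8 $\times$ the target Nyquist, then decimation),
applies a zero-phase 1 Hz high-pass, and re-references to the channel
average. `segment_epochs()` cuts non-overlapping 4-s windows inside
annotated blocks (partial windows dropped); `reject_epochs()` is an
automated amplitude-threshold (default 100 $\mu$V) stand-in for visual
artifact screening. Independent-component decomposition and
component-level artifact removal are out of scope.

`welch_psd()` averages Hann-tapered one-sided periodograms over kept
epochs, one taper per 4-s epoch with no sub-segmentation or overlap --- the
simplest scheme consistent with "average periodogram over epochs" --- giving
a 0.25 Hz grid. Densities are normalized so the spectral integral equals
the window-power-normalized variance of the tapered epoch (Parseval; the
test suite asserts this to $10^{-6}$). `band_power()` takes the **mean
density** over the bins with $6 \le f \le 10$ Hz, both endpoints included
(17 bins): a mean, not an integral, because the study's contrasts are
reported in $\mu V^2/Hz$. All kept EO epochs of a session are pooled
before banding (per-block weighting is not applied). Phantom recordings
are analyzed at the full 2500 Hz rate with no downsampling or high-pass so
the 217/868 Hz pulsation components stay visible.

## The five models and their parameterization

The contrast is modeled as normal with a residual scale $\sigma$ common to
all observations. Five mean structures are compared: no contrast (M1), one
common contrast (M2), one per group (M3), one per region (M4), one per
group and region (M5). Evidence for model $M$ is the marginal likelihood

$$Z_M = \int p(\sigma) \int p(\beta)\,
  N(d \mid X_M \beta, \sigma^2 I)\, d\beta\, d\sigma,$$

with independent copies of the chosen mean prior on each coefficient.

A genuinely open design choice is how the factor means are coded. This
package's default codes them the way regression-style Bayesian fitters do:
an intercept plus offsets (treatment coding), so for M5 the twelve
coefficients are intercept, five region offsets, a group offset and five
interaction offsets. The alternative, placing the prior on each cell mean
directly, is available as `parameterization = "cellmeans"`. The choice is
not innocuous: under informative priors the two induce different effective
priors on the cell means (an offset prior shrinks *differences*, a
cell-mean prior shrinks *levels*), and with diffuse-but-proper priors the
evidences can differ by factors of 2--4 for the many-parameter models.
Treatment coding is the default because it reproduces the reference
results this package ships (both the likelihood-ratio table and the
detailed posterior pattern: under the flat mean prior the posterior modes
equal the raw group means exactly, and under the standard-normal prior the
intercept mode sits *above* the group-1 sample mean because shrinkage of
the group offset is partly absorbed by the intercept --- a signature only
treatment coding produces).

### Priors

The 3 $\times$ 3 sensitivity grid crosses mean priors
$\{N(0,1),\ \mathrm{Cauchy}(0,1),\ U(-8,8)\}$ with scale priors
$\{U(0,5),\ \text{half-normal}(0,2),\ \Gamma(\text{shape}=2,\text{rate}=2)\}$.
$\sigma$ is the residual *standard deviation* (the posterior mode near
0.81 matches the spread of the contrasts; reading it as a variance would
not). $\Gamma(2,2)$ has mean 1; the half-normal has scale 2. The
$U(0,5)$ support is truncated at 5; unbounded scale priors are integrated
to the point where remaining prior mass is below $10^{-8}$ (12 for both),
far beyond any appreciable likelihood.

### Numerics

The outer $\sigma$ integral is a trapezoid quadrature on a 4000-point grid
(log-spaced below 0.1 Hz-equivalents, linear above), with the error
estimated by grid halving and reported in the diagnostics. The inner
coefficient integral is:

* **Normal prior** --- exact: the Gaussian marginal via Cholesky of
  $\sigma^2 I + X^\top X$.
* **Uniform prior** --- exact Gaussian integral times a box-mass factor
  (product of marginal normal probabilities of $[-8,8]$ around the GLS
  estimate); the factor is indistinguishable from 1 wherever the
  integrand contributes.
* **Cauchy prior, $\le 2$ coefficients** --- tensor Gauss--Hermite
  quadrature (40 nodes per dimension) against the Gaussian likelihood
  factor.
* **Cauchy prior, $> 2$ coefficients** (M4, M5) --- importance sampling
  with a multivariate-t (df 7, scale inflated 1.3$\times$) proposal
  centered at the GLS mode and a $\sigma$ proposal taken from the
  normal-prior posterior; 40,000 draws, fixed internal seed so results
  are reproducible by default, standard error and effective sample size
  in the diagnostics. Model-selection margins in this family are many
  orders of magnitude, so the Monte-Carlo error is immaterial there.

Everything is carried in the log domain with log-sum-exp.
`evidence_mc_oracle()` provides the independent cross-check: brute
prior-draw importance sampling, practical only at small $n$, used by the
test suite to validate the quadrature engine. `inner_mean_integral()` is
the scalar reference implementation of the per-cell integral (conjugate
closed form / adaptive Gauss--Kronrod), against which the vectorized
engine path is tested.

Likelihood-ratio matrices are oriented **column over row**:
entry $(r, c) = Z_c / Z_r$, so the best model's column is large.

### Posterior summaries

`model3_posterior()` evaluates the M3 joint over (intercept, group offset,
$\sigma$) on a deterministic grid: 160 $\sigma$ points spanning
0.55--1.8 $\times$ the pooled ML scale, and a lattice of about 400 points
per mean parameter spanning $\pm 8$ conditional standard errors. Marginal
modes are grid argmaxima with local quadratic refinement; intervals are
equal-tailed. The group-2 mean ($\beta_0 + \beta_1$) lives on the same
lattice and is accumulated along antidiagonals; the difference
(group 1 $-$ group 2) is the mirrored offset marginal. In the cellmeans
parameterization the difference is a numerical convolution of the two
conditional marginals mixed over $\sigma$. Reference "modus" values were
obtained by posterior sampling and are reproduced here by deterministic
quadrature; agreement to $\pm 0.02$ is the appropriate expectation, not
bit-level equality.

## Mixed-model companion test

`fit_random_intercept()` fits `contrast ~ group + (1 | subject)` by REML
(delegated to `lmerTest`, Satterthwaite degrees of freedom; in this
balanced design the fit collapses exactly to the two-sample t test on
subject means, which the tests assert). The group effect is reported as
group 1 minus group 2 to match the sign of the Bayesian difference. The
degrees of freedom are between-subject ($n_\text{subjects} - 2$): the
group effect is a between-subject contrast. On the packaged table this
gives an effect of $-0.734\ \mu V^2/Hz$ with $|t| = 2.65$ ($p = 0.013$).
The reference report quotes $t = 5.5$, $p < 0.001$ for this analysis; that
value is not reproducible from the packaged per-subject table under any
standard specification we tried (random-intercept REML/ML, with or
without region, cluster-robust or plain OLS). It coincides exactly with
the one-sample t statistic of the group-2 subject means against zero
($0.826 / (0.600/\sqrt{16}) = 5.50$, df 15), so it most likely refers to
that contrast or to a fit on unaggregated session-level data. The package
reports the model as specified and leaves the discrepancy visible rather
than re-tuning the model to hit the printed value.

## Synthetic EEG generator

The generator exists so the full pipeline is testable without data
downloads; its defaults are the study conditions. Per block, the signal is
a sum of

* **1/f background**: one-sided PSD $S(f) = a f^{-\beta}$ with
  $\beta = 1$, $a = 15\ \mu V^2/Hz$ at 1 Hz (a resting-EEG-like floor of
  $\sim 1.5\ \mu V^2/Hz$ at 10 Hz);
* **alpha**: a random-phase narrowband oscillation, synthesized in the
  frequency domain with a Gaussian spectral bump (FWHM 2 Hz) centered at
  10 Hz --- band-limited noise, not a sinusoid, so power spreads over a
  band as on the real scalp. Peak density per region (EC, sham):
  occipital 20, parietal 16, central 10, temporal 9/9, frontal
  8 $\mu V^2/Hz$, the posterior-dominant gradient of resting alpha. Eyes
  open attenuates alpha power by 0.5;
* **mains**: sinusoids at 50 Hz (2 $\mu$V) and its printed odd harmonics
  (0.2--0.5 $\mu$V);
* **pulsation** (RF on only): sinusoids at 217 Hz (0.8 $\mu$V) and
  868 Hz (0.4 $\mu$V). The 900 MHz carrier is metadata --- unsampleable
  at 2500 Hz;
* **sensor noise**: white, 1 $\mu$V SD.

Random phases with deterministic amplitudes make each block's realized
spectrum match the target density exactly, so long-run Welch estimates
converge tightly and expectations are computable in closed form.
Components above the configured Nyquist are skipped (relevant only for
deliberately desk-scaled 250 Hz runs).

Subject heterogeneity is a log-normal alpha-power multiplier (log-SD 0.4,
mean fixed at 1 so cohort expectations are unchanged), shared between a
subject's two sessions --- between-subject variability then exceeds
within-subject variability, as in real resting EEG. Breaks are drawn
uniformly from 6--16 s. The exposure multiplies EO alpha power by
`emf_effect[EO]`; the EC effect defaults to 1 (none), reflecting that an
exposure effect is hard to resolve against strong EC alpha --- a stated
assumption, not a finding. Carryover defaults to on: the effect persists
into the sham session that follows exposure, giving group 1 an expected
contrast of zero, which is the pattern in the reference data.

`calibrate_emf_effect()` closes the loop between configuration and
measurement: average referencing mixes independent per-channel spectra
($S_c \mapsto (1-1/C)^2 S_c + C^{-2}\sum_{k \ne c} S_k$), the Gaussian
bump puts only part of the alpha mass into 6--10 Hz when centered at
10 Hz, and EO attenuation scales everything; the helper inverts this
linear map so the default `emf_effect[EO]` ($\approx 1.51$) yields an
expected measured group difference of exactly 0.72 $\mu V^2/Hz$, the
effect size the design is meant to resolve. Filter gains in-band
(high-pass at 1 Hz, anti-alias at 100 Hz) are treated as unity; the
residual bias is well below the tolerances used.

What the generator does **not** emulate: eye-blink and muscle artifacts
(the rejection stage is exercised with injected spikes instead),
inter-channel correlation beyond the common mains/pulsation components,
non-stationarity within blocks, and any physiological mechanism of the
exposure effect. Passing recovery tests therefore show that the
*pipeline* is unbiased under the assumed signal model, not that real
exposure effects of this size exist.

## Problem sizes used by the shipped checks

The replication bundle runs on the packaged 192-contrast table (seconds
to ~20 s for all nine priors). Simulation-based checks use desk-scale
recordings chosen for tight-but-fast statistics: 250 Hz sampling with one
representative channel per region, sessions without the 15-min washout
(it contributes no analysis epochs), and 50-replicate batches for the
selection/coverage properties with a reduced 800-point $\sigma$ grid
(grid-halving error $< 10^{-4}$ there). The end-to-end recovery check
simulates the full 32-subject cohort with all five EO/EC cycles.

## Known limitations

* EDF/BrainVision ingestion is not provided; recordings enter as in-memory
  matrices (the generator) and leave as TSV/JSON.
* The evidence engine assumes a common residual scale, as the models
  specify; heteroscedastic extensions would need a different inner
  integral.
* The importance-sampling path (Cauchy prior, M4/M5) reports its standard
  error but is not a deterministic quadrature; with default draws the SE
  is ~0.01--0.03 in log evidence.
* The per-subject "mean" column of the packaged table is used only as a
  transcription checksum; it enters no model.
* The packaged contrasts carry two printed decimals; analyses on the
  unrounded originals would differ in the third decimal, which the
  stated tolerances absorb.
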