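# emfeeg

Does radiofrequency (RF) exposure from a mobile-phone-like signal change
the resting EEG? `emfeeg` is an R toolchain for answering that question
with a double-blind, counterbalanced crossover design: every subject is
recorded in two sessions of alternating eyes-open (EO) / eyes-closed (EC)
blocks, with a 900 MHz GSM-style exposure (217 Hz pulsation) active in
one session and sham in the other. It is written for EEG researchers and
biostatisticians who want the complete chain — signal simulation, spectral
reduction, and the Bayesian model comparison — as tested, reusable
functions rather than one-off scripts.

## What it computes

The datum is the **PSD contrast** `d[s, r]`: session-B minus session-A
alpha-band (6–10 Hz) power spectral density for subject `s` and scalp
region `r`, in μV²/Hz, eyes open. Contrasts are modeled as normal with a
common residual scale σ, and five mean structures are compared by marginal
likelihood:

| Model | mean structure           | mean parameters |
|-------|--------------------------|-----------------|
| M1    | 0                        | 0               |
| M2    | m                        | 1               |
| M3    | m(group)                 | 2               |
| M4    | m(region)                | 6               |
| M5    | m(group × region)        | 12              |

Evidence is `Z_M = ∫ p(σ) ∫ p(β) N(d | X_M β, σ² I) dβ dσ`, computed by
deterministic quadrature (closed forms where they exist, seeded
importance sampling for the many-parameter Cauchy-prior case), over a
3 × 3 sensitivity grid of diffuse priors — N(0,1) / Cauchy(0,1) / U(−8,8)
on each mean coefficient and U(0,5) / half-normal(0,2) / Γ(2,2) on σ.
Pairwise likelihood ratios are reported as 5 × 5 matrices (entry (r, c) =
Z_c / Z_r), with posterior modes and 95% equal-tailed credible intervals
for the two-group model, plus a REML random-intercept mixed model as the
frequentist companion. A synthetic multichannel EEG generator (1/f
background, reactive region-weighted alpha, mains harmonics, 217/868 Hz
pulsation artifact, crossover block schedule) and a phantom-recording QC
make the whole chain testable end to end. The methods vignette
(`vignettes/methods.Rmd`) documents every model and numerical choice.

## Worked example

The packaged study table holds 192 contrasts (32 subjects × 6 regions;
group 1 = RF in session A, group 2 = RF in session B):

```r
library(emfeeg)

tab <- load_table1()
tapply(tab$contrast, tab$group, mean)
#>          1          2
#> 0.09208333 0.82583333
```

Group 2 (exposed in the second session) gained ~0.73 μV²/Hz of alpha-band
power from session A to B; group 1 barely moved. The model comparison
makes that impression quantitative:

```r
pr <- prior_spec("normal", "uniform")   # N(0,1) means, U(0,5) sigma
lr_matrix(tab, pr)
#> likelihood ratios (column model over row model)
#>   priors: contrast Normal (0,1) | sigma Uniform (0,5)
#>         Model 1  Model 2  Model 3  Model 4  Model 5
#> Model 1 1        5e+08    3.38e+15 1.77e+05 4.06e+09
#> Model 2 2e-09    1        6.77e+06 0.000353 8.11
#> Model 3 2.95e-16 1.48e-07 1        5.22e-11 1.2e-06
#> Model 4 5.66e-06 2.83e+03 1.92e+10 1        2.3e+04
#> Model 5 2.47e-10 0.123    8.34e+05 4.35e-05 1
#> highest evidence: Model 3
```

Model 3 — a contrast that differs **by group** but not by region — beats
every alternative by at least ~7 × 10⁵, and `run_replicate()` shows the
same winner under all nine prior combinations. Its posterior:

```r
model3_posterior(tab, pr)
#> Model 3 posterior (contrast prior Normal (0,1) | sigma prior Uniform (0,5) )
#>   parameter    mode ci_lower ci_upper
#>    m_group1  0.0963  -0.0675   0.2558
#>    m_group2  0.8209   0.6563   0.9806
#>       sigma  0.8063   0.7314   0.8958
#>  difference -0.7246  -0.9548  -0.4984
```

The group difference (group 1 minus group 2) is −0.72 μV²/Hz with a 95%
credible interval well away from zero: the exposure raised alpha power in
the EO condition, and the effect does not resolve into particular
regions. The frequentist companion agrees on the effect size:

```r
fit_random_intercept(tab)
#> random-intercept mixed model (REML)
#>   group effect (g1 - g2): -0.7338  SE 0.2767  t = -2.652  df = 30.0  p = 0.0127
#>   variance components: subject 0.5985, residual 0.0831
```

Hardware sanity check — the pulsed carrier must show up at 217/868 Hz and
nowhere in the physiological range:

```r
run_phantom(duration_s = 48, seed = 7)
#> phantom QC: PASS
#>   max |PSD difference| in physiological band: 1.05 SE
#>   peaks RF on (Hz):  50, 217, 868
#>   peaks RF off (Hz): 50
```

End-to-end synthetic validation — simulate a 32-subject cohort whose
configured effect is a 0.72 μV²/Hz group difference and recover it
through the full pipeline:

```r
cfg <- sim_config(sampling_rate = 250)    # desk-scale: one channel/region
res <- run_synthetic(cfg, n = 32, seed = 42,
                     schedule_args = list(washout_s = 0))
res$recovered_difference    # within 20% of 0.72
res$winner                  # "Model 3"
```

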