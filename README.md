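# srcse

Simulation and quantification toolkit for **saturation-recovery
chemical-shift-encoded (SR-CSE) multiparametric muscle MRI**: one
acquisition that yields water-specific T1 (T1_Water), proton density fat
fraction (PDFF) and R2\* on an intrinsically co-registered grid, plus
the downstream muscle-composition and normative-statistics analyses
built on those maps.

## Who this is for, and the problem it addresses

T1 mapping is the workhorse quantitative MRI probe of edema, fibrosis
and inflammation, but skeletal muscle always contains some fat, and fat
relaxes almost four times faster than muscle water (T1 ≈ 370 vs
≈ 1400 ms at 2.89 T). Conventional T1 methods (MOLLI, SASHA) read the
mixture and acquire a fat-modulated bias of tens of ms per percent of
intramuscular fat — large enough to push a healthy muscle into the
"abnormal" range. SR-CSE removes the confound by separating water and
fat first (multi-echo chemical-shift encoding with joint B0/R2\*
estimation) and computing T1 from the water images alone, via a
Bloch-simulation lookup table that accounts for the ramped single-shot
readout.

No human data ships with (or is required by) this package: it provides
digital tube and thigh phantoms and a synthetic normative cohort
generator with known ground truth, so every part of the chain —
acquisition physics, reconstruction, segmentation, composition
reporting, statistics — is exercised end to end against truth. It is
aimed at quantitative-MRI methodologists and at anyone who needs a
transparent, fully synthetic testbed for water-specific T1 and muscle
fat quantification.

## The model in brief

Per voxel, water and fat amplitudes $W, F$ obey

$$s(TE) = (W + F\,c(TE))\; e^{i2\pi \Delta f_0 TE}\, e^{-R_2^* TE},$$

with $c(TE)$ the six-peak fat phasor. Separation is variable projection
over a $(\Delta f_0, R_2^*)$ candidate grid with seeded region-growing
field-map smoothness; the prepared and unprepared series share one
field/R2\* map pair, and

$$\mathrm{PDFF} = 100\,\frac{f}{f + w}, \qquad
  \frac{|W_{prep}|}{|W_{unprep}|} \xrightarrow{\;\text{Bloch LUT}\;} T_{1,Water}.$$

Composition metrics follow: MFF_Intra (mean muscle PDFF), MFF_Inter /
MFV pools, and slab-corrected volumes (factor 59.5/17.5 for the default
five-slice, 10.5 mm-gap prescription).

## Worked example

Simulate a thigh, acquire at SNR 50, reconstruct, and report:

```r
library(srcse)
m <- run_pipeline(run_config(
  phantom = list(type = "thigh", matrix_size = c(64L, 32L), n_slices = 1L,
                 mff_intra_pct = 2.6, t1_water_ms = 1445),
  seed = 42, out_dir = "demo_run", snr = 50))
```

This writes PDFF/T1/B0/R2\* NIfTI maps, a composition report and a
ground-truth sidecar (JSON), and a seed/checksum manifest into
`demo_run/`. The recovered report versus the generator truth:

```
MFF_Intra: 2.54 % (truth 2.58)
T1_Water: 1450 ms (truth 1445)
R2*: 42.2 1/s (truth 42.0)
muscle volume: 79 mL (truth 79)
```

i.e. the water-specific T1 is recovered within a few ms and the
intramuscular fat fraction within a few hundredths of a percent, at
desk-scale phantom size.

Normative statistics on a synthetic cohort (63 male, 67 female):

```r
coh <- make_cohort(63, 67, seed = 1)
normative_table(coh$t1w_ms, coh$sex)
#>    group  n   mean     sd     p5    p95
#> 1 female 67 1446.5 23.145 1411.3 1484.3
#> 2   male 63 1406.9 24.110 1363.6 1445.7
fit <- fit_covariate_model(coh$t1w_ms, coh$age, coh$male)
fit$coefficients
#>        term     beta   se   ci_low  ci_high std_beta         p
#> 1 intercept 1428.791 6.77 1415.402 1442.180       NA 1.36e-163
#> 2       age    0.372 0.13    0.116    0.629    0.189  4.74e-03
#> 3      male  -39.708 4.03  -47.687  -31.729   -0.647  2.39e-17
```

The sex-specific means (≈1445 vs ≈1409 ms) and the male-sex coefficient
(≈ −35 ms, here −39.7 at this seed's sampling error) are the normative
structure the generator encodes.

The fat-bias side of the method is available through the MOLLI/SASHA
simulators: `simulate_molli()` / `simulate_sasha()` +
`fit_molli()` / `fit_sasha()` show apparent T1 rising with fat fraction
while the SR-CSE `estimate_t1water()` route stays put, and
`fit_bias_model()` fits the bias-vs-fat-fraction line from ROI tables.

A thin command-line wrapper over the same functions is installed at
`inst/cli/srcse.R` (subcommands `simulate-phantom`, `simulate-cohort`,
`recon`, `t1map`, `fitmolli`, `fitsasha`, `bias`, `segment`, `compose`,
`report`, `run`).

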