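---
title: "Structure-property-uptake analysis of copolymer particle libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-property-uptake analysis of copolymer particle libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptakemva)
```

## The problem

Combinatorial soap-free emulsion polymerization produces libraries of latex
nanoparticles — here poly(styrene-*co*-methyl methacrylate) — that vary
simultaneously in copolymer composition, molecular weight, diameter and
surface charge.  Understanding which of these coupled properties drives
cellular uptake requires a multivariate treatment rather than one-variable-
at-a-time comparisons.  `uptakemva` implements that treatment as a tested
pipeline: size quality control, a physical particle-size model, standardized
PCA, multiple linear regression with a relative variable-impact metric, and
a logarithmic dose-uptake model, together with a synthetic-library
generator so that every stage can be exercised and validated without any
measured data set.

## Size quality control

Dynamic light scattering reports an intensity-weighted hydrodynamic
diameter and is exquisitely sensitive to aggregates; electron microscopy
reports a number-weighted diameter of dried single particles and is not.
The ratio `r = d(DLS)/d(SEM)` therefore separates three regimes:

* `r > 1.2` — aggregation during the DLS measurement,
* `r < 0.8` — DLS over-approximates the size (broad dispersity),
* `0.8 <= r <= 1.2` — consistent, well-dispersed sample.

Thresholds are strict and applied to the full-precision ratio; a value
sitting exactly on a boundary is classified consistent, because published
tables show boundary ratios (after 1-decimal rounding) without an
aggregation footnote.  Display rounding is half-up to one decimal
(`round_half_up()`), matching how such tables are printed; all comparisons
keep full precision.  Independently of the ratio, DLS diameters of 800 nm
or more are not treated as single particles; samples failing either check
are excluded from size modelling.  Samples whose micrographs show only
agglomerates have no SEM diameter, a missing ratio, and class `unknown` —
this is data, not an error.

```{r qc}
ref <- reference_dls_sem()
qc <- flag_single_particles(ref)
table(qc$dispersion_class)
```

`screen_redundant_variables()` computes the pairwise Pearson correlation
matrix and flags any variable whose largest absolute correlation reaches a
threshold (default 0.7).  On generated libraries the polydispersity index
is flagged against the DLS diameter — aggregation inflates both — which is
why PdI does not enter the PCA variable set as an independent variable.

## The micellar size model

In soap-free emulsion polymerization each initiator-derived charged moiety
starts one chain and ends up on the particle surface.  Two
proportionalities follow: particle volume scales with (chains per particle)
x (chain length, Mn), and the magnitude of the zeta potential scales with
the surface charge density, i.e. with chains per particle over surface
area.  Eliminating the unobserved chains-per-particle count leaves

$$d = k \,(-z)\, \bar M_n,$$

with `d` in nm, `-z` in mV, `Mn` in kg mol^-1 and `k` a single constant
absorbing density, packing and double-layer factors (nm mV^-1 mol kg^-1).
Because the derivation rests on stated proportionalities rather than an
explicit printed algebra, `predict_diameter()` and `calibrate_k()` accept
configurable exponents `d = k (-z)^a Mn^b` with defaults `a = b = 1`.

Calibration is least squares through the origin (the model is a pure
proportionality, so no intercept), with the closed-form solution
`k = sum(d u) / sum(u^2)` for `u = (-z)^a Mn^b`, computed over QC-passing
samples only.  The root-mean-square error of prediction is reported on the
same subset and is an in-sample quantity; no held-out split is attempted at
these cohort sizes.

## Standardized PCA and the variable-impact metric

PCA uses autoscaled variables (mean 0, sample standard deviation 1, with
the n - 1 divisor throughout) and eigendecomposition of the correlation
matrix; loadings are unit-norm eigenvectors, scores the data projections.
Eigenvector signs are arbitrary, so each component is oriented to make its
largest-magnitude loading positive — a fixed, documented convention that
makes loadings comparable across runs.  Zeta potentials are negated
(`transform_zeta()`) so every variable enters with positive sign.
Rank-deficient inputs are legal; trailing components simply carry zero
variance and are flagged.

Multiple linear regression deliberately runs on *raw-scale* data (no
standardization), with the scale information recovered in the impact
metric:

$$I_v^{(j)} = \frac{|\beta_j\, s_j|}{\sum_m |\beta_m\, s_m|},$$

where `s_j` is the predictor's sample standard deviation.  The product
`beta * sd` is unit-free, so `I_v` is invariant to the units any predictor
is recorded in, sums to one, and ranks predictors by how much of the
response's spread they move.  Collinear designs are refused with a
condition-number diagnostic rather than silently producing unstable
coefficients.

Mean confidence ellipses for bivariate scatter use the Hotelling $T^2$
statistic: the sample covariance scaled by 1/n with squared radius
$\frac{p(n-1)}{n-p} F_{p,\,n-p}(\text{level})$, $p = 2$.  This bounds the
*mean*, not the data cloud — the natural reading of a "mean confidence
ellipse" — and reports a trend sign from the sample correlation.

## The logarithmic uptake model

Uptake saturates: the percentage of particle-positive cells grows
degressively with particle load.  The model is

$$U_P = u_S \log_{10} \tilde p + u_L,$$

with $\tilde p = (p \cdot \text{solid}_{meas}/\text{solid}_{theo})/p_0$
the solid-content-corrected dimensionless load and $p_0 = 1$ ug mL^-1 the
standard load.  `u_S` (% per decade) measures how steeply uptake rises
with dose; `u_L` (%) is the level at the standard load.  Fitting is OLS of
`U_P` on `log10(p_tilde)` over at least three distinct loads; replicates
pool into the fit.  Fits with `R^2 < 0.80` (strict) are flagged excluded:
they do not follow the model (e.g. saturated-flat samples) and their
reference uptake is reported missing.  The reference uptake at a nominal
100 ug mL^-1 load is clipped to [0, 100] *at reporting time only*; the raw
fitted value is retained.  The expected error `Er` is the pooled
within-load replicate standard deviation — since the reported uptake is a
linear function of the measurements, this is its first-order measurement
error; that propagation rule is an interpretation, stated as such.

The log base is configurable; base 10 is canonical because the slope then
reads directly as "percent per decade of dose".

```{r uptake}
ref_u <- reference_uptake_fits()
ref_u$excluded <- is.na(ref_u$u_p_ref)
unlist(summarize_uptake(ref_u, "RAW"))
```

## The synthetic-library generator

`synth_params()` fixes the emulated study conditions; `simulate_library()`
draws one library.  What the generator emulates, and the reasoning behind
each default:

* **Design**: 5 feed ratios (0-100 mol % Sty) x 5 concentration factors
  (0.2-1.0, factor 1.0 = 2.625 mol L^-1 so that 0.8 maps to 2.10
  mmol mL^-1) x labeled/nonlabeled, minus the two Sty0 points at factor
  1.0 — a 48-member library.
* **Composition**: an ideal Mayo-Lewis-type curve
  `x/100 = E f / (E f + 1 - f)` with a single enrichment factor
  `E = 7/3`, pinned at the homopolymer endpoints and calibrated so a
  50 mol % feed yields ~70 mol % styrene in the copolymer; additive
  Gaussian noise of 2 mol % (the characteristic error of NIR composition
  determination) applies between the endpoints.
* **Mn and zeta**: linear trends — Mn rising with monomer concentration
  and falling with styrene feed, the zeta-potential magnitude rising with
  concentration.  Only the *directions* of these trends are established;
  the slopes here are synthetic choices placing Mn in ~90-350 kg mol^-1
  and -z in ~25-46 mV, realistic for sulfate-initiated soap-free latexes.
* **Diameters**: the true diameter follows the micellar forward model
  `d = k_true (-z) Mn` with `k_true = 0.05`, giving ~150-800 nm.  It is
  evaluated at the *realized* Mn and -z (measurement scatter is treated as
  sample-to-sample variation), so the calibration stage is estimable
  without an errors-in-variables correction.  SEM diameters are read to
  50 nm precision; DLS diameters carry multiplicative lognormal noise
  (keeping them positive) and, with probability 0.1 per sample, an
  aggregation inflation factor drawn uniform on [1.5, 5] — the range
  observed ratios for aggregated samples span.  PdI is shifted upward for
  aggregated samples, which is what makes it a redundant variable.
* **Uptake**: per-cell-line linear maps from composition to `(u_S, u_L)`.
  RAW-type phagocytic cells are high and nearly composition-independent
  (u_S 28-32, u_L 18-20); HEK-type nonphagocytic cells rise steeply with
  styrene content (u_S 15-35, u_L 5-11).  The maps are scaled so the
  noiseless model stays inside [0, 100] over the assay loads 8-160
  ug mL^-1 — published per-sample slope/level magnitudes cannot be made
  jointly consistent with those loads and a 0-100 % response under any
  fixed corrected load, so self-consistent magnitudes were chosen once and
  the qualitative structure kept.  Triplicate measurements per load
  (Gaussian noise, sd 3 % points, clipped to [0, 100]) reflect standard
  flow-cytometry practice and give the exclusion rule enough points to be
  sharp.
* **Randomness**: one integer seed; the physicochemical stage uses
  `seed`, the uptake stage `seed + 1`.  Identical seed and parameters give
  byte-identical tables.

Every latent value (true diameter, aggregation flag and factor, true
uptake parameters, chains-per-particle count) is emitted in row-aligned
truth tables, enabling parameter-recovery tests.

What the generator does **not** emulate: polymerization kinetics,
non-Gaussian measurement error, correlated day effects, cytotoxicity and
endotoxin artifacts, or any surface-chemistry effect on uptake beyond the
composition maps.  Passing recovery tests therefore demonstrates that the
analysis inverts its own forward model at realistic noise — not that the
forward model is a complete account of real libraries.

## Numerical choices and degenerate inputs

* Sample standard deviation (n - 1) everywhere.
* `round_half_up()` for display; full precision in comparisons.
* Micrograph rounding (50 nm) is considered part of the observation model
  and is disabled in `synth_params_noiseless()`, so noiseless forward
  simulation is exactly invertible.
* Zero-variance variables are an error naming the column, in
  `standardize()` and `screen_redundant_variables()` alike.
* Perfectly correlated pairs are legal in PCA (trailing zero-variance
  components) and in ellipses (minor semi-axis collapses to 0); a
  zero-variance margin is a degenerate-covariance error.
* Missing data are handled complete-case per analysis, with dropped counts
  messaged and excluded samples logged with machine-readable reason codes
  (`aggregate`, `low-solid-content`, `low-R2`, `missing-data`).

## The pipeline

`run_pipeline(pipeline_config(...))` chains the stages: QC, size-model
calibration on QC-passing samples, standardized PCA of
{c, x, Mn, d, -z} and an MLR of `d` on {x, -z, Mn} over non-aggregated
samples (aggregation inflates the hydrodynamic diameter, so aggregated
samples would contaminate both), per-sample uptake fits with
low-solid-content and R^2 exclusion, and finally the uptake feature table
{x, Mn^2, d, -z, U_P(RAW), U_P(HEK)} feeding the uptake PCA, the HEK
uptake MLR and the simple/group-mean composition correlations.  Mn enters
the uptake stage squared because the size model is multiplicative in Mn,
and squaring it linearizes that contribution for the regression.
Artifacts carry no timestamps, so a config plus seed reproduces
byte-identical outputs.

```{r pipeline}
res <- run_pipeline(pipeline_config(synth = synth_params(), seed = 7))
res
```

## Problem sizes and limitations

Validation runs use the 48-member default library; recovery studies use
100 replicate libraries for the size-model constant and a few hundred
fits for the uptake model — cohort sizes at which every stage completes in
seconds while estimator spread is still measurable.  Known limitations:
the size model is in-sample and assumes ideal micellar constitution (no
Debye-layer or Henry-function corrections); the uptake model is purely
phenomenological with no endocytosis kinetics; PCA/MLR results on
generated data inherit every simplification of the generator listed above.
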