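---
title: "Methods: simulation, chemometric calibration and selection concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, chemometric calibration and selection concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nirscassava` implements an end-to-end phenotyping pipeline for cassava root
quality traits — starch content (StC) and dry matter content measured by the
oven reference (DMCo) and the gravimetric air/water proxy (DMCg) — from
handheld near-infrared spectra of the kind produced by pocket 740–1070 nm
sensors on fresh root surfaces and on mashed root pulp. Because raw
field-trial data of this kind are rarely shareable, the package is built
around a synthetic-data generator whose outputs exercise every downstream
stage: spectral pre-treatment comparison, calibration with three regression
engines under a repeated cross-validation and residual-trimming protocol,
chemometric validation metrics, multi-environment mixed-model analysis with
BLUP deregression, and chance-corrected concordance between phenotype-based
and model-based selection of the top clones.

This vignette records the models, the defaults and the design decisions, so
that every number the package produces can be traced to an explicit choice.

# The trait model

Plot-level trait values are generated (and later re-estimated) under the
standard multi-environment linear mixed model

$$Y_{ijlk} = \mu + g_i + \beta_j + r_{l(j)} + \rho_{k(l)} + g\beta_{ij} + \varepsilon_{ijlk}$$

with clone effects $g_i \sim N(0, \sigma^2_g)$ shared across environments,
fixed environment effects $\beta_j$, replication-within-environment
$r_{l(j)} \sim N(0, \sigma^2_r)$, block-within-replication
$\rho_{k(l)} \sim N(0, \sigma^2_k)$, clone-by-environment interaction
$g\beta_{ij} \sim N(0, \sigma^2_{ge})$ and residual
$\varepsilon \sim N(0, \sigma^2_e)$. The generator draws the environment
effects once (from a configurable $N(0, \sigma^2_{env})$) and then treats
them as fixed, honouring the fixed-effect status of environment in the
estimation model.

Default variances (trait-percent², chosen once as representative of
advanced cassava yield trials, where clonal variance dominates): clone 6
(StC) / 8 (DMCo), replication 0.5, block 0.25, clone-by-environment 1.5,
residual 2.0 (StC) / 1.5 (DMCo); trait means 30% (StC) and 35% (DMCo);
environment sd 2%. These means are deliberate placeholders for a plausible
breeding population — the source study does not report its population
moments. DMCg is generated as DMCo plus independent $N(0, 1.5^2)$
measurement noise, making the gravimetric trait intrinsically harder to
predict than the oven reference, which reproduces the qualitative trait
ordering seen in practice. StC and DMCo are generated independently; real
populations show substantial genetic correlation between them, which the
generator does not emulate (see Limitations).

# The spectral forward model

Each reading $r$ of plot $p$ is generated as

$$A_r(\lambda) = a_r \sum_k G_k(\lambda)\; l_k^\top t_r + b_r + c_r \tilde\lambda + \varepsilon_r(\lambda)$$

where $G_k$ are Gaussian absorption bands, $l_k$ their loadings (absorbance
per trait-percent), $t_r$ the trait values seen by the reading, $a_r$ a
multiplicative scatter factor, $b_r$ an additive baseline offset, $c_r$ a
linear tilt over the centred wavelength axis, and $\varepsilon$ iid channel
noise. The default band set places a water-dominated band at 970 nm (sd
35 nm, negative DMCo loading: more dry matter displaces water), a C–H/starch
band at 910 nm (sd 25 nm) and a secondary combination band at 1020 nm —
domain-plausible stand-ins for the O–H/C–H overtone structure of the
740–1070 nm window; the device range is the only anchor the source material
provides, so band placement is configurable. The wavelength grid is 331
channels at 1 nm; the physical 12-photodetector architecture and its
interpolation are not modelled.

The two sample preparations differ in three ways, all configurable:

* **Acquisition effort** — 47 readings per plot (fresh) versus 4 (mashed),
  matching the acquisition protocol the pipeline emulates.
* **Scatter and noise** — fresh surfaces carry roughly five-fold larger
  multiplicative slope, offset and tilt dispersion, plus plot-level scatter
  components shared by all readings of a plot (the surface condition of that
  plot's roots), and four-fold larger channel noise.
* **Trait linkage** — fresh readings perturb the plot's trait values per
  reading (within-root heterogeneity, sd 1.5%) and per plot (sampling bias
  of the scanned roots, sd 1.0%); mashed pulp is nearly homogeneous
  (0.1% for both).

The plot-level scatter and trait-bias components are what make the fresh
regime durably harder: per-reading disturbances average away across 47
readings, but plot-level ones do not, which is exactly the mechanism by
which fresh-root spectra underperform in practice. With these defaults the
pipeline reproduces the headline contrast — mashed calibrations beat fresh
calibrations for every engine and every trait — without any per-test tuning.

# Pre-treatments

Seven configurations are implemented: raw, first derivative (`d1`), SNV,
MSC, derivative + detrend (`d1_dt`), derivative + MSC (`d1_msc`), and
Savitzky–Golay smoothing + derivative + SNV (`sg_snv`). Decisions worth
recording:

* The "first derivative" is the **gap-segment derivative** (gap span 11,
  segment 7, per-nm units), matching the integration of the SG filter with
  gap-segment differentiation described in the methodology the package
  follows; a plain Savitzky–Golay derivative remains available through
  `savitzky_golay(deriv_order = 1)`.
* SNV uses the $n-1$ (sample) standard deviation.
* The MSC reference defaults to the column mean of the dataset it is given;
  in the pipeline the reference is always learned on the **calibration
  partition** and reused for holdout spectra, eliminating one subtle leakage
  channel.
* Detrend default degree is 2, a common chemometric choice for curvilinear
  baselines.
* Edge handling preserves vector length: SG uses asymmetric truncated-window
  fits; the gap-segment derivative pads with the nearest valid value.
* The IQR outlier screen computes per-channel type-7 Tukey fences
  (multiplier 1.5) and flags a reading when more than 10% of its channels
  are outside the fences. The 10% channel fraction operationalizes a
  per-sample rule that the emulated protocol states only loosely; fences
  learned on the calibration partition can be re-applied to holdout data.
* The treatment comparison list follows the configuration set actually
  reported in the emulated study's results (raw, d1, snv, msc, d1_dt,
  d1_msc, sg_snv); a derivative + SNV composition remains expressible via
  the primitives.

A note on honest outcomes: with the default (low-scatter mashed) generator,
`raw` often wins the pre-treatment comparison, because SNV-type corrections
remove amplitude information that the noise-free forward model stores in
band depth. Scatter correction earns its keep exactly when multiplicative
contamination is strong — the package's scatter-contamination scenario
(slope sd 0.4 at both reading and plot level) demonstrates this, and the
test suite asserts it there, not at the clean defaults.

# Calibration protocol

Modelling is **plot-level**: readings are averaged to one mean spectrum per
plot after treatment and outlier screening (the emulated workflow models
plot-level traits; its spectra-to-plot mapping is unstated). The data are
split 80/20 at the plot level, seeded; all partitioning derives from one
master seed via a Lehmer-style seed mixer, so fold assignments are
byte-identical across engines.

Three engines run behind one contract:

* **PLS** — NIPALS PLS1, written in-package (centering, covariance-maximal
  weight extraction, deflation, coefficients re-expressed in original
  units). Component count is chosen by repeated-CV RMSE under the
  one-standard-error rule, capped at 20.
* **SVM** — $\varepsilon$-SVR with RBF kernel at the standard configuration
  $C = 1$; open parameters are set to $\varepsilon = 0.1$ and
  $\gamma = 1/(n_{channels} \cdot \overline{\mathrm{var}})$ (documented
  non-study defaults).
* **XGB** — gradient boosting at the published operating point: 200 rounds,
  depth 5, $\eta = 0.3$, $\gamma = 5$, subsample 0.7, colsample 0.7,
  min child weight 1; single-threaded and seeded for reproducibility.

The two-stage protocol: stage 1 runs repeated 5-fold cross-validation (5
repetitions by default; the bundled analyses use 2 to stay fast) on the full
calibration set; each sample's residual is its absolute cross-validated
prediction error averaged over repetitions — cross-validated rather than
refit residuals, to avoid optimistically trimming exactly the points the
model already fits; the worst 20% (floor) are removed once. Stage 2 reruns
the repeated CV on the retained samples (these are the reported calibration
metrics, pooled out-of-fold per repetition and averaged over repetitions —
one of the two common conventions, chosen for stability) and refits the
final model, which alone generates holdout predictions.

The pre-treatment comparison fits only PLS (the comparison stage of the
emulated workflow does likewise), ranks treatments by CV Pearson R
(descending) and RMSE (ascending) within each sample type, and averages
ranks across both metrics and both sample types; exact ties fall back to
the canonical treatment order, and the tie-break is recorded.

# Metrics

`compute_metrics()` reports Pearson `r`; `r2` as the square of `r` (matching
the chemometric convention where R = 0.97 is reported alongside R² = 0.94;
the 1 − SSE/SST definition is available behind a flag); RMSE; additive bias
`mean(predicted − observed)`; the OLS slope of predicted on observed
(calibration tables in this literature sometimes report a slope-like "bias"
clustering near 1 — both candidates are therefore computed under distinct
names, with the additive form as the default "bias"); `rpd` with the
standard deviation of the **reference** values in the numerator (the
definition admits either reference or predicted; the reference convention is
chosen and logged); and `rpiq` with the type-7 interquartile range of the
reference values. A perfect fit reports RPD/RPIQ as `Inf` with a warning
rather than failing.

# Mixed model, BLUPs, deregression

REML estimation is implemented in-package (the emulated workflow used a
packaged solver, so the algorithm is the implementer's choice; ours is
validated against the balanced-design ANOVA closed form to 1e-6 and against
`lme4` on unbalanced multi-environment fits):

* The residual variance is profiled out; the search runs over **log variance
  ratios** $\log \lambda_k = \log(\sigma^2_k/\sigma^2_e)$, Nelder–Mead for
  two or more components, Brent-type scalar minimization otherwise.
* The profiled restricted likelihood is evaluated through Henderson's
  mixed-model equations with one sparse Cholesky factorization per
  evaluation; the quadratic form is computed as
  $\lVert y - M\hat b\rVert^2 + \hat b^\top D \hat b$ (both terms positive)
  rather than $y^\top y - \hat b^\top M^\top y$, whose catastrophic
  cancellation otherwise caps the attainable precision near 1e-5.
* Log ratios are confined to $[-13, 13]$ by a quadratic penalty: beyond
  that box the coefficient matrix is numerically singular and a ratio of
  $e^{13} \approx 4\times10^5$ is already "effectively zero/fixed".
* PEV is the diagonal of the clone block of the inverse coefficient matrix
  times $\hat\sigma^2_e$ — the standard prediction-error-variance
  convention, which (unlike `lme4`'s conditional variances) includes
  fixed-effect uncertainty.

Deregression removes shrinkage for selection:
$\mathrm{dBLUP}_i = \mathrm{BLUP}_i / (1 - \mathrm{PEV}_i/\hat\sigma^2_g)$,
i.e. division by reliability. Clones at or below the reliability floor
(default 0.05) receive a missing dBLUP with a warning instead of an
exploding value. The genotypic variance in the denominator is the
combined-analysis estimate (a single $\hat\sigma^2_g$ per trait), not
per-trial values.

# Selection concordance

`select_top_fraction()` takes the top $\lceil 0.2 n \rceil$ clones ("top"
meaning largest, as higher starch and dry matter are the breeding goals);
cutoff ties break by ascending clone id with a warning. Cohen's unweighted
kappa is computed as $(p_o - p_e)/(1 - p_e)$ from the 2×2
selected/not-selected confusion matrix. The kappa formula is implemented in
its standard Cohen (1960) form; a printed variant with a plus sign in the
numerator circulating in the applied literature contradicts both the
statistic's definition and its own stated 0–1 range, and is not used. The
degenerate case $p_o = p_e = 1$ is defined as kappa = 1.

In the pipeline, the phenotype ranking uses dBLUPs of the observed trait,
and each engine's ranking uses **dBLUPs of its plot-level predictions**
(the same mixed model fitted to predictions), so both sides of the
comparison sit on the same footing — this mirrors constructing confusion
matrices from deregressed values on both sides. When a prediction set
carries no detectable genetic variance (the $\sigma^2_g \to 0$ boundary,
all deregressions undefined) the ranking falls back to plain clone means;
this occurs only for engines that have already failed on that trait.
Selection universes are the clones with defined phenotype dBLUPs; pairwise
engine comparisons share that universe.

# Orchestration and reproducibility

`run_pipeline()` executes the whole study replica from a single
configuration: simulate → treat (calibration-learned MSC references and IQR
fences) → PLS-based treatment comparison per trait → engine calibration with
residual trimming and holdout validation → REML/dBLUP → kappa concordance.
Every factorial cell is serialized as JSON on completion (making reruns
resumable), failures are logged per cell without aborting the others, and a
manifest records seeds, chosen treatments and an MD5 checksum of every
output file. By default the non-PLS engines run only on each trait's winning
treatment — the workflow of the emulated study; `full_factorial = TRUE`
calibrates every engine on every treatment. The numbered scripts under
`analysis/` present the same stages as a narrated sequence.

Problem sizes bundled with the package (the `analysis/` scripts, the demo
configuration and the acceptance script) use 100 clones × 2 environments ×
2 replications with 2 CV repetitions — the package's chosen demonstration
scale, small enough to run interactively while leaving every contrast of
interest clearly resolved. The variance-recovery simulations use 200 clones
× 3 environments × 2 replications.

# What passing tests do and do not show

The generator emulates: trait architecture with clone-dominant variance,
fixed environments, replications and incomplete blocks; trait-linked
Gaussian-band absorbance; multiplicative/additive/tilt scatter at reading
and plot level; within-root heterogeneity of fresh samples; gross
aberrant-scan outliers. It does **not** emulate: instrument response and
detector physics, wavelength-dependent scatter, nonlinear
absorbance–composition relationships, genetic correlation between traits,
augmented designs with check varieties, or spectral drift over sessions.
Consequently, green tests demonstrate that the pipeline's machinery is
correct and that its qualitative contrasts (mashed > fresh; scatter
correction pays under scatter; high calibration accuracy implies high
selection concordance) emerge for the stated reasons — they do not certify
hardware-level prediction accuracies on real roots.

Other known limitations: the band model makes spectra nearly linear in the
traits, which flatters linear PLS relative to SVM/XGB (on real fresh-root
spectra tree ensembles often win); REML assumes homogeneous residual
variance across environments; and kappa on a 100-clone universe moves in
steps of 1/16 at a 20% selected fraction, so small-sample kappas are coarse.
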