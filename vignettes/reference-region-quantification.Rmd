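---
title: "Reference-region quantification of synaptic density PET: models, simulation design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-region quantification of synaptic density PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`refkin` validates noninvasive quantification of [18F]SynVesT-1, a PET
radiotracer for the synaptic vesicle glycoprotein 2A (SV2A) used as an in
vivo proxy for synaptic density. The gold-standard analysis requires
arterial blood sampling to build a metabolite-corrected arterial input
function (AIF) and a 120-minute scan — both burdensome in elderly and
movement-disorder populations. The package implements the full
quantification chain (blood processing, compartment and reference-tissue
models, voxelwise parametric imaging) together with a synthetic-data
generator, so that the agreement between invasive and noninvasive methods,
group comparability, and the effect of shortening the scan can all be
studied under known ground truth.

## Models

**One-tissue compartment model (1TCM).** Tissue activity follows
$C_T(t) = K_1 \, (C_P \otimes e^{-k_2 t})(t)$, where $C_P$ is the
metabolite-corrected plasma input, $K_1$ (mL/cm³/min) the influx rate and
$k_2$ (1/min) the efflux rate. The total volume of distribution is
$V_T = K_1/k_2$. Binding potential relative to the nondisplaceable
compartment uses the centrum semiovale (CS), a white-matter region with
minimal SV2A expression, as the reference:
$BP_{ND} = V_T^{ROI}/V_T^{CS} - 1$.

**SRTM.** The simplified reference tissue model removes the blood input by
using the reference TAC $C_R$:
$C_T = R_1 C_R + (k_2 - R_1 k_{2a})\, (C_R \otimes e^{-k_{2a} t})$,
with $R_1 = K_1/K_1'$, $k_{2a} = k_2/(1 + BP_{ND})$. Three parameters
$(R_1, k_2, BP_{ND})$ are estimated per region.

**SRTM2.** Fixing the reference efflux constant $k_2'$ reduces the model to
two parameters $(R_1, k_{2a})$:
$C_T = R_1 C_R + R_1 (k_2' - k_{2a})\, (C_R \otimes e^{-k_{2a} t})$, with
$BP_{ND} = R_1 k_2' / k_{2a} - 1$. Two policies for $k_2'$ are supported:
a population value (`pop`: the mean CS $k_2$ from 1TCM fits across
subjects), and a coupled fit (`coupled`: one shared $k_2'$ estimated
jointly across all grey-matter regions of a subject, then fixed for
per-region refits — the two-step procedure).

**Logan reference plot.** Ordinary least squares of
$\int_0^t C_T / C_T$ on $[\int_0^t C_R + C_R/k_2'] / C_T$ over frames with
mid-time $\ge t^*$ (default 30 min); the slope is the distribution volume
ratio, $BP_{ND} = DVR - 1$.

**Frame weights.** All fits are weighted by a count-statistics model,
$w_i = (\Delta t_i d_i)^2 / \max(C_i \Delta t_i d_i, \varepsilon)$ with
$d_i$ the F-18 decay factor (half-life 109.77 min) at the frame mid-time,
normalized to mean one. Parameter uncertainty is reported as relative
standard error (rSE, %) from the Gauss–Newton covariance scaled by the
weighted residual variance; derived quantities ($V_T$, SRTM2 $BP_{ND}$) use
the delta method.

## Blood processing

The automatic-sampler whole-blood curve (1-s sampling over 0–22 min) is
corrected for the tubing delay by time-shifting and for dispersion by
inverting the monoexponential kernel $(1/\tau)e^{-t/\tau}$ via
$c_{true} = c_{meas} + \tau \, dc_{meas}/dt$. The derivative uses a 3-point
centered stencil after a 5-sample moving average — a deliberate bias/noise
compromise for 1-s data; the round trip (apply then correct, τ = 5 s,
delay = 10 s) recovers smooth curves within 1% RMS of peak. τ and the delay
are inputs (known exactly in simulation, user-measured for real data);
estimating the delay from data is out of scope. The corrected curve is
converted to plasma with the fitted plasma-to-whole-blood ratio (constant
by default, linear drift optional), merged with the manual plasma samples
(linear interpolation between samples after the sampler window, log-linear
extrapolation beyond the last sample at 110 min), and multiplied by a Hill
parent-fraction curve $pf(t) = 1 - (1-pf_\infty)t^h/(t_{50}^h + t^h)$
fitted to the measured fractions from eight fixed starts with box bounds
($pf_\infty \in [0,1]$, $t_{50} \in (0,500]$, $h \in (0,10]$). The −5 min
baseline sample is background and never enters any fit.

## Numerical choices

* All convolutions run on a uniform 1-s grid using the exact per-step
  analytic update for piecewise-linear inputs (a first-order recursive
  filter), avoiding FFT edge effects on short scans.
* Frame averages of convolved curves use the identity
  $\int_{frame} C = (\int_{frame} u - \Delta C)/k$, which is exact for the
  piecewise-linear discretization and needs the convolution only at frame
  boundaries.
* The measured reference TAC enters SRTM-family convolutions after
  piecewise-linear interpolation to the fine grid, anchored at zero at
  injection; the direct $R_1 C_R$ term uses the measured frame values.
* Nonlinear fits are bounded Levenberg–Marquardt (`minpack.lm`) from fixed
  multi-start lists; where a parameter enters linearly ($K_1$, $R_1$) it is
  profiled over a log grid of the decay constant to seed the polish. Best
  weighted RSS wins; ties break by start order; solutions at a box bound
  are flagged. Bounds: $K_1 \in (10^{-4}, 2]$, $k_2 \in (10^{-4}, 1]$,
  $R_1 \in (0.05, 3]$, SRTM $BP_{ND} \in (-0.9, 20]$.
* The coupled SRTM2 fit minimizes the summed per-region weighted RSS over
  the shared $k_2'$ by golden-section search; at each candidate $k_2'$ the
  inner per-region problem is solved exactly (profiled $R_1$ over a
  precomputed 80-point log grid of $k_{2a}$, then a bracketed 1-D
  refinement). This is the same optimum as a joint nonlinear fit over
  $1 + 2 \times n_{ROI}$ parameters, reached far more robustly.
* Voxelwise SRTM2 uses basis functions: 100 log-spaced $k_{2a}$ values in
  [0.006, 0.6] 1/min (covering $BP_{ND} \in (-0.5, 20)$ at
  $k_2' = 0.037$), a weighted 2-parameter linear solve per voxel and basis,
  discrete minimization over the grid with one parabolic refinement step in
  $\log k_{2a}$, and the apparent efflux derived from the fitted
  coefficients ($k_{2a} = k_2' - \theta_2/\theta_1$) so that voxels
  indistinguishable from the reference get $BP_{ND} = 0$ rather than an
  arbitrary grid value. Only final $BP_{ND}$ values outside $(-0.9, 30]$
  are clamped and counted; negative convolution coefficients are allowed
  (legitimate when $k_{2a} > k_2'$).
* Logan integrals are trapezoids over frame mid-points anchored at
  $(0, 0)$, with eligibility by frame mid-time $\ge t^*$.
* The 1TCM has no blood-volume term by default (none is used in the
  analysis this package mirrors); the spillover-free synthetic data make it
  unnecessary.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions.

* **Schedule.** 6 × 30 s, 3 × 60 s, 2 × 120 s, 22 × 300 s — 33 contiguous
  frames totaling 120 min. (The acquisition protocol this mirrors lists
  these durations; their count is 33, and that is what the package uses.)
* **Input function.** Feng-type bolus: linear rise to a peak ~1 min post
  injection (default peak 132 kBq/mL, rise slope 300 kBq/mL/min), then a
  tri-exponential decay with rates (4, 0.25, 0.015) 1/min and amplitudes
  (100, 20, 12) kBq/mL, putting the 90-min tail near 2% of peak. No
  published plasma peak or parent-fraction time course exists for this
  tracer in this population, so these are plausible, configurable
  placeholders.
* **Metabolism.** Hill parent fraction with $pf_\infty = 0.2$,
  $t_{50} = 20$ min, $h = 1.5$; measurement noise additive Gaussian
  SD 0.02, clipped to [0, 1]. Plasma/whole-blood ratio constant at 1.25
  (no time dependence is modeled by default; a linear drift is available).
* **Reference region.** CS $k_2 \sim N(0.036, 0.006)$ (controls) or
  $N(0.037, 0.005)$ (patients), truncated above 0.01 1/min; CS
  $V_T \sim N(3.6, 0.9)$ and $N(3.5, 0.4)$ mL/cm³ — the anchors for the
  whole validation.
* **Target regions.** 28 grey-matter labels with true $BP_{ND}$ spanning
  0.5–4.5, multiplied by 0.85 in the patient group (a global synaptic-loss
  factor; the affected subset and factor are configurable) and by
  per-subject log-normal jitter (SD 0.05). Regions are parameterized by the
  influx ratio $R_1 \sim N(2.0, 0.2)$ truncated to [0.5, 2.8]: region
  $K_1 = R_1 K_1^{CS}$ and $k_2$ follows from $K_1/V_T$. This keeps
  grey-matter influx nearly constant across binding levels (perfusion, not
  binding, sets $K_1$) and all true parameters inside the fit bounds.
* **Noise.** Per-frame Gaussian with
  $SD = scale \cdot \sqrt{C_i/(\Delta t_i d_i)}$, seeded and clipped at
  zero. At the default activity scale, `scale = 0.05` produces late-frame
  coefficients of variation near 1% for hot regions — mild, ROI-level
  noise. Voxel-level phantoms use `scale = 0.3`, giving per-voxel CV of
  roughly 5–10%.
* **Blood data.** Automatic sampler: the true whole-blood curve with the
  subject's dispersion (τ = 5 s) and delay (10 s) applied, 1-s sampling,
  0–22 min. Manual samples at 2.5, 7, 12, 15, 20, 30, 45, 60, 90 and
  110 min. Blood amplitude noise is off by default (configurable CV).
* **Seeds.** Every stochastic operation takes an explicit seed; cohorts
  derive per-subject and per-curve streams from the master seed, so a
  cohort regenerates bitwise-identically.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: scanner resolution and partial-volume
effects, attenuation/scatter and reconstruction artifacts, inter-frame
motion, spill-in into the white-matter reference region, true biological
heterogeneity of metabolite kinetics, and any deviation of tissue kinetics
from the one-tissue model. The synthetic tissue *is* 1TCM by construction,
so reference-method agreement here is a consistency check of estimators
under the model, plus noise — not evidence about model adequacy in vivo.
In particular, the small negative bias that real SRTM2 shows against 1TCM
(driven by CS specific binding and resolution effects) is not reproduced;
on synthetic data the methods are nearly unbiased when $k_2'$ is close to
truth, and the phantom's voxelwise maps show a small noise-induced
*positive* bias at high $BP_{ND}$ instead (a Jensen effect of $1/k_{2a}$).

## Statistical analyses

Method agreement is assessed per subject: OLS regression of a method's
$BP_{ND}$ on 1TCM $BP_{ND}$ across regions (OLS, not Deming, matching the
convention of the analysis mirrored here; both variables are estimates, so
slopes are mildly attenuated by noise in the 1TCM axis), pooled regression
across all points, and percent bias
$100 (BP_{ND} - BP_{ND}^{1TCM})/BP_{ND}^{1TCM}$ summarized across regions
within subject first, then across subjects and groups. Group differences
use Welch's unequal-variance t-test on subject-level means (n = subjects,
not regions, to avoid pseudo-replication); identical degenerate groups get
p = 1 by convention. No multiple-testing correction is applied — these are
descriptive validation analyses, not confirmatory hypothesis tests. Time
stability truncates each scan to $t_{max} \in \{40, 60, 80, 90, 100\}$ min
(whole frames only), refits, and reports percent bias against the same
method's full-length estimate; subjects with short scans take part in all
comparisons but are excluded from the population $k_2'$ by default.

## Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` use: a deterministic noiseless
28-region subject (CS $k_2 = 0.037$, $V_T = 3.5$) for oracle recovery of
every model; 20 replicate cohorts of 3 + 5 subjects at noise scale 0.05
for the agreement study; one 7-subject cohort for time stability; and
20 × 20 × 10 phantoms (4000 voxels, 10 regions) for voxelwise consistency.
These sizes keep each stage to seconds–minutes while leaving Monte-Carlo
margins well inside the asserted tolerances.

## Known limitations

* Delay and dispersion constants are inputs, not estimated.
* No 2-tissue models, no Patlak, no blood-volume term, no partial-volume
  correction, no atlas handling (region identity is a label).
* The dispersion inversion amplifies high-frequency noise; with noisy
  sampler data a stronger smoother (or regularized deconvolution) would be
  needed.
* Coupled-$k_2'$ estimates inherit the usual identifiability weakness when
  all regions share similar $k_{2a}$; the synthetic cohort's spread of
  binding levels is favorable in this respect.
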