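---
title: "Multiparametric MRI biomarkers of antiangiogenic therapy: models, phantom calibration and recovery"
author: "gliomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric MRI biomarkers: models and phantom calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomark)
```

## Scope

`gliomark` implements the quantitative-MRI biomarker panel used to monitor
anti-angiogenic (VEGFR-inhibitor) therapy response in orthotopic mouse
glioma — tumor volume, T2, ADC, SPION-based relative cerebral and
microvascular blood volume (rCBV/rMBV), the relative vessel caliber index
(rVCI), and DCE-derived K^trans^ and ν~e~ — together with a digital
mouse-brain phantom generator whose two-arm longitudinal cohorts carry
known, adjustable group effects. Because no animal images are deposited
anywhere, validation is by *parameter recovery*: the generator encodes
arm-level effect sizes, and the package must recover them through the full
forward-simulate → fit → summarize chain, never by reading the encoded
values.

## Signal models

**Relaxometry.** Multi-echo spin-echo and gradient-echo magnitudes follow
$S(TE) = S_0 e^{-TE \cdot R}$ with $R = R_2 = 1/T_2$ (spin echo) or
$R_2^* = 1/T_2^*$ (gradient echo). An intravascular iron-oxide agent
(SPION, $r_2 = 40\ \mathrm{mM^{-1}s^{-1}}$) adds a steady-state rate
offset, so $\Delta R_2^{(*)} = R^{(*)}_{2,\mathrm{post}} -
R^{(*)}_{2,\mathrm{pre}}$ is proportional to blood volume —
$\Delta R_2^*$ weighted toward all vessel calibers (rCBV),
$\Delta R_2$ toward microvessels (rMBV). The default fit is weighted
least squares on $\log S$ with weights $S^2$ (the first-order variance
correction after the log transform); `method = "nlls"` refines it with
Levenberg–Marquardt. Voxels whose first-echo signal falls below
$3\hat\sigma$ are excluded, with $\hat\sigma$ estimated from in-plane
corner air patches via the Rician background mean
$\mathbb{E}[M] = \sigma\sqrt{\pi/2}$. Fitted rates must be positive; a
constant echo train is degenerate and marked invalid. Echo trains default
to TE = 10–100 ms (10 echoes, SE) and 2.5–20 ms (8 echoes, GRE).

**Diffusion.** $S(b) = S_0 e^{-b \cdot ADC}$ at $b = 0, 756, 1506\
\mathrm{s/mm^2}$, fitted by ordinary least squares on $\ln S$ versus $b$
(unweighted, matching the stated method). The estimate is invariant to
global scaling and b-value order; ADCs outside $(0, 10^{-2})\
\mathrm{mm^2/s}$ are rejected.

**Relative vessel caliber index.** Per ROI,
$\mathrm{VCI} = ADC^{1/2}\,(\Delta R_2^*/\Delta R_2)^{3/2}$ up to
constants that cancel in the tumor-over-contralateral-cortex ratio
$\mathrm{rVCI}$. The exponents are configurable
(`vci_exponents`); `(0, 1, -1)` selects the pure blood-volume ratio
$Q = \Delta R_2^*/\Delta R_2$. We default to the vessel-size-index power
law because it is the canonical form and because it alone satisfies the
physical requirement that an *equal* fractional change of both
blood-volume weightings (no caliber change) leaves rVCI unchanged — a
property the test suite asserts. ROI means are taken before the power law;
voxelwise VCI with its noisy $\Delta R_2$ denominator is available behind
a flag.

**DCE.** The bi-exponential arterial input function
$C_p(t) = D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ drives the two-compartment
tissue concentration (closed form, with the $k_{ep} \to m_i$ removable
singularity handled by its limit $a_i\,t\,e^{-m_i t}$ below
$|m_i - k_{ep}| < 10^{-8}\ \mathrm{min^{-1}}$):
$$C_t(t) = D\,K^{trans}\sum_{i=1,2} a_i\,
\frac{e^{-k_{ep}t} - e^{-m_i t}}{m_i - k_{ep}},\qquad
k_{ep} = K^{trans}/\nu_e,$$
then $R_1(t) = R_1(0) + r_1 C_t(t)$ and the spoiled-gradient-echo signal
$S \propto \sin\alpha\,(1 - e^{-TR\,R_1})/(1 - \cos\alpha\,e^{-TR\,R_1})$
with TR = 50 ms, $\alpha$ = 35°, 4.8 s frames, injection ≈ 30 s after the
start. Fitting is bounded Levenberg–Marquardt over
$(K^{trans} \in [0, 10]\ \mathrm{min^{-1}},\ \nu_e \in (0,1),\ s)$,
multi-started on a 3×3 log grid, ties broken by lowest residual then
lowest $K^{trans}$; the scale $s$ absorbs global calibration, so the fit
is signal-scale invariant. The same model primitives serve the forward
simulator and the fitting path, and an independent trapezoidal-convolution
oracle verifies the closed form to $10^{-6}$ relative.

The AIF constants are deliberately *placeholders* — the classic
bi-exponential plasma values $a_1 = 3.99, a_2 = 4.78\ \mathrm{kg/L}$,
$m_1 = 0.144, m_2 = 0.0111\ \mathrm{min^{-1}}$ — because the empirically
measured rodent constants the protocol refers to are not printed in any
accessible source here. `load_config(strict = TRUE)` therefore refuses to
run without an explicit `aif` block. Recovery results are unaffected by
the particular constants since forward and inverse paths share them.
$R_1(0)$ is fixed from config (default $1/1.9\ \mathrm{s^{-1}}$, a
plausible brain value at 9.4 T) since the protocol includes no
pre-contrast T1 mapping; $r_1 = 3.3\ \mathrm{mM^{-1}s^{-1}}$ is likewise a
documented high-field Gd-DTPA anchor.

**IVM permeability.** From a fluorescence line profile perpendicular to a
vessel of radius $r$: $P = (1-HT) \cdot \frac{r}{2}\,
\frac{d}{dt}\big[\tfrac{1}{r}\int_{|x|>r} F\,dx\big] / (F_v - F_i)$, the
slope of the lumen-excluded extravascular line integral normalized by the
plasma-to-interstitium contrast. The two sides of the lumen are
integrated separately, the hematocrit multiplier defaults to 1, and the
estimate is invariant to uniform affine intensity recalibration.

## The phantom cohort and its calibration

A phantom is a 64×64×11 grid at 150 µm × 150 µm × 0.5 mm holding a
spherical tumor (day-0 radius 1.1 mm, i.e. a 2–3 mm-diameter lesion) in
one hemisphere, a fixed 1 mm contralateral-cortex reference sphere, and a
3-voxel in-plane air border used for noise estimation. Baseline tissue
values (editable via `cohort_spec(tissue = ...)`): cortex T2 = 40 ms,
T2\* = 28 ms, ADC = 7×10⁻⁴ mm²/s, ΔR2 = 5 s⁻¹, ΔR2\* = 25 s⁻¹; tumor
T2 = 52 ms (anchored so the control arm reaches ≈ 52.8 ms on day 2),
T2\* = 35 ms, ADC = 7×10⁻⁴, ΔR2 = 6, ΔR2\* = 30 (day-0 blood-volume
ratios 1.2), K^trans^ = 0.1 min⁻¹, ν~e~ = 0.3. ADC, ν~e~ and K^trans^
anchors are literature-style values, not study claims.

Noise is Rician on magnitudes (Gaussian on the complex channels), with
sigma expressed as a fraction of the mean baseline tissue signal;
`noise_sigma = 0.02` is SNR 50, the level used throughout.

**Group-effect profiles.** Each arm ships day-2/day-0 multiplicative
factors: control — volume 2.30, ΔR2\* 1.141, ΔR2 0.794, T2 1.016,
ADC 0.976, K^trans^ 1.063, ν~e~ 0.972; cediranib — volume 1.94,
ΔR2\* 0.835, ΔR2 0.608, T2 0.914, ADC 0.938, K^trans^ 0.657, ν~e~ 0.684.
These factors emulate published effect sizes of VEGFR-inhibitor therapy in
the orthotopic U87 model. Per-animal factors are drawn log-normally
(mean-preserving) around them with per-biomarker coefficients of variation
back-derived from the published per-arm SEMs under an assumed n = 8/arm
($CV = SEM\sqrt{n}/(100 f)$): e.g. control ΔR2\* CV 0.057, cediranib ΔR2
CV 0.27, T2 CVs 0.036/0.043, ADC CVs 0.090/0.075, K^trans^ CVs 0.42/0.435,
volume CVs 0.41/0.51. A single pooled CV cannot work: it would make the
ADC arm difference spuriously significant, whereas the emulated statistics
(significant T2 arm difference, non-significant ADC difference at the same
n) require exactly this heteroscedasticity. Baseline day-0 values carry a
10 % between-animal CV (cortex 5 %). The rVCI has no factor of its own —
it is a deterministic function of the ΔR2\*, ΔR2 and ADC factors — and the
ex-vivo water content uses an 80 % anchor with the treated arm 6.3 %
lower (relative) and a small per-visit weighing jitter.

Day-2 tumor radii scale as the cube root of the drawn volume factor,
capped at 2.2 mm so growth stays inside the field of view
(skull-constrained growth; the cap affects well under 1 % of draws).

**What the generator does not emulate.** Homogeneous spherical tissue:
no partial volume, intratumoral heterogeneity, necrosis, hemorrhage,
motion, or B0/B1 inhomogeneity, and no session-to-session registration
error (ROIs are per-session and only ROI summaries are compared, never
voxelwise differences). Passing recovery tests therefore demonstrates
estimator correctness and pipeline integrity under the encoded
conditions, not robustness to those confounds.

## Numerical and design choices

* **Coordinates/formats:** NIfTI-1 with JSON sidecars (BIDS-like keys);
  the sidecar is authoritative for echo times, frame timing and voxel
  geometry; masks live in the voxel space of their series. Signal units
  are arbitrary throughout — every biomarker is a ratio or a fitted rate.
* **Negative ΔR voxels** (noise) stay in ROI means unbiased but are
  flagged; clamping at zero exists for display only.
* **Pre-SPION T2** feeds the edema biomarker (iron oxide would confound
  it); echo-1 exclusion for gradient-echo fits is not applied.
* **Tumor segmentation:** hyperintensity threshold at cortex mean +
  2 SD on a RARE-style T2-weighted volume simulated at an effective
  TE of 60 ms (a RARE factor of 16 implies a long effective echo time; a
  10 ms contrast would be unrealistically flat). At SNR 50 the 2-SD
  threshold admits ≈ 2 % scattered salt voxels across the brain, so the
  largest 6-connected component is kept by default — both `k` and the
  cleanup are configurable. A known interaction worth keeping: under the
  treated arm's T2 reduction an unlucky baseline draw can leave day-2
  tumor T2 near cortex T2, collapsing segmentation contrast for that
  animal — exactly the failure mode hyperintensity segmentation has under
  anti-edema therapy.
* **Injection timing** is taken from the series; when absent it is
  detected as the argmax of the baseline-z-scored signal derivative.
* **Statistics:** one-way ANOVA (two arms) on per-animal percent changes
  with a closed-form F (unit-tested against `stats::aov` and $t^2$);
  SEM = SD/√n everywhere; tumor volume reported as percent of baseline,
  all other biomarkers as signed percent change, both conventions behind
  an explicit flag. No multiple-testing correction is applied across
  biomarkers, matching common practice in these panels.
* **Determinism:** every random stream derives from one integer seed via
  a multiplicative-congruential tag hash (`derive_seed`), so cohorts,
  visits and pulse sequences are independently reproducible and a rerun
  of any stage is bit-identical.

## Problem sizes used in validation

The shipped validation runs use the full acquisition geometry (64×64×11,
10/8-echo trains, 3 b-values, 100 DCE frames) with n = 8 animals per arm
at SNR 50 — about 15 s per two-arm study on one core. Unit and property
tests use a reduced 40×40×9 geometry and 10⁴-voxel Monte-Carlo panels
(median T2/ADC bias < 2 % at SNR 50; DCE K^trans^ median |error| < 5 % at
5 % noise over 200 replicates); the ANOVA null calibration uses 10⁴
simulated cohorts (type-I error 0.05 ± 0.01).

## Known limitations

* rVCI is *derived*: because the generator encodes the published ΔR2\*,
  ΔR2 and ADC effects faithfully, the implied rVCI change
  ($\approx +70\%$ for the control arm under the default exponents)
  follows mathematically and is what the pipeline recovers; the published
  group-mean rVCI changes in this model (≈ +34 %) are not jointly
  consistent with the published blood-volume changes under any fixed
  power law, presumably because group averaging does not commute with
  the ratio formula in heterogeneous real data.
* Arm means of the widest-CV biomarkers (tumor volume, K^trans^) carry
  the full calibrated between-animal spread (SEM ≈ ±33 and ±10–16 points),
  so any single simulated cohort legitimately lands anywhere in that
  band.
* The Tofts model here is the standard form without a plasma-volume
  term; reference-region methods, measured AIFs and T2\*-leakage
  correction are out of scope, as are DICOM ingestion and inter-session
  registration.

```{r example, eval = FALSE}
# a complete miniature study
spec <- cohort_spec(n_per_arm = 4, seed = 7, noise_sigma = 0.02,
                    grid_dim = c(40, 40, 9), tumor_center_vox = c(13, 20, 5),
                    tumor_radius_mm = 0.8, cortex_radius_mm = 0.8,
                    max_tumor_radius_mm = 1.3)
res <- run_full(spec, protocols = c("ssc", "dwi", "t2w"))
res$changes
res$comparisons$t2_ms
```
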