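---
title: "Aggregate g-ratio mapping: model, calibration, and what the simulations establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate g-ratio mapping: model, calibration, and what the simulations establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggratio)
```

## The model

The g-ratio of a myelinated axon is the ratio of its inner (axonal) to outer
(axon plus myelin sheath) radius, $g = R_I/R_O$. It is a key determinant of
conduction velocity, with a healthy optimum around 0.6–0.8. MRI cannot
resolve single axons, but under the standard three-compartment white-matter
model — myelin (MVF), axonal (AVF) and extracellular (EVF) volume fractions
with $\mathrm{MVF}+\mathrm{AVF}+\mathrm{EVF}=1$ — a voxel-level *aggregate*
g-ratio can be defined from the volume fractions alone:

$$ g = \sqrt{1 - \frac{\mathrm{MVF}}{\mathrm{MVF}+\mathrm{AVF}}}
     = \sqrt{\frac{\mathrm{AVF}}{\mathrm{AVF}+\mathrm{MVF}}}. $$

For a single fibre with circular cross-section this reduces exactly to
$R_I/R_O$; for a voxel it is a fibre-area-weighted summary of the microscopic
g-ratios, and it is invariant to a common rescaling of MVF and AVF (i.e. it
does not depend on the fibre volume fraction). `g_from_volume_fractions()`
implements this; `aggregate_from_population()` aggregates an explicit axon
population (per-axon $R_I$, $R_O$, plus a packing fraction) by direct area
summation and returns both the aggregate g and the fibre-area-weighted mean
of the microscopic g-ratios, which coincide exactly for uniform-g
populations.

Diffusion MRI measures the axon *water* fraction
$\mathrm{AWF} = f_{AW}/(f_{AW}+f_{EW}+f_{CSF})$, not the AVF, because myelin
water is invisible at typical diffusion echo times. Two conversions close the
gap (`awf_from_noddi()`, `avf_from_awf()`):

$$ \mathrm{AWF} = \nu(1-\nu_0), \qquad
   \mathrm{AVF} = (1-\mathrm{MVF})\,\mathrm{AWF}, $$

with $\nu$ and $\nu_0$ the stick and isotropic signal fractions of a
NODDI-style three-compartment fit. The rescaling to AVF is exact only when
the entire bound (macromolecular) proton pool belongs to myelin; the
four-pool bookkeeping in `voxel_composition()` exposes this assumption as the
non-myelin bound fraction `f_bnm`, which defaults to zero.

## Calibration

Histology supports an approximately linear relation between myelin
biomarkers $M$ (MWF, BPF, MTsat, MTV, ...) and the MVF:
$\mathrm{MVF} = \alpha M + \beta$, with hardware- and protocol-dependent
coefficients that are unknown in vivo. Single-point calibration (SPC)
collapses both unknowns into one effective constant estimated in a reference
ROI, $\alpha_{\mathrm{eff}} = \mathrm{MVF}^\*/\langle M\rangle_{ROI}$, after
which calibrated maps are $\alpha_{\mathrm{eff}} M$ with no offset.

* `spc_mvf()` sets $\mathrm{MVF}^\*$ to a literature reference MVF.
* `spc_gratio()` chooses $\mathrm{MVF}^\*$ so that the ROI-level aggregate
  g-ratio, recomputed from the calibrated ROI-mean MVF and the ROI-mean AWF,
  equals a reference g-ratio (for example 0.71 in the medullary pyramid).
  The defining 1-D minimisation has a closed form: with
  $A = \langle \mathrm{AWF}\rangle_{ROI}$,
  $$ \mathrm{MVF}^\* = \frac{A\,(1-g_{\mathrm{ref}}^2)}
       {g_{\mathrm{ref}}^2 + A\,(1-g_{\mathrm{ref}}^2)}. $$
  We implement the closed form (exact and deterministic) and retain a
  bounded numerical minimiser only as an independent test oracle.

Design choices where the formulation is open:

* The ROI summary is the arithmetic mean of each input ($M$, AWF) over the
  ROI, computed first, with missing voxels excluded; an ROI without a single
  valid sample is an error.
* Calibrated values are clipped to $[0,1]$ with a logged count — clipping is
  reported, never silent.
* The ROI AWF entering the g-referenced closed form is the raw (measured)
  AWF; AWF is calibration-independent in this pipeline, so the distinction
  is moot but documented.
* Voxels with $\mathrm{MVF}+\mathrm{AVF}=0$ have no defined g-ratio and
  propagate as missing values, never as 0 or 1.
* Fraction sums are validated to 1e-9 and violations raise errors; nothing
  is silently renormalised.

## The synthetic cohort: what it emulates, and what it does not

Ground-truth volume fractions in the validation literature come from electron
microscopy of mouse nerves spanning hypo- to hyper-myelination. Those tables
are not deposited, so `build_cohort()` generates a stand-in: each sample is a
population of axons (default 500) with Gamma-distributed inner radii (shape
5, scale 0.1 µm — mean radius 0.5 µm, a realistic white-matter scale) and
microscopic g-ratios from a hierarchical Beta law. A sample-level mean g is
drawn from a Beta(5, 5) rescaled to [0.5, 0.95]; axons within the sample draw
their g around that mean with concentration 60, keeping the within-sample
spread small (so each sample respects the regime in which the aggregate and
area-weighted summaries agree to <2%) while the *cohort* spans myelin volume
fractions of roughly 0.1–0.5 — the hypo- to hyper-myelination axis. Packing
fractions are uniform on [0.55, 0.85]. Demyelination is modelled as
proportional sheath thinning, $R_O' = R_I + d\,(R_O - R_I)$: the axon is
untouched, MVF falls, and g rises — the canonical demyelination trajectory.

Biomarkers enter at the summary level by inverting the linear law,
$M = (\mathrm{MVF}-\beta)/\alpha$, with additive Gaussian noise whose default
standard deviation is **zero**: the simulation scenario this emulates is
explicitly noise-free, with unbiased references and known AVF. The default
slope/offset triples (MWF-like 1.6/0.01, BPF-like 0.8/0.05, MTV-like
1.2/0.02) are configuration, not literature facts — the source figure's
fitted coefficients are not printed in any accessible table — and are chosen
once to give one slope-dominated, one offset-bearing and one intermediate
marker.

What a green test therefore establishes: the *algebraic* behaviour of the
calibration procedures under the stated generative model — exact correction
of slope-only miscalibration, the bias-for-error trade-off under offset
miscalibration, fixed-point behaviour of the g-referenced calibration. What
it does not establish: agreement with any empirical bias/error table (the
underlying EM data are not available), behaviour under measurement noise,
fixation effects, or model misspecification of the diffusion fractions. No
MR signal formation (relaxation, magnetisation transfer, diffusion) is
simulated anywhere.

A note on parameter recovery: with biomarker noise, the noise sits on $M$,
so the unbiased recovery regression is $M$ on MVF (slope $1/\alpha$),
inverted afterwards; regressing MVF on a noisy $M$ attenuates the slope
(errors-in-variables), which the tests avoid by construction.

## Evaluation

`bland_altman()` quantifies agreement between ground-truth and MR-derived
g-ratios: bias is the mean paired difference $\delta g = g_{GT} - g_{MRI}$,
error is $1.96\,\mathrm{sd}(\delta g)$ with the sample (n−1) standard
deviation, per the original limits-of-agreement convention. Pairs with a
missing member are dropped pairwise with a reported count; fewer than two
valid pairs is an error. `run_calibration_experiment()` crosses biomarkers
with calibration modes (`none`, `g_spc`, `mvf_spc`), chaining
calibration → Eq-2 rescaling → aggregate g per sample, and reports one row
per condition; a condition whose calibration legitimately fails (e.g. an
MTsat-like proxy used uncalibrated) appears as a failed row rather than
disappearing. The reference ROI defaults to the middle tercile of true MVF
and reference values default to the exact ROI truth, matching the
unbiased-reference assumption of the simulated scenario; biased references
are a knob.

The two regimes the experiment reproduces, and which the acceptance tests
assert: under slope-only miscalibration both SPC modes correct the g-ratio
exactly (bias = error = 0 to numerical precision); under offset-dominated
miscalibration the g-referenced SPC reduces |bias| but does not reduce error
— calibration trades bias for sensitivity.

## Voxel maps

The map pipeline reads co-registered NIfTI-1 volumes, converts $\nu,\nu_0$
to AWF, applies a calibration, computes g per voxel and masks the result by
the overlap of two white-matter tissue-probability maps: a voxel survives
only where **both** probabilities strictly exceed the threshold (default
0.5, applied to each TPM independently). Strictness means a probability of
exactly 0.5 is excluded. No resampling, registration or reorientation is
performed — misaligned inputs (affine disagreement beyond 1e-4 per element,
a tolerance sized to absorb header rounding but not true misalignment) are
rejected, because residual misalignment between modalities corrupts the
fused g-ratio and its correction belongs upstream. Missing voxels are stored
as NaN and a companion mask volume is written alongside every g-ratio map.

Because no maintained NIfTI reader is available in the supported dependency
set, the package carries a deliberately minimal single-file NIfTI-1
reader/writer (3-D volumes, five common datatypes, scl slope/intercept on
read, sform affine); it is not a general NIfTI library and rejects what it
does not understand rather than guessing.

## Numerical conventions and limitations

* All fractions are dimensionless; radii are in µm; π cancels in every area
  ratio and is omitted.
* The closed forms are exact; the only tolerance-bearing comparisons are
  validator sum checks (1e-9) and the test-oracle agreements (1e-8, 1e-10,
  1e-12 as stated per property).
* Cohort generation is hermetic: the seed lives in the configuration, the
  global RNG state is saved and restored, and identical configurations give
  bit-identical cohorts.
* Unmyelinated axons are excluded from the ground truth by default (the
  `unmyelinated_fraction` knob exists because their contribution to AVF is a
  real, unresolved validation question).
* The package does not fit diffusion or relaxometry models, estimate
  $\nu/\nu_0$ from raw data, perform distortion correction or segmentation,
  or attempt two-parameter (slope + offset) calibration against histology.
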