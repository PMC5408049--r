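---
title: "Quantifying myocardial blood flow and the transmural perfusion ratio from dynamic CT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctmpi methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Dynamic contrast-enhanced CT myocardial perfusion imaging (CT-MPI) scans the
left ventricle repeatedly during the first pass of an iodine bolus and
converts the resulting time–attenuation curves (TACs) into absolute
myocardial blood flow (MBF, ml/100 ml/min). Because coronary ischaemia hits
the subendocardium first, a relative index — the transmural perfusion ratio
(TPR), subendocardial over subepicardial MBF — is a candidate marker that
should be insensitive to global under- or over-estimation of absolute flow.
`ctmpi` implements the full chain on simulated data with known ground truth:
a digital perfusion phantom, per-voxel MBF quantification, transmural
profiling, and the diagnostic statistics used to compare both indices
against an invasive fractional flow reserve (FFR) reference, where
FFR ≤ 0.80 defines a haemodynamically significant territory.

## Forward model

**Arterial input.** The arterial input function (AIF) is a gamma-variate
bolus with baseline,

$$A(t) = b + a\left(\frac{t-t_0}{\alpha\beta}\right)^{\alpha}
  e^{\,\alpha-(t-t_0)/\beta}, \qquad t > t_0,$$

normalised so that $a$ is the peak enhancement above baseline and the peak
sits at $t_0 + \alpha\beta$. The gamma-variate is the standard first-pass
model: smooth, positively skewed, and fittable from a dozen samples. Its
running integral has a closed form through the regularised incomplete gamma
function (`aif_integral()`), which makes the convolution below analytic.

**Tissue enhancement.** Tissue is modelled by a flow-scaled plug-flow (box)
impulse-residue function $R(t) = \mathbf 1\{0 \le t < T\}$: a contrast
particle entering the voxel stays for a transit time $T$ and then leaves.
The noiseless tissue curve is

$$C(t) = b_{\mathrm{tis}} + \frac{\mathrm{MBF}}{6000}
  \left[G(t-d) - G(t-d-T)\right],$$

with $G$ the AIF-enhancement integral and $d$ an arterial-to-tissue delay.
The constant 6000 is the units bridge: flow per unit tissue volume per
second multiplied by 100 ml and 60 s/min gives ml/100 ml/min. The box
residue keeps the relation between flow and the maximal upslope exact: as
long as $T$ exceeds the bolus rise time, the maximal slope of $C$ equals
$\mathrm{MBF}/6000 \times a$, so dividing the maximal model-curve slope by
the AIF maximum recovers flow — the maximal-slope readout implemented in
`compute_mbf()`.

## The phantom

`phantom_spec()` describes a short-axis annulus at 0.35 × 0.35 mm pixels
(3 mm slices) imaged in shuttle mode: two overlapping stacks at alternating
table positions, each sampled every second heartbeat (per-stack period
$2 \times 60/\mathrm{HR}$ s, caudal offset by one beat, first sample 5 s
after contrast start), 9–14 time points per stack. Defaults use 12 time
points at 83 bpm, the modal values of the emulated acquisition protocol.
The descending aorta is a homogeneous disk following the AIF; attenuation
noise is i.i.d. Gaussian (default SD 10 HU) under a single integer seed.

Each angular sector is a coronary territory (LAD/LCX/RCA) with an
epicardial plateau flow, a transmural ratio $r$, and a reference FFR.
Within a sector the transmural flow profile interpolates from
$r \times \mathrm{MBF}_{epi}$ at the endocardial border to
$\mathrm{MBF}_{epi}$ at the epicardial border. The default shape is a
*step*: two plateaus joined by a linear ramp over the central 40–60 % of
wall depth. With this construction the generated transmural ratio is, by
design, exactly the ratio that band-averaged endo/epi sampling should
recover, so phantom truth and measurement target coincide. A straight
*linear* gradient is also available (`transmural_shape = "linear"`) for
profile-shape recovery checks; under a linear blend the band-mean ratio is
mathematically larger than $r$, which is why it is not the default.

What the phantom deliberately does **not** emulate: CT projection physics
and reconstruction kernels, iodine beam hardening, partial-volume blur at
the lumen border, cardiac/respiratory motion, and vendor non-rigid
registration. Passing tests therefore demonstrate correctness of the
quantification chain under its own forward model — not robustness to
scanner artefacts.

## Estimation

**AIF.** `extract_aif()` averages the aortic region per time point of each
stack and merges both stacks ("double sampling"), doubling the temporal
density, then fits the gamma-variate by bounded Levenberg–Marquardt least
squares with data-driven starts. A bolus-free region (sample range below
10 HU) is rejected; a convergence failure falls back to raw-sample maximum
and finite-difference slope, flagged `converged = FALSE`.

**Hybrid model.** `fit_hybrid_model()` fits
$b + f\,[G(t-d)-G(t-d-T)]$ to a TAC by profiled least squares: for each
candidate $(T, d)$ on a bounded grid ($T \in [1, 30]$ s, $d \in [0, 10]$ s,
coarse grid then one local refinement) the model is linear in $(b, f)$ and
solved in closed form, with $f$ clamped to $[0, 500/6000]$ — a
physiologically generous 500 ml/100 ml/min cap. The fit is deterministic;
there is no random restart.

**Per-voxel maps and shared kinetics.** With only 9–14 noisy samples per
voxel the pair $(T, d)$ is not identifiable voxel-wise: a free per-voxel
search selects degenerate short-transit cells whose maximal-slope readout
is biased upward (about +50 % in sector means at 10 HU noise in our
simulations). `compute_mbf_map()` therefore estimates the residue shape
once per slice from the mask-mean TAC — whose noise is smaller by the
square root of the voxel count — and fits only $(b, f)$ per voxel. The
per-voxel problem is then linear in flow and the sector-mean bias drops
below 1 %. Fully independent per-voxel fits remain available via
`shared_kinetics = FALSE`.

**Regions of interest.** `measure_roi_mbf()` averages the map over a
polygonal ROI, enforcing the 50 mm² minimum area (409 pixels at 0.35 mm)
and rejecting ROIs leaving the myocardial mask.

## Transmural profile and TPR

`sample_profile()` draws one sample line per degree along the local radial
direction (the surface normal of the circular annulus; for non-circular
masks the endo/epi borders are detected along each ray from the mask), and
samples MBF at 0.4 mm depth intervals by bilinear interpolation — sub-pixel
sampling is required since the step (0.4 mm) exceeds the pixel (0.35 mm).
The mean over lines at each depth is the transmural profile.

`select_endo_epi()` supports manual depth selection (mirroring reader
picks on the profile curve) and an automatic mode averaging the profile
over 10–35 % and 65–90 % of wall depth. The excluded 10 % margins keep
samples away from the LV lumen and the epicardial border, where
displacement artefacts concentrate; the band means sit inside the
endocardial and epicardial halves, so on the step-shaped phantom the
automatic TPR equals the generated ratio. TPR is the plain ratio
`endo_mbf / epi_mbf`; thresholding is inclusive (MBF ≤ 76 ml/100 ml/min,
TPR ≤ 0.82 positive for ischaemia).

## Diagnostic statistics

* Contingency metrics are kept at full precision internally and displayed
  as integer percentages rounded half away from zero.
* Confidence intervals for territory-level proportions use a Wald interval
  with the ratio-estimator (cluster-summed) variance
  $\sum_i (x_i - \hat p n_i)^2 / (\sum_i n_i)^2$ over patients, which
  inflates the variance when territories within a patient agree and reduces
  exactly to the binomial Wald variance with one territory per patient.
* AUC uses the Mann–Whitney construction with tie correction, oriented so
  that lower MBF/TPR indicates disease; variances and the correlated-AUC
  comparison follow the DeLong placement-value decomposition with a
  two-sided normal test.
* The Youden threshold maximises $J$ over inclusive cut-points at observed
  score values; ties break toward higher sensitivity, then the lower
  threshold; perfectly separated classes return the midpoint of the
  separating gap.
* The inter-reader ICC is the single-measure two-way absolute-agreement
  coefficient, ICC(A,1) (a consistency variant is available); the group
  comparison is a pooled-variance two-sided t-test (Welch via
  `var_equal = FALSE`); the intermediate-flow sub-analysis keeps
  territories with MBF in the inclusive range 50–100 ml/100 ml/min.
* The joint MBF/TPR interpretation is reported as quadrant counts against
  the two thresholds; no single combined decision rule is asserted beyond
  the product score MBF × TPR used for its ROC curve.
* The effective-dose helper multiplies the dose–length product by
  0.014 mSv/(mGy·cm).

## Synthetic cohorts

`simulate_cohort()` draws territory-level measurements directly: 43
patients with 94 territories (2–3 each), 48 ischaemic; MBF from
N(71.3, 24.3) (ischaemic) and N(92.2, 21.6) (normal). The ischaemic TPR is
N(0.85, 0.31). Two quantities are not documented for the emulated study
and were fixed once: the normal-territory TPR, N(1.00, 0.25) — chosen so
the implied TPR AUC, $\Phi(0.15/\sqrt{0.31^2+0.25^2}) \approx 0.65$,
matches the reported discrimination — and the latent MBF–TPR correlation,
$\rho = 0.6$, reflecting that both indices derive from the same flow map.

`run_experiment()` instead runs the full imaging chain per patient:
sector layouts are drawn with territory-mean flows from the same status
distributions (the epicardial plateau is back-computed through the shape
mean $(1+r)/2$), phantoms generated, maps quantified, and each territory
measured by a sector ROI and an auto-band profile. Outputs (territory CSV,
metrics JSON, per-patient maps, log) carry an MD5 manifest; file MD5s are
an integrity record, not a cryptographic guarantee. Disabling the
quantification stage reuses cached maps byte-for-byte.

## Problem sizes and numerical conventions

The test suite and the recovery studies run phantoms at desk scale —
64–128 px grids with 4–10 mm walls and one or two slices — which keeps a
full phantom-to-TPR cycle well under a second while preserving all
geometric relations (pixel 0.35 mm, step 0.4 mm, band fractions). The
package defaults describe the realistic geometry (256 px, 20/30 mm
annulus). Voxel indices are 1-based in R with physical pixel centres at
$(i-\tfrac12)\times$ pixel size; angles are degrees counter-clockwise from
+x; all stochastic draws flow from a single integer seed per object, and
estimation itself is deterministic.

Degenerate inputs have defined behaviour: zero amplitude or flow gives
flat curves; flat TACs give zero flow; bolus-free AIF regions error;
single-voxel masks are allowed; empty masks, single-cluster CIs and
one-class ROC inputs error with explicit messages.

## Known limitations

* The estimator shares its forward model with the phantom; recovery
  results certify the implementation, not the vendor model family.
* No motion, beam hardening, or partial-volume simulation; the
  edge-artefact robustness test uses a synthetic bright rim instead.
* The cluster variance adjustment is one defensible choice among several;
  printed clinical confidence intervals are not reproduction targets.
* Slice resampling to the 3 mm / 1.5 mm display geometry is recorded in
  the map metadata but maps are computed on the native slice grid.
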