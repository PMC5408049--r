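# ctmpi — dynamic CT myocardial perfusion quantification and the transmural perfusion ratio

`ctmpi` is an R package for quantitative analysis of dynamic
contrast-enhanced CT myocardial perfusion imaging (CT-MPI), built for
methodologists who need the whole measurement chain testable against known
ground truth. Clinical CT-MPI and invasive pressure-wire data are not
public, so the package pairs every analysis stage with a digital perfusion
phantom that emulates the acquisition: a short-axis left-ventricular
annulus at 0.35 × 0.35 mm pixels, shuttle-mode sampling of two interleaved
slice stacks (9–14 time points per stack, one visit every second
heartbeat), a descending-aorta arterial input region, transmural
endo-to-epi flow gradients, sector-shaped perfusion defects and Gaussian
attenuation noise.

The quantitative core:

* **Arterial input function (AIF).** Gamma-variate bolus model
  `A(t) = b + a ((t−t₀)/(αβ))^α exp(α − (t−t₀)/β)`, fitted by bounded
  least squares to the aortic samples of both stacks merged ("double
  sampling").
* **Hybrid deconvolution / maximal-slope MBF.** Tissue enhancement is the
  AIF convolved with a flow-scaled plug-flow impulse-residue function;
  myocardial blood flow is read out as the maximal upslope of the fitted
  model curve divided by the AIF maximum, converted to ml/100 ml/min via
  `f × 6000`. Per-voxel maps share the residue kinetics estimated from the
  high-signal mean curve, keeping the voxel-level problem linear in flow.
* **Transmural perfusion ratio (TPR).** Perpendicular line samples across
  the wall at 0.4 mm intervals produce a transmural MBF profile; TPR is
  subendocardial over subepicardial MBF, selected manually or from
  automatic depth bands (10–35 % / 65–90 %) that avoid the artefact-prone
  borders. Territories are called ischaemic at MBF ≤ 76 ml/100 ml/min or
  TPR ≤ 0.82 against an invasive FFR ≤ 0.80 reference.
* **Diagnostic statistics.** Contingency metrics with cluster-adjusted
  confidence intervals (territories nested in patients), Mann–Whitney
  AUC with DeLong variances and correlated-AUC tests, Youden-optimal
  thresholds, the combined MBF × TPR score, Pearson correlation, ICC(A,1),
  Cohen's kappa, pooled t-tests, and a DLP → effective dose utility
  (factor 0.014 mSv/(mGy·cm)).

## Worked example

```r
library(ctmpi)

spec <- phantom_spec(grid_nx = 96, grid_ny = 96, endo_radius_mm = 8,
                     epi_radius_mm = 14, aorta_center = c(29.5, 5),
                     aorta_radius_mm = 2.5, n_slices = 1,
                     noise_sd_hu = 5, seed = 42)
ph  <- generate_phantom(spec)
aif <- extract_aif(ph$series)
map <- compute_mbf_map(ph$series, aif, ph$truth$sector_of_voxel > 0)

band <- wall_band(spec$lv_center, 5, 115, endo_radius_mm = 8,
                  epi_radius_mm = 14)
select_endo_epi(sample_profile(map, band))
```

The phantom's LAD sector carries a subendocardial defect (epicardial flow
91, transmural ratio 0.64, FFR 0.69). The session prints:

```
Arterial input function fit (gamma-variate)
  samples   : 12 (double-sampled over stacks)
  converged : TRUE
  max value : 300.2 HU above baseline
  max slope : 116.66 HU/s
  peak time : 12.50 s
MBF map: 96 x 96 x 1 @ 0.35 mm (slices 3.0 mm / 1.5 mm increment)
  3376 masked voxels; MBF mean 85.4, sd 17.1 ml/100 ml/min
TPR 0.65 (subendocardial 58.4 / subepicardial 89.6 ml/100 ml/min, auto selection)
```

so the fitted AIF reproduces the generating bolus (peak 300 HU at 12.5 s),
the map recovers the annulus flows, and the automatic transmural bands in
the LAD sector measure a TPR of 0.65 against the generated 0.64 — below
the 0.82 threshold, correctly positive for ischaemia.

A territory-level cohort with the full statistical battery:

```r
coh <- simulate_cohort(seed = 1)       # 43 patients, 94 territories
diagnostic_report(coh)
#> Diagnostic evaluation: 94 territories in 43 patients (48 ischaemic by FFR <= 0.80)
#>   MBF<=76    TP 31 FP  8 TN 38 FN 17 | sens 65 % spec 83 % ppv 79 % npv 69 % acc 73 % (66-81 %)
#>   TPR<=0.82  TP 29 FP 10 TN 36 FN 19 | sens 60 % spec 78 % ppv 74 % npv 65 % acc 69 % (61-77 %)
#>   ...
#>   AUC: MBF 0.86, TPR 0.74, MBF x TPR 0.83; DeLong MBF vs TPR p = 0.006
```

`run_experiment(run_config(...))` chains everything — phantom cohort →
AIF → MBF maps → territory measurements → diagnostics — with deterministic
seeds, cached map reuse and an MD5 output manifest; `recovery_study()`
sweeps transmural ratios, noise levels and global flow scalings to
quantify bias and demonstrate that TPR is invariant to global flow scaling
while absolute MBF shifts proportionally. A thin command-line wrapper
lives at `inst/cli/ctmpi.R`.

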