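# aggratio

Aggregate MR g-ratio mapping for white matter: the volume-fraction g-ratio
model, single-point calibration of myelin biomarkers, Bland–Altman
bias/error evaluation on synthetic cohorts with known ground truth, and a
NIfTI voxel-map pipeline with tissue-probability masking.

## The problem

The g-ratio of a myelinated axon — inner (axonal) over outer (axon + myelin)
radius, healthy optimum ≈ 0.6–0.8 — controls conduction velocity, but single
axons are far below MRI resolution. Under the three-compartment white-matter
model (myelin, axonal and extracellular volume fractions,
MVF + AVF + EVF = 1), a voxel-level *aggregate* g-ratio is

```
g = sqrt(1 − MVF/(MVF + AVF)) = sqrt(AVF/(AVF + MVF))
```

which equals the fibre-area-weighted mean of the microscopic g-ratios for
uniform-g populations and is independent of the fibre volume fraction.
Diffusion MRI supplies the axon *water* fraction AWF = ν(1 − ν₀) (NODDI
signal fractions), rescaled to AVF = (1 − MVF)·AWF; myelin biomarkers M
(MWF, BPF, MTsat, MTV) relate to MVF linearly, MVF = αM + β, with unknown
hardware-dependent coefficients. **Single-point calibration** fixes one
effective constant α_eff from a reference ROI — either from a reference MVF
(α_eff = MVF_ref / ⟨M⟩_ROI) or from a reference g-ratio (e.g. 0.71 in the
medullary pyramid), for which the defining minimisation has the closed form

```
MVF* = A(1 − g_ref²) / (g_ref² + A(1 − g_ref²)),   A = ⟨AWF⟩_ROI
```

The package is for researchers developing or auditing g-ratio mapping
pipelines: it makes the calibration algebra executable and testable, and
reproduces in simulation the central caution about single-point calibration
— it removes bias but can increase error.

## Worked example

```r
library(aggratio)

# 1. A synthetic cohort with known ground truth, spanning hypo- to
#    hyper-myelination, and a miscalibrated biomarker (alpha = 1, beta = 0.05)
specs  <- data.frame(kind = "M", alpha = 1, beta = 0.05, noise_sd = 0)
cohort <- build_cohort(cohort_config(n_samples = 200, seed = 1,
                                     biomarker_specs = specs))

# 2. Evaluate no-calibration vs g-referenced single-point calibration
ex <- run_calibration_experiment(cohort, modes = c("none", "g_spc"))
print(ex$table, row.names = FALSE)
#>  biomarker  mode alpha_eff          bias       error   n status
#>          m  none  1.000000 -3.928656e-02 0.005600451 200     ok
#>          m g_spc  1.178408  5.033985e-05 0.021933425 200     ok
```

The uncalibrated arm underestimates MVF by the offset, so its g-ratio is
biased high by ≈0.04; g-referenced calibration removes the bias (5e-5) but
the error roughly quadruples — calibration trades bias for sensitivity (see
the methods vignette).

Voxel maps:

```r
g <- gratio_map(myelin_map, nu_map, calib,
                mask = overlap_mask(tpm_mt, tpm_dwi, threshold = 0.5),
                nu0_map = nu0_map)
write_nifti(g, "gratio.nii.gz")
```

A CLI mirrors the stages (`simulate`, `evaluate`, `calibrate`, `map`):

```sh
Rscript -e 'aggratio::gratio_cli()' simulate --seed 1 --n 200 --out cohort.csv
Rscript -e 'aggratio::gratio_cli()' evaluate --cohort cohort.csv --out results.csv
```

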