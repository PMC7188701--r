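# dynfet

Quantification and prognostic analysis of dynamic
O-(2-[¹⁸F]-fluoroethyl)-L-tyrosine (FET) brain PET in neuro-oncology.

Amino-acid PET is acquired dynamically (0–50 min post-injection, 16 frames)
at the initial diagnosis of malignant astrocytic gliomas. `dynfet` computes
the five standard imaging biomarkers from such a series and runs the
downstream survival analysis in which they are evaluated as prognostic
markers:

* **TBR_max** — mean SUV of a 1.6 cm circular ROI centred on the hottest
  voxel of the 20–40 min summed image, divided by the healthy-brain
  reference mean (a crescent ROI over the contralateral centrum semiovale);
* **TBR_mean** — mean SUV of the 2D auto-contour at TBR ≥ 1.6 in the
  hottest voxel's transversal slice, divided by the reference mean;
* **MTV** — volume (mL) of the 3D auto-contour at TBR ≥ 1.6;
* **TTP** — time-to-peak of the tumour time–activity curve from a 2 mL
  spherical VOI: minutes from acquisition start through the frame with
  maximum mean SUV, set to the acquisition end (50 min) for steadily
  increasing curves with no identifiable peak;
* **slope** — late-phase (20–50 min) OLS slope of the TAC in SUV/h.

The statistics stage mirrors the standard biomarker workflow: ROC analysis
of each parameter against a favourable overall survival of ≥ 24 months
(empirical AUC with Hanley–McNeil SE; optimal cutoff maximizing
sensitivity × specificity), univariate Kaplan–Meier/log-rank comparisons of
PFS and OS at the derived or user-fixed thresholds, and a multivariate Cox
proportional-hazards model over the univariately significant factors.

A synthetic-data module generates digital dynamic-PET phantoms (background
ellipsoid, spherical tumour, crescent reference mask, exact frame-averaged
kinetics, truncated-Gaussian noise) and survival cohorts whose prognosis is
driven by the tumour's kinetic class (washout vs plateau TAC, exponential
OS medians 29 vs 12 months), with full ground truth recorded — so the
entire pipeline is testable without clinical data.

## Worked example

Quantify a noiseless washout-class phantom and analyse a simulated cohort:

```r
library(dynfet)

ph <- generate_phantom(noise_sigma = 0)
q  <- quantify_patient(ph$series, ph$reference_mask)
print(q)
#> Static FET PET parameters
#>   TBR_max  2.240
#>   TBR_mean 2.240
#>   MTV      4.617 mL
#>   max voxel (z,y,x) = (12, 16, 24); tumour detected: TRUE
#> Kinetic FET PET parameters
#>   TTP   11.0 min (peak identified)
#>   slope -1.8697 SUV/h
```

The phantom's tumour follows an early-peak washout curve: the pipeline
finds the peak in the frame ending at 11 min (an unfavourable TTP ≤ 25
min), a clearly negative late-phase slope, and an MTV of 4.62 mL for the
10 mm-radius tumour (analytic volume 4.19 mL; the difference is
voxelization at 3 mm spacing). Both tumour-to-brain ratios are ≈ 2.24,
the tumour's late-window uptake over the background of 1 SUV.

```r
res <- generate_cohort(cohort_config(n_patients = 60, seed = 42))
rep <- run_survival_analysis(res$cohort,
                             pipeline_config(thresholds = c(ttp_min = 25)))
rep$t3_univariate[4, c("criterion", "os_p", "os_median_fav",
                       "os_median_unfav")]
#>      criterion     os_p os_median_fav os_median_unfav
#>   ttp_min > 25 0.001760         27.52           11.84
```

Patients with TTP > 25 min (plateau-class tumours) survive a median 27.5
months versus 11.8 months for early-peak tumours (log-rank p = 0.0018),
reflecting the generator's calibration of 29 vs 12 months. The report also
contains the ROC table (`rep$t2_roc`) and the multivariate Cox stage
(`rep$t4_cox`) over the OS-significant factors.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/dynfet simulate --out data/ --seed 9 --n-patients 45
Rscript inst/cli/dynfet quantify --image pet.nii.gz --frames frames.csv \
    --ref-mask ref.nii.gz --out out/
Rscript inst/cli/dynfet survival --cohort data/cohort.csv --out report/ \
    --threshold ttp_min=25 --subgroup idh=wildtype
```

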