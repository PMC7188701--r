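---
title: "Quantification and prognostic modelling of dynamic FET PET: methods"
author: "dynfet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and prognostic modelling of dynamic FET PET: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfet)
```

# The analysis problem

Dynamic PET with the amino-acid tracer O-(2-[18F]-fluoroethyl)-L-tyrosine
(FET) is used at the initial diagnosis of malignant astrocytic gliomas to
characterize the lesion beyond anatomy. Two families of image-derived
biomarkers are in routine use:

* **Static parameters**, read off a single evaluation image summed over
  20-40 min post-injection: the maximum and mean tumour-to-brain ratios
  (TBR~max~, TBR~mean~) and the metabolic tumour volume (MTV).
* **Dynamic parameters**, read off the lesion's time-activity curve (TAC)
  over the full 0-50 min acquisition: the time-to-peak (TTP) and the
  late-phase slope.

`dynfet` implements the full chain from a 4D SUV image to these five
parameters, and the downstream prognostic analysis in which they are
thresholded by ROC analysis and evaluated against progression-free and
overall survival (PFS, OS) with Kaplan-Meier/log-rank and Cox
proportional-hazards models. A synthetic-data module generates digital
phantoms and survival cohorts with recorded ground truth, so that every
stage of the chain is testable without access to clinical data.

# Quantification model

## Units and geometry

All quantification operates on standardized uptake values
(SUV = activity concentration / (injected dose / body weight)); conversion
from Bq/mL happens once at ingest, driven by a JSON calibration sidecar.
Voxel grids are indexed (z, y, x) with physical spacing in mm; masks must
be supplied on the identical grid and are never resampled, which keeps all
geometric operations bit-exact and testable. Decay correction is assumed to
have been applied by the scanner. An optional isotropic Gaussian
pre-smoothing (FWHM in mm) is available for cross-scanner harmonization
experiments but is off by default.

## Static parameters

The evaluation image is the duration-weighted mean of all frames lying
fully inside the 20-40 min window (on the default 16-frame schema - five
1-min, five 3-min, six 5-min frames - these are the four 5-min frames
ending at 25, 30, 35 and 40 min). The healthy-brain reference is the
arithmetic mean SUV over a user-supplied mask, in practice a crescent over
the contralateral centrum semiovale; automatic reference placement is
deliberately out of scope because it is an expert-validated manual step.

* **TBR~max~** is the mean SUV of a circular in-plane ROI of diameter
  1.6 cm centred on the maximum-uptake voxel, divided by the reference
  mean. The disc is a true physical disc (centre-in-disc membership with
  anisotropy-aware in-plane distances), so the same code is correct for
  non-square in-plane spacing.
* **TBR~mean~** comes from a 2D auto-contour: the 4-connected component of
  voxels at or above 1.6 x reference mean, within the transversal slice of
  the max voxel, that contains the max voxel.
* **MTV** comes from the analogous 3D auto-contour (6-connectivity), as
  voxel count x voxel volume in mL.

Seeding the contour at the max voxel, rather than taking every
supra-threshold voxel in the field of view, is a deliberate choice: an
auto-contour is a single closed region around the lesion, and disconnected
supra-threshold tissue must not inflate MTV. Ties at the maximum are broken
toward the lowest (z, y, x) index, making every downstream quantity
deterministic. All static parameters are invariant under rescaling the
image by any positive constant, which the suite checks.

## Dynamic parameters

The tumour TAC is the frame-wise mean SUV over a 2 mL spherical VOI
(radius (3 x 2000 / 4 pi)^(1/3) = 7.82 mm) centred on the max voxel of the
evaluation image. A reference TAC over the reference mask is extracted and
exported for inspection but enters no derived statistic.

**TTP** is the elapsed time from acquisition start through the frame with
the maximum mean SUV, i.e. that frame's *end* time; ties take the earlier
frame. When the earliest maximum falls in the final frame the curve is
steadily increasing with no identifiable peak: `peak_identified` is FALSE
and TTP is set to the acquisition end (50 min). This operationalization
("earliest global-max frame is the final frame") was chosen over any
peak-prominence rule because the latter would introduce unstated
parameters. Frame-end timing makes the no-peak fallback the natural limit
of the same convention; a frame-mid-time variant is available behind the
`ttp_use_mid_time` flag for sensitivity analyses. A constant TAC yields the
first frame's end time with a warning.

**Slope** is the ordinary least-squares slope of mean SUV against frame
mid-time over the frames whose mid-times fall in the 20-50 min window (the
six 5-min frames, mid-times 22.5-47.5 min, on the default schema),
multiplied by 60 to give SUV/h. Mid-times are the standard abscissae for
frame-averaged activity. Slope is exactly shift-invariant and scales
linearly with the TAC, and the estimator recovers a noiseless linear late
phase to machine precision.

# Statistical model

## ROC thresholds

Each PET parameter is assessed against a dichotomized outcome: overall
survival of at least 24 months is *favourable*. Patients who died earlier
are *unfavourable*; patients censored alive before 24 months carry no
information about the landmark and are excluded, with the exclusion count
always reported (treating them as unfavourable would bias against
long-censored survivors).

The AUC is the empirical rank/pair-counting estimate with ties counting
1/2, auto-oriented so the reported AUC is at least 0.5 (the orientation is
returned, since in this application higher TTP is favourable while higher
TBR is unfavourable). Its standard error is the Hanley-McNeil two-sample
formula. Candidate cutoffs are midpoints between consecutive distinct
values; the optimal cutoff maximizes sensitivity x specificity, with ties
broken toward higher specificity for determinism. A subtlety worth noting:
re-running ROC on the thresholded variable gives AUC = (sensitivity +
specificity)/2 at the operating point, which can exceed the continuous
AUC when the empirical ROC curve is non-concave - thresholding is not
guaranteed to be information-decreasing in the empirical-AUC sense, and the
test suite asserts the identity rather than a monotonicity that does not
hold.

## Survival analyses

Univariate comparisons use the product-limit estimator and the two-group
log-rank test (via the `survival` package). The reported per-group median
is the earliest event time at which the survival step function reaches 0.5
or below, and is undefined (NA) when the curve never does. PET parameters
are dichotomized at their ROC-derived threshold unless a fixed threshold is
supplied (e.g. the conventional 25 min for TTP); clinical factors use their
conventional cuts (age < 70, complete resection, IDH mutant, MGMT
methylated, KPS = 100).

The multivariate Cox model (partial likelihood, Efron tie correction, Wald
inference) includes the factors that were univariately significant for OS
at alpha = 0.05 - the endpoint being modelled. TTP and MTV enter
continuously (their hazard ratios are per minute and per mL); the other
factors enter as indicators at their thresholds. Constant covariates and
complete separation are rejected with actionable errors; events-per-
covariate below 10 triggers a warning. Analyses can be restricted to a
subgroup (typically IDH-wildtype patients, the group in which kinetic
parameters carry most prognostic weight) via the configuration.

# The synthetic-data generator

## Time-activity model

Both tissue classes follow
$u(t) = b + A\,(1 - e^{-t/\tau})\,e^{-wt}$:
an uptake saturation with time constant $\tau$ (min) modulated by
mono-exponential washout $w$ (per min). With $w > 0$ the curve peaks at
$t^* = \tau \log(1 + 1/(w\tau))$ and declines - the early-peak phenotype
of aggressive gliomas; with $w = 0$ it increases monotonically toward a
plateau - the steadily-increasing phenotype. Frame values are the *exact*
closed-form time-average of $u$ over each frame interval, not point
samples, because the estimators' frame-timing conventions are part of what
must be tested. Noise is i.i.d. Gaussian per voxel and frame, truncated at
zero (the simplest noise respecting SUV non-negativity); no attempt is
made at reconstruction-correlated noise.

Washout-class tumours draw $w$ from U(0.010, 0.018) per min and $\tau$
from U(2, 4) min, giving continuous peaks at about 7-13 min, late-window
TBR near 2, and clearly negative slopes (about -1 to -3 SUV/h);
plateau-class tumours draw $\tau$ from U(8, 15) min with $w = 0$, giving
TTP = 50 min and positive slopes. During design, a variant parameterized
directly by peak time was rejected: a single-exponential washout cannot
produce a late (18-20 min) peak together with a non-flat tail, so such
curves are intrinsically unclassifiable at any realistic noise level, which
is a property of the curve family rather than of the estimator. Amplitudes
are drawn from U(2.8, 4) SUV over a background of 1 SUV, typical of FET in
high-grade glioma versus healthy brain.

## Phantom geometry

The digital phantom is a background ellipsoid (brain) with an embedded
spherical tumour (default radius 10 mm) and a contralateral in-plane
half-annulus as the reference crescent. The requested tumour centre is
snapped to the nearest voxel centre and that voxel is marked as the unique
hottest voxel by an infinitesimal (1 part in 10^9) relative boost. Real
lesions have a unique hottest voxel; without this, a perfectly uniform
ball's maximum is tied and the deterministic tie-break would place the
ROI/VOI centre at the ball's pole rather than inside the lesion. The boost
changes the extracted TAC by less than one part in 10^9 per frame.

## Cohorts

Fast (tabular) mode draws each patient's kinetic class (default 50%
washout), simulates a noisy 16-frame TAC (sigma = 0.05 SUV) and derives
`ttp_min` and `slope_suv_per_h` by running the package's own estimators on
it, so that the estimators sit inside the simulation loop. TBR and MTV,
which require an image, are drawn from class-conditional distributions
with the washout class shifted upward, reflecting the weaker prognostic
separation of static parameters. Image mode instead builds a phantom per
patient and runs the full quantification (intended for small n).

Survival is class-conditional exponential: OS medians 29 (plateau) versus
12 (washout) months and PFS medians 13 versus 7 months, with the
favourable medians assigned to the late-TTP class, matching the direction
in which TTP above 25 min is favourable. PFS is clipped to OS.
Administrative censoring times are uniform on a 24-96 month window
(roughly 15-20% censoring, as in a multi-year accrual with extended
follow-up). Covariate frequencies reflect a typical newly diagnosed
malignant-astrocytoma case mix (75% IDH-wildtype, 58% MGMT-methylated,
complete resection / partial resection / biopsy at 48/17/35%, age
~N(55, 12) truncated to 21-78 years). By default covariates are
prognostically inert (survival depends on kinetic class only); an MGMT
effect can be co-simulated via `mgmt_log_hr`, e.g. log(29/12) to mirror a
methylated-versus-unmethylated median ratio. All randomness flows through
one mandatory seed; identical seeds give bit-identical cohorts, phantoms
and downstream reports.

What the generator does *not* emulate - PET physics (scatter, randoms,
resolution, reconstruction artefacts), anatomical realism, correlated
noise, non-exponential survival, covariate-kinetics correlations - bounds
what green tests prove: they validate the estimators, the statistical
machinery, and the plumbing, not clinical performance on real images.

# Numerical and design notes

* Connected components use a vectorized seeded dilation to a fixed point;
  a brute-force queue flood fill serves as its test oracle.
* Window boundaries must coincide with frame boundaries; mismatches are
  errors listing the available boundaries rather than silent re-binning.
* The TBR~max~ disc is clipped at image borders with a warning.
* Cox convergence is declared at fewer than 100 iterations with the
  tightened tolerance 1e-9; singular designs and separated covariates are
  errors, not silent NAs.
* KM medians follow the "earliest time S(t) <= 0.5" rule stated above;
  note that some software instead reports the midpoint of the plateau when
  the curve hits 0.5 exactly.

## Validation problem sizes

The shipped validation suite exercises: MTV of a digitized 10 mm sphere at
2 mm and 0.5 mm spacing against the analytic 4.19 mL (observed errors
about 5% and 0.1%); exact TTP and slope (error < 1e-9 SUV/h) recovery on
noiseless 2 mm phantoms; TTP-class accuracy and slope bias over 500 noisy
TACs; AUC equality with pair counting over 1000 random instances
(n <= 50); KM/log-rank/Cox calibration over 500-1000 replicates
(n = 40-200); and end-to-end power and Cox-entry over 200 and 60 simulated
45-patient cohorts. At these sizes the whole suite runs in about two
minutes on a single core.

Under the default cohort calibration (n = 45, balanced classes, OS medians
29 versus 12 months, ~17% censoring) the TTP log-rank split is significant
in roughly three quarters of replicates - the Schoenfeld approximation
gives power 0.78 with ~38 events, and only a censoring-free design at this
n reaches 0.84 - so detecting this effect reliably at the 5% level needs
either the full event count or a somewhat larger cohort. The acceptance
suite reports the measured proportion as-is rather than resizing the
cohort to force significance.

# Limitations

* No DICOM ingestion, registration, resampling or partial-volume
  correction; inputs must share one voxel grid.
* Reference-region placement is the user's responsibility.
* No compartmental kinetic modelling (Patlak/Logan) - TTP and slope are
  deliberately model-free summaries.
* The Cox stage performs no proportional-hazards diagnostics and no
  multiple-testing correction, mirroring common practice in this
  biomarker literature; interpret multivariate p-values accordingly.
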