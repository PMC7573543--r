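---
title: "Phantom-calibrated radiomics for HEAML vs HCC/FNH: models and design choices"
author: "PhantomRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-calibrated radiomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hepatic epithelioid angiomyolipoma (HEAML) is a rare, potentially malignant
liver tumour that is easily confused on contrast-enhanced CT and MRI with
two far more common blood-rich lesions, hepatocellular carcinoma (HCC) and
focal nodular hyperplasia (FNH). A radiomics approach extracts a large panel
of quantitative texture descriptors from the lesion's region of interest
(ROI) on the arterial-phase image, screens them, and learns a *radiomics
signature* — a machine-learned HEAML probability — which is then fused with
routine clinical covariates (sex, age, maximum diameter, tumour location,
alcoholism/smoking) in a logistic model and delivered to clinicians as a
nomogram.

Patient images for this task are not publicly available. The package
therefore ships a first-class phantom cohort simulator whose clinical
covariates are calibrated to the published class-conditional statistics and
whose lesion textures are controllable, so that every stage of the pipeline
— and the qualitative claims about it — can be tested end to end.

## The phantom cohort generator

`generateClinicalCohort()` draws, per subject and independently, sex, lobe
and alcoholism/smoking as Bernoulli variables and age and maximum diameter
as positive-truncated Gaussians (truncation by redraw), using per-class
`ClassProfile` parameters. The HEAML profiles equal the published HEAML
column of the clinical characteristics table for each modality (CT: 79%
female, age 47.7 ± 10.4 y, diameter 4.4 ± 1.8 cm, 89% left lobe, 11%
alcoholism/smoking; analogously for MRI). The published non-HEAML column
pools HCC and FNH; the package's HCC and FNH sub-profiles are package
defaults chosen so that the enrolment-weighted mixture (CT 78:59, MRI 77:30)
reproduces the printed non-HEAML numbers within rounding, with HCC
male-dominant and older and FNH predominantly female and younger. Default
cohort sizes follow the enrolment counts (CT 33/78/59, MRI 30/77/30).

`generatePhantom()` renders each lesion as a filled axis-aligned ellipse
(eccentricity 0.7) whose major axis matches the subject's diameter to within
one pixel. In-mask intensity is

    base + field + noise,

where `field` is white noise smoothed by a Gaussian kernel of SD
`correlationLength` (pixels) and rescaled so its peak-to-peak swing is twice
`heterogeneityAmp` (the amplitude is half the swing — a *range*, not an SD:
under range-relative discretization this makes the correlation length map
monotonically onto NGTDM coarseness, which is the point of the dial), and
`noise` is i.i.d. Gaussian with SD `noiseSd`. The background is a distinct
constant (55% of base) plus the same noise. Gray values are rounded to
integers, emulating quantized scanner output; this also makes the NIfTI and
16-bit PNG dialects bit-equivalent. In `generateStudy()` the *rendered*
diameter is capped at 90% of the field of view and floored at 5 px (so the
ROI always has the >= 9 pixels the texture matrices need); the clinical
table keeps the unclipped value.

Default texture profiles come in two settings: `"separable"` (HEAML
smoother, stronger heterogeneity: correlation length 6 px and amplitude/noise
~4, vs 2–2.5 px and ~1.3 for HCC/FNH) — the documented strong-separation
condition — and `"identical"`, under which images carry no class signal and
downstream AUCs must sit at chance.

What the phantoms do *not* emulate: scanner physics, contrast kinetics,
partial-volume and motion artefacts, inter-observer segmentation
variability, and any real correlation between clinical covariates and lesion
texture. Passing recovery tests on phantoms therefore validates the
*pipeline machinery*, not clinical performance on patients.

## Preprocessing

Images are resampled to a common spacing (default 1 x 1 mm, a config value —
the source protocol resamples without stating a target) by separable
*natural cubic splines*; masks by nearest neighbour so they stay binary.
Natural splines reproduce constants and linear ramps exactly, which the
tests exploit as closed-form oracles. For thin stacks, `selectSlice()`
implements the maximum-diameter protocol: the slice with the largest in-mask
area, ties to the lowest index.

ROI intensities are discretized with a *fixed bin count* (64 by default,
matching the protocol's "64 bins" wording) over the in-mask range:
`bin(x) = floor((x - min)/(max - min) * n) + 1`, max mapped to `n`, constant
ROIs to level 1. Fixed-count binning makes all texture features invariant to
affine intensity shifts, which is also tested.

## The 423-feature panel

Per channel the panel is 7 first-order + 9 GLCM + 13 GLRLM + 13 GLSZM +
5 NGTDM = 47 features; with the original image and 8 wavelet channels this
gives 47 + 8 x 47 = 423. The source protocol prints only these counts, not
the feature list, so the membership follows the classical texture-analysis
literature (Haralick co-occurrence statistics; Galloway/Chu/Dasarathy
run-length set; Thibault size-zone set; Amadasun–King NGTDM), fixed so the
arithmetic matches and including the features the study discusses by name
(correlation, sum average, variance, coarseness, busyness).

Numerical conventions, fixed because the formulas are undefined on
degenerate ROIs: all entropies in log base 2; first-order kurtosis is
non-excess; skewness/kurtosis of a constant ROI are 0; first-order energy is
the sum of squared discretized gray values (uniformity carries the
sum-of-squared-probabilities role); GLCM correlation of a constant ROI is 1;
NGTDM coarseness/busyness/strength denominators carry an epsilon guard of
1e-6 (a constant ROI has coarseness 1e6 and contrast = busyness = 0).
Matrices are 2-D, distance 1, summed over the four standard directions and
(for GLCM) symmetrized; GLSZM zones are 8-connected; NGTDM neighbourhoods
are mask-restricted 3 x 3. The matrix kernels are compiled (Rcpp); the test
suite checks them against independent brute-force R enumerations on random
ROIs.

## Wavelet channels

A single-level 2-D Haar transform yields 4 sub-bands, not the 8 additional
channel images the protocol describes; since 376 = 8 x 47 must hold, the
package uses a **two-level stationary (a trous) Haar transform** — 4
sub-bands per level, each already at the original image size, consistent
with "decomposed images equal in size to the original". This interpretation
is deliberate and recorded here. The implementation uses the single-phase
scheme `A = (x + S_d x)/2`, `D = (x - S_d x)/2` with symmetric border
reflection and dilation d = 1 (level 1, on the input) or 2 (level 2, on the
level-1 LL band); under it the lone inverse reconstruction of a sub-band
equals its coefficient image, the four level-1 channels sum exactly to the
input, and the level-2 channels sum to L1.LL — properties the tests assert
at 1e-8. Channels are computed on the continuous (resampled) image and each
is discretized independently within the mask; discretizing first would
destroy the high-frequency content the detail channels measure.

## Screening, split, SMOTE

The cohort is split 2:1 within each group (`floor(n/3)` of each group to
test, so training is never smaller than test and group composition is
consistent). Screening uses a plug-in mutual-information estimator: each
feature is discretized into 10 equal-frequency bins (tied quantiles merged)
and MI with the binary label is computed in nats, ranked descending with
name tie-breaks. The estimator is deterministic and invariant to monotone
feature transforms; the protocol names only "mutual information", so the
estimator is a package choice. Default panel sizes after screening are the
published 80 (CT) and 95 (MRI).

SMOTE raises the minority (HEAML) count to the majority count: each
synthetic sample is `x + u (z - x)`, `u ~ U(0,1)`, with `z` one of the
`k = 5` nearest minority neighbours (Euclidean distance on
train-standardized features; the interpolation itself happens in the
original feature space so synthetic rows are exact convex combinations —
asserted exactly in the tests). SMOTE and screening accept only the training
partition by interface, so the test cohort cannot leak; SMOTE is never used
on the fusion path.

## Signature models

Three signatures are supported: random forest (RF), ridge logistic
regression (RR) and a single-hidden-layer neural network (ANN). "Ridge
regression" in a binary task is score-scale ambiguous, so RR is implemented
as L2-penalized logistic regression, making all three scores probabilities.
Hyperparameters are chosen by exhaustive grid search with internal
stratified 5-fold CV, selection metric AUC (the study's evaluation
currency), ties to the earliest declared grid row, winner refit on the full
training cohort. The declared default grids (the protocol states none) are
RF trees {100, 300, 500} x node size {1, 5, 10} (the R random forest exposes
node size rather than depth), RR penalty 1e-3..1e3 by decade, ANN hidden
units {4, 16} x weight decay {1e-4, 1e-2}. All stochastic fits are seeded;
the per-fold fit seed does not depend on the grid point, so per-point CV
AUCs can be recomputed independently — the selection oracle in the tests.

AUC is computed as tie-aware pairwise concordance (checked against an O(n^2)
count); its 95% CI uses the DeLong variance via pROC. Calibration curves use
equal-frequency score groups (tied quantiles merged).

## Fusion models and evaluation

The fusion model is a multivariate logistic regression of the binary group
on the signature score plus a clinical covariate subset chosen by exhaustive
AIC minimization over all 2^5 subsets; the signature score is forced into
every candidate (the model is a *fusion* by construction — whether
signature-free subsets were allowed originally is unknowable), ties broken
toward fewer covariates then lexicographically. Fits use IRLS
(|delta logLik| < 1e-8); perfect separation is detected and the fit
ridge-stabilized (penalty 1e-6) and flagged. Binary covariates are 0/1-coded
and continuous ones standardized on the training data.

Ten-fold stratified cross-validation is fully nested: inside each training
fold the MI screening is redone, the signature score is produced
*out-of-fold* (5 inner folds) by a fixed, declared RF configuration
(300 trees, node size 1), and the AIC selection is refit — the leakage-free
reading of a protocol that is silent on the point. A full nested grid search
would multiply cost roughly ninefold without changing what the CV measures,
so the fixed configuration is the package default. Both the mean of fold
AUCs and the pooled out-of-fold AUC are reported, since "average CV AUC" is
ambiguous; nothing gates on the pooled value.

Decision curves use net benefit `NB(t) = TP/n - FP/n * t/(1-t)`
(classification at score >= t) against treat-all and treat-none. The
pointwise lower bound `NB(model) >= min(NB(all), 0)` holds in expectation;
on finite random instances the tests allow a sampling-noise band of
`3 sqrt(pi(1-pi)/n) (1 + t/(1-t))`.

The nomogram follows the standard points convention: each covariate's
contribution `beta x` is mapped affinely to points with zero at the
contribution-minimizing endpoint of its observed range; the widest-ranging
covariate spans 0–100; total points map back to probability through the
logistic inverse of the reassembled linear predictor. The rescaling is
algebraically exact, and the round trip is asserted at 1e-9.

Clinical group comparisons reproduce the published table's conventions:
two-sided Mann–Whitney U (normal approximation with tie correction, no
continuity correction) for age and diameter, two-sided Pearson chi-squared
without continuity correction for the binary covariates, display floored at
"<0.001".

## Statistical framing of the recovery checks

Per-seed AUCs on cohorts of this size are noisy (a null AUC with 28
positives has SD ~ 0.06 for the 10-fold mean and more for a 2:1 test split),
so the recovery suite aggregates: over 10 seeded CT-default cohorts with
separable texture, the *mean* RF-signature test AUC and the *mean* fusion
10-fold CV AUC must reach 0.9, and on label-permuted versions of the same
cohorts both means must fall inside [0.35, 0.65]. A label permutation moves
only the group label, leaving images and clinical covariates with their
subjects. The fusion-superiority check (fusion >= signature-only and >=
clinical-only) is a per-seed majority over the same 10 replicates, with ties
counting in favour — on strongly separable cohorts both models are often at
ceiling. Similarly, the coarseness dial is checked as an aggregate: over 30
paired seeds with noise-free fields differing only in correlation length
(2 vs 8 px), the longer correlation must give the higher mean coarseness and
win the per-seed majority; with strong white noise the effect is genuinely
drowned, which is a property of range-relative binning, not a bug.

The AIC-recovery properties are framed to match AIC's actual behaviour: a
single pure-noise covariate survives subset selection with probability
P(chi2_1 > 2) ~ 0.16, so "exactly the signal covariate and nothing else" is
not a high-probability event with five candidates. The tests therefore
assert that a strong sex effect is retained in >= 8/10 replicates while
noise covariates are selected well below chance, and that with an all-noise
clinical pool the mean selected subset stays small.

## Problem sizes and runtime choices

The package's test and acceptance runs use 64 x 64 px phantoms at 1 mm
spacing with the default enrolment counts (170 CT / 137 MRI), 10 recovery
seeds, 5 acceptance seeds for CT and 3 for MRI, and a single declared RF
configuration inside the fusion CV. At these sizes a full cohort extraction
takes a few seconds and the entire recovery study a few minutes on one CPU;
128 px images are the documented higher-fidelity setting. These sizes are
package choices that keep the feedback loop fast while leaving all
statistical margins comfortable.

## Known limitations

- Phantom lesions are stationary Gaussian textures on an elliptical
  support; real lesions have structured heterogeneity (necrosis, fat,
  draining veins) that the generator does not model.
- The published patient-data AUCs are not reproducible without the patient
  images; the package's AUC targets live on its own synthetic conditions.
- The exact identity of the original 7 first-order and 9 GLCM features is
  unrecoverable from the source; the panel here is one classical,
  count-consistent choice.
- 2-D only, single phase, no shape/morphology features, Haar wavelets only
  — matching the source protocol's scope.
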