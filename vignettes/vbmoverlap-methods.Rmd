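---
title: "Methods: factorial VBM and conjunction-overlap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial VBM and conjunction-overlap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Voxel-based morphometry (VBM) compares local tissue volume across subjects
on spatially normalized, modulated tissue maps. `vbmoverlap` implements a
complete VBM analysis for a 2 x 2 factorial design — biological sex
(male/female) crossed with diagnosis (autism/control) — and, on top of it, a
*spatial* question that a factorial magnitude test cannot answer by itself:
do the brain regions where a diagnosis effect appears coincide with the
regions that are sexually dimorphic in neurotypical controls?

Two competing hypotheses make directional predictions about that
coincidence. The extreme-male-brain (EMB) account predicts that the autism
effect is aligned with typical masculinization: where male controls exceed
female controls (MC > FC), the autism group should exceed its same-sex
control group in the same direction. The gender-incoherence account predicts
the reverse alignment for males (a "feminized" shift). Both are tested here
as *directional conjunction overlaps* between thresholded group-difference
maps, with significance calibrated by a smoothness-matched Monte Carlo null.

# Pipeline and model

## Preprocessing conventions (`tissue_maps`)

* **Analysis mask.** Group comparisons are restricted to voxels where a
  template (the voxel-wise mean of all subjects' modulated maps — a
  study-specific template analogue, since nonlinear template construction is
  out of scope) has a partial volume estimate above 0.25. Templates already
  on the PVE scale (maximum at most 1) are used as-is; larger-valued
  templates are normalized by their maximum.
* **Tissue-specific rescaling.** Each modulated map is divided by the
  subject's total volume of the same tissue class (the integral of the map,
  in cm^3), giving maps of *relative* volume. Rescaling is per tissue, not
  by total brain volume, because grey and white matter totals do not scale
  linearly with each other. A multiplicative global group difference (e.g.
  larger male brains) cancels exactly under this rescaling, which the test
  suite verifies.
* **Smoothing.** Separable Gaussian convolution parameterized by FWHM in mm,
  `sigma = FWHM / (2 sqrt(2 ln 2))` per axis in voxel units, with
  half-sample symmetric (reflective) boundaries. Reflective extension
  conserves the integrated tissue volume exactly for a normalized symmetric
  kernel and keeps near-edge marginal smoothness stationary — an assumption
  the random-field machinery relies on.

## Voxel-wise GLM (`glm`)

At every in-mask voxel an ordinary least squares model is fitted with a
common design: sum-to-zero coded sex (M = +1) and diagnosis (autism = +1),
their product as the interaction, mean-centred age as a nuisance covariate,
and sum-coded centre dummies for multicentre designs. Contrasts are tested
as `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` on `n - rank` degrees of
freedom. Voxels with numerically zero residual variance are flagged and
excluded from inference.

The planned pairwise comparisons (MC–FC, MA–MC, FA–FC) are run as separate
two-group GLMs with the age covariate rather than as contrasts within the
four-group model; the multicentre male comparison requires a separate model
in any case, and the same constructor serves both by dropping factors with
a single observed level. (Whether the pairwise models should carry the age
covariate was an open choice; it is included by default for consistency
with the factorial model.)

**Smoothness estimation.** Residual images are standardized voxel-wise to
unit mean square — which absorbs the error-degrees-of-freedom loss — and the
per-axis derivative variance `lambda_d` is the mean squared forward
difference between adjacent in-mask voxels, averaged over residual images.
Then `FWHM_d = sqrt(4 ln 2 / lambda_d)` (voxels) and the search region
counts `V / prod(FWHM)` resels. The lattice version of this estimator is
biased upward for small FWHM (about +9% at 2 voxels, vanishing for smoother
fields) because the forward difference underestimates the derivative
variance; the same discretization affects the Monte Carlo field generator in
the same direction, so matched-null comparisons are consistent. The
estimator is validated against direct simulation, not against any published
implementation.

## Cluster-level inference (`cluster_inference`)

One-sided thresholding at a voxel-level probability `p` keeps voxels with
`t > qt(1 - p, df)`; connected components are extracted at 18-connectivity
by default (faces and edges — a common VBM convention; configurable since
no single convention is universal). For a cluster of `k` voxels at Gaussian
height `u = qnorm(1 - p)` (probability matching of the t threshold), the
stationary random-field model gives

* expected suprathreshold volume `E[N] = V (1 - Phi(u))`,
* expected cluster count `E[m] = R rho3(u)`,
  `rho3(u) = (4 ln 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2/2)`,
* mean extent `nbar = E[N] / E[m]`, and
* `P(extent >= k) = exp(-beta k^{2/3})`, `beta = (Gamma(5/2)/nbar)^{2/3}`,

the per-cluster (uncorrected) extent p-value. Lower-dimensional
Euler-characteristic terms are omitted; the 3D resel term dominates for the
mask sizes targeted here, and the simulation oracle in the test suite bounds
the residual error (within a factor 2 of the empirical null). Thresholds
with `u <= 1` are rejected — the EC density changes sign there — with advice
to use a stricter forming threshold. Cluster-wise control is
Benjamini–Hochberg step-up over the cluster p-values of one contrast's map
("topological FDR"), retained at `q < 0.05`; the two one-sided contrasts of
an effect are corrected separately by default (a pooled mode would also be
defensible; per-contrast matches how the forming threshold is declared).

A non-stationary option converts each cluster's extent to resels through a
local resels-per-voxel lattice estimated from the residuals before applying
the same size distribution. It is off by default: published
non-stationarity corrections come in several non-equivalent forms, and the
stationary variant is the one validated by simulation here.

## The conjunction-overlap statistic (`overlap`)

Group-difference maps are compared on a *ladder* of 500 voxel-level
thresholds, `p_k = k x 1e-4` (P = 0.0001 to 0.05) — the unique uniform grid
matching both endpoints and the count — so that a claimed overlap can be
shown to be consistent across thresholds rather than an artefact of one.
No cluster-extent threshold is applied on the ladder: extent corrections
would differ between maps and distort the overlap.

For each rung, the two direction-matched conjunction pairs are evaluated
(for the masculinized mode: `dx+ AND sex+`, `dx- AND sex-`; the feminized
mode crosses the directions) and each conjunction is expressed as a
percentage of the *diagnosis* map's suprathreshold voxels, then the two
percentages are averaged. The denominator convention follows the way the
overlap is described for the diagnosis maps; the percentage of the other
map and a symmetric mean-denominator variant are computed alongside, since
"proportion of the suprathreshold voxels for each map" admits either
reading. Maps with different degrees of freedom are compared on the
Gaussian scale (`z = qnorm(pt(t, df))`, computed tail-wise in log space),
so a rung means the same voxel-level probability in both maps. Rungs where
a denominator is empty are flagged and excluded from averaging and from
p-value computation — the strict tail of the ladder can empty a sparse map.

**Monte Carlo null.** Each iteration generates two pairs of independent
Gaussian fields — mirroring the two direction-pairs of the observed
statistic — the first member of each pair smoothed to the estimated
smoothness of the diagnosis map and the second to that of the sex map
(matching each map separately; a single common smoothness would also be
defensible but is not the default). Fields are white noise convolved under
periodic boundary conditions (exactly stationary on the lattice),
standardized within the mask, thresholded by the Gaussian quantile at every
rung, and summarized with the same denominator convention and averaging as
the observed statistic. The empirical p at a rung is the fraction of null
samples at or above the observed overlap; p = 0 is reported as less than
one over the iteration count, and overlap curves floor it at
`1/(n_iterations + 1)`. A low p (< 0.001) flags non-random overlap; a high
p (> 0.999) flags significant *non*-overlap.

## Study logic (`emb_evaluation`)

`run_question1()` fits the factorial model, reports FDR-retained
interaction and main-effect clusters, and traces the similarity of the
female and male diagnosis maps (FA–FC vs MA–MC, same-direction
conjunctions) against the null. `run_question2()` evaluates the
prerequisite/requisite chain: S1 — retained clusters in the control sex
comparison; S2/S3 — non-random directional overlap of the male/female
diagnosis map with the control sex map. A requisite holds when the
empirical p is below 0.001 at at least 90% of the defined rungs at or below
p = 0.025. A claim of overlap that does not depend on the choice of
threshold needs an explicit consistency rule; this one fixes the decision
points (cluster q < 0.05, overlap p < 0.001) and demands they hold across
the informative part of the ladder rather than at one rung. If S1 fails, S2/S3 are *not evaluable* (NA) rather than
false. `write_report()` emits a deterministic JSON verdict plus TSV curve
and cluster tables.

# The synthetic cohort generator

Studies of this design rarely deposit subject-level imaging data, so the
generator is the package's test bed: it emulates DARTEL-style modulated, smoothed tissue
maps for the four groups with plantable ground truth, and every downstream
claim in the test suite is checked against that ground truth.

What it generates, per subject: an ellipsoidal "brain" support carrying a
flat baseline whose integral matches published group mean totals (grey
matter 914/940/824/845 cm^3 for MC/MA/FC/FA, white matter 510/513/448/465
cm^3, as multiplicative group scales on a male-control baseline); planted
spherical effect fields (sex, diagnosis-within-sex, interaction crossover,
linear age slope) smoothed by the noise kernel so effects are spatially
smooth like real VBM effects; and Gaussian subject noise smoothed to 8 mm
FWHM (2 voxels — the scale of the preprocessed maps it emulates), generated
on a grid padded by three FWHM and cropped so edge voxels keep stationary
marginal smoothness, and scaled so the *marginal* post-smoothing SD equals
`subject_noise_sd`. A per-subject global scale jitter (CV 0.085) reproduces
the published between-subject spread of total volumes (SD ~ 78 cm^3 on a
914 cm^3 mean). Ages are uniform on 18–49 years, the published range.
Negative voxels after summation are clipped to zero and counted.

Two generator choices deserve comment:

* **Noise is restricted to the brain support.** Modulated tissue maps are
  identically zero outside the brain. Whole-grid noise would be half-clipped
  outside the support, biasing every integrated total upward by a constant
  and breaking the totals calibration; restricting noise to the support
  keeps the in-mask statistics identical and the totals exact.
* **Digit ratios.** 2D:4D ratios are drawn per group around published
  female means (FC 0.975, FA 0.967, left hand) with an optional coupling
  slope linking a named ground-truth region's relative volume to the ratio;
  male means are not published for this measure and default to a typical
  value (0.947). Ratios are truncated to the plausible interval (0.7, 1.2).

What it does **not** emulate: cortical anatomy and folding, segmentation
and registration error, non-stationary anatomical smoothness,
tissue-class-dependent covariance, site effects beyond a centre label, or
any behavioural phenotype. Passing tests therefore demonstrate that the
*statistical machinery* behaves as claimed under known ground truth — not
that the generator reproduces real MRI data. Planted effect amplitudes are
chosen for testability, since standardized voxel-level effect sizes for
real cohorts of this kind are not available to calibrate against: with `subject_noise_sd = 0.1`, an amplitude of 0.12–0.15 gives
within-group Cohen's d of 1.2–1.5, comfortably detectable at n = 30/group
without saturating every rung of the ladder.

# Numerical and design notes

* Voxel coordinates are 0-based lattice indices; mm positions are
  `origin + index * voxel_size`. One stated convention avoids off-by-one
  cluster coordinates.
* Cluster peaks are the maximum-t voxel, ties broken by lowest linear
  index; components sorted by extent descending.
* The t-to-z map is monotone and computed per tail in log probability space,
  so extreme t values do not saturate.
* Designs are checked for full column rank; collinear columns are named in
  the error. Factors with one observed level are dropped with a message
  (e.g. centre dummies in a single-centre cohort).
* Monte Carlo fields with FWHM below half a voxel trigger a warning:
  lattice discreteness breaks the calibration the null relies on.
* All simulation entry points take explicit integer seeds; reports are
  byte-identical across runs with the same seeds.

## A known property of shared-control conjunctions

The planned comparisons FA–FC and MC–FC share the FC subjects, so their
noise t-maps are positively correlated (+0.5 for equal group sizes) even
with no true effects anywhere. The Monte Carlo null, by definition, draws
*independent* field pairs and therefore understates the random overlap of
shared-group comparisons; simulation in this package shows an effect-free
shared-control overlap curve sitting well above the 99.5th null percentile
purely from the shared group. Consequences drawn here: (i) detection
claims (S2/S3) are made against the independent-pairs null — that is what
the overlap statistic is defined against — and the planted-recovery tests
confirm they respond to real coupling far above this baseline; (ii)
*specificity* is evaluated with disjoint samples — the diagnosis maps from
one simulated cohort, the control sex map from an independent cohort — the
design one would ideally use for the whole analysis if two large samples
were available. A correlated null (simulating the shared-group correlation
explicitly) would change the definition of the statistic and is
deliberately not the default.

# Problem sizes

The test suite exercises unit properties on 12–24 voxel lattices and the
study logic at the full default scenario (40 x 48 x 40 voxels at 4 mm,
n = 30/group). Decision-scale checks use 5000 null iterations for the
calibration of the Monte Carlo null, 1000 for the planted-recovery verdict,
and 20 replicates x 500 iterations for specificity; the acceptance script
reports the same quantities with 5 specificity replicates. These sizes were
chosen so the full suite completes comfortably on a single CPU while
keeping Monte Carlo standard errors well inside the asserted tolerances.

# Limitations

* Stationary random-field inference is the validated default; the
  non-stationary resel-rescaling option is an interpretation of a cited but
  unspecified correction and is validated only by simulation.
* The GRF extent model omits lower-dimensional EC terms and uses the
  large-`u` size distribution; accuracy is bounded by simulation (factor 2
  on tail probabilities), not proved.
* The smoothness estimator and the null generator share a lattice
  discretization bias (~ +9% at 2-voxel FWHM); absolute FWHM values carry
  that bias even though matched-null inference does not.
* Verdict booleans depend on Monte Carlo resolution: the p < 0.001 rule is
  only attainable with at least 1000 null iterations.
* The null percentile band describes the *null* statistic. An observed
  curve computed from maps that carry true (even independently placed)
  effects has larger sampling variance than the band — true suprathreshold
  voxels change both numerator and denominator — so occasional whole-curve
  excursions outside the band are expected under independence and should be
  judged across replicates, not from a single curve.
* The synthetic cohort validates machinery, not anatomy; nothing here
  certifies behaviour on real MRI data with non-stationary smoothness and
  registration artefacts.
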