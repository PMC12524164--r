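---
title: "Quantitative fibrosis morphometry and NIT evaluation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative fibrosis morphometry and NIT evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## What the package models

fibroquant implements a digital-pathology workflow for staging liver
fibrosis in MASLD (metabolic dysfunction-associated steatotic liver
disease) from two-channel multiphoton microscopy, together with the
statistical layer used to compare it against non-invasive tests (NITs).
The two channels are second-harmonic generation (SHG), which is specific
to fibrillar collagen, and two-photon excitation fluorescence (TPEF),
which shows tissue autofluorescence. From these the pipeline derives
named quantitative fibrosis parameters (q-FPs) per lobular region, a
continuous qFibrosis score, and diagnostic comparisons (ROC/AUC,
cutoffs, correlation, agreement, variable importance) against serum
scores and elastography.

Because no biopsy images or patient-level data are publicly deposited
for this kind of study, the package ships a synthetic data layer with
exact ground truth: tissue phantoms that emulate the lobular anatomy the
segmentation must recover, and patient cohorts whose stage-conditional
distributions are calibrated to published summary statistics of a
99-patient MASLD cohort. Every downstream module is tested against this
ground truth.

## The image pipeline

**Segmentation.** Collagen is segmented on the SHG channel by Otsu's
threshold (exhaustive maximization of between-class variance over a
256-bin histogram; tied maximizers are averaged so symmetric histograms
split centrally), restricted to tissue. Components smaller than 15 µm²
are removed as noise (strict inequality; at the default pitch of
0.390625 µm/px the boundary falls exactly between 98 and 99 pixels),
then enclosed gaps of at most 2 px are filled. Tissue is segmented on
the TPEF channel the same way, keeping components strictly larger than
0.1 mm² (exactly 655,360 px at default pitch). Collagen uses 8-connected
components (thin fibres touch diagonally), tissue 4-connected; both are
configurable.

**Lumens and landmarks.** Enclosed holes in the tissue mask of at least
100 µm² become lumen objects — blood vessels, bile ducts, and fissures;
smaller sinusoid-scale holes are ignored. Each lumen is described by
area, eccentricity, boundary circularity, neighbour count, and the
fraction of a 6 µm collar ring occupied by collagen: portal tracts carry
a collagenous sheath, central veins a much thinner wall, so the collar
fraction is the dominant discriminative feature. A depth-limited CART
tree (rpart) trained on ground-truth-labelled phantom lumens classifies
lumens into portal tract / central vein / other. On held-out phantom
lumens the tree exceeds 95% accuracy.

**Zonation.** The five-region zone map follows lobular anatomy: the
portal region is the collagen collar around portal lumens together with
any collagen component contiguous with it (portal stroma and bridging
septa); the central-vein region is built symmetrically, with portal
priority for components touching both. Periportal and pericentral bands
extend 100 µm (default) from their landmark regions by geodesic distance
inside tissue — the 8-neighbour shortest path with steps 1 and √2, so
bands wrap around lumens rather than crossing them. A pixel inside both
bands goes to the nearer landmark; exact ties go to periportal, since
periportal fibrosis dominates MASLD staging. Zone 2 is the remaining
parenchyma. With no classified landmark the whole parenchyma is zone 2.
The band widths are configuration, not published values; every q-FP
table records the bands used.

**Morphometry.** Each 8-connected collagen component is one "string".
Length is the arc length of its morphological skeleton (Zhang–Suen
thinning; orthogonal steps count 1, diagonal √2); width is the ribbon
estimate area/length. A component whose nominal width would exceed its
length is a blob, not a ribbon, and is re-parameterised as
length = width = √area. Strings are classified thick/thin at 3 µm,
long/short at 40 µm (closed lower bounds, so the pairs partition
exactly), and aggregated/distributed by morphological closing at 5 µm:
a string is aggregated when its fused cluster reaches 200 µm² of
collagen. None of these four thresholds is published; all are
configurable and recorded. The q-FP vector follows the
`<metric><region>` naming grid (`#Str`, `#ShortStr`, `#LongStr`,
`#ThinStr`, `#ThickStr`, `StrArea`, `StrLength`, `StrWidth`, `%<R>`,
`%<R>Agg`, `%<R>Dis` over regions PT, PeriPortal, ChickenWire, Zone2,
CV, PeriCentral, plus overall metrics and `%SHG`, the overall collagen
fraction). Counts are additionally emitted as densities per mm² of
region tissue (suffix `Dens`); correlation analyses should use the
densities. The proprietary 186-parameter catalogue of the commercial
instrument is not reconstructed; this documented grid is the package's
versioned parameter set.

**Chicken-wire.** Perisinusoidal/pericellular fibrosis has no published
operational definition, so the package uses a documented surrogate: a
string is chicken-wire when it lies in zone 2 or the pericentral band,
is thinner than 3 µm, and sits more than 10 µm (geodesic) from
landmark-attached collagen. ChickenWire is an overlay region: flagged
strings remain counted in their zone, and its percentage metrics use the
zone 2 + pericentral tissue area as denominator.

## The qFibrosis score

Per-area q-FPs are max-normalized (each feature divided by its training
maximum, so training values lie in [0, 1]); zero-maximum columns are
dropped with a warning. Forward sequential selection against stage
minimizes 5-fold stage-stratified cross-validated residual error,
stopping at 17 features or when CV error stops improving — the selection
criterion is not published, and CV-RSS is this package's documented
choice; the cap of 17 honours the size of a widely cited international
qFibrosis model. An ordinary least-squares regression of stage (numeric
0–4) on the selected features yields the score. New specimens are scored
with the frozen training maxima — values may exceed 1 outside the
training range — so a fitted model never depends on the test set.
`tidy()` and `glance()` expose coefficients and fit summaries.

## The synthetic data layer

**Phantoms.** A phantom is a square mosaic (default 1024 px = 400 µm at
0.390625 µm/px = 0.16 mm², so the 0.1 mm² tissue filter is exercisable;
a single 512 px tile of 0.04 mm² could never pass it alone). Portal
tracts and central veins are interleaved on a jittered checkerboard;
portal lumens get a solid collagen collar whose thickness grows
2.5 + 2.0·stage µm, central veins a thin wall of 1.2 + 0.6·stage µm.
Short radial spurs (2·stage per tract) emulate the fibrous expansion of
the portal tract. Collagen strings are planted zone by zone until the
requested added density is reached — periportal
0.02/0.07/0.13/0.20/0.28 for F0–F4, with finer and sparser chicken-wire
strings in zone 2 and pericentrally — and bridging septa connect portal
to central landmarks from F3. Fill strings keep an 8 µm stand-off from
vessel walls and septa and are laid down essentially non-touching (10%
contact probability), so regional fibrosis remains a population of
distinct fibres rather than one percolated cluster; this is what lets
per-region counts and widths respond smoothly to stage. The TPEF channel
is bright parenchyma (0.55 ± 0.07) with dark lumens; the SHG channel is
planted collagen (0.68 ± 0.08) over low background noise (|N(0.05,
0.025)|), Otsu-separable by construction. Ground truth (zone map,
collagen mask, lumen classes, string inventory) is exact, and the same
seed gives a bit-identical phantom.

What the phantoms do **not** emulate: optical physics (PSF, photon
noise), steatosis vacuoles, inflammation, stitching artefacts, or real
fibre morphology (curvature, branching, orientation coherence). Passing
tests on phantoms therefore demonstrates algorithmic correctness against
known geometry, not clinical performance.

**Cohorts.** Each patient draws a true stage and stage-conditional
clinical variables. Variables published as mean (SD) — platelets, CAP,
qF — are normal; skewed variables published as median (IQR) — age, BMI,
labs, PDFF, both stiffness measures — are log-normal with parameters
solved from the printed median m and quartiles:
µ = log m, σ = (log q₃ − log q₁)/(2·z₀.₇₅). Proportions (sex, diabetes)
are Bernoulli. Negative draws of physical quantities are redrawn and
counted; the qF score is left untruncated because it is a regression
output whose calibrated F0 mean (0.94) must be recovered exactly in
expectation. The default stage split is 17/16/32/28/6 (n = 99). The
generated cohort reproduces the published medians per stage but not the
joint dependence structure between variables (each is drawn
independently given stage), which caps how far correlation analyses on
synthetic cohorts should be interpreted.

**NIT formulas.** APRI, AAR, FIB-4, NFS, FAST and MAST are implemented
with the established published forms as defaults: FIB-4 divides by
√ALT, NFS uses the binary hyperglycemia indicator, and FAST/MAST return
their logistic transform (MAST with base-10 logs). Literal "as printed"
variants (ALT⁻¹, glucose in mmol/L, linear predictors) are provided for
comparison but produce values incompatible with the published cohort
medians (MAST 0.13 and FAST 0.63 lie in (0,1); NFS medians near −2.5);
the defaults are the internally consistent reading. Albumin is ingested
in g/L and converted to g/dL for the NFS term.

## The diagnostic layer

AUC is the Mann–Whitney statistic scaled by n₁n₀ (ties count ½), with a
class-stratified percentile bootstrap CI (2000 replicates, seeded) —
bootstrap rather than DeLong because it generalizes to the cutoff
metrics. Candidate cutoffs are the observed score values, and a positive
call is score ≥ cutoff. Three cutoff rules: the smallest cutoff
maximizing Youden's J; the largest cutoff with sensitivity ≥ 90%
(maximizing specificity under the constraint); the smallest cutoff with
specificity ≥ 90% (maximizing sensitivity), flagged when unattainable.
Se/Sp/PPV/NPV come from the 2×2 table, with undefined predictive values
returned as NA rather than imputed. Spearman correlations use mid-ranks
with t-approximation p-values (exact permutation below n = 10) and
Bonferroni adjustment across the grid. Stage-wise comparisons run a
Kruskal–Wallis omnibus plus all pairwise Mann–Whitney tests with
Bonferroni-multiplied p-values. Weighted kappa defaults to linear
disagreement weights (the quadratic variant is available; the choice is
not published). Random-forest importance reports both permutation
importance (increase in out-of-bag MSE) and total node-impurity
decrease from a seeded regression forest.

## Reproducibility and problem sizes

One top-level seed fans out deterministically to every stochastic
sub-step (`derive_seed()`), so `run_pipeline()` with the same
`run_config()` reproduces every artifact byte for byte. The package's
own studies use 512² px phantoms (200 µm mosaics) with the tissue filter
and zone bands scaled to the canvas (a quarter of the canvas area;
50 µm bands), 50 phantoms per stage for the ordinal-fidelity analysis
and 30 per stage in the bundled acceptance script, and synthetic cohorts
of n = 99 matching the published stage split. At these sizes the
end-to-end phantom study runs in a few minutes on a single core.

## Known limitations

- The ribbon width estimate saturates once bridging septa merge portal
  structures into one mesh: skeleton branches inflate length and deflate
  width, so `StrWidthPT` responds more weakly to stage than `%PeriPortal`
  or `StrLengthPT`. Splitting strings at zone borders would avoid this
  but is unstable and deliberately not done.
- Majority-zone assignment means a septum crossing several zones is
  counted entirely in one region.
- Synthetic cohorts have no within-stage correlation between variables,
  and phantom q-FPs are paired to cohort patients only by stage, so
  cross-domain correlation heatmaps are illustrative.
- The qFibrosis model here is fit on phantoms; its coefficients and
  cutoffs are not transferable to real SHG/TPEF images.
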