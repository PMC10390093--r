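---
title: "Multi-aspect fractal dimension and texture analysis of tumor masks: methods and design"
author: "fracmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-aspect fractal dimension and texture analysis of tumor masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracmorph)
```

## The scientific problem

Low-grade gliomas (LGG) tend to grow as well-circumscribed, compact
lesions; high-grade gliomas (HGG) grow irregularly, with rough margins and
infiltrative branching into surrounding tissue, and typically show solid
contrast enhancement where LGG enhancement is weak or patchy.  A
box-counting fractal dimension (FD) summarizes exactly this kind of shape
irregularity in one scalar: the more space-filling and irregular a
structure is across scales, the higher its FD.

`fracmorph` implements a radiomic pipeline around this idea.  For each
subject it takes five binary region masks — whole tumor, enhanced tumor,
edema, and non-tumorous gray matter (GM) and white matter (WM), the tumor
having been subtracted from the tissue masks — and computes:

* **15 FD features**: FD of three morphological *aspects* of each region —
  the *general structure* (the mask itself), its *boundary* (voxels with
  at least one unset face neighbour) and its *skeleton* (topology-preserving
  thinning to 1-pixel width).
* **25 texture features**: five Haralick statistics (angular second
  moment, contrast, inverse difference moment, correlation, entropy) from
  a gray-level co-occurrence matrix (GLCM) per region.

Feature families are then compared between cohorts with normality-gated
two-sample tests under Benjamini–Hochberg FDR correction, and classified
with cross-validated SVMs (linear, polynomial, RBF kernels), reporting
accuracy, sensitivity, specificity and AUC with HGG as the positive class.

Because clinical MRI of this kind is not freely redistributable, the
package ships a synthetic-data module that generates (i) reference
fractals with known dimensions and (ii) two-group tumor-like cohorts with
the geometric and textural contrasts the analysis is supposed to detect.
Everything downstream is validated end-to-end against these.

## Box-counting fractal dimension

A structure covered by a grid of boxes of side $S$ occupies $N(S)$ boxes;
for a fractal, $N \propto S^{-D}$, i.e.

$$D = \frac{\log_{10} N}{\log_{10} (1/S)},$$

and $D$ is estimated as the negative slope of an ordinary least-squares
fit of $\log_{10} N$ on $\log_{10} S$ over a range of scales.  The
implementation:

* **Grid**: a single grid anchored at the array origin, conceptually
  zero-padded to a multiple of $S$.  No offset-minimization sweep is
  performed.
* **Scale schedule**: geometric, $S = b^0, b^1, \dots$ with base
  $b = 2$ (base 3 available, e.g. for carpet-type fixtures), up to the
  largest power not exceeding half the shortest axis of the *set-voxel
  bounding box*.  Keying the top scale to the object rather than the
  canvas makes the estimate invariant to surrounding empty background;
  for a small object on a large canvas, canvas-keyed coarse scales would
  saturate at a handful of occupied boxes and drag the fitted slope down.
  At least three scales are always scheduled, so a single voxel yields a
  flat curve and $D = 0$.
* **Fit**: all scheduled scales enter the fit; no manual cutoff.
  $r^2$ is always reported so poor scaling regimes are visible.  A
  perfectly flat curve has $D = 0$ and, by convention, $r^2 = 1$ (the fit
  is exact).  The intercept is on the base-10 scale.
* **Missing regions** (e.g. no contrast enhancement in an LGG-like
  subject) produce missing-value records that downstream statistics and
  classification drop pairwise, rather than errors.

On aligned self-similar fixtures the estimator is exact to floating-point
precision: the depth-5 Sierpinski carpet on a base-3 schedule gives
$D = \log 8 / \log 3 = 1.892789\ldots$ with $r^2 = 1$, the depth-5
Sierpinski triangle $\log 3/\log 2 = 1.584963\ldots$, a filled square 2, a
straight line 1, a single voxel 0.

### Finite-resolution bias on smooth shapes

Digitized smooth curves do not reach their ideal dimension of 1 at finite
resolution with a single fixed grid: the pixel-level count of a digital
circle follows taxicab geometry (about $4\sqrt 2\,r$ pixels) while coarse
scales follow Euclidean covering, and closed contours lose a constant
number of boxes at the coarsest scales ($N = 4L/S - 4$ for a square ring).
In practice a radius-40 digital circle measures $D \approx 0.86$–$0.95$
and a full-canvas square ring $\approx 1.11$.  The package does not hide
this bias (no scale trimming, no grid sweeps); tests assert smooth-curve
FDs within $\pm 0.15$ of 1, and group *contrasts* — which is what the
analysis consumes — are unaffected because both cohorts are measured with
the same protocol.

## Morphological aspects

* **Boundary**: set voxels with at least one unset face neighbour
  (4-connectivity in 2D, 6-connectivity in 3D; outside the array counts
  as unset).  This "remove the interior" definition makes the boundary a
  subset of the mask and idempotent on 1-voxel-thick input.
* **Skeleton**: Zhang–Suen deletion conditions applied *sequentially* —
  each candidate is re-tested against the live image, so every removal is
  of a simple, non-endpoint pixel and connected components are preserved
  exactly.  (The classic parallel formulation deletes isolated 2×2 blocks
  entirely, destroying components.)  A post-pass removes residual 2×2
  blocks: first by locally simple-point deletion, and at arm junctions —
  where no pixel of the block passes the local crossing-number test but
  the arms reconnect outside the 3×3 window — by a tentative deletion
  accepted only if the global 8-connected component count is unchanged.
  The result contains no fully set 2×2 block, is a subset of the input,
  preserves component count, and is a fixed point of the operator.
* **3D masks** are thinned slice-by-slice along the third axis.  A
  "1-pixel-wide" medial structure is intrinsically a per-slice notion for
  tumor cross-sections, and reported per-aspect FDs below 1 in this
  problem domain indicate sparse, per-slice 2D sets; a full 3D medial-axis
  thinning is deliberately out of scope.  Box counting itself is fully
  volumetric when given 3D input.

## GLCM texture features

Images are quantized to 8 bits per region (min–max rescaling to 0–255
with half-up rounding; constant regions map to 0).  The GLCM counts pairs
of gray levels at displacement (0, 1) — one pixel at 0° — by default,
asymmetric, 256 levels, with *both* endpoints of a pair required to lie
inside the region mask (per-region masked GLCM rather than a bounding
rectangle).  All of offset, symmetry and level count are configurable.
The five features use the standard definitions; entropy uses the natural
logarithm; correlation is reported as missing for zero-variance regions
instead of propagating NaN.

## Group statistics

Each feature is compared between cohorts with Student's two-sample
$t$-test (equal variances) if *both* groups pass Shapiro–Wilk normality at
$\alpha = 0.05$, otherwise with the Mann–Whitney $U$ test; all tests are
two-sided.  Note that two independent normality gates at $\alpha = 0.05$
route Gaussian data to the $t$-test in only $\approx 0.95^2 \approx 90\%$
of samples — this is a property of the gate, not a defect.  Constant
samples are treated as non-normal; two identical zero-variance samples
give $p = 1$ by convention.

FDR correction is Benjamini–Hochberg, applied *within* each feature
family — the 15 FD features and the 25 texture features are adjusted
separately, mirroring analyses that report the two families in separate
tables.  Significance is declared at adjusted $p < 0.05$.  Under a global
Gaussian null the gated test's empirical type-I error is $0.05 \pm 0.01$
(checked at 10,000 replicates with the study's group sizes 27/15).

## Classification

The cross-validation protocol is **5 repeated stratified 70/30
train/test splits** (default), with plain stratified 5-fold CV available
via `mode = "kfold"`.  The repeated-split default reconciles a common but
internally inconsistent protocol description ("five-fold cross-validation
with 70% of the data for training and 30% for testing"): it honours both
the five resamples and the 70/30 ratio.  Within each split, features are
standardized using training-fold statistics only — a test-fold outlier
cannot leak into the scaler (this is asserted by test).  The SVM uses
cost 1 and RBF bandwidth $\gamma = 1/p$ on standardized features
(equivalently $1/(p \cdot \mathrm{var})$); class imbalance (27/15) is
handled by stratification only.  `selectBestKernel()` runs linear,
polynomial and RBF kernels on *identical* folds and returns the report
with the highest AUC (ties: accuracy, then the simpler kernel).
Sensitivity and specificity take HGG as the positive class.  AUC is the
normalized Mann–Whitney statistic
$P(s_{\mathrm{HGG}} > s_{\mathrm{LGG}}) + \tfrac12 P(\text{tie})$,
computed from midranks of the SVM decision values.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs.  Each subject's tumor is a star-shaped region around a
jittered centre whose boundary radius is modulated by a random sum of
sinusoids (`roughnessAmplitude` $\in [0,1]$, `roughnessFrequency`
harmonics, normalized so the amplitude is exact), plus optional
random-walk branch protrusions grown outward from the boundary; the mask
is always a single connected component and is deterministic given its
seed.  Concentric radial rescalings of the same boundary field carve the
subregions, which guarantees the containment invariants: the enhanced
core lies inside 0.55× the radial field and the edema shell is the part
of the tumor outside 0.8× of it.  GM is a wobbly annulus and WM the disc
it encloses (a 110 px brain on the 256 px reference canvas, rescaled with
canvas size), both with the whole tumor subtracted, so the non-tumorous
regions never intersect the tumor by construction.

The two groups differ in (defaults on the 256 px canvas):

| parameter | LGG-like | HGG-like | emulates |
|---|---|---|---|
| base radius (px) | 30 ± 4 | 48 ± 5 | HGG lesions are bulkier |
| roughness amplitude | 0.10 ± 0.05 | 0.55 ± 0.10 | well-circumscribed vs irregular margins |
| harmonics | 6 | 14 | finer-scale margin irregularity in HGG |
| branches (Poisson mean) | 0.3 | 6 | infiltrative growth |
| enhancement solidity | 0.15 ± 0.05 | 1.0 | patchy rim vs solid enhancing core |
| enhancement texture contrast | 0.5 | 4 | heterogeneous enhancement in HGG |

Enhancement *solidity* deserves a note: the general-structure FD of any
filled blob is close to 2 regardless of its outline, so outline roughness
alone cannot reproduce the large enhanced-region general-FD gap seen
between grades (a low-grade value near 1.2 is only attainable for a
sparse, curvilinear structure).  Low-grade gliomas indeed enhance weakly
and partially; modelling their enhancement as a thin rim of the core
(solidity 0.15) and high-grade enhancement as the full core (solidity 1)
reproduces group means near 1.2 vs 1.7 and makes the enhanced-region
general FD the top-ranked discriminator, with boundary and skeleton FDs
higher in the HGG-like group as well.  `cohortEffect(separation = s)`
interpolates all group differences linearly; `separation = 0` is the null
configuration with identical group distributions, used for calibration.

Textured interiors mix a smooth Gaussian-blurred random field with a
fine-scale pixel-decorrelated component at weight $c/(1+c)$ for contrast
level $c$.  Because 8-bit quantization min–max rescales each region, only
the *shape* of the field — its fine-scale variance share — survives
normalization, so this parameterization is what makes GLCM contrast and
entropy increase monotonically in $c$; at $c = 0$ (and zero noise) the
interior is constant.

Per-subject sub-seeds are drawn once from the master seed, so any subject
is reproducible in isolation; re-running a study with the same
configuration reproduces byte-identical output tables.

What the generator does **not** emulate: MRI physics (no bias field, no
noise correlation structure, no partial-volume effects), registration
error, multifocal tumors, or anatomically realistic cortical folding in
the GM/WM masks.  Passing tests therefore demonstrate that the *pipeline*
recovers planted geometric and statistical structure under controlled
conditions — not that any particular clinical accuracy would be attained
on real MRI.

## Problem sizes used in validation

Reference-fractal checks run on grids up to 243²; oracle-equivalence
properties compare against brute-force enumeration on ≥100 random masks
(≤32²), ≥100 random 8×8 images and ≥100 random score vectors; morphology
contracts are property-checked on ≥50 random blobs; type-I calibration
uses 10,000 gated tests at group sizes 27/15; effect recovery uses 100
independent default cohorts (27/15 at 256²) and null calibration 50
cohorts with zero separation.  The acceptance script reruns the study
end-to-end at the default sizes with a user-supplied seed.

## Known limitations

* Single fixed-grid box counting carries the finite-resolution biases
  discussed above; absolute FD values should be compared only within a
  fixed protocol.
* The skeleton of a near-circular region is nearly degenerate (a few
  pixels), so skeleton-FD fits on smooth small regions have low $r^2$;
  the $r^2$ field is reported precisely so such estimates can be
  filtered.
* GLCM features are computed at a single offset; multi-angle averaging
  and other Haralick statistics are out of scope.
* The gated test's family (t vs Mann–Whitney) is chosen per feature from
  the data, which makes the exact null distribution a mixture; the
  empirical calibration above is the relevant guarantee.
* No hyperparameter search is performed for the SVM; reported metrics are
  for the fixed defaults.
* The cohort simulator produces 2D slices (the 256² reference canvas).
  The analysis path itself accepts 3D masks — box counting and boundary
  extraction are fully volumetric, skeletons are per-slice — but no 3D
  shape generator is provided.
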