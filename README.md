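# fracmorph

Multi-aspect **fractal dimension (FD)** and **GLCM texture** analysis of
brain-tumor segmentation masks, for distinguishing low-grade (LGG) from
high-grade (HGG) glioma-like cohorts.

Low-grade gliomas grow as compact, well-circumscribed lesions; high-grade
gliomas have rough margins, infiltrative branching, and solid contrast
enhancement.  The box-counting fractal dimension quantifies exactly this
irregularity: cover a structure with boxes of side *S*, count the occupied
boxes *N(S)*, and estimate

    D = -slope of log10 N(S) vs log10 S

by ordinary least squares over a geometric scale schedule.  `fracmorph`
computes *D* for three morphological **aspects** of each region — the
general structure, its one-voxel boundary, and its thinned skeleton —
over five regions per subject (whole tumor, enhanced tumor, edema, and
non-tumorous gray/white matter with the tumor subtracted), giving 15 FD
features, alongside 25 Haralick texture features (ASM, contrast, IDM,
correlation, entropy; 5 per region) from per-region masked gray-level
co-occurrence matrices.  Feature families are compared between cohorts
with normality-gated t / Mann-Whitney tests under Benjamini-Hochberg FDR,
and classified with cross-validated SVMs (linear / polynomial / RBF),
reporting accuracy, sensitivity, specificity and AUC with HGG positive.

Because clinical MRI of this kind is not redistributable, the package
includes a first-class synthetic module: reference fractals with known
dimensions (Sierpinski carpet and triangle, squares, lines, discs) for
validating the estimator, and a two-group tumor-cohort simulator
(smooth/compact vs rough/branched masks with textured interiors) for
validating the whole pipeline.  See the methods vignette
(`vignettes/fracmorph-methods.Rmd`) for the model, parameter defaults and
design decisions.

## Worked example

```r
library(fracmorph)

## the estimator is exact on aligned self-similar fixtures
carp <- genReferenceFractal("sierpinski_carpet", 5)
fitFD(boxCount(carp, defaultScales(carp, 3)))
#> FDResult [NA/NA] D = 1.8928 (r2 = 1.0000, 5 scales)
log10(8) / log10(3)
#> [1] 1.892789

## one subject: masks in, 15 FD + 25 texture features out
co <- genCohort(nLGG = 27, nHGG = 15, seed = 7)
s  <- cohortSubjects(co)[[1]]
feats <- extractSubjectFeatures(s$masks, s$images)
length(feats)
#> [1] 40
round(feats[c("fd_whole_tumor_general", "fd_whole_tumor_boundary",
              "fd_enhanced_tumor_general")], 3)
#>  fd_whole_tumor_general fd_whole_tumor_boundary fd_enhanced_tumor_general
#>                   1.738                   0.962                     1.138

## the full study: statistics + classification
report <- runStudy(studyConfig(seed = 7))
print(report)
#> Study report: 42 subjects, 15 FD + 25 texture features
#> FDR-significant FD features: fd_whole_tumor_general, fd_whole_tumor_boundary,
#>   fd_whole_tumor_skeleton, fd_enhanced_tumor_general, fd_enhanced_tumor_boundary,
#>   fd_edema_general, fd_edema_boundary, fd_edema_skeleton, fd_wm_general,
#>   fd_wm_boundary, fd_wm_skeleton
#> Top feature set by AUC: fd_whole_tumor_boundary (linear kernel, AUC 100.0%)

subset(report$statsFD, feature == "fd_enhanced_tumor_general",
       c(mean_group1, mean_group2, p_adjusted))
#>   mean_group1 mean_group2   p_adjusted
#> 4    1.194801    1.736137 2.855768e-07
```

The group means above (≈1.19 for LGG-like vs ≈1.74 for HGG-like
enhanced-region general FD) reflect the planted contrast between sparse
rim-like and solid enhancement; higher boundary and skeleton FDs in the
HGG-like group reflect margin roughness and branching.  At the default
effect strength several FD features separate the groups completely, so
multiple feature sets tie at AUC 100% and the report lists the first.  `runStudy()` also
writes `features.csv`, `stats_fd.csv`, `stats_texture.csv` and
`classification.csv/.json` when given `outDir`.

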