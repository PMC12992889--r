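# pulmolayer

Regional lung analysis for CT pulmonary angiography (CTPA): an iterative
threshold-descent algorithm orders lung voxels from the contrast-filled
central vessels to the periphery and cuts the ordering into four
equal-volume concentric layers (Q1–Q4); a masked multi-angle
maximum-intensity-projection (MIP) renderer turns any combination of layers
into standardized 2D views; and a frozen-encoder classifier with a grouped
repeated cross-validation harness measures how much each vascular region
contributes to separating chronic-embolism-like cases from controls. A
synthetic CTPA phantom generator (ellipsoidal lungs, branching vessel trees,
injectable layer-localized disease signal) makes the entire pipeline
testable without clinical data.

## Who this is for

Researchers studying *where* diagnostic signal lives in vascular CT: the
package's masking schemes (`Q1`, `Q1Q2`, …, `full`, plus `initial` — the
automatic lung segmentation without the proximal vessels) restrict the MIP
input to chosen concentric zones, and the evaluation harness compares the
schemes' AUROCs with paired nonparametric statistics.

## The core algorithm

For one lung with full mask M (|M| = N voxels):

1. Seed with the voxels attaining max HU in M (inclusion step 0).
2. Lower the threshold by 1 HU; voxels of M at or above it join with the
   current step index.
3. Apply a morphological closing (4 mm ball, physical units) to the
   included region, clipped to M; enclosed voxels join at the same step.
4. Repeat until M is exhausted. fraction(v) = cumulative count at the end
   of v's step / N ∈ (0, 1].
5. Layers: Qk = { v : fraction(v) ∈ ((k−1)/4, k/4] }.

With closing disabled this is exactly a sort by descending HU with tie
grouping, which is how the tests verify it. Layer sizes deviate from N/4 at
most by the largest tie group straddling a quartile cut (reported as
`tieSpillover`).

## Worked example

```r
library(pulmolayer)

ph <- generatePhantom(phantomSpec(seed = 3))
ph$volume
#> CTVolume 96x96x96, spacing 2x2x2 mm, HU range [-1024, 437]

lay <- computeLayers(ph$volume, ph$masks, side = "left",
                     closingRadiusMM = 4, huStep = 1)
lay
#> LayerMaskSet: N=62224 | Q1-Q4 = 15419/15683/15431/15691 | tie spillover 227/229/261
```

The left lung's 62,224 voxels split into four layers within 0.9 % of
N/4 = 15,556; the residual imbalance is bounded by the tie groups
straddling the quartile cuts (227–261 voxels). Rendering and scoring one scheme:

```r
region <- combineLayers(lay, "Q1Q2")
mips <- renderMIPSet(ph$volume, region, makeViewSet(), scheme = "Q1Q2",
                     side = "left",
                     frameMask = maskArray(ph$masks, "left", "full"))
mips
#> MIPSet: 11 views 224x224 | scheme Q1Q2 | left lung | window L200/W700
```

A full scheme-comparison experiment on the bundled demonstration cohort
(30 cases with a Q1-confined vessel-dilatation signal vs 30 controls,
grouped 3-shuffle × 3-fold × 2-repeat CV) recovers the localization: the
schemes containing the proximal layer reach a mean cross-validated AUROC of
1.00 (`full`, `Q1`, `initial`) while the periphery-only scheme `Q4` stays
at 0.63 — the signal is where it was injected.

## Command line

A thin CLI over the same functions ships in `inst/cli/pulmolayer.R`
(subcommands `phantom`, `cohort`, `layer`, `mip`, `measure`), e.g.

```sh
Rscript inst/cli/pulmolayer.R phantom --seed 1 --grid 96 --spacing 2 --out demo/
Rscript inst/cli/pulmolayer.R layer --ct demo/ct.nii.gz --masks demo/ --side left --out demo/
```

## Package layout

| Area | Files |
| --- | --- |
| S4 containers (CTVolume, LungMaskSet, OrderedFractionMap, LayerMaskSet, MIPSet, ExperimentResult) | `R/AllClasses.R`, `R/AllGenerics.R` |
| Phantom generator and signal injection | `R/phantom.R` |
| Threshold-descent layering | `R/layering.R`, `src/kernels.cpp` |
| MIP rendering and view augmentation | `R/projection.R`, `src/kernels.cpp` |
| Encoder registry and trainable tail | `R/classifier.R` |
| CV design, AUROC, scheme statistics, measurements | `R/evaluation.R` |
| Orchestration, caching, NIfTI I/O | `R/workbench.R`, `R/io.R` |

The methods vignette (`vignettes/methods.Rmd`) documents the model,
parameter choices, numerical conventions and limitations.
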