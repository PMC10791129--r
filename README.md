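# ncuquant

Quantitative analysis of the **neuro-cutaneous unit** — the interface
between epidermal keratinocytes and intraepidermal nerve fibers (IENF) —
in expansion-microscopy (ExM) z-stacks of human skin, for labs measuring
fiber ensheathment and connexin-43 (Cx43) contacts in diagnostic skin
biopsies (e.g. small fiber neuropathy vs healthy control cohorts).

The pipeline works on four-channel stacks (DAPI nuclei, WGA membranes,
PGP9.5 fibers, Cx43) and computes, inside an epidermal 3D box, the two
voxel-count statistics

```
ensheathment ratio = [px(PGP9.5) − px(PGP9.5 ∧ WGA)] / px(PGP9.5)
Cx43 contact ratio =  px(PGP9.5 ∧ Cx43 ∧ WGA)        / px(PGP9.5)
```

together with everything around them:

* **Expansion-factor QC** from epidermal nucleus sizes pre/post expansion
  (segmentation → equivalent diameters → ratio of per-section medians →
  median across sections, with SD and MAD).
* **Retrospective flat-field correction** (percentile-projection gain
  field, structure-masked, unit mean).
* **Trainable voxel segmentation**: a multi-scale feature bank (Gaussian,
  gradient magnitude, Laplacian, DoG, structure-tensor eigenvalues at
  σ ∈ {0.5, 1, 2, 4} voxels) feeding a random-forest ensemble trained on
  five consecutive fully annotated z-planes per channel, plus
  anisotropy-aware morphological opening.
* **Group comparison** of per-ROI ratios with a two-sided Mann-Whitney U
  test (exact by full enumeration for n₁+n₂ ≤ 20 without ties).
* **Calcium trace analysis** for keratinocyte/sensory-neurite co-cultures:
  dF = F/F0 (F0 = first time point), spontaneous-activity calls at an
  inclusive ≥ 10% increase, peak/onset detection, and
  keratinocyte-to-neurite lead-lag coupling.
* A **synthetic epidermis phantom** (Voronoi keratinocytes, tubular ≤ 1 µm
  fiber with a designed ensheathed fraction, 0.2–0.4 µm Cx43 puncta, PSF +
  gain field + Poisson/read noise) with exact voxel ground truth, so the
  whole chain is testable without clinical data.

Classes are S4 (`MultichannelStack`, `PhantomSpec`, `PhantomTruth`,
`RenderedPhantom`, `VoxelClassifier`, `CalciumTraceSet`); see the
methods vignette (`vignettes/ncu-quantification.Rmd`) for the models,
assumptions, parameter defaults and limitations.

## Worked example

Generate a phantom with a designed ensheathed fraction, segment the
rendered channels from five annotated planes, and recover the ratios:

```r
library(ncuquant)

spec <- phantomSpec(shape = c(64, 128, 128), nCells = 10,
                    photonScale = 200, seed = 0)
ph <- simulatePhantom(spec)
ph$truth
#> PhantomTruth: 64 x 128 x 128 voxels; 10 cells
#>   fiber voxels: 832 (494 ensheathed), Cx43 voxels: 192
#>   true ensheathment ratio: 0.6071, true Cx43 contact ratio: 0.0343

box <- do.call(epidermalBox, unname(ph$truth@epidermalBox))
masks <- lapply(c(wga = "wga", pgp95 = "pgp95", cx43 = "cx43"), function(ch) {
  tm <- slot(ph$truth, c(wga = "membraneMask", pgp95 = "fiberMask",
                         cx43 = "cx43Mask")[[ch]])
  segmentVolume(getChannel(ph$rendered@stack, ch),
                annotationsFromMask(tm, pickTrainingPlanes(tm)),
                correctGain = (ch == "wga"),
                smoothRadius = if (ch == "cx43") 0 else 1,
                voxelSize = spec@voxelSize, channel = ch, seed = 42)$mask
})
res <- quantifyROI(masks$pgp95, masks$wga, masks$cx43, box,
                   sampleId = "phantom0", group = "HC")
c(res$ensheathmentRatio, res$cx43ContactRatio)
#> [1] 0.7032967 0.0266876
```

The estimated ensheathment ratio (0.703) sits within 0.10 of the designed
truth (0.607) and the Cx43 contact ratio (0.0267) within 0.008 of its
truth (0.0343) — segmentation noise at photon scale 200, not counting
error: on the truth masks the same counting path returns the designed
ratios exactly. Group comparison on a result table:

```r
mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#> $U
#> [1] 0
#> $p
#> [1] 0.1
#> $method
#> [1] "exact"
```

A thin command-line front end covering the whole chain
(`phantom | qc-expansion | segment | quantify | compare | calcium`) is
installed at `inst/scripts/ncupipe.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/ncupipe.R", package="ncuquant"))')" \
  phantom --seed 1 --shape 24,48,48 --ncells 3 --out phantom_out/
```

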