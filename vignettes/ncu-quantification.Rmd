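---
title: "Quantifying keratinocyte-nerve fiber interactions in expanded skin"
author: "ncuquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying keratinocyte-nerve fiber interactions in expanded skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncuquant)
```

## The scientific problem

Intraepidermal nerve fibers (IENF) are unmyelinated sensory terminals of
about 1 µm calibre that run through the epidermis, where keratinocytes can
ensheathe them — the fiber tunnels *through* the cell rather than between
cells. The fraction of fiber that is ensheathed, and the frequency of
connexin 43 (Cx43) plaque contacts between keratinocytes and fibers, are
structural readouts of the neuro-cutaneous unit (NCU) with potential
diagnostic value in small fiber neuropathy (SFN). Expansion microscopy
(ExM) swells hydrogel-embedded skin sections roughly fourfold and
isotropically, so these sub-micrometre relationships become resolvable on
ordinary fluorescence microscopes.

`ncuquant` implements the full quantitative chain for four-channel
z-stacks (DAPI nuclei, WGA membranes, PGP9.5 fibers, Cx43):

1. **Expansion-factor QC** from epidermal nucleus sizes pre vs post
   expansion.
2. **Retrospective flat-field correction** of the WGA channel.
3. **Trainable voxel segmentation** per channel from five annotated
   consecutive z-planes, followed by morphological opening.
4. **3D epidermal cropping and voxel colocalization**, yielding the two
   headline statistics

   $$\mathrm{ensheathment\ ratio} =
     \frac{px(\mathrm{PGP9.5}) - px(\mathrm{PGP9.5 \wedge WGA})}
          {px(\mathrm{PGP9.5})},\qquad
     \mathrm{Cx43\ contact\ ratio} =
     \frac{px(\mathrm{PGP9.5 \wedge Cx43 \wedge WGA})}
          {px(\mathrm{PGP9.5})}.$$

5. **Group comparison** of per-ROI ratios (healthy controls vs SFN) with
   an exact Mann-Whitney U test.
6. **Calcium trace analysis** of keratinocyte/sensory-neurite co-cultures:
   dF = F/F0 normalization, spontaneous-activity calls at a ≥ 10%
   increase, and keratinocyte-to-neurite lead-lag coupling.

Because clinical raw stacks are large and not redistributable, the package
ships a **synthetic epidermis phantom** with exact voxel-level ground
truth; every stage is validated against designed answers.

## The phantom: what it emulates, and what it does not

`phantomSpec()` describes a block of epidermis (default 64 × 256 × 256
voxels at 0.25 µm isotropic; tests and the acceptance runs use
64 × 128 × 128, i.e. 16 × 32 × 32 µm, to keep runtimes in minutes):

* **Keratinocytes** as a nearest-seed (Voronoi) partition grown from
  Poisson-disc seed points. The minimum seed separation guarantees each
  cell holds one spherical nucleus plus the membrane shell; a spec that
  cannot satisfy this is rejected with a sizing error rather than silently
  degraded.
* **Membrane (WGA)** as all voxels within `membraneThickness` of an
  inter-cell boundary.
* **One connected tubular fiber** (radius 0.5 µm, i.e. the ≤ 1 µm IENF
  calibre) crossing the volume in z as a jittered random walk. Runs of
  consecutive z-planes alternate between *inter-cell* routing — those
  fiber voxels are painted into the membrane mask, as a fiber squeezed
  between membranes is WGA-positive — and *intracellular tunneling* —
  those fiber voxels are cleared of membrane. Run lengths are drawn so the
  membrane-negative fraction matches `ensheathedFraction` exactly at the
  plane level, stratified so the target holds both over the whole fiber
  and inside the epidermal box. "Ensheathed" is thus *literally*
  fiber ∧ ¬membrane by construction, the same WGA-negativity proxy the
  ratio uses on real data.
* **Cx43 puncta**: spheres with diameters uniform in 0.2–0.4 µm (the
  plaque size implied by persistence over ≥ 2 serial 100 nm sections),
  centered on membrane voxels. A fraction `cx43ContactFraction` is placed
  on or immediately adjacent to the fiber (guaranteeing voxel overlap);
  the rest stays at least two punctum diameters away. Centers keep a
  minimum separation of one punctum plus two voxels so puncta never merge
  into one 26-connected component; if the geometry cannot hold the
  requested count at that separation the generator warns and places fewer.
  The default density (120 puncta per 16 × 32 × 32 µm block, contact
  fraction 0.1) reflects the abundance of plaques at
  keratinocyte-keratinocyte contact zones and yields contact ratios of a
  few percent — the scale reported for patient material.
* **Forward imaging model**: per channel, the truth mask is blurred with a
  Gaussian PSF, a constant background is added, the result is multiplied
  by a smooth illumination gain field, scaled to expected photons,
  Poisson-sampled, and Gaussian read noise is added. The default PSF sigma
  of 0.1 µm is the *effective* resolution in biological coordinates after
  ~4× physical expansion (≈ 250 nm optical ÷ 3.8). The background term
  (5% of `photonScale`) models autofluorescence and stray light; it is
  multiplied by the gain, which is what makes retrospective flat-field
  estimation from the image itself possible at all. The gain field is
  smoothed white noise at half the image extent — vignetting-like
  inhomogeneity is very low-frequency — normalized to unit mean.

The phantom does **not** emulate: depth-dependent aberrations, layer
differentiation gradients across the epidermis, anisotropic or nonrigid
expansion distortion, fiber branching, or structured (non-Poisson) camera
noise. Passing the phantom recovery checks therefore demonstrates that the
measurement chain is unbiased under a controlled, idealized imaging model;
it does not certify segmentation quality on arbitrary clinical material,
where annotation quality dominates.

```{r phantom-example}
spec <- phantomSpec(shape = c(24, 64, 64), nCells = 4, nucleusRadius = 1.5,
                    cx43Count = 30, dermisMargin = 3, cornifiedMargin = 3,
                    seed = 1)
ph <- simulatePhantom(spec)
ph$truth
```

## Expansion-factor QC

Nuclei are segmented in 2D (pre-expansion snaps; maximum projections of
20 µm stacks post expansion) by Gaussian smoothing, global Otsu threshold,
hole filling, size filtering, distance-transform watershed for touching
nuclei, and border-object removal. Per section the factor is the ratio of
median equivalent diameters (post / pre); the overall factor is the median
across sections. The ratio-of-medians-then-median aggregation is a
deliberate choice: a per-nucleus ratio is undefined without one-to-one
nucleus pairing, which re-expansion destroys. Both SD and MAD of the
per-section factors are reported because the dispersion convention of
reported "±" values for this quantity is ambiguous. Measured sizes are
reported on the expanded scale; rescaling into biological units is left to
downstream consumers so the correction is applied exactly once.

```{r expansion-example}
img <- simulateNucleusImage(nNuclei = 10, seed = 41)
post <- simulateNucleusImage(nNuclei = 10, seed = 41, scaleFactor = 3.83)
pre <- measureNuclei(segmentNuclei2D(img), 0.5, "s1", "pre")
postTab <- measureNuclei(segmentNuclei2D(post), 0.5, "s1", "post")
estimateExpansionFactor(pre, postTab)$medianFactor
```

## Flat-field correction

Uneven illumination across the epidermal layers is modeled as a smooth
multiplicative field with unit mean. The estimator is retrospective: the
per-pixel 20th-percentile projection across z tracks background (which
scales with the gain thanks to the ever-present autofluorescence floor).
Two robustness measures matter in practice:

* z-windowed averaging (window = nz/4, capped at 8 planes) before taking
  the percentile — the low quantile of a Poisson variate is biased by
  ≈ −0.84 σ, and averaging shrinks that bias by √window;
* structure masking: pixels whose projection exceeds twice the median
  (e.g. membrane walls running through every plane) are excluded and
  infilled by normalized smoothing of their surroundings.

Heavy Gaussian smoothing (σ = image width / 8) then removes residual
structure, and the field is normalized to unit mean so correction
preserves total intensity. This is a percentile-projection flat-field, not
a low-rank + sparse decomposition; the latter could be dropped in behind
the same two-function interface (`estimateGainField`,
`correctIllumination`). By default only the WGA channel is corrected; a
flag on `segmentVolume` extends it to other channels.

## Voxel classification

Per channel, each voxel is described by a multi-scale 2D feature bank
computed per z-plane: Gaussian-smoothed intensity, gradient magnitude,
Laplacian, difference-of-Gaussians (σ vs 1.6 σ), and the two structure-
tensor eigenvalues, at σ ∈ {0.5, 1, 2, 4} voxels (24 features). A
random-forest ensemble (bagged, feature-subsampled trees trained in a
single boosting round) is fit on **exactly five consecutive, fully
annotated z-planes** — the training contract mirrors manual annotation
practice, where a human paints a thin slab rather than scattered voxels.
Training is class-balanced; because sparse structures (a thin fiber, Cx43
puncta) may contribute only tens of positive voxels in five planes, the
minority class is upsampled with replacement to the majority count
(capped at 4000 per class) instead of downsampling the majority — keeping
background diversity is what makes puncta segmentation precise. The
probability threshold is 0.5 and ties go to foreground, a fixed documented
tie-break. Predictions are deterministic for a fixed seed, and a
serialized classifier reloads to bit-identical predictions.

Binary masks are smoothed by morphological **opening** (erosion then
dilation) with an ellipsoidal element, the axial radius scaled by the
voxel-size ratio. Opening is the right order for speck removal and is
idempotent; the radius default is 1 voxel. For punctate channels (Cx43)
smoothing should be disabled — an opening of radius 1 deletes objects at
the plaque scale, which is the filter's purpose on membranes and fibers
but destructive on puncta.

## Counting, ratios and group comparison

Colocalization is strict voxel-wise logical AND with no proximity
tolerance — the statistics are pure pixel-count ratios, so adding a
distance band would change their definition (a dilation-based tolerance is
available explicitly, default off). All counting is restricted to an
axis-aligned epidermal box that excludes dermal fiber signal below and the
stratum corneum above; in the phantom the box also excludes a one-voxel
border so boundary-clipped membranes never enter counts. Boxes are
1-based, inclusive integer ranges per (z, y, x) axis — the natural
convention for R array indexing.

A ROI with zero fiber voxels yields a *flagged missing* ratio, never 0 or
1, so fiber-free ROIs cannot bias group means. Ratios are kept as
fractions end to end and only formatted as percentages in reports.

The serial-section plaque-persistence rule (keep Cx43 components spanning
≥ 200 nm of axial extent, i.e. ≥ 2 sections of 100 nm) is implemented as a
3D connected-component filter. It is **off by default** in the ExM
pipeline — it is a criterion for serial-section array tomography — and
available as a flag.

Group statistics are computed over ROIs (the cohort sampling unit:
13 HC vs 10 SFN ROIs), not pooled voxels and not per-subject aggregates;
per-subject aggregation can be performed on the result table if wanted.
The Mann-Whitney U test is two-sided; for n1 + n2 ≤ 20 without ties the
null distribution is enumerated completely (all C(n1+n2, n1)
assignments), otherwise a normal approximation with tie and continuity
correction is used. Descriptives include mean, SD (n−1), median, IQR,
min, max — both SD and IQR because the "±" convention of reported cohort
summaries is often unstated.

```{r mw-example}
mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
```

## Calcium traces

Normalization is literally dF = F/F0 with F0 the first time point — a
ratio, not a relative change; `relativeTraces()` exposes the
(F − F0)/F0 view for interoperability, and a robust baseline (mean of the
first k frames) is available but off by default because the definition
fixes the first frame. Activity requires a ≥ 10% increase, *inclusive*
(max dF ≥ 1.10 exactly is active). Peaks are local maxima of a 5-frame
moving average with prominence ≥ 0.10; the onset is the last frame before
the peak at or below 20% of the rise. Coupling pairs each neurite peak
with the nearest earlier keratinocyte onset within a 30 s window; the
window and onset fraction are free parameters (the underlying observation
is qualitative) and are echoed in every output. At 4 Hz sampling, a
designed 2 s keratinocyte lead is recovered in sign in ≥ 19/20 simulated
pairs; the lead magnitude carries a ± 1–2 s detector bias from smoothing
and onset discretization, which is why the recovery criterion is the sign,
not the value.

## Numerical and design choices

* **Determinism**: every stochastic step (phantom geometry, rendering,
  classifier subsampling and tree growth) derives from explicit integer
  seeds; identical specs give bit-identical volumes, and the RNG state of
  the calling session is restored afterwards.
* **Array convention**: (z, y, x[, channel]) with physical sizes in µm;
  boxes inclusive 1-based.
* **Morphology at borders**: erosion treats out-of-volume voxels as
  foreground so objects touching the border are not eroded from outside;
  the epidermal box excludes the border anyway.
* **3D connected components** use 26-connectivity (6-connectivity
  available), implemented as a vectorized frontier BFS.
* **TIFF IO**: multi-page TIFF with a JSON sidecar for channel names,
  voxel sizes and intensity scale; integer round trips are exact, float32
  round trips are exact to single precision.
* **Problem sizes**: tests and the acceptance script run 10 phantoms at
  64 × 128 × 128 voxels, chosen as the smallest volume that holds ~10
  keratinocytes at realistic cell size and a fiber long enough for stable
  ratio statistics.

## Known limitations

* The voxel classifier is a stand-in for whatever proprietary model a lab
  uses; the training contract (five consecutive planes per channel) and
  the feature bank are fixed, but absolute Dice on real stacks depends on
  annotation quality.
* The flat-field estimator assumes a nonzero background that scales with
  the gain; a channel with truly zero background (or background dominated
  by gain-independent camera offset) would need offset subtraction first.
* The exact Mann-Whitney implementation enumerates up to n1 + n2 = 20;
  cohorts at this scale (23 ROIs) use the corrected normal
  approximation, as standard tools do.
* Expansion-factor QC assumes isotropic expansion; it cannot detect
  nonrigid distortion (explicitly out of scope — the nucleus statistic
  replaces manual ROI alignment).
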