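---
title: "Quantifying ER organisation in an image-based siRNA screen: models, parameters and validation"
author: "erscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER organisation in an image-based siRNA screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

The endoplasmic reticulum of an adherent mammalian cell has two visually
distinct domains: a bright, dense perinuclear region enriched in sheet ER,
and a peripheral network of tubules whose junctions enclose polygonal gaps
of cytoplasm. Perturbations that remodel the ER shift two complementary,
per-cell readouts:

* **mean tubular-ER polygon area** (µm²) — the average area of the regions
  fully enclosed by tubules in the peripheral network. Larger polygons mean
  a sparser network; smaller polygons a more densely packed one.
* **% dense perinuclear ER** — the percentage of the cytoplasm occupied by
  high-intensity ER signal within the perinuclear zone, a proxy for the
  extent of sheet ER. An increase reads as expansion of the sheet ER, a
  decrease as its contraction.

`erscreen` implements these readouts as an automated pipeline for 96-well
siRNA screens imaged in three channels (a general-ER reporter such as
Sec61β-mEmerald, a nuclear stain, a plasma-membrane stain), together with
the surrounding screen machinery: plate-layout handling, seeded-watershed
segmentation, INCENP-based transfection QC, per-well cell sampling and
Dunnett many-to-one statistics against a pooled non-targeting control
(NTC). Because no public image set accompanies this assay, the package
also contains a synthetic-microscopy generator with exact ground truth;
every stage is validated against it.

## The synthetic-data generator

`synthesize_cell()` renders a cell as concentric geometry at 0.28 µm/px
(the effective lateral resolution of a 63×/1.15 NA water objective on a
confocal high-content system; all defaults below are stated in pixels at
this scale):

* a disk of radius `cell_radius` (default 64 px ≈ 18 µm, a well-spread
  U‑2 OS-sized cell) outlined by a bright membrane rim;
* a nucleus: one disk of radius `nucleus_radius` (default 19 px ≈ 5.3 µm),
  or, for the INCENP phenotype, a connected union of 4–7 overlapping lobes
  around a small core. The union reaches ~2.5–3× the normal nuclear area,
  reflecting the polyploid, grape-like nuclei left by 72 h of failed
  nuclear fission, with strongly reduced circularity;
* a dense perinuclear annulus starting at the nucleus edge, of width
  `dense_band_fraction × (cell_radius − nucleus_radius)` (default 0.25)
  drawn at `dense_intensity_ratio` (default 3) times tubule brightness;
* a peripheral tubule mesh: seed points on a jittered square lattice
  (`mesh = "voronoi"`, irregular convex-ish faces) or an exact hexagonal
  lattice (`mesh = "hex"`, used for closed-form oracles) with spacing
  `tubule_spacing` (default 8 px ≈ 2.2 µm, a dense tubular mesh), drawn as
  the locus where the two nearest-seed distances differ by at most
  `tubule_width` (default 2 px). The enclosed faces of this mesh — the
  connected non-tubule components that touch neither the dense band nor
  the cell edge — are recorded as ground-truth polygons by pixel counting,
  and the dense-ER ground truth is the exact pixel share of the annulus in
  the cytoplasm.

The noise model is applied last, in order: Gaussian blur (σ 1 px, a PSF
proxy), Poisson shot noise at `photon_scale` 200 expected photons per
unit intensity, additive Gaussian read noise (σ 3 counts), rounding to
non-negative integer counts. With `enabled = FALSE` the clean piecewise-
constant render is returned; several exactness tests rely on this.
Optional 5-slice z-stacks give each cell its own in-focus slice (cells
sit at different heights) with blur and attenuation growing away from it;
the default maximum-intensity projection then outperforms any single
slice, which is asserted on generated stacks.

`synthesize_screen_plate()` composites whole wells: cell radii are
log-normal (CV 12%), nuclear radii a log-normal fraction (0.30) of the
cell radius, tubule spacing and dense-band fraction log-normal around
their (condition-scaled) means (CV 15% and 10%). Condition effects are
multiplicative shifts of tubule spacing (`polygon_effect`) and dense-band
fraction (`dense_effect`); INCENP wells draw multilobed nuclei at a
configurable rate (default 0.8). Cell density defaults to ~4 cells per
384–448 px field; placements are rejection-sampled non-overlapping
circles and may touch the field border, where they are flagged and later
excluded. The outer 36 wells of the plate hold untreated cells (edge-
effect sinks) and are not simulated by default since they never enter
analysis.

What the generator does *not* emulate: real PSF structure and spectral
bleed-through, intensity vignetting, cell crowding and touching cells,
three-way ER morphology (tubules/sheets/matrices), or biological
covariation between readouts. Passing tests therefore demonstrate that
the measurement and statistics machinery is correct and calibrated on
images with these properties — not that the pipeline is robust to every
artefact of real microscopy.

## Segmentation

Nuclei: smooth (σ 2 px) → global Otsu threshold → morphological closing
(radius 2 px) → hole filling → distance-transform watershed with a high
merge tolerance (8 px) → size filter (≥ 50 µm²). The closing and the
tolerance deliberately keep the lobes of a multilobed nucleus as one
object, because the INCENP phenotype is scored on whole-nucleus area and
circularity; touching nuclei of distinct cells are still split.

Cells: seeded watershed (`EBImage::propagate`, the constrained seeded
region growing common in high-content pipelines) grown from the nucleus
labels over the smoothed membrane intensity, restricted to a foreground
mask obtained by filling the thresholded membrane outline and then
intersecting with pixels that carry ER signal (above 0.4× the median
smoothed ER intensity of the foreground). The ER-support step matters:
the filled hull of two closely apposed cells can span the dark pocket
between them, and without it that background is annexed into a cell and
scored as huge spurious "polygons". When no membrane channel exists the
smoothed ER channel serves as both landscape and foreground source.
Labels touching the image frame are excluded from all analysis.

## The two ER readouts

**Perinuclear band.** The band is defined in normalised radial
coordinates: a cytoplasm pixel belongs to it when
`d_nuc / (d_nuc + d_mem) ≤ band_fraction` (default 0.5), where `d_nuc`
and `d_mem` are exact Euclidean distances to the nucleus and to the cell
exterior. The distances come from an exact separable distance transform
(compiled; lower-envelope algorithm), so the band agrees pixel-for-pixel
with a brute-force nearest-neighbour search — a property the tests assert
literally. `band_fraction` 0 gives an empty band, 1 the whole cytoplasm.

**% dense perinuclear ER.** Dense pixels are ER intensities above a
per-cell threshold, intersected with the band, divided by the cytoplasm
area. The default threshold is *peripheral-referenced*: 1.25× the 90th
percentile of ER intensity in the cytoplasm outside the band. The
rationale: the quantity of interest is signal brighter than tubules, and
the peripheral cytoplasm provides a per-cell estimate of tubule
brightness regardless of the absolute intensity scale. A median + k·MAD
variant over the whole cytoplasm is available
(`morph_config(dense_thresh_method = "mad")`), but with a gap-dominated
intensity distribution its threshold sits below tubule brightness, so
tubules crossing the band would be mis-counted as dense ER and inflate
the readout by several points whenever the true dense annulus is thinner
than the measuring band; it is therefore not the default. Both variants
are scale-free: multiplying the ER channel by any constant leaves the
readout unchanged (asserted as a test).

**Tubular polygons.** Within the peripheral region (cytoplasm minus the
band) the ER image is lightly smoothed (σ 0.5 px; a Hessian-ridge
"tubeness" enhancement is available for uneven backgrounds) and
binarised by Otsu's threshold computed over peripheral pixels. Polygons
are the connected components of the non-tubule pixels that are *fully
enclosed* — components touching the band edge, the cell edge or the
image frame are discarded, which prevents unbounded background counting
— and at least `min_polygon_area_um2` (0.25 µm²) large. Areas convert to
µm² by the squared pixel size. The smoothing scale is deliberately small:
at σ 1 the recovered tubule lines thicken enough to bias face areas ~13%
low on the hexagonal-lattice oracle; at σ 0.5 the bias is ~1–2%, inside
the 10% oracle tolerance, while binarisation remains reliable at the
default noise level because tubule-to-gap contrast is large.

**Nuclear shape.** Circularity is `4πA/P²`, clipped at 1. The perimeter
estimator is fixed and named: the *half-pixel-offset smoothed boundary
chain* — trace the 8-connected outer contour, smooth the vertex
coordinates with a circular moving average (window 5) to remove the
digitisation staircase, sum the closed polyline length, and add π for
the half-pixel outward offset of pixel centres relative to the true
region boundary. On rasterised disks (r ≥ 30 px) it yields circularity
≥ 0.95 and on axis-aligned squares (side ≥ 50 px) values within 5% of
the continuum π/4; both are asserted. Circularity thresholds elsewhere in
the package assume this estimator.

Per-cell means aggregate polygon areas; a cell with no enclosed polygon
reports a missing mean (never 0), and such cells are excluded pairwise
from the polygon readout only.

## INCENP transfection QC

INCENP knockdown blocks nuclear fission and produces enlarged, irregular
multilobed nuclei — a visible transfection reporter. A nucleus is called
multilobed when its area exceeds an area threshold *and* its circularity
falls below a circularity threshold. The default thresholds are
calibrated on the generator's normal-nucleus population pushed through
the full segmentation and measurement path: the 97.5th percentile of
area and the 2.5th percentile of circularity (n = 600, seed 101;
`calibrate_nucleus_classifier()` regenerates them after any change to
the generator geometry). On balanced held-out sets this classifier is
~95% sensitive and >99% specific. Plate efficiency is the mean phenotype
fraction over the two INCENP wells (a config flag demands every well
individually instead — the assay description does not say which rule the
original screen used), and the plate gate is inclusive at 65%. Because a
percentage estimated from few dozen nuclei is noisy, QC wells default to
more imaged fields than candidate wells (`incenp_fields`), mirroring
real screens where QC wells are scored over many fields.

## Screen statistics

Analysis drops edge and INCENP wells, then samples up to 70 cells per
well without replacement (seeded; short wells contribute everything with
a warning). With 3 wells per target this yields the ≥ 210 cells per
condition that the assay design calls for; the NTC control pools its
wells (9 in a full three-replicate screen) into one group.

Each readout is tested by one-way ANOVA with single-step Dunnett
many-to-one comparisons against the pooled NTC (equal-variance pooled
estimate, two-sided, multivariate-t critical distribution via
`multcomp`). The quasi-Monte-Carlo integration inside the multivariate-t
is pinned to an internal seed so results are reproducible and invariant
to the order conditions appear in the data. Adjusted p-values map to the
conventional star levels (* < 0.05, ** < 0.01, *** < 0.001,
**** < 0.0001; ns otherwise), and a direction (increased/decreased) with
its biological interpretation — decreased polygon area → "more densely
packed tubular ER network", increased → "less dense tubular ER network";
increased dense fraction → "expansion of the dense sheet ER", decreased
→ "contraction of the sheet ER" — is assigned only to significant
conditions.

Hit calling controls the family-wise error of the *whole screen*: a
screen calls a condition if either readout fires, so the advertised α
(default 0.05) is split across the two readouts before the Dunnett
adjustment (a condition is a hit when its adjusted p < α/2 on some
readout). Within a single readout the Dunnett procedure is exact, which
the tests verify three ways: the two-group limit equals the pooled
t-test to 1e-6; a toy fixture matches a 10⁶-draw Monte-Carlo max-|t|
oracle to 1e-3; and the null family-wise error over 1000 simulated
screens lands at 0.05 ± 0.02.

The unit of analysis defaults to the cell, mirroring per-cell screen
analyses of this kind; because within-well pseudoreplication is a known
caveat of that choice, `analyze_screen(unit = "well")` aggregates to
well means first. The generator draws cells independently within wells,
so the cell-level default is exactly calibrated on simulated screens;
on real data the well mode is the conservative option.

## qPCR knockdown quantification

Relative expression uses the −ΔCt method: per replicate,
ΔCt = Ct(target) − Ct(GAPDH); per sample the relative expression is
2^−(mean ΔCt − mean ΔCt(NTC)). Normalising by the control's *mean* ΔCt
makes the NTC self-normalise to exactly 1. Group comparisons run on the
replicate ΔCt values by one-way ANOVA with Tukey's HSD, the standard
choice when several siRNAs are compared among themselves as well as to
the control. Three biological replicates are the expected design.

## Numerical choices and degenerate inputs

* Otsu thresholds use a 256-bin histogram on intensities normalised to
  [0, 1]; ties in the between-class variance resolve to the lowest bin.
* The exact Euclidean distance transform is compiled (separable
  lower-envelope parabolas); `Inf` is returned when the target set is
  empty.
* Mesh rendering finds nearest/second-nearest lattice seeds in the 3×3
  lattice neighbourhood of each pixel's node (compiled), which is exact
  for the jitter amplitude used (±0.35 × spacing).
* A uniform ER channel yields 0% dense ER under both threshold variants;
  a cell with no peripheral region yields no polygons; an empty nucleus
  mask or a nucleus outside its cell raises a geometry error; blank
  nuclear images segment to zero nuclei and zero cells (with a warning).
* All simulator randomness is seeded per object (cell, field, well) by
  integer derivation from one top-level seed and restores the caller's
  RNG state, so identical inputs reproduce identical images bit for bit.

## Validation problem sizes

The shipped tests validate the pipeline at sizes chosen to exercise each
claim while staying desk-runnable: recovery of both readouts across a
4×4 grid of (tubule spacing × dense-band fraction) with 30 cells per
point (rank correlation ≥ 0.9, dense error ≤ 3 points); hexagonal-
lattice and per-pixel band oracles; Dunnett calibration over 1000
simulated screens plus a 10⁶-draw Monte-Carlo fixture; and 20 seeded
end-to-end screens of 23 conditions (effect conditions on 3 wells, null
conditions on 2, NTC on 6 fields per well, INCENP QC wells on 9) at
384 px fields and ~4 cells/field, in which two
"denser-network/expanded-sheet" conditions and one "sparser-network"
condition among 20 nulls must be recovered exactly, with directions, no
false positives at screen-wide α = 0.05, and INCENP wells simulated at
an 0.8 phenotype rate passing the 65% gate. These sizes put every group
within the regime where the cell-level Dunnett analysis is calibrated
(a screen following the full assay design — 70 cells × 3 wells per
condition — sits far deeper inside it).

## Known limitations

Absolute polygon areas are biased low relative to geometric truth (tubule
lines thicken under the PSF and binarisation), so the readout is used
comparatively — against the in-screen NTC — exactly as the assay
intends; rank correlation with truth exceeds 0.9 across the tested
grid. A sparser tubule mesh slightly lowers the measured dense fraction
(fewer bright tubule crossings inside the band), a ~1-point coupling
visible on strong polygon effects. The multilobed classifier is
calibrated on the generator's phenotype geometry and should be
recalibrated for real assays. The generator's simplified optics and
isolated, convex cells mean segmentation performance on real confluent
monolayers will be worse than the IoU ≥ 0.8/0.9 achieved here.
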