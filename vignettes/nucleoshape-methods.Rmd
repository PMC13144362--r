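---
title: "Quantifying nucleolar shape and the chromatin-nucleolus interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar shape and the chromatin-nucleolus interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(nucleoshape)
library(dplyr)
```

## The measurement problem

Nucleoli are the largest membraneless organelles of the nucleus. In live
cells they are typically irregular, with alternating concave and convex
stretches of boundary, and they are wrapped in a thin shell of
peri-nucleolar heterochromatin; chromatin also reaches into the nucleolar
interior as discrete foci. Perturbations that detach chromatin from the
nucleolar surface make nucleoli rounder and darker inside. Quantifying
this phenotype requires a chain of image measurements:

1. segment nuclei and nucleoli from fluorescence channels;
2. split each nucleus into *nucleolar interior*, *peri-nucleolar rim* and
   *nucleoplasm* by mask shrink/expand algebra, and measure chromatin
   enrichment ratios in those compartments;
3. measure nucleolar shape (ellipse-fit aspect ratio, circularity) and
   summarise per nucleus;
4. detect intranucleolar chromatin foci and build concentric-ring radial
   intensity profiles from each focus to the nucleolar edge;
5. measure the signed nanometre displacement between two fluorophores
   across the nucleolar boundary by Gaussian line-profile fitting with
   bead-based chromatic-aberration correction;
6. normalise fluorescence-recovery (FRAP) traces; and
7. aggregate a high-content siRNA screen from per-cell records to
   per-gene values.

Every stage is implemented here against a synthetic microscopy-scene
generator that knows the ground truth, so each measurement can be tested
as a parameter-recovery problem rather than by eyeballing.

## The synthetic scene model

`scene_params()` describes a scene; `generate_scene()` renders it and
returns exact ground truth. The geometric model is:

* **Nucleus**: a filled ellipse (default semi-axes 78 x 100 px).
* **Nucleoli**: star-convex regions with boundary radius
  $r(\theta) = r_0\,(1 + \sum_m a_m \cos(m\theta + \varphi_m))$ — a
  low-order Fourier perturbation of a circle. It is smooth, its
  irregularity is tunable through the amplitudes $a_m$, and its area,
  perimeter and moments admit dense-quadrature / super-sampled ground
  truth (the package uses 8192 quadrature nodes and 8x super-sampling;
  both agree with closed forms for circles and ellipses to better than
  0.5%).
* **Chromatin channel**: nucleoplasm baseline (default 100 photons),
  interior factor 0.5 inside nucleoli, a peri-nucleolar band at factor
  2.0 spanning `rim_width_nm` (default 200 nm) on *each side* of the
  nucleolar boundary, and bright foci at factor 1.0 (2x contrast over
  the darkened interior). The band straddles the boundary deliberately:
  peri-nucleolar heterochromatin overlaps the marker-based nucleolus
  segmentation inward, which is exactly why interior masks are *shrunk*
  before measuring interior chromatin. The band's extent uses the same
  Euclidean pixel-set distance as the morphological shrink/expand
  operators, so eroding the true mask by the rim width exactly excludes
  it and dilating exactly covers it — the analysis convention and the
  generative convention coincide by construction rather than by half-pixel
  accident.
* **Nucleolus channel**: uniform fill (150) with a dim nucleoplasm pool
  (15), emulating a granular-component marker.
* **Marker channel(s)**: a Gaussian shell of the signed boundary distance
  with sigma 100 nm, at a signed offset `offset_nm` (positive = towards
  the nucleolar interior). The default +100 nm emulates an interface
  protein sitting just inside the chromatin rim centre; with
  `coat_foci = TRUE` the marker also coats each focus surface, which is
  what produces the characteristic radial ordering around intranucleolar
  foci.
* **Optics and noise**: per-channel sub-pixel chromatic shift (applied by
  Fourier phase shift, so structure moves but noise stays uncorrelated
  between channels), Gaussian PSF blur (default sigma 40 nm = 1 px at the
  default 40 nm pixel), then Poisson shot noise on the blurred field and
  additive Gaussian read noise (SD 2). No public noise figures exist for
  the motivating acquisitions; the defaults correspond to a
  photon-limited confocal image with peak SNR around 10, chosen once as
  typical and not revisited. `no_noise()` disables both noise terms for
  oracle tests.

Scenes are bit-identical for identical parameters and seed.

What the generator does *not* emulate: uneven illumination or background
gradients, cell-to-cell intensity variation, touching nuclei, 3D defocus
(z-stacks are supported at the container level, with the analysis run on
the highest-marker-mean slice), and camera artefacts. Tests passing on
these scenes therefore demonstrate correctness of the measurement
algebra and estimator calibration, not robustness to every real-world
artefact.

## Segmentation choices

`segment_regions()` implements adaptive Otsu thresholding: Otsu
thresholds are computed on a grid of `window_px` windows (defaults 101 px
for nuclei, 51 px for nucleoli) and bilinearly interpolated to every
pixel. Two guards make this robust:

* Local thresholds are clamped to `[0.7, 1.5]` times the global Otsu
  threshold — otherwise windows containing only background segment their
  own noise. The same convention is used by established high-content
  pipelines.
* `otsu_classes = 3` switches to three-class Otsu with the middle and
  upper classes as foreground. This is the standard option for a
  chromatin channel whose foreground contains a much brighter
  substructure (the peri-nucleolar band can be 4x the nucleoplasm):
  two-class Otsu then bisects foreground from bright band instead of
  background from cell.

Masks are hole-filled, components below `min_area_px` are removed, and
labelling is 8-connective. Children (nucleoli, foci) are linked to the
parent owning the plurality of their pixels; ties go to the lower parent
label, and children mostly on background are dropped.

Nucleus-level QC excludes nuclei whose area or circularity falls outside
mean ± 2 SD across the analysed dataset, or whose nucleolar-marker mean
is below a floor. With fewer than 3 nuclei the SD is undefined and the
shape exclusion is skipped with a warning; with SD = 0 the interval is a
point and equality passes.

## The partition and enrichment ratios

`make_partition()` uses distance-threshold (Euclidean disc) morphology:
interior = nucleolus eroded by `k_px`; rim = nucleolus dilated by `k_px`
minus the interior; nucleoplasm = nucleus minus all dilated nucleoli; all
clipped to the parent nucleus. The disc element makes `k_px` directly
interpretable in nanometres: `default_k_px()` returns
`round(200 / pixel_size_nm)`, i.e. 5 px at 40 nm/px for a ~200 nm rim
half-width. The implementation (EBImage's exact Euclidean distance map)
is tested for *exact* agreement against a brute-force pairwise-distance
oracle.

`enrichment()` averages the per-nucleolus region means across the
nucleolar children of a nucleus first and then divides by the parent's
nucleoplasm mean, so nuclei with several nucleoli are not dominated by
the largest one. A uniform image gives exactly 1 by construction. On the
standard synthetic scene the recovered ratios carry a small, fully
explained bias (rim ≈ 1.91 for a true 2.0, interior ≈ 0.57 for a true
0.5): the 1 px PSF bleeds the bright band across the interior edge, and
the focus contributes ~2% to the interior mean. Both effects shrink with
larger nucleoli and narrower PSFs; recovery stays within 15% of truth
under the default conditions and the ratios order strictly with the true
rim factor.

## Shape metrics

Aspect ratio uses the moments-equivalent ellipse (identical normalised
second central moments) — the parameter-free "fit an ellipse" convention
of standard image-analysis software. Circularity is
$4\pi\,\mathrm{area}/\mathrm{perimeter}^2$.

The perimeter estimator deserves a note, because discrete estimators
disagree more than one might expect. Counting weighted boundary steps
(straight/diagonal/corner at $1, \sqrt2, (1+\sqrt2)/2$) is exact on
axis-aligned rectangles but overestimates a disc's perimeter by ~5%
(circularity 0.91); pure Cauchy–Crofton direction counting is near-exact
on discs but underestimates a square by ~6% (circularity 0.88 instead of
$\pi/4 = 0.785$). Neither meets the package's accuracy goals on both
shapes, so `shape_metrics()` measures the length of the sub-pixel 0.5
iso-contour of the lightly smoothed mask (Gaussian sigma 1 px, marching
squares with linear interpolation). That estimator is near-exact on both
families (disc circularity 0.99, square 0.81) and rotation-stable to
within 3%. Very small discs can exceed circularity 1 slightly — a known
discretisation artefact that is reported unclipped with a flag.

Per-nucleus summaries take the median across child nucleoli (midpoint of
the central pair for even counts), the summed nucleolar area, and the
count.

## Intranucleolar foci and FC regions

Foci are segmented per nucleolus: erode the nucleolar mask by 20 px to
form an interior sub-region clear of the rim; subtract the upper quantile
(default the 75th percentile — "upper quartile" is the standard reading,
and the quantile is per-nucleolus so a bright nucleolus does not mask a
dim one) of chromatin intensity in that sub-region; clip negatives;
Gaussian-smooth (sigma 1 px, configurable); Otsu-threshold within the
sub-region; and keep components with area strictly above 15 px and
circularity strictly above 0.7. The strict inequalities are semantic
("above 15 pixels"), and the tests pin them with planted 15 px and 16 px
components. On the default noisy scenes, detection of 4 px-radius,
2x-contrast foci achieves F1 = 1.0 over 20 scenes.

FC (fibrillar-centre) regions come from an externally supplied
pixel-classifier probability map: threshold at 0.5, label inside
nucleoli, link to parents, and report per nucleus the median FC area and
the FC density (count over summed nucleolar area). Training a classifier
is out of scope by design — the probability map is an input.

## Concentric rings and radial profiles

The "50 concentric rings from the focus to the edge of the expanded
nucleolus" construction is realised with the normalised radial coordinate

$$ f(p) = \frac{D_a(p)}{D_a(p) + D_e(p)}, $$

where $D_a$ is the distance to the anchor and $D_e$ the distance to the
nearest non-mask pixel; ring index $= \min(n, \lfloor f\,n\rfloor + 1)$.
Rings conform to the mask edge for irregular masks — the edge is always
ring $n$ — which is the property the radial-distribution measurement
needs. The implementation is tested for pixel-exact agreement with a
brute-force oracle. One geometric consequence worth knowing: for an
anchor *on* the mask edge, $f$ jumps from 0 (the anchor pixel) to at
least 1/3 one pixel away, because $D_e$ can grow at most one pixel per
pixel of $D_a$; low rings other than ring 1 are then structurally empty.

Per-ring channel means are computed on raw intensities; empty rings are
missing values, not zeros, so min–max scaling is not distorted.
`piecewise_minmax()` rescales each channel independently within rings
1–15 (around the focus) and 16–50 (around the rim); constant segments
map to zero, and the scaling is idempotent. `sector_profile()` applies
the same construction from the mask centroid with 10 bins and a single
scaling segment, snapping the anchor to the nearest mask pixel (with a
flag) for crescent-shaped masks. One ring profile is produced per focus;
profiles of nearby foci are not merged.

On the standard scene the pipeline reproduces the qualitative interface
ordering: around the focus the marker (which coats the focus surface)
peaks at a larger ring than chromatin; at the periphery the marker peaks
inside the chromatin rim peak while the nucleolar fill falls across the
marker peak.

## Two-colour displacement at the boundary

`extract_line_profile()` samples each channel by bilinear interpolation
at 1 px steps along an oriented outside-to-inside segment, averaging two
parallel lines (the conventional 2 px width). Per channel the profile is
background-corrected by subtracting its minimum and normalised to unit
sum, then a 3-parameter Gaussian $A e^{-(x-\mu)^2/2\sigma^2}$ is fitted
(no constant offset: the baseline is ~0 after the subtraction, and the
fourth parameter destabilises fits on short profiles). Initialisation is
deterministic — $\mu_0$ at the argmax, $A_0$ the maximum, $\sigma_0$ the
half-width at half-maximum over 1.177 — so results are reproducible
without random restarts.

The displacement is $\Delta = \mu_a - \mu_b$ along the line (positive =
channel *a* deeper towards the nucleolar interior); reversing the line
orientation flips the sign exactly. Where the original workflow
discarded bad fits by visual inspection, the package substitutes an
explicit automated rule: a line is accepted only if both fits converge
with $r^2 \ge 0.8$ and both sigmas lie within 0.5–10 pixel-sizes. Both
thresholds are configurable; on clean simulated lines about 80% pass,
the rejections coming from the small positive noise floor that the
minimum-subtraction leaves and the offset-free model cannot absorb. The
accepted mean stays unbiased: across true offsets −60…+60 nm the
recovered means are within a few nm, strictly ordered, with zero-offset
bias well under 5 nm at n = 200 lines.

Chromatic aberration is calibrated from a two-channel bead field:
local-maximum detection, 5x5 intensity-weighted-centroid refinement
(sufficient for mean-offset estimation at 0.1 px accuracy, far cheaper
than per-bead PSF fitting), mutual-nearest matching, and the mean
(dy, dx) offset with its dispersion from at least 5 pairs. The
correction projects the 2D offset onto the unit line direction and
subtracts it from $\Delta$ — correcting the measurement without
resampling the image. An injected 0.5 px shift is recovered to within
0.1 px and the corrected displacement bias drops below 10 nm. Pooling
for reporting is per line (with per-nucleus means also available),
matching how such displacements are usually quoted.

## FRAP normalisation

The motivating experiments name a reference region (inside the cell,
away from the bleach) and a background region (outside the cell) without
stating the formula, so the package adopts double normalisation — the
standard that cancels acquisition photobleaching:

$$ N(t) = \frac{(B(t) - G(t)) / (R(t) - G(t))}
               {\left\langle (B - G)/(R - G) \right\rangle_{\text{pre}}} $$

Pre-bleach normalises to 1 (the pre-bleach mean, not the first
post-bleach point, anchors the curve). The plateau is the mean of the
last 20 frames and the apparent recovery fraction is
$(\text{plateau} - \text{floor})/(1 - \text{floor})$ with the floor at
the first post-bleach frame. The floor estimate includes whatever
recovery happened during the first frame interval, which biases the
recovery fraction slightly low (0.59 recovered for a true mobile
fraction of 0.60 at rate 0.05/frame) — visible, quantified, and well
inside the ±0.05 band. Aggregation resamples curves onto the first
curve's grid by linear interpolation and reports pointwise mean ± SD
with n. A single-exponential fit is available (`fit_recovery_exponential()`)
but is deliberately not part of the standard pipeline, which reports raw
recovery curves.

## Screen aggregation

Per-cell records carry a well, gene, siRNA, class label and measurement.
Class labels are inputs from any upstream classifier — the package never
trains one. `filter_cells()` keeps interphase cells and computes
per-gene apoptotic fractions on the pre-filter set;
`exclude_genes()` drops genes whose fraction is *strictly* greater than
20% ("more than 20%" — exactly 20% is retained).
`summarize_screen()` takes the per-well median of the per-cell value,
then the per-gene mean of its wells' medians; control wells are kept as
per-well medians, their median being the reference for per-gene deltas.
`rank_rounding_hits()` orders non-excluded genes by ascending value
(rounder nucleoli have aspect ratios nearer 1) with lexicographic
tie-breaks. Summaries are invariant to input row order, and filtering
commutes with summarisation. On a simulated 50-gene screen with evenly
spaced true shifts (2 siRNAs x 3 wells x 200 cells), recovered gene
ranks correlate with truth at Spearman ≈ 1.0.

## Problem sizes and test design

The test-suite and the acceptance script use: 256 x 256 px scenes at
40 nm/px; 200 lines per displacement condition across five true offsets;
50 beads for chromatic calibration; 20 random masks for the ring oracle
and 6 for the exact partition oracle; 20 noisy scenes for foci F1; 15
FRAP curves of 400 frames; and a 50-gene, 324-well, ~60k-cell simulated
screen. These sizes give stable estimates (the enrichment ratios, for
example, vary by under ±0.005 across seeds) while keeping a full run in
about a minute.

Where a check has an independent route — brute-force distance
transforms, quadrature closed forms, spreadsheet-style recomputation,
analytic FRAP expectations — the test compares the implementation
against that oracle rather than against itself.

## Known limitations

* Analyses are 2D single-slice; a single pixel size applies to both
  axes. No 3D morphology (sphericity), no watershed splitting of
  touching nuclei.
* No flat-field or background correction is applied before
  quantification; if the acquisition needs one, apply it upstream.
* Proprietary microscope formats (CZI, ND2) are not read; convert to
  TIFF/OME-TIFF first. Pixel size and channel roles come from the
  configuration, not from image metadata, whose dialects vary.
* Absolute circularity values depend on the perimeter estimator;
  comparisons across software should use the same estimator, and the
  package claims estimator-internal consistency rather than numeric
  parity with any specific program.
* Statistical testing on the resulting tables (Kruskal–Wallis, Dunn,
  Wilcoxon) is left to the standard R routines.

## A compact end-to-end example

```{r pipeline, eval = FALSE}
gs <- generate_scene(scene_params(seed = 1))
nuclei <- segment_regions(gs$scene, "chromatin", min_area_px = 1000,
                          window_px = 101, kind = "nucleus",
                          otsu_classes = 3)
nucleoli <- segment_regions(gs$scene, "nucleolus", min_area_px = 200,
                            window_px = 51, kind = "nucleolus") |>
  assign_children(nuclei)

part <- make_partition(nucleoli, nuclei, k_px = default_k_px(40),
                       pixel_size_nm = 40)
enrichment(part, gs$scene, "chromatin")

shape_metrics(nucleoli) |>
  summarize_per_nucleus(nucleoli$parent_of)

foci <- segment_intranucleolar_foci(gs$scene, nucleoli)
anchor <- shape_metrics(foci)[1, c("centroid_y", "centroid_x")]
rings <- ring_map(unlist(anchor),
                  dilate_disc(nucleoli$labels == foci$parent_of[["1"]], 5),
                  n_rings = 50)
prof <- ring_profile(rings, gs$scene) |> piecewise_minmax(split = 15)
autoplot(prof)
```
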