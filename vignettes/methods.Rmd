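---
title: "Methods: segmentation model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinseg)
```

This vignette is the package's own account of its science: the model
behind each processing stage, the parameters that matter and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The measurement model

A myelinated fibre in cross-section is three nested regions: the axon,
the inner tongue (uncompacted, cytoplasm-filled innermost myelin), and
the compact myelin ring. Writing $A_a \le A_i \le A_f$ for the axon,
inner-region (axon + tongue) and whole-fibre areas, all diameters are
circle-equivalent, $d = 2\sqrt{A/\pi}$, and

$$g_{\mathrm{myelin}} = \frac{d_i}{d_f} = \sqrt{A_i/A_f},\qquad
  g_{\mathrm{axon}} = \frac{d_a}{d_f},\qquad
  \text{tongue index} = g_{\mathrm{myelin}} - g_{\mathrm{axon}} \ge 0 .$$

The circle-equivalent convention makes the g-ratios functions of areas
only; they are insensitive to in-plane shape and mildly biased for very
elongated fibres (we also report moment-based eccentricity so such
fibres can be filtered downstream). The tongue index is zero exactly
when the axon fills the inner region.

Assumptions: sections are transverse (a strongly oblique cut inflates
areas anisotropically); compact myelin is the darkest extended class in
the image; each fibre's inner region is a single connected hole in the
myelin mask.

## Pixel classification

Per pixel we compute a multi-scale feature bank at Gaussian scales
$\sigma \in \{0.3, 0.7, 1.0, 1.6, 3.5, 5, 10, 15, 30, 50\}$ px:
smoothed intensity; Laplacian of Gaussian, gradient magnitude and
difference of Gaussians ($\sigma$ vs $0.66\sigma$) as edge features; and
the eigenvalues of the structure tensor (integration scale $0.5\sigma$,
floored at 0.3) and of the Hessian as texture features. The smallest
scale contributes smoothing only; scales above half the shorter image
side are skipped. Filters are separable sampled-Gaussian convolutions
with mirror boundaries; the sampled kernels carry discrete moment
corrections so that order-0 kernels preserve constants and order-1/2
kernels differentiate ramps and parabolas exactly, which is what makes
the analytic oracle tests in the suite exact rather than approximate.

Classification is a two-pass *autocontext* scheme. Stage A is a
100-tree random forest (sqrt-mtry, seeded, single-threaded for
determinism) over four classes: compact myelin, axoplasm, membrane,
mitochondria. Stage B re-classifies with the raw features plus stage A's
probability channels and their Gaussian smoothings at every scale, after
relabelling mitochondria scribbles as axoplasm. The merge is the reason
the final axon instances have no mitochondria-shaped holes; the
autocontext pass gives stage B spatial context a single forest lacks.
The final stack has three channels (myelin, axoplasm, membrane)
renormalised to sum to one per pixel.

## Candidate extraction and object classification

Axoplasm candidates follow the literal operator order smooth → threshold
→ size-filter: Gaussian smoothing at $\sigma = 2.0$ px of the axoplasm
channel, binarisation at $\ge 0.6$, 8-connected labelling, rejection of
components under 10 px. Candidate labels are renumbered in raster-scan
order of first pixel so runs are reproducible pixel-for-pixel.

The object classifier is a second random forest over shape (area,
perimeter, circularity, convex area, solidity, eccentricity, equivalent
diameter, bounding-box extent) and intensity-distribution features
(mean, SD, min, max, 5 quantiles, a fixed 10-bin histogram). Location
features are deliberately excluded: where an object sits in the image
carries no class information and would invite overfitting to the
training field of view. Three classes are annotated (large axon, small
axon, inner tongue); anything else stays unannotated and is eliminated
later by the Stage-3 overlap gate. When no object model is supplied a
geometric fallback is used: candidates with solidity < 0.8 (crescents)
are tongues, the rest axons.

## The three stages

**Stage 1 — inner regions.** The myelin mask is the per-pixel argmax of
the probability stack (no extra threshold parameter), optionally closed
with a radius-1 box. Components of the *inverted* mask are candidates; a
component is selected iff it (a) does not touch the border, (b) has area
in `[min_area_px, max_area_fraction × image area]`, and (c) has mean
axoplasm probability ≥ `axoplasm_gate`. Defaults: 50 px, 0.05, 0.4. The
area floor is half the smallest inner region we expect at the working
resolution (axon radius ≳ 10 px); the 5 % ceiling rejects interstitial
space; the probability gate rejects enclosed background, which is
membrane-/background-classified rather than axoplasm-classified.
Everything not selected is kept in the rejected state — curation can
toggle it back, and nothing is silently dropped.

**Stage 2 — fibres.** Selected inner regions seed a marker-controlled
expansion over the myelin mask: every myelin pixel 8-connected to a seed
within (myelin ∪ seeds) joins the seed with the smallest geodesic
distance, ties to the lower label. We use a uniform cost (pure geodesic
distance) implemented as a level-synchronous multi-source BFS: it is
deterministic, has no extra parameter, and is exactly checkable against
an independent shortest-path oracle, which the test suite does on random
masks. A probability-weighted cost would need a surface definition that
nothing in the data pins down. The known failure mode is inherited
deliberately: a *missed* seed leaves its ring unclaimed or lets a
neighbour's territory overflow — which is precisely what toggling the
seed back in during curation repairs.

**Stage 3 — axons.** An axon-class candidate is selected iff ≥ 50 % of
its area (`overlap_fraction`) lies inside a single inner region, and is
assigned to that fibre; tongue-class candidates that touch a fibre are
kept as rejected; candidates overlapping no inner region are dropped as
extra-fibre tissue (cells, unmyelinated axons). If several axons claim
one inner region only the largest stays selected.

**Axon correction.** The membrane class systematically shaves a rim
(about the predicted membrane band's half-width) off every axon
candidate, because the axolemma *is* axon tissue but is classified as
membrane. The default correction therefore fills holes and dilates the
selected axon by a 2-px disc; the hierarchy clipping that follows bounds
the grown region inside its inner region, so the correction cannot
overshoot into myelin. `none`, `fill_holes`, `convex_hull` and `closing`
remain available for data where the bias is absent or different.

## Hierarchy and post-processing

Inner and fibre regions are reduced to their largest connected component
(stray pixels from curation); axons may stay composite. Containment is
enforced by clipping (inner ∩ fibre, then axon ∩ inner — the axon never
breaks through the inner region). A fibre with no surviving axon can
duplicate its inner region as the axon (`duplicate_inner_as_axon`,
default on, flagged in the output): this encodes the biological reading
that an undetectably thin tongue means axon ≈ inner region, and makes
the tongue index exactly 0 rather than leaving a missing value.
Border-touching fibres are measured and flagged, never dropped —
exclusion is the evaluation pairing's decision, not the measurement's.

## Evaluation protocol

Instance matching uses IoU with greedy one-to-one pairing in descending
IoU (ties: lower target, then lower prediction label). Thresholds below
0.5 are refused: above 0.5 two distinct predictions cannot both clear
the threshold against one target, so the greedy pairing is provably the
optimal assignment — the suite verifies this by brute force on small
maps. Precision, recall and F1 (`2TP/(2TP+FN+FP)`, identical to the
harmonic mean) are computed per threshold over 0.5–0.9 step 0.05 and
averaged arithmetically; the mean Jaccard is the mean over *target*
objects of their best IoU.

Measurement agreement: border fibres are removed from both sides, the
rest matched at IoU ≥ 0.5, and paired values compared with Lin's
concordance correlation coefficient
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ (1/n moment
estimators; 95 % CI by Fisher z-transform with Lin's asymptotic SE) and
Bland-Altman bias ± 1.96 SD (sample SD, differences taken as
prediction − target, so underestimation shows as negative bias).
False-negative/positive rates use pooled denominators across images.

## The phantom generator

`generate_phantom()` draws TEM-like cross-sections with exact analytic
ground truth. Per fibre: an elliptical axon (geometric-mean radius
lognormal, meanlog log 14, sdlog 0.25, clamped to 10–40 px; axis ratio
uniform in [1, 2]); a target myelin g-ratio from a truncated normal
(0.75 ± 0.06 on [0.60, 0.90], the typical corpus-callosum range); a
tongue fraction from Beta(2, 8) capped at 0.45 — small tongues for
mature fibres, occasional large ones as in remyelination. The inner
ellipse is the axon scaled to area $A_a/(1-\mathrm{tf})$ and the axon is
offset along its major axis until internally tangent, which makes the
tongue a simply connected crescent; the fibre ellipse scales the inner
one by $1/g$. Fibres are placed by rejection sampling with ≥ 2 px
clearance (so neighbouring rings are never 8-connected and the
extracellular space stays border-connected, as in tightly packed but
resolvable tissue), then painted at intensity levels extracellular 0.80,
axoplasm 0.75, tongue 0.65, membrane 0.35, myelin 0.15, mitochondria
0.25, with a 1-px membrane line at the axon boundary, optional
mitochondria (p = 0.3 per fibre), unmyelinated axons (expected 0.15 per
fibre, painted but absent from the ground truth — they exercise the
"only myelinated axons" gate), Gaussian blur (0.7 px) and additive noise
(SD 0.05) clipped to [0, 1]. Everything derives from one integer seed.

The truth table's areas and g-ratios come from the generating ellipse
geometry, not from the rasters, so recovery tests measure segmentation
plus discretisation error, not a raster-to-raster identity.

`ideal_probabilities()` converts a semantic mask into the probability
stack an error-free classifier would emit: one-hot myelin / axoplasm /
membrane-and-background, with the membrane channel additionally covering
a 3-px band (half-width 1) around the axolemma inside the inner region,
then per-channel blur and renormalisation. The band width is a modelling
choice with a geometric derivation: smoothing at $\sigma = 2$ drops a
zero-stripe of width $w$ in a unit field below the 0.6 candidate
threshold only for $w \ge 3$ px, and trained classifiers widen 1-px
membranes to about that scale — with a narrower band no classifier
output, however perfect, could separate axon from tongue under the
standard candidate extraction.

**What the phantoms do not emulate:** real TEM texture (lamellar myelin
substructure, cytoskeletal texture in axoplasm), staining gradients,
tissue-processing artefacts, myelin debris and degenerated dark axons,
touching/overlapping fibres, and out-of-plane obliquity. Green phantom
tests therefore demonstrate that the pipeline's logic and numerics are
correct under the stated geometry and noise model; they do not certify
performance on any particular real dataset, for which classifier
training on that data and its own validation remain necessary.

## Numerical and degenerate-input policy

* Connected components are 8-connected; label numbering is raster-scan
  order of first pixel; all ties anywhere resolve to the lower label.
* Contrast normalisation splits its saturation budget equally between
  tails (k = ⌊n·f/2⌋ pixels clipped per tail, order statistics, not
  interpolated quantiles, so the clipped counts are exact); a constant
  image normalises to all zeros with a warning rather than an error so
  batch runs proceed.
* Downsampling is block-mean (anti-aliased, intensity-conserving);
  ragged edges are cropped with a warning; the pixel size is multiplied
  by exactly the integer factor.
* Probability stacks are renormalised to a per-pixel simplex with a
  1e-6 tolerance check; empty candidate sets, empty hierarchies and
  zero-seed floods all return well-formed empty results.
* Curation polygons are rasterised by even-odd crossing number at pixel
  centres; self-intersecting or < 3-vertex polygons are rejected.
* Coordinates are 0-based (x right, y down) in exported GeoJSON; label
  masks round-trip exactly through 16-bit TIFF up to label 65535.

## Problem sizes used in the checks

The acceptance checks run a 50-fibre 768² phantom for end-to-end
recovery, a 320²/10-fibre phantom quartet for the classifier loop
(200 scribbles per class on one training phantom), 200 random 64² masks
against the flooding oracle, 500 fuzzed candidate sets for the hierarchy
invariants, and 200 random toy maps against the exhaustive matching
oracle — sizes at which every check completes in seconds to a couple of
minutes on a single CPU while still exercising the full code paths.

## Known limitations

* G-ratios are area-based; no fitted-circle/ellipse or perimeter-based
  variants, and no "corrected g-ratio" beyond the tongue index.
* The pipeline is 2D; no multi-page TIFF or 3D morphometry.
* One inner region per fibre is assumed; fibres whose myelin ring is
  broken in the image arrive as curation cases, not automatic successes.
* Random-forest probability calibration is not post-processed; the 0.6
  candidate threshold is the operating point, not a calibrated
  probability.
* The CLI is a thin wrapper for batch work; there is no interactive
  editing — curation is file-based by design.
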