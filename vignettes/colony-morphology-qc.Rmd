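---
title: "Quantitative colony-morphology quality control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative colony-morphology quality control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonymorph)
```

`colonymorph` implements a label-free evaluation of human pluripotent
stem-cell (hPSC) colony morphology from phase-contrast images. This
vignette is the package's own account of the models behind each stage, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the design choices that were genuinely open.

## The problem

hPSC cultures drift: subclones with impaired differentiation capacity
arise without any change in the culture protocol, and an experienced
culture operator recognises them by eye — colonies lose their sharp bright
border, the periphery flattens, the outline collapses. The package encodes
that judgement as a reproducible pipeline: segment colonies, measure a
fixed morphometric panel, cluster the panel into recurring morphologies,
and classify newly imaged colonies against that database. The
collapsed-edge cluster (lettered **A**) is the signature of the unstable
phenotype; its fraction in a culture is the quality readout.

## Colony recognition

The recogniser is a six-step pipeline with the reference parameter values
as defaults (`segmentation_config()`):

| step | operation | default | unit | why |
|---|---|---|---|---|
| 1 | background flattening | kernel 7, grey 90 | px, 8-bit level | remove illumination structure slower than the kernel; restore a fixed working level |
| 2 | texture recognition | 50 candidates, threshold 0.5 | — | per-pixel texture classification, best held-out candidate wins |
| 3 | noise reduction | 2,046 | px | smallest component area that survives |
| 4 | object filling | 30 | px | largest enclosed hole that is filled |
| 5 | manual cleansing | exclusion list | labels | never automated; debris judgement stays with the operator |
| 6 | size gate | 30,000 (strict >) | px | excludes immature and partial objects |
| — | maturity gate | 1,000 (strict >) | µm equivalent diameter | smaller colonies are too young to have representative morphology |

Step 1 estimates the local background by grayscale morphological opening
with a square structuring element and restores the configured grey level;
a constant image maps to the constant grey level exactly, and ramps slower
than the kernel scale are removed to within quantisation. Because the
kernel is small, absolute intensity differences between colony interior
and background are largely flattened too — deliberately so: the
recognition signal is *texture*, not brightness.

Step 2 replaces a proprietary texture learner with a documented
equivalent: per-pixel features (local mean and SD in 5- and 11-px windows,
box-smoothed gradient magnitude at both scales, and an 8-bin local
intensity entropy in a 9-px window), a logistic pixel classifier, and a
selection loop that fits 50 randomised configurations (random feature
subsets, random training subsamples; the first candidate is always the
plain full fit) and keeps the one with the highest held-out pixel
accuracy. Only behavioural equivalence on fixtures is claimed, not formula
equivalence with any commercial implementation.

Connectivity is 8-connected for foreground and 4-connected for holes (the
standard complementary convention). The noise threshold is interpreted as
*remove components strictly smaller than* 2,046 px, keeping the stated
value as the smallest surviving size. Labels are assigned in raster-scan
order of each component's first pixel, so segmentation output is
deterministic.

## The morphometric panel

`morph_parameters()` registers 120 parameters in three families: 38
*volume* (sizes, axes, interior and rim-band intensity statistics, local
texture magnitudes), 12 *shape* (circularity 4πA/P², solidity, convexity,
eccentricity, extent, aspect ratio, …) and 70 *frequency* (boundary
spectrum and curvature). The exact parameter list of the original
commercial panel is not public; this panel is a documented, versioned
equivalent that covers the three families and the two anchored
descriptors: *outline smoothness* (complemented by `outline_waviness`,
the energy in boundary harmonics 2–8) and *fibrous points*
(`high_band_energy`, harmonics 16–64, plus the count of boundary-curvature
peaks above 3 in units of the mean curvature of the equivalent circle).

The boundary model: the traced outer contour is resampled to 256
equal-arclength points, anchored at the boundary point farthest from the
centroid, lightly smoothed (circular 3-point mean), and described by the
radius-about-centroid series; harmonic amplitudes are scaled by the mean
radius so they are dimensionless. All parameters are translation
invariant; shape and frequency parameters are intensity invariant; and
everything is exactly invariant under 180° image rotation whenever the
anchor point is unique (ties — perfect disks — fall back to traversal
order, and the tests cover them with discretisation tolerances instead).
This invariance is what makes the plate-rotation reproducibility
experiment meaningful.

Parameter selection is a two-stage filter, applied in this order:

1. **Correlation filter** (default |r| > 0.98, strict): a greedy pass in
   canonical panel order drops any parameter that correlates above the
   threshold with an already-kept parameter; the earliest kept correlate
   is recorded as its representative. Correlations with a zero-variance
   parameter are defined as 0. Canonical order as the tie-break is a
   choice the source material leaves open; it is recorded in the
   `filter_report` for audit.
2. **CV filter** (default CV > 30, strict): coefficient of variation
   100·SD/|mean| on raw values; zero-mean parameters (infinite CV) are
   dropped, constants (CV 0) kept. The decision is invariant to positive
   rescaling.

The composition is idempotent, so a selected panel passes its own filter.

## Database construction and pruning

Selected parameters are z-standardised per parameter (sample SD, n−1).
Standardisation is introduced here deliberately: uncentred correlation
across parameters with heterogeneous units would otherwise be dominated by
large-magnitude parameters (raw areas are ~10⁵, circularity ~1). It can
be turned off (`scale = FALSE`) for strict-replication runs on pre-scaled
data.

Clustering is average-linkage agglomeration under the uncentred
correlation similarity s(x,y) = Σxᵢyᵢ/(‖x‖‖y‖) with distance 1 − s. The
engine is `stats::hclust` on that distance; the test suite holds it to an
independent O(n³) textbook re-implementation on random instances.

**Pruning.** The dendrogram is cut with the *test of no correlation*:
t = r√(n−2)/√(1−r²) under the null of no correlation between two
colonies' parameter vectors. Inverted, `critical_r(n_params, alpha)`
returns r\* = t\*/√(df + t\*²) with df = n_params − 2. Clusters are the
maximal subtrees whose internal merge similarities all strictly exceed
r\*, so every within-cluster merge is more similar than chance correlation
at level α. With 27 parameters and α = 0.05 this gives r\* = 0.380863
(t\* = 2.059539). The threshold is applied to the tree's uncentred
similarities although the test is derived for Pearson r — the source
procedure conflates the two, and both similarity definitions are
selectable (`similarity = "pearson"`).

Clusters containing strictly more than `floor(0.05 · N)` colonies are
*major* (at N = 303 the count threshold is 15: a 16-colony cluster is
major, a 15-colony one minor; both printed forms of the rule hold
simultaneously). Letters A, B, … are assigned by a composite key:
aberrant-enriched clusters first (within-line existence ratio higher in
the designated aberrant line than in the reference line), then major
before minor, then descending mean colony area; at most 20 letters (A–T)
are available.

## Classification

A query colony is standardised with the *database's* statistics and
assigned the cluster of the database colony with the highest centred
Pearson correlation; ties break by database order, and the runner-up is
reported for audit. Matching uses centred Pearson even though the tree is
uncentred — the asymmetry mirrors the reference procedure and is
documented rather than hidden. No assignment is rejected: the
no-correlation test is not applied to classification, but a configurable
`min_r` warning is available (off by default). Batch classification never
aborts; per-colony failures become flagged rows.

## The synthetic microscope

`scene_spec()` / `render_scene()` emulate the acquisition geometry of an
automated incubator-microscope: square 8-bit tiles, 2 µm/px (1,000 px ≈
2 mm). A colony is a radius-modulated closed curve
r(θ) = r₀(1 + Σₖ aₖcos(kθ + φₖ)) + spikes(θ): `edge_irregularity` scales
the low-harmonic amplitudes (k = 2…6, total excursion equal to the
parameter), `fibrousness` adds sparse narrow angular bumps
(high-curvature protrusions). Optics are approximated as a bright rim
halo (5 px wide, `halo_strength` above background) and a darker textured
interior (25 levels below background, bounded-uniform texture), on a
smooth planar gradient, with additive Gaussian noise and 8-bit
quantisation last. The interior texture is bounded so a noise-free render
keeps a documented minimum contrast on every foreground pixel
(`min_contrast()`); debris are small bright specks far below the
noise-reduction gate. All randomness derives from the scene seed, so
identical specs render bit-identically; the 180° re-imaging variant
(`render_rotated`) rotates the deterministic content and draws fresh
pixel noise, exactly like re-imaging a physically rotated plate.

What the generator does **not** emulate: wave-optical phase contrast
(real halos have spatial structure and shading), cell-scale texture
(interiors are i.i.d. texture, not packed nuclei), colony growth between
frames, meniscus and well-edge effects, and focus drift. Passing tests on
synthetic scenes therefore demonstrate the *pipeline's* correctness and
internal consistency — not that the texture recogniser or the specific
panel would meet any particular accuracy on real microscope data.

**The two-population benchmark.** `make_two_population_benchmark()` is the
calibrated study fixture: balanced single-colony scenes of the healthy
(`esc_like`: irregularity 0.03–0.08, fibrousness ≤ 0.3, halo 60, texture
SD 12) and collapsed (`collapsed_edge`: +0.22 irregularity, +1.4
fibrousness, −30 halo, −3 texture SD at `effect = 1`) phenotypes, with
`effect` interpolating the gap (at 0 the arms coincide and only the truth
label differs — for that reason the benchmark bypasses the
collapsed-edge irregularity floor that `colony_spec()` enforces for
user-declared colonies). Colony size is a *controlled* nuisance: radii are
drawn from a tight band (255–280 px, still above the 1-mm maturity gate)
and the 856-px tile is sized so even a worst-case collapsed outline
cannot clip the border. The contrast between the arms is morphological by
definition, and after per-parameter standardisation any size spread
re-inflates to unit variance and would dilute within-class similarity
without informing the class distinction; controlling it keeps the fixture
a test of morphology recovery, not of size binning.

## Expression validation

The statistical tail runs on probes × colonies log2 matrices.
Normalisation subtracts each colony's 75th percentile (linear
interpolation between order statistics — R's default quantile type 7), so
every column's 75th percentile is 0 afterwards. "Benjamini–Hochberg
t-test" is implemented as per-probe two-sample t-tests with BH adjustment
across all tested probes; the Welch unequal-variance form is the default
because single-colony group sizes are small and unbalanced (6 vs 26 in the
motivating design), with the pooled form selectable. Fold changes are
ratios of linear-scale group means (de-logged base 2), directional
("higher/lower in the target cluster"). The expression tree uses the same
average-linkage uncentred-correlation engine as the colony database, with
optional per-probe median centring (baseline shift, default on); PCA is a
per-probe-centred SVD with the sign convention that each component's
largest-magnitude loading is positive. `synth_expression()` provides the
matching generator (group mean shifts of log2(fold) on spiked probes).

Real-data probe counts from any particular microarray experiment are not
reproducible from synthetic matrices and are not claimed; the tests
instead verify calibration (null FDR within Monte-Carlo error of the 5%
target over 200 replicates), power (≥ 90% recovery of 4-fold spikes at
6 vs 26 colonies, 100 spiked of 2,000 probes), and oracle equivalence of
the BH step and the tree engine.

## Numerical choices and degenerate inputs

- Coordinates are (row, column), top-left origin; areas in pixels;
  physical lengths via `um_per_px` (default 2).
- Sample SD (n−1) everywhere a convention is needed; documented where it
  changes hand-checkable values.
- Tie-breaks are canonical-order everywhere: first maximum in
  classification, smallest leaf pair in clustering, earliest parameter as
  correlation representative.
- Zero-variance parameters: correlation defined as 0 in the filter;
  rejected with a named error in standardisation; zero-norm vectors are
  errors in uncentred correlation.
- Colonies touching the image border are profiled but flagged and excluded
  from database construction by default.
- The foreground probability threshold is fixed at 0.5 (symmetric
  default, exposed on the model object).

## Problem sizes in the test suite

The suite exercises the full pipeline at fixture scale, chosen to keep a
complete run in the tens of minutes on one core: the texture model trains
on two 400-px scenes; the benchmark study uses 20 colonies per class for
the database and an independent 20 per class held out (856-px tiles); the
plate-rotation experiment re-images 15 colonies; tree oracles run on 200
random instances of up to 8 leaves; the expression null simulation uses
200 replicates of 100 probes at 6 vs 8 colonies. Scaling any of these up
is a matter of parameters, not code.

## Known limitations

- The texture recogniser is linear on fixed features; heavily structured
  real backgrounds (vessel edges, meniscus shading) would need either
  richer features or retraining per imaging setup.
- Merged colonies are not split; the pipeline follows the source
  procedure in excluding them upstream (manual cleansing).
- The 120-parameter panel is an equivalent reconstruction, not the
  original commercial list; parameter *counts* after filtering depend on
  the data and no particular surviving count is claimed.
- Debris is handled only by the size threshold of the noise-reduction
  step; floating debris above that size would require manual exclusion,
  which is exactly the failure mode the rotation experiment surfaced in
  the motivating study.
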