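---
title: "Microscopic cytometry of microalgae: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscopic cytometry of microalgae: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaecyto)
```

# The measurement model

The pipeline turns pairs of pixel-aligned epi-fluorescence rasters — one
chlorophyll-autofluorescence channel, one Nile-Red (neutral lipid) channel —
into per-cell records and population statistics. Three assumptions carry the
whole method:

1. **Chlorophyll is a reliable trigger.** Every cell of interest contains a
   chloroplast whose autofluorescence is well above the background noise
   floor. Detection therefore runs on the chlorophyll channel *only*; the
   lipid channel is read out but never influences which pixels belong to a
   cell. This is what makes the method unsupervised: no cell-geometry model,
   no training data.
2. **Channels are pixel-aligned.** Filter-cube switching on an
   epi-fluorescence stand images the same field through both filter sets;
   no registration is attempted.
3. **Summed raw intensity is proportional to amount.** Per-cell chlorophyll
   and lipid "amounts" are sums of raw camera counts over the cell's pixel
   set, taken from the *unmodified* rasters — never from the
   contrast-enhanced image used for detection, which exists solely to decide
   which pixels are cellular. Densities (amount per pixel of cell area) are
   then interpretable as intracellular concentrations.

## Detection

`segment_field()` composes five steps on the chlorophyll channel:

* **Grayscale conversion** (`grayscale_mode`, default `"luminosity"` with
  weights 0.2989/0.5870/0.1140): RGB cameras store the red fluorescence
  across channels; a 2-D input passes through unchanged.
* **Contrast enhancement** (`low_pct`/`high_pct`, default 1/99): a linear
  stretch mapping the two percentiles to the dynamic range. Its purpose is
  physical, not cosmetic: light scattered inside the non-fluorescent cell
  body is much dimmer than the chloroplast, and the stretch (with clipping)
  compresses chloroplast and body toward the top of the range so a *single*
  threshold can separate cell area from background. The output is kept
  continuous; no integer re-quantization is introduced.
* **Threshold optimization**: the single threshold maximizing between-class
  variance over a 256-bin histogram (Otsu's criterion), `optimal_threshold()`.
  16-bit data is simply binned coarser; the returned threshold is in
  intensity units and foreground is *strictly above* it.
* **Small-object removal** (`min_object_pixels`, default 10 px): debris and
  noise specks are not cells. The default corresponds to objects well below
  1 µm-scale cell cross-sections at typical 40x sampling; a component with
  exactly `min_object_pixels` pixels is kept.
* **Connected-component labeling** (`connectivity`, default 8): labels are
  assigned 1..n in row-major raster-scan order of each component's first
  pixel, which makes runs bit-reproducible.

## Quantification

`measure_cells()` revisits the unmodified rasters at the labeled
coordinates. Per cell: pixel count (the primary size measure), equivalent
sphere diameter $2\sqrt{n_{px}/\pi}$, per-channel summed amount, density =
amount / pixel count, and the fraction of pixels at or above the saturation
ceiling. Saturated cells are *flagged, not censored*: the record keeps its
(clipped) amount, and downstream analysis can exclude flagged cells with a
switch. Density is normalized per pixel of projected *area*, not per
estimated sphere volume — sizes are reported in pixels as primary data, and
area normalization makes density independent of the sphericity assumption.

## Population structure

For one snapshot (timepoint x condition), each parameter is divided by its
snapshot mean (`relativize()`), giving RCS, RCCA, RCLA, RCCD, RCLD with mean
exactly 1. Association between parameters uses Spearman's rank correlation
with mid-rank tie handling — monotone, not linear, association is the
scientifically meaningful notion here, and it is invariant to the relative
scaling. Cell-to-cell heterogeneity is summarized by the coefficient of
variation: dimensionless, hence comparable across parameters with different
units and across timepoints.

**Transition states** track lipid accumulation against the *starting*
population: the day-0 snapshot's median absolute lipid density $m_0$ defines
thresholds $m_0 \times \{2, 10\}$ (configurable), partitioning $[0,\infty)$
into "Start-RCLD", "2-fold", and "10-fold" bands. Two choices matter:

* **Absolute density, not per-snapshot RCLD**: each snapshot renormalizes
  to mean 1, so relative values cannot be compared against a day-0 anchor;
  the state definition must use the absolute scale.
* **Median as the baseline statistic** (configurable to mean): day-0
  populations already show a right tail of early lipid-rich cells, and the
  median is robust to it.
* **Boundary ownership**: a cell exactly at a threshold belongs to the
  higher state, so state assignment is monotone in density.

# The synthetic generator

No public microscope dataset accompanies this method, so the package ships
a first-class generator with exact ground truth.

**Scenes** (`render_scene()`): non-overlapping circular cells (rejection
sampling, 1-px minimum gap) with a bright concentric chloroplast disk
(fraction 0.6 of the radius, intensity 140–200 a.u.) inside a dimmer
scattering body, punctate lipid droplets in the second channel, background
8 a.u., additive Gaussian noise (sd 2 a.u.) clipped to the sensor range.
The body default of 100 a.u. reflects the regime the trigger design
requires: in real epi-fluorescence images the cell volume is visibly filled
by scattered pigment fluorescence, and the single-threshold procedure
presumes the (enhanced) body clears the optimized threshold. With a body
far dimmer than the chloroplast on a sparsely covered field, the
between-class-variance optimum instead falls between body and chloroplast
and only chloroplasts would be segmented — a genuine limitation of
single-threshold detection, documented below. The truth table records both
the noiseless *injected* per-cell amounts and the *realized* amounts (the
rendered noisy raster summed over the true pixel set); readout is compared
per cell against the realized truth, and against the injected truth at the
$\pm 3\sigma\sqrt{n_{px}}$ noise-propagation band, which a cell exceeds
with probability 0.27% even for a perfect segmenter.

**Populations** (`sample_population()`): log-normal sizes; chlorophyll
amount and lipid density coupled to size through a Gaussian copula. A
Spearman target $\rho_s$ maps to the latent correlation via
$\rho_g = 2\sin(\pi\rho_s/6)$, exact for the Gaussian copula. Defaults
mirror a healthy day-0 culture: size–chlorophyll $\rho_s = 0.96$,
size–lipid-density $\rho_s = 0$. The lipid *density* is the generator's
primitive (concentration is the physiologically meaningful quantity) and is
drawn from a log-normal mixture via its inverse CDF (monotone bisection),
which preserves the copula coupling; lipid amount derives as density x
size. `simulate_time_course()` multiplies each cell's density by per-cell
non-decreasing log-normal factors, so the Start-band population fraction is
structurally non-increasing — cells accumulate TAG and never fall back.

**What the generator does not emulate** — hence what green tests do *not*
show about real data: touching or dividing cells, non-circular and
sponge-like degraded chloroplast morphologies, spatially correlated
(structured) background, chromatic aberration or channel misregistration,
photobleaching, and spectral cross-talk between chlorophyll and Nile-Red
emission. Results on real images depend on these factors; the tests certify
the algorithmic chain, not the optics.

# Numerical choices

* Threshold ties (equal between-class variance) break to the lowest
  maximizer. Between two well-separated modes the variance is *constant*
  across the empty histogram gap, so the chosen threshold sits at the low
  edge of that plateau — equally optimal, and deterministic.
* Foreground is strictly `> t`; pixels at the threshold are background.
* Constant (degenerate-histogram) images segment to an empty mask with a
  warning rather than an error, so batch runs survive blank fields.
* Contrast enhancement of a constant image returns it unchanged.
* The per-cell CSV is written at 15 significant digits; write-then-read
  round trips are lossless at that precision.
* Mixture quantiles use 80 bisection iterations, ample for double
  precision over the densities involved.

# Problem sizes and statistical calibration

The test suite and `scripts/acceptance.R` use sizes chosen so sampling
error is controlled without excessive runtime: 200 scenes of 100 cells
(384x384 px) for recall, 20 scenes of 40 cells for conservation and
recovery, populations of n = 1000 for correlation and mixture checks, and
n = 10,000 cells (100 rendered 360x360 fields) for the full
simulate–process–analyze closure. The closure size matters: the Spearman
estimator has standard error $\approx 1/\sqrt{n-1}$ near $\rho = 0$
(~0.032 at n = 1000), so recovering a zero target within ±0.03 reliably
requires the larger n; at n = 10,000 the standard error is ~0.01. For the
same reason the per-seed correlation-recovery test at n = 1000 asserts a
±3·SE band rather than a fixed ±0.03.

# Known limitations

* **Touching cells are not split** (no watershed): the method targets
  dilute suspensions where clumping is rare; clumps are counted as one cell.
* **Single-threshold detection** assumes the enhanced cell body is
  separable from background by one global threshold; very dim cell bodies
  relative to their chloroplasts revert detection to chloroplast area.
* Multi-page/z-stack TIFFs and proprietary microscope formats are out of
  scope; convert to single-plane TIFF/PNG first.
* Amounts are arbitrary-unit fluorescence sums; cross-experiment comparison
  requires the relative scaling, identical acquisition settings, or an
  external calibration.
* Saturated cells bias amounts downward at high expression; the saturation
  flags exist precisely so users can quantify and, if needed, exclude them.
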