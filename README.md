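# algaecyto

Microscopic cytometry of microalgae: unsupervised single-cell quantification
of size, chlorophyll, and Nile-Red-stained neutral lipids from dual-channel
epi-fluorescence images, with population-structure analytics for lipid-
accumulation time courses (e.g. nitrogen-starvation experiments on green
algae such as *Acutodesmus obliquus*).

## Who this is for

Algal biotechnology and systems-biology labs that image cultures on a
standard epi-fluorescence microscope and want per-cell numbers — not bulk
averages — for chlorophyll and triacylglycerol (TAG) content, and who need
to follow how a population differentiates into subpopulations during lipid
production. Bulk solvent extraction hides exactly this heterogeneity.

## The method

**Detection (trigger signal).** Cells are found using chlorophyll
autofluorescence only; the lipid channel never participates in detection.
The chlorophyll raster is (1) collapsed to grayscale (luminosity weights
0.2989/0.5870/0.1140 for RGB input), (2) contrast-stretched between its 1st
and 99th intensity percentiles so the dim light scattered inside the
non-fluorescent cell body rises above the detection threshold, (3) binarized
at the single threshold `t*` maximizing the between-class variance of the
256-bin intensity histogram (Otsu's criterion),

```
t* = argmax_t  w0(t) w1(t) [mu0(t) - mu1(t)]^2
```

with ties broken by the lowest maximizer, (4) cleaned of connected
components below `min_object_pixels` (default 10), and (5) labeled into
cells by 8-connected component analysis.

**Quantification (raw readout).** The label coordinates are then applied to
the *unmodified* raw rasters of both channels: per cell, the pixel count
(size), the equivalent sphere diameter `2 * sqrt(npx / pi)`, summed
chlorophyll and lipid intensities (amounts, a.u.), per-pixel densities
(amount / size), and the fraction of pixels at the sensor ceiling.

**Population structure.** Per snapshot (one timepoint x condition), each
parameter is divided by its snapshot mean to give the dimensionless relative
columns RCS, RCCA, RCLA, RCCD, RCLD (mean 1 by construction); pairwise
Spearman rank correlations (mid-rank ties), cell-to-cell heterogeneity
(coefficient of variation), and *transition states* — bands of absolute
lipid density at fold multiples (default 2x, 10x) of the day-0 population
median — track how cells move toward high-lipid states over time.

**Synthetic ground truth.** `render_scene()` draws ground-truthed image
pairs (cells with bright chloroplast cores and dimmer bodies, punctate lipid
droplets, Gaussian noise, sensor clipping); `sample_population()` draws
per-cell records with log-normal sizes, a Gaussian-copula rank-correlation
structure, and log-normal lipid-density mixtures, so every pipeline stage is
testable without microscope data.

## Worked example

```r
library(algaecyto)

spec <- scene_spec(n_cells = 40L, seed = 7)           # ground-truthed field
sc   <- render_scene(spec, field_id = "demo_t0_minusN",
                     timepoint = 0, condition = "minusN")
mask <- segment_field(sc$field)                        # trigger = chlorophyll
mask$n_cells
#> [1] 40
rec <- measure_cells(mask, sc$field)                   # raw-channel readout
head(round(rec[, c("pixel_count", "equiv_diameter", "chl_amount",
                   "lipid_amount", "chl_density", "lipid_density")], 2), 3)
#>   pixel_count equiv_diameter chl_amount lipid_amount chl_density lipid_density
#> 1         196          15.80      23751         1536      121.18          7.84
#> 2          94          10.94      10755         3205      114.41         34.10
#> 3         136          13.16      16981         1979      124.86         14.55
```

All 40 synthetic cells are recovered; cell 1 is a large cell (196 px, about
15.8 px equivalent diameter) with low lipid density, cell 2 a small cell
whose lipid density (34.1 a.u./px) is four times higher — the size-lipid
decoupling the method is built to expose.

```r
snap <- build_snapshot(rec)
spearman_rho(snap$RCS, snap$RCCA)   # size tracks chlorophyll tightly
#> [1] 0.992
heterogeneity(snap$RCLD)            # strong cell-to-cell lipid variability
#> [1] 0.55

pop0  <- sample_population(population_spec(n_cells = 1000, seed = 1))
model <- fit_transition_model(build_snapshot(pop0))    # day-0 anchor
model$fold_thresholds
#> [1]  5.995 29.975
tc <- simulate_time_course(population_spec(n_cells = 1000, seed = 1),
                           timepoints = c(0, 4, 8))
sapply(c(0, 4, 8), function(d) assign_states(model, tc[tc$timepoint == d, ]))
#>            day0  day4  day8
#> Start-RCLD    1 0.422 0.421
#> 2-fold        0 0.575 0.001
#> 10-fold       0 0.003 0.578
```

By day 8 about 58% of cells exceed ten times the starting lipid density
while 42% never left the start band, and no mass returns to lower states —
the population has split into two subpopulations.

A shell front-end wraps the same functions
(`system.file("exec", "algaecyto", package = "algaecyto")`):

```sh
algaecyto simulate --spec scene.json --out imgs/
algaecyto process  --input imgs/ --out run/     # cells.csv + manifest.json
algaecyto analyze  --cells run/cells.csv --baseline-time 0 --out run/
```

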