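#' Specification of a synthetic dual-channel scene
#'
#' Describes a ground-truthed field of view emulating epi-fluorescence images
#' of microalgal cells: circular cells containing a bright concentric
#' chloroplast region and a dimmer scattering cell body in the chlorophyll
#' channel, punctate Nile-Red-bright lipid droplets in the lipid channel,
#' additive Gaussian background noise, and sensor clipping at a configurable
#' ceiling. Cells are placed without overlap by rejection sampling.
#'
#' Default intensities place both the chloroplast and the cell body far above
#' the background noise floor (>= 5 noise SDs), mimicking healthy cultures
#' where autofluorescence is a reliable trigger signal.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_radius_range `c(min, max)` cell radius in pixels.
#' @param chloroplast_fraction Fraction of the cell radius occupied by the
#'   bright chloroplast disk, in `(0, 1]`.
#' @param chl_intensity_range `c(min, max)` chloroplast intensity (a.u.);
#'   each cell draws uniformly from this range.
#' @param body_intensity Intensity of the dim scattering cell body (a.u.).
#' @param n_droplets_range Integer range of lipid droplets per cell.
#' @param droplet_intensity Intensity of a lipid droplet in the lipid
#'   channel (a.u.).
#' @param droplet_radius_frac Droplet radius as a fraction of the cell
#'   radius.
#' @param background_level Mean background intensity in both channels (a.u.).
#' @param noise_sd Standard deviation of the additive Gaussian noise (a.u.).
#' @param ceiling Sensor ceiling; rendered intensities are clipped to
#'   `[0, ceiling]`.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; rendering is deterministic per seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       n_cells = 40L,
                       cell_radius_range = c(4, 8),
                       chloroplast_fraction = 0.6,
                       chl_intensity_range = c(140, 200),
                       body_intensity = 100,
                       n_droplets_range = c(0L, 5L),
                       droplet_intensity = 120,
                       droplet_radius_frac = 0.25,
                       background_level = 8,
                       noise_sd = 2,
                       ceiling = 255,
                       bit_depth = 8L,
                       seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            n_cells >= 0L,
            cell_radius_range[1L] >= 1,
            cell_radius_range[2L] >= cell_radius_range[1L],
            chloroplast_fraction > 0, chloroplast_fraction <= 1,
            noise_sd >= 0, ceiling > 0,
            background_level >= 0, background_level <= ceiling,
            body_intensity <= ceiling, droplet_intensity <= ceiling,
            max(chl_intensity_range) <= ceiling)
  structure(as.list(environment()), class = "scene_spec")
}

disk_indices <- function(cx, cy, r, nr, nc) {
  ri <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  ci <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  grid <- expand.grid(row = ri, col = ci)
  keep <- (grid$row - cy)^2 + (grid$col - cx)^2 <= r^2
  (grid$col[keep] - 1L) * nr + grid$row[keep]
}

#' Render a synthetic scene
#'
#' Draws the noiseless chlorophyll and lipid signal rasters from a
#' [scene_spec()], adds truncated Gaussian noise, clips at the ceiling, and
#' returns the rendered field together with a per-cell ground-truth table.
#' The truth table carries, per cell, the center, radius, true pixel count,
#' the noiseless injected amounts (`chl_injected`, `lipid_injected` —
#' background included, since readout sums raw counts), and the realized
#' amounts actually present in the rendered rasters over the cell's true
#' pixel set (`chl_amount`, `lipid_amount`).
#'
#' @param spec A `scene_spec`.
#' @param field_id,timepoint,condition Metadata stamped onto the returned
#'   field.
#' @return List with elements `field` (a `fluor_field`) and `truth`
#'   (data frame).
#' @export
render_scene <- function(spec, field_id = "synthetic", timepoint = NA_real_,
                         condition = NA_character_) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  # place cells without overlap (1-pixel gap), away from the border
  radii <- stats::runif(spec$n_cells, spec$cell_radius_range[1L],
                        spec$cell_radius_range[2L])
  cx <- cy <- numeric(spec$n_cells)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * max(1L, spec$n_cells)
  while (placed < spec$n_cells) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: could not place ", spec$n_cells,
           " non-overlapping cells", call. = FALSE)
    r <- radii[placed + 1L]
    x <- stats::runif(1, 1 + r + 1, nc - r - 1)
    y <- stats::runif(1, 1 + r + 1, nr - r - 1)
    if (placed == 0L ||
        all((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2 >
            (radii[seq_len(placed)] + r + 2)^2)) {
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    }
  }
  chl_sig <- matrix(spec$background_level, nr, nc)
  lip_sig <- matrix(spec$background_level, nr, nc)
  truth <- data.frame(cell_id = seq_len(spec$n_cells),
                      cx = cx, cy = cy, radius = radii,
                      pixel_count = integer(spec$n_cells),
                      chl_injected = numeric(spec$n_cells),
                      lipid_injected = numeric(spec$n_cells),
                      n_droplets = integer(spec$n_cells))
  pix_sets <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    px <- disk_indices(cx[i], cy[i], radii[i], nr, nc)
    pix_sets[[i]] <- px
    chl_sig[px] <- spec$body_intensity
    core <- disk_indices(cx[i], cy[i],
                         radii[i] * spec$chloroplast_fraction, nr, nc)
    chl_sig[core] <- stats::runif(1, spec$chl_intensity_range[1L],
                                  spec$chl_intensity_range[2L])
    nd <- if (spec$n_droplets_range[2L] > 0)
      sample(spec$n_droplets_range[1L]:spec$n_droplets_range[2L], 1L) else 0L
    dr <- max(1, spec$droplet_radius_frac * radii[i])
    for (d in seq_len(nd)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, max(0, radii[i] - dr))
      dpx <- disk_indices(cx[i] + rad * cos(ang), cy[i] + rad * sin(ang),
                          dr, nr, nc)
      lip_sig[dpx] <- spec$droplet_intensity
    }
    truth$n_droplets[i] <- nd
    truth$pixel_count[i] <- length(px)
    truth$chl_injected[i] <- sum(chl_sig[px])
    truth$lipid_injected[i] <- sum(lip_sig[px])
  }
  clip <- function(m) {
    if (spec$noise_sd > 0)
      m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
    m[m < 0] <- 0
    m[m > spec$ceiling] <- spec$ceiling
    matrix(round(m), nr, nc)
  }
  chl <- clip(chl_sig)
  lip <- clip(lip_sig)
  truth$chl_amount <- vapply(pix_sets, function(p) sum(chl[p]), numeric(1))
  truth$lipid_amount <- vapply(pix_sets, function(p) sum(lip[p]), numeric(1))
  field <- fluor_field(chl, lip, field_id = field_id,
                       bit_depth = spec$bit_depth,
                       saturation_ceiling = spec$ceiling,
                       timepoint = timepoint, condition = condition)
  list(field = field, truth = truth)
}

#' Specification of a synthetic single-cell population
#'
#' Statistical generator of per-cell records mirroring the population
#' structure of a nitrogen-starvation experiment: log-normal cell sizes, a
#' chlorophyll amount tightly rank-correlated with size (healthy cultures
#' show Spearman rho near 0.96), and a lipid DENSITY drawn from a log-normal
#' mixture (modelling the split into low- and high-lipid subpopulations)
#' with a configurable, typically near-zero, rank correlation to size. The
#' lipid amount derives as density x size. Rank correlations are imposed by
#' a Gaussian copula: a Spearman target rho_s maps to the latent Gaussian
#' correlation via `rho_g = 2 * sin(pi * rho_s / 6)`.
#'
#' @param n_cells Number of cells.
#' @param size_meanlog,size_sdlog Log-normal parameters of cell size
#'   (pixels); defaults give a median near 150 px.
#' @param chl_meanlog,chl_sdlog Log-normal parameters of the chlorophyll
#'   amount (a.u.).
#' @param rho_size_chl Target Spearman correlation between size and
#'   chlorophyll amount (default 0.96).
#' @param rho_size_lipid Target Spearman correlation between size and lipid
#'   density (default 0).
#' @param lipid_weights Mixture weights over lipid-density components,
#'   summing to 1.
#' @param lipid_meanlog,lipid_sdlog Per-component log-normal parameters of
#'   the lipid density (a.u./pixel), same length as `lipid_weights`.
#' @param timepoint,condition Metadata stamped on the records.
#' @param seed Integer seed; sampling is deterministic per seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_cells = 1000L,
                            size_meanlog = 5.0, size_sdlog = 0.4,
                            chl_meanlog = 8.5, chl_sdlog = 0.5,
                            rho_size_chl = 0.96,
                            rho_size_lipid = 0,
                            lipid_weights = 1,
                            lipid_meanlog = log(3), lipid_sdlog = 0.15,
                            timepoint = 0, condition = "minusN",
                            seed = 1L) {
  stopifnot(n_cells >= 1L,
            abs(sum(lipid_weights) - 1) < 1e-8,
            all(lipid_weights >= 0),
            length(lipid_meanlog) == length(lipid_weights),
            length(lipid_sdlog) %in% c(1L, length(lipid_weights)),
            abs(rho_size_chl) <= 1, abs(rho_size_lipid) <= 1)
  if (length(lipid_sdlog) == 1L)
    lipid_sdlog <- rep(lipid_sdlog, length(lipid_weights))
  structure(as.list(environment()), class = "population_spec")
}

# quantile function of a log-normal mixture, by monotone bisection
qlnorm_mixture <- function(p, weights, meanlog, sdlog) {
  cdf <- function(x) {
    s <- 0
    for (i in seq_along(weights))
      s <- s + weights[i] * stats::plnorm(x, meanlog[i], sdlog[i])
    s
  }
  lo <- rep(stats::qlnorm(1e-12, min(meanlog), max(sdlog)), length(p))
  hi <- rep(stats::qlnorm(1 - 1e-12, max(meanlog), max(sdlog)), length(p))
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    below <- cdf(mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Sample a synthetic per-cell population
#'
#' Draws cell records from a [population_spec()]: sizes log-normal,
#' chlorophyll amounts and lipid densities coupled to size through a
#' Gaussian copula hitting the target Spearman correlations, lipid densities
#' pushed through the inverse CDF of the configured log-normal mixture.
#'
#' @param spec A `population_spec`.
#' @return Data frame of cell records (same columns as [measure_cells()]).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  g <- function(rho_s) 2 * sin(pi * rho_s / 6)  # Spearman -> latent Pearson
  z_size <- stats::rnorm(n)
  mix <- function(rho, z, z_new) rho * z + sqrt(1 - rho^2) * z_new
  z_chl <- mix(g(spec$rho_size_chl), z_size, stats::rnorm(n))
  z_lip <- mix(g(spec$rho_size_lipid), z_size, stats::rnorm(n))
  size <- stats::qlnorm(stats::pnorm(z_size),
                        spec$size_meanlog, spec$size_sdlog)
  chl <- stats::qlnorm(stats::pnorm(z_chl), spec$chl_meanlog, spec$chl_sdlog)
  lip_density <- qlnorm_mixture(stats::pnorm(z_lip), spec$lipid_weights,
                                spec$lipid_meanlog, spec$lipid_sdlog)
  pixel_count <- pmax(1L, as.integer(round(size)))
  data.frame(field_id = "population", cell_id = seq_len(n),
             pixel_count = pixel_count,
             equiv_diameter = 2 * sqrt(pixel_count / pi),
             chl_amount = chl,
             lipid_amount = lip_density * pixel_count,
             chl_density = chl / pixel_count,
             lipid_density = lip_density,
             saturated_fraction_chl = 0,
             saturated_fraction_lipid = 0,
             timepoint = spec$timepoint,
             condition = spec$condition,
             stringsAsFactors = FALSE)
}

#' Simulate a monotone lipid-accumulation time course
#'
#' Starting from one baseline population, each cell's lipid density is
#' multiplied at every subsequent timepoint by a per-cell, non-decreasing
#' accumulation factor (log-normal increments, a configurable fraction of
#' "responder" cells accumulating much faster). Cells therefore never fall
#' back to lower densities, mirroring nitrogen-starvation dynamics where
#' TAG is accumulated but not degraded, and the population gradually splits
#' into low- and high-lipid subpopulations.
#'
#' @param baseline_spec A [population_spec()] for day 0.
#' @param timepoints Increasing numeric vector of days, starting at the
#'   baseline day.
#' @param responder_fraction Fraction of cells with fast accumulation.
#' @param responder_rate,base_rate Mean per-day log-increment of the lipid
#'   density for responders and non-responders.
#' @param rate_sd SD of the per-cell per-day log-increment noise.
#' @return Combined cell-record data frame over all timepoints.
#' @export
simulate_time_course <- function(baseline_spec,
                                 timepoints = 0:8,
                                 responder_fraction = 0.6,
                                 responder_rate = 0.45,
                                 base_rate = 0.02,
                                 rate_sd = 0.05) {
  stopifnot(inherits(baseline_spec, "population_spec"),
            all(diff(timepoints) > 0))
  base <- sample_population(baseline_spec)
  n <- nrow(base)
  responder <- stats::runif(n) < responder_fraction
  rate <- ifelse(responder, responder_rate, base_rate)
  out <- list(base)
  dens <- base$lipid_density
  for (k in seq_along(timepoints)[-1L]) {
    dt <- timepoints[k] - timepoints[k - 1L]
    # non-negative log-increment: densities never decrease
    inc <- abs(stats::rnorm(n, rate * dt, rate_sd * sqrt(dt)))
    dens <- dens * exp(inc)
    snap <- base
    snap$lipid_density <- dens
    snap$lipid_amount <- dens * snap$pixel_count
    snap$timepoint <- timepoints[k]
    out[[k]] <- snap
  }
  do.call(rbind, out)
}

#' Render a sampled population as image scenes
#'
#' Bridges the statistical population generator and the image pipeline:
#' cells from `records` are laid out over as many fields as needed, each as
#' a uniform disk whose radius reproduces the record's pixel count and whose
#' per-pixel chlorophyll and lipid intensities reproduce the record's
#' amounts. Background and truncated Gaussian noise are added as in
#' [render_scene()]. Processing the returned fields with the default
#' pipeline recovers the population's sizes, amounts, and rank-correlation
#' structure up to pixelation and noise.
#'
#' @param records Cell-record data frame (e.g. from [sample_population()]).
#' @param image_shape Field of view shape in pixels.
#' @param cells_per_field Maximum number of cells laid out per field.
#' @param background_level,noise_sd,ceiling,bit_depth Rendering parameters;
#'   the default 16-bit ceiling keeps quantization error negligible.
#' @param seed Integer seed for placement and noise.
#' @return List of `fluor_field` objects.
#' @export
scenes_from_population <- function(records, image_shape = c(360L, 360L),
                                   cells_per_field = 100L,
                                   background_level = 5, noise_sd = 2,
                                   ceiling = 65535, bit_depth = 16L,
                                   seed = 1L) {
  records <- as.data.frame(records)
  set.seed(seed)
  nr <- image_shape[1L]; nc <- image_shape[2L]
  n <- nrow(records)
  n_fields <- ceiling(n / cells_per_field)
  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    idx <- ((f - 1L) * cells_per_field + 1L):min(f * cells_per_field, n)
    sub <- records[idx, , drop = FALSE]
    radii <- sqrt(sub$pixel_count / pi)
    cx <- cy <- numeric(nrow(sub))
    placed <- 0L; tries <- 0L
    while (placed < nrow(sub)) {
      tries <- tries + 1L
      if (tries > 4000L * nrow(sub))
        stop("placement error: fields too crowded", call. = FALSE)
      r <- radii[placed + 1L]
      x <- stats::runif(1, 2 + r, nc - r - 1)
      y <- stats::runif(1, 2 + r, nr - r - 1)
      if (placed == 0L ||
          all((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2 >
              (radii[seq_len(placed)] + r + 3)^2)) {
        placed <- placed + 1L
        cx[placed] <- x; cy[placed] <- y
      }
    }
    chl <- matrix(background_level, nr, nc)
    lip <- matrix(background_level, nr, nc)
    for (i in seq_len(nrow(sub))) {
      px <- disk_indices(cx[i], cy[i], radii[i], nr, nc)
      chl[px] <- sub$chl_amount[i] / length(px)
      lip[px] <- sub$lipid_amount[i] / length(px)
    }
    noisy <- function(m) {
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      m[m < 0] <- 0; m[m > ceiling] <- ceiling
      matrix(round(m), nr, nc)
    }
    tp <- unique(sub$timepoint)[1L]
    cond <- unique(sub$condition)[1L]
    fid <- if (!is.na(tp) && !is.na(cond))
      sprintf("pop_f%03d_t%g_%s", f, tp, cond) else sprintf("pop_f%03d", f)
    fields[[f]] <- fluor_field(noisy(chl), noisy(lip),
                               field_id = fid,
                               bit_depth = bit_depth,
                               saturation_ceiling = ceiling,
                               timepoint = tp, condition = cond)
  }
  fields
}
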