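#' Segmentation parameters
#'
#' Bundles the tunable parameters of the unsupervised object-recognition
#' routine. Detection always runs on the chlorophyll channel: chloroplast
#' autofluorescence is the trigger signal, and the contrast enhancement lifts
#' the dimmer, scattering cell body above the detection threshold so that the
#' full cell area (not just the chloroplast) is segmented.
#'
#' @param min_object_pixels Connected foreground components smaller than this
#'   are discarded as debris/noise. Default 10 pixels.
#' @param low_pct,high_pct Percentile pair of the saturation-stretch contrast
#'   enhancement; intensities at or below the `low_pct` percentile map to 0,
#'   at or above the `high_pct` percentile to the dynamic-range maximum.
#'   Defaults 1 and 99.
#' @param grayscale_mode How RGB rasters are collapsed to one intensity plane:
#'   `"luminosity"` (weights 0.2989, 0.5870, 0.1140), `"max-channel"`
#'   (per-pixel channel maximum), or `"single-channel"` (input must already be
#'   2-D).
#' @param connectivity Pixel adjacency used for component labeling: 4
#'   (edge neighbours) or 8 (edge + diagonal neighbours). Default 8.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_object_pixels = 10L,
                                low_pct = 1, high_pct = 99,
                                grayscale_mode = c("luminosity", "max-channel",
                                                   "single-channel"),
                                connectivity = 8L) {
  grayscale_mode <- match.arg(grayscale_mode)
  min_object_pixels <- as.integer(min_object_pixels)
  if (is.na(min_object_pixels) || min_object_pixels < 1L)
    stop("min_object_pixels must be an integer >= 1", call. = FALSE)
  if (!is.numeric(low_pct) || !is.numeric(high_pct) ||
      low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("percentiles must satisfy 0 <= low_pct < high_pct <= 100",
         call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(min_object_pixels = min_object_pixels,
                 low_pct = low_pct, high_pct = high_pct,
                 grayscale_mode = grayscale_mode,
                 connectivity = connectivity),
            class = "segmentation_params")
}

#' Collapse a raster to a single intensity plane
#'
#' @param raster A 2-D matrix or a height x width x 3 RGB array.
#' @param mode `"luminosity"`, `"max-channel"`, or `"single-channel"`.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(raster, mode = c("luminosity", "max-channel",
                                          "single-channel")) {
  mode <- match.arg(mode)
  # an already-2-D raster is returned unchanged under every mode
  if (is.matrix(raster)) return(raster)
  if (mode == "single-channel")
    stop("single-channel mode requires a 2-D raster", call. = FALSE)
  if (length(dim(raster)) != 3L || dim(raster)[3L] != 3L)
    stop("raster must be 2-D or a 3-channel RGB array", call. = FALSE)
  if (mode == "luminosity") {
    0.2989 * raster[, , 1L] + 0.5870 * raster[, , 2L] + 0.1140 * raster[, , 3L]
  } else {
    pmax(raster[, , 1L], raster[, , 2L], raster[, , 3L])
  }
}

#' Percentile-based linear contrast stretch
#'
#' Maps the `low_pct` percentile of the image to 0 and the `high_pct`
#' percentile to `max_out`, linearly in between, clipping outside. This is the
#' enhancement step that artificially raises the light scattered inside the
#' non-fluorescent cell body so the whole cell clears the detection threshold.
#' Output is continuous (no integer quantization). Degenerate images whose two
#' percentiles coincide (e.g. constant rasters) are returned unchanged.
#'
#' @param gray Numeric matrix.
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @param max_out Upper end of the output dynamic range (e.g. 255 for 8-bit).
#' @return Numeric matrix with values in `[0, max_out]` (or the input,
#'   unchanged, when the stretch is degenerate).
#' @export
enhance_contrast <- function(gray, low_pct = 1, high_pct = 99,
                             max_out = 255) {
  if (!is.matrix(gray)) stop("gray must be a 2-D matrix", call. = FALSE)
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("percentiles must satisfy 0 <= low_pct < high_pct <= 100",
         call. = FALSE)
  qs <- stats::quantile(gray, probs = c(low_pct, high_pct) / 100,
                        names = FALSE, type = 7)
  if (qs[2L] <= qs[1L]) return(gray)
  out <- (gray - qs[1L]) * (max_out / (qs[2L] - qs[1L]))
  out[out < 0] <- 0
  out[out > max_out] <- max_out
  out
}

#' Optimal single threshold by between-class variance
#'
#' Computes the threshold separating background from objects by maximizing the
#' between-class variance of the intensity histogram (Otsu's criterion) over
#' `n_bins` equal-width bins spanning `range`. Ties are broken by the lowest
#' maximizing threshold. The returned value `t` is in intensity units;
#' foreground is defined as strictly `> t`.
#'
#' @param gray Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256; 16-bit data is simply
#'   binned coarser).
#' @param range Length-2 intensity range covered by the histogram; defaults to
#'   the observed range of `gray`.
#' @return A single numeric threshold: the upper edge of the last bin
#'   assigned to the background class.
#' @export
optimal_threshold <- function(gray, n_bins = 256L, range = NULL) {
  v <- as.numeric(gray)
  if (is.null(range)) range <- c(min(v), max(v))
  if (range[2L] <= range[1L])
    stop("degenerate histogram: image has fewer than two distinct values",
         call. = FALSE)
  n_bins <- as.integer(n_bins)
  bw <- (range[2L] - range[1L]) / n_bins
  idx <- pmin(pmax(floor((v - range[1L]) / bw), 0), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  mids <- range[1L] + (seq_len(n_bins) - 0.5) * bw
  p <- counts / sum(counts)
  # cut after bin k: background = bins 1..k, foreground = bins (k+1)..n
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * mids)[-n_bins]
  mu <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  if (!any(is.finite(bcv)))
    stop("degenerate histogram: image has fewer than two distinct values",
         call. = FALSE)
  k <- which.max(bcv)  # which.max returns the first (lowest) maximizer
  range[1L] + k * bw
}

#' Binarize at a threshold and remove small objects
#'
#' Pixels strictly above `threshold` become foreground; connected foreground
#' components (under `connectivity`) with fewer than `min_object_pixels`
#' pixels are removed.
#'
#' @param gray Numeric matrix.
#' @param threshold Intensity threshold; ties at the threshold are background.
#' @param min_object_pixels Minimum retained component size, in pixels.
#' @param connectivity 4 or 8.
#' @return A logical matrix.
#' @export
binarize_and_clean <- function(gray, threshold, min_object_pixels = 10L,
                               connectivity = 8L) {
  fg <- gray > threshold
  if (min_object_pixels > 1L && any(fg)) {
    lab <- label_components(fg, connectivity)
    if (lab$n_cells > 0L) {
      sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n_cells)
      drop <- which(sizes < min_object_pixels)
      if (length(drop)) fg[lab$labels %in% drop] <- FALSE
    }
  }
  fg
}

# Connected-component labeling over the pixel-adjacency graph.
# Components are numbered 1..n in row-major raster-scan order of their
# first-encountered pixel, so label order is deterministic.
label_components <- function(binary, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  labels <- matrix(0L, nr, nc)
  fgi <- which(binary)  # column-major linear indices
  n_fg <- length(fgi)
  if (n_fg == 0L) return(list(labels = labels, n_cells = 0L))
  row <- ((fgi - 1L) %% nr) + 1L
  col <- ((fgi - 1L) %/% nr) + 1L
  # map from linear index to 1..n_fg vertex id
  vid <- integer(nr * nc)
  vid[fgi] <- seq_len(n_fg)
  offs <- list(c(1L, 0L), c(0L, 1L))                     # down, right
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))         # both diagonals
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- row + o[1L]; c2 <- col + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[nb] > 0L
    from <- c(from, vid[fgi[ok]][hit])
    to <- c(to, vid[nb][hit])
  }
  if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = n_fg, directed = FALSE)
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_len(n_fg)
  }
  # relabel by raster-scan (row-major) order of each component's first pixel
  scan_order <- (row - 1L) * nc + col
  first_seen <- tapply(scan_order, comp, min)
  new_id <- integer(length(first_seen))
  new_id[order(first_seen)] <- seq_along(first_seen)
  labels[fgi] <- new_id[comp]
  list(labels = labels, n_cells = max(new_id))
}

#' Assign foreground pixels to distinct cells
#'
#' Connected-component labeling of a binary raster. Labels form the contiguous
#' set `1..n_cells`, numbered in row-major raster-scan order of each
#' component's first-encountered pixel.
#'
#' @param binary Logical matrix.
#' @param connectivity 4 or 8.
#' @return A `label_mask`: list with `labels` (integer matrix, 0 = background)
#'   and `n_cells`.
#' @export
assign_cells <- function(binary, connectivity = 8L) {
  if (!is.matrix(binary)) stop("binary must be a matrix", call. = FALSE)
  res <- label_components(binary != 0, as.integer(connectivity))
  structure(res, class = "label_mask")
}

#' Segment a fluorescence field
#'
#' The full object-recognition routine, applied to the chlorophyll channel
#' only (the lipid channel never participates in detection): grayscale
#' conversion, percentile contrast stretch, between-class-variance threshold,
#' binarization with small-object removal, and component labeling. If the
#' enhanced chlorophyll channel is degenerate (constant), the whole image is
#' treated as background and an empty mask is returned with a warning.
#'
#' @param field A `fluor_field` from [read_field()] or [render_scene()].
#' @param params A [segmentation_params()] object.
#' @return A `label_mask`.
#' @export
segment_field <- function(field, params = segmentation_params()) {
  stopifnot(inherits(field, "fluor_field"),
            inherits(params, "segmentation_params"))
  max_out <- 2^field$bit_depth - 1
  gray <- to_grayscale(field$chl_raw, params$grayscale_mode)
  enh <- enhance_contrast(gray, params$low_pct, params$high_pct, max_out)
  thr <- tryCatch(optimal_threshold(enh, range = c(0, max_out)),
                  error = function(e) NULL)
  if (is.null(thr)) {
    warning("degenerate chlorophyll histogram in field '", field$field_id,
            "': treating whole image as background", call. = FALSE)
    return(assign_cells(matrix(FALSE, nrow(gray), ncol(gray)),
                        params$connectivity))
  }
  fg <- binarize_and_clean(enh, thr, params$min_object_pixels,
                           params$connectivity)
  assign_cells(fg, params$connectivity)
}
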