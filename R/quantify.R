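#' Per-cell readout of one raw channel
#'
#' For each label in the mask, sums the raw intensities over the cell's pixel
#' coordinates and reports the fraction of those pixels at or above the
#' saturation ceiling. The raster must be the UNMODIFIED acquisition data:
#' readout never uses the contrast-enhanced image that drove detection.
#'
#' @param mask A `label_mask` from [segment_field()] / [assign_cells()].
#' @param raw 2-D numeric matrix, same shape as the mask.
#' @param ceiling Saturation ceiling in intensity units.
#' @return Data frame with one row per label: `cell_id`, `pixel_count`,
#'   `amount` (summed intensity), `saturated_fraction`.
#' @export
readout_channel <- function(mask, raw, ceiling) {
  stopifnot(inherits(mask, "label_mask"))
  if (!identical(dim(mask$labels), dim(raw)[1:2]))
    stop("readout error: mask and raster shapes differ", call. = FALSE)
  n <- mask$n_cells
  if (n == 0L)
    return(data.frame(cell_id = integer(0), pixel_count = integer(0),
                      amount = numeric(0), saturated_fraction = numeric(0)))
  lab <- mask$labels[mask$labels > 0L]
  vals <- raw[mask$labels > 0L]
  px <- tabulate(lab, nbins = n)
  amount <- as.numeric(rowsum(vals, lab, reorder = TRUE))
  sat <- as.numeric(rowsum(as.numeric(vals >= ceiling), lab, reorder = TRUE))
  data.frame(cell_id = seq_len(n), pixel_count = px, amount = amount,
             saturated_fraction = sat / px)
}

#' Measure all cells of a field
#'
#' Builds one record per detected cell: size in pixels, equivalent sphere
#' diameter `2 * sqrt(pixel_count / pi)`, summed chlorophyll and Nile-Red
#' amounts read from the unmodified raw channels (RGB data is collapsed with
#' the same grayscale mode as segmentation, but never contrast-enhanced),
#' per-pixel densities, and per-channel saturated fractions.
#'
#' @param mask A `label_mask` derived from the field's chlorophyll channel.
#' @param field The `fluor_field` the mask was computed from.
#' @param params The [segmentation_params()] used (supplies the grayscale
#'   mode; enhancement percentiles are irrelevant here by design).
#' @return Data frame of cell records (see [write_cell_table()] for columns).
#' @export
measure_cells <- function(mask, field, params = segmentation_params()) {
  stopifnot(inherits(mask, "label_mask"), inherits(field, "fluor_field"))
  chl_raw <- to_grayscale(field$chl_raw, params$grayscale_mode)
  lip_raw <- to_grayscale(field$lipid_raw, params$grayscale_mode)
  ceiling <- field$saturation_ceiling
  chl <- readout_channel(mask, chl_raw, ceiling)
  lip <- readout_channel(mask, lip_raw, ceiling)
  data.frame(field_id = rep(field$field_id, nrow(chl)),
             cell_id = chl$cell_id,
             pixel_count = chl$pixel_count,
             equiv_diameter = 2 * sqrt(chl$pixel_count / pi),
             chl_amount = chl$amount,
             lipid_amount = lip$amount,
             chl_density = chl$amount / chl$pixel_count,
             lipid_density = lip$amount / lip$pixel_count,
             saturated_fraction_chl = chl$saturated_fraction,
             saturated_fraction_lipid = lip$saturated_fraction,
             timepoint = rep(field$timepoint, nrow(chl)),
             condition = rep(field$condition, nrow(chl)),
             stringsAsFactors = FALSE)
}
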