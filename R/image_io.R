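#' Construct a fluorescence field
#'
#' A `fluor_field` holds the two pixel-aligned acquisition channels of one
#' field of view: the chlorophyll autofluorescence channel (the segmentation
#' trigger) and the Nile-Red neutral-lipid channel, plus acquisition
#' metadata. Intensities are raw camera counts in arbitrary fluorescence
#' units; nothing is rescaled on input.
#'
#' @param chl_raw,lipid_raw Numeric matrices (grayscale) or height x width x 3
#'   arrays (RGB) of identical height and width.
#' @param field_id Character identifier of the field of view.
#' @param bit_depth 8 or 16; bounds the admissible intensity range
#'   `[0, 2^bit_depth - 1]`.
#' @param saturation_ceiling Intensity at or above which a pixel is considered
#'   clipped by the sensor. Defaults to `2^bit_depth - 1`; cameras that store
#'   12-bit data in 16-bit containers can set it lower.
#' @param timepoint Acquisition time in days.
#' @param condition Culture condition label (e.g. `"control"`, `"minusN"`).
#' @return A list of class `fluor_field`.
#' @export
fluor_field <- function(chl_raw, lipid_raw, field_id = "field",
                        bit_depth = 8L, saturation_ceiling = NULL,
                        timepoint = NA_real_, condition = NA_character_) {
  dims <- function(x) dim(x)[1:2]
  if (!identical(dims(chl_raw), dims(lipid_raw)))
    stop("channel-pairing error: chlorophyll and lipid rasters differ in shape",
         call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (is.null(saturation_ceiling)) saturation_ceiling <- maxv
  if (saturation_ceiling > maxv)
    stop("saturation_ceiling exceeds the dynamic range", call. = FALSE)
  rng <- range(chl_raw, lipid_raw)
  if (rng[1L] < 0 || rng[2L] > maxv)
    stop("intensities outside [0, 2^bit_depth - 1]", call. = FALSE)
  structure(list(field_id = as.character(field_id),
                 chl_raw = chl_raw, lipid_raw = lipid_raw,
                 bit_depth = bit_depth,
                 saturation_ceiling = saturation_ceiling,
                 timepoint = as.numeric(timepoint),
                 condition = as.character(condition)),
            class = "fluor_field")
}

#' @export
print.fluor_field <- function(x, ...) {
  d <- dim(x$chl_raw)
  cat(sprintf("<fluor_field '%s'> %dx%d, %d-bit%s, t = %s d, condition = %s\n",
              x$field_id, d[1L], d[2L], x$bit_depth,
              if (length(d) == 3L) " RGB" else "",
              format(x$timepoint), x$condition))
  invisible(x)
}

# decode one raster file to integer intensities; no rescaling
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
    img <- round(img * (2^bits - 1))
  } else {
    stop("format error: unsupported raster format '", ext,
         "' (TIFF or PNG expected)", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else if (dim(img)[3L] != 3L)
      stop("format error: rasters must be grayscale or RGB", call. = FALSE)
  }
  list(img = img, bits = as.integer(bits))
}

#' Read a dual-channel field from disk
#'
#' Decodes the chlorophyll and lipid rasters (TIFF or PNG, grayscale or RGB)
#' and validates them into a [fluor_field()]. Intensities are never rescaled:
#' the maximum of the returned raster equals the maximum stored in the file.
#' RGB rasters are retained as 3-D arrays and collapsed to grayscale only
#' downstream, by [segment_field()] / [measure_cells()].
#'
#' @param chl_path,lipid_path Paths to the two channel images.
#' @param meta Named list of metadata: `field_id`, `timepoint`, `condition`,
#'   and optional overrides `bit_depth` and `saturation_ceiling`.
#' @return A `fluor_field`.
#' @export
read_field <- function(chl_path, lipid_path, meta = list()) {
  for (p in c(chl_path, lipid_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  chl <- read_raster(chl_path)
  lip <- read_raster(lipid_path)
  if (!identical(dim(chl$img)[1:2], dim(lip$img)[1:2]))
    stop("channel-pairing error: '", basename(chl_path), "' and '",
         basename(lipid_path), "' differ in shape", call. = FALSE)
  bit_depth <- meta$bit_depth %||% max(chl$bits, lip$bits)
  fluor_field(chl$img, lip$img,
              field_id = meta$field_id %||%
                sub("\\.[^.]*$", "", basename(chl_path)),
              bit_depth = bit_depth,
              saturation_ceiling = meta$saturation_ceiling,
              timepoint = meta$timepoint %||% NA_real_,
              condition = meta$condition %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a field's channels as TIFF files
#'
#' Stores both channels as uncompressed grayscale TIFFs at the field's bit
#' depth, so that [read_field()] round-trips the rasters bit-identically.
#'
#' @param field A `fluor_field` with 2-D (grayscale) channels.
#' @param chl_path,lipid_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_field <- function(field, chl_path, lipid_path) {
  stopifnot(inherits(field, "fluor_field"))
  maxv <- 2^field$bit_depth - 1
  tiff::writeTIFF(field$chl_raw / maxv, chl_path,
                  bits.per.sample = field$bit_depth, compression = "none")
  tiff::writeTIFF(field$lipid_raw / maxv, lipid_path,
                  bits.per.sample = field$bit_depth, compression = "none")
  invisible(c(chl_path, lipid_path))
}

cell_table_columns <- c("field_id", "cell_id", "pixel_count", "equiv_diameter",
                        "chl_amount", "lipid_amount", "chl_density",
                        "lipid_density", "saturated_fraction_chl",
                        "saturated_fraction_lipid", "timepoint", "condition")

#' Write a per-cell table to CSV
#'
#' One row per detected cell with the documented column set (`field_id`,
#' `cell_id`, `pixel_count`, `equiv_diameter`, `chl_amount`, `lipid_amount`,
#' `chl_density`, `lipid_density`, `saturated_fraction_chl`,
#' `saturated_fraction_lipid`, `timepoint`, `condition`). Numeric values are
#' written at full double precision (15 significant digits), so a write/read
#' round trip is lossless.
#'
#' @param records Data frame of cell records (possibly empty).
#' @param path Output CSV path.
#' @export
write_cell_table <- function(records, path) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(cell_table_columns, names(records))
  for (mc in missing_cols) records[[mc]] <- if (nrow(records)) NA else logical(0)
  records <- records[, cell_table_columns, drop = FALSE]
  # write.csv renders doubles at 15 significant digits, so the round trip
  # is lossless at that precision
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-cell table written by [write_cell_table()]
#'
#' @param path CSV path.
#' @return A data frame with the documented column types.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(field_id = "character",
                                       condition = "character"))
  for (cc in c("pixel_count", "cell_id"))
    if (cc %in% names(df)) df[[cc]] <- as.integer(df[[cc]])
  df
}

#' Discover and pair channel files in a directory
#'
#' Files are paired per field of view by filename: the chlorophyll channel
#' matches `chl_pattern`, the lipid channel `lipid_pattern`, and the common
#' stem (the filename with the channel tag removed) identifies the field.
#'
#' @param dir Directory containing the images.
#' @param chl_pattern,lipid_pattern Regular expressions tagging the two
#'   channels; defaults `"_chl"` and `"_nr"`.
#' @return Data frame with columns `field_id`, `chl_path`, `lipid_path`.
#' @export
pair_channels <- function(dir, chl_pattern = "_chl", lipid_pattern = "_nr") {
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  stems <- sub("\\.[^.]*$", "", files)
  chl <- grepl(chl_pattern, stems)
  lip <- grepl(lipid_pattern, stems)
  chl_ids <- sub(chl_pattern, "", stems[chl])
  lip_ids <- sub(lipid_pattern, "", stems[lip])
  common <- intersect(chl_ids, lip_ids)
  if (length(common) == 0L)
    stop("configuration error: no paired channel files found in '", dir, "'",
         call. = FALSE)
  data.frame(field_id = sort(common),
             chl_path = file.path(dir, files[chl][match(sort(common), chl_ids)]),
             lipid_path = file.path(dir, files[lip][match(sort(common), lip_ids)]),
             stringsAsFactors = FALSE)
}
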