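#' Calibrated micrograph field
#'
#' A `calibrated_field` bundles one RGB brightfield photomicrograph with its
#' spatial calibration and provenance labels: which sample (patient) it comes
#' from, which of that sample's high-power fields it is, and the comparison
#' group of the sample. All downstream measurements convert pixel counts and
#' pixel lengths to physical units through `scale` (micrometers per pixel);
#' nothing is stored per pixel in physical units.
#'
#' Pixels are held as an `H x W x 3` array of integers in `[0, 255]`,
#' row-major with the origin at the top-left (matrix row 1, column 1).
#'
#' @param pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @param scale micrometers per pixel; must be a positive number.
#' @param sample_id opaque sample (patient/slide) label.
#' @param field_index integer index of the field within the sample (1-based).
#' @param group_label `"disease"` or `"control"`.
#' @param subgroup optional clinical subgroup tag, `"clinical_liver_disease"`
#'   or `"none"` (default).
#' @return An object of class `calibrated_field`.
#' @export
calibrated_field <- function(pixels, scale, sample_id, field_index,
                             group_label = c("disease", "control"),
                             subgroup = c("none", "clinical_liver_disease")) {
  group_label <- match.arg(group_label)
  subgroup <- match.arg(subgroup)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop_validation("pixels must be an H x W x 3 array, got %d dimension(s)",
                    length(dim(pixels) %||% dim(as.matrix(pixels))))
  if (dim(pixels)[3] != 3L)
    stop_validation("expected an RGB image with 3 channels, got %d channel(s)",
                    dim(pixels)[3])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_validation("pixel values must lie in [0, 255] in all three channels")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop_validation("scale (um per pixel) must be a positive number, got %s",
                    paste(format(scale), collapse = ","))
  if (!is_count(field_index) || field_index < 1)
    stop_validation("field_index must be a positive integer")
  structure(
    list(pixels = pixels, scale = as.numeric(scale),
         sample_id = as.character(sample_id),
         field_index = as.integer(field_index),
         group_label = group_label, subgroup = subgroup),
    class = "calibrated_field")
}

#' @export
print.calibrated_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_field> %s / field %d (%s%s)\n", x$sample_id,
              x$field_index, x$group_label,
              if (x$subgroup == "none") "" else paste0(", ", x$subgroup)))
  cat(sprintf("  %d x %d px, %.4g um/px (%.3g x %.3g um)\n",
              d[1], d[2], x$scale, d[1] * x$scale, d[2] * x$scale))
  invisible(x)
}

# Decode a TIFF or PNG raster to an H x W x C array in [0,1].
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop(sprintf("unsupported image format '.%s' (expected TIFF or PNG)", ext)))
  img
}

#' Load one calibrated micrograph
#'
#' Reads a TIFF or PNG photomicrograph from disk and attaches its spatial
#' calibration and provenance labels. Grayscale images are rejected (the
#' stain-separation step needs color information); an alpha channel, if
#' present, is dropped with a warning.
#'
#' @param path path to a TIFF or PNG file.
#' @inheritParams calibrated_field
#' @return A [calibrated_field].
#' @export
load_field <- function(path, scale, sample_id, field_index,
                       group_label = c("disease", "control"),
                       subgroup = c("none", "clinical_liver_disease")) {
  img <- read_raster(path)
  if (length(dim(img)) == 2L)
    stop_validation("'%s' is a single-channel image (1 channel); RGB required",
                    path)
  nc <- dim(img)[3]
  if (nc == 1L)
    stop_validation("'%s' is a single-channel image (1 channel); RGB required",
                    path)
  if (nc == 4L) {
    warning(sprintf("'%s': dropping alpha channel", basename(path)),
            call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop_validation("'%s' has %d channels; RGB required", path, nc)
  }
  pixels <- round(img * 255)
  storage.mode(pixels) <- "integer"
  calibrated_field(pixels, scale, sample_id, field_index,
                   group_label = match.arg(group_label),
                   subgroup = match.arg(subgroup))
}

#' Write a calibrated field to an 8-bit TIFF
#'
#' Inverse of [load_field()] up to the sidecar metadata: pixel data round-trip
#' bit-exactly through the file.
#'
#' @param field a [calibrated_field].
#' @param path output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "calibrated_field"))
  tiff::writeTIFF(field$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Load a batch of fields from a manifest
#'
#' The manifest is a CSV with header
#' `path,sample_id,field_index,group_label,subgroup,scale_um_per_px`
#' (`subgroup` may be omitted). Relative image paths are resolved against the
#' manifest's own directory. Fields are returned in manifest row order.
#'
#' @param manifest path to the manifest CSV.
#' @return A list of [calibrated_field] objects (empty, with a warning, for an
#'   empty manifest).
#' @export
load_batch <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                         comment.char = "#")
  required <- c("path", "sample_id", "field_index", "group_label",
                "scale_um_per_px")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_validation("manifest is missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("manifest contains no rows; returning an empty batch",
            call. = FALSE)
    return(list())
  }
  if (is.null(tab$subgroup)) tab$subgroup <- "none"
  tab$subgroup[is.na(tab$subgroup) | tab$subgroup == ""] <- "none"
  key <- paste(tab$sample_id, tab$field_index, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate (sample_id, field_index) in manifest: %s",
                    paste(unique(key[duplicated(key)]), collapse = "; "))
  scale_per_sample <- tapply(tab$scale_um_per_px, tab$sample_id,
                             function(s) length(unique(s)))
  if (any(scale_per_sample > 1))
    stop_validation("inconsistent scale within sample(s): %s",
                    paste(names(scale_per_sample)[scale_per_sample > 1],
                          collapse = ", "))
  base_dir <- dirname(normalizePath(manifest))
  lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, tab$path[i])
    load_field(p, scale = tab$scale_um_per_px[i],
               sample_id = tab$sample_id[i],
               field_index = tab$field_index[i],
               group_label = tab$group_label[i],
               subgroup = tab$subgroup[i])
  })
}
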