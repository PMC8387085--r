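#' Run configuration for the measurement pipeline
#'
#' Validates all tunables before any image is processed. The configuration is
#' echoed into the provenance header of every output file.
#'
#' @param threshold integer in `[0, 255]` or `"auto"`; default 250 keeps
#'   every extracted (sub-white) pixel, the "select all IHC-positive areas"
#'   rule.
#' @param min_pixels artefact filter (default 10 px).
#' @param feret_mode `"projection"` (axis-projection mean, default) or
#'   `"caliper"`.
#' @param aggregation_level `"patient"`, `"field"`, or `"roi"`.
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @param exclude_border drop ROIs touching the field border (default
#'   `FALSE`; kept for sensitivity analysis).
#' @param thickness_filtered compute thickness on the artefact-filtered mask
#'   instead of the whole-image mask (default `FALSE`).
#' @param seed integer seed for any stochastic step.
#' @param save_stages write a 4-panel stage image per field.
#' @param save_thickness_map write a per-field thickness map PNG.
#' @return A validated `run_config` list.
#' @export
run_config <- function(threshold = 250L, min_pixels = 10L,
                       feret_mode = c("projection", "caliper"),
                       aggregation_level = c("patient", "field", "roi"),
                       test = c("student", "welch"),
                       exclude_border = FALSE,
                       thickness_filtered = FALSE,
                       seed = NULL,
                       save_stages = FALSE, save_thickness_map = FALSE) {
  if (!identical(threshold, "auto") &&
      (!is_count(threshold) || threshold < 0 || threshold > 255))
    stop_validation("threshold must be an integer in [0,255] or \"auto\"")
  if (!is_count(min_pixels) || min_pixels < 1)
    stop_validation("min_pixels must be a positive integer")
  structure(list(threshold = threshold,
                 min_pixels = as.integer(min_pixels),
                 feret_mode = match.arg(feret_mode),
                 aggregation_level = match.arg(aggregation_level),
                 test = match.arg(test),
                 exclude_border = isTRUE(exclude_border),
                 thickness_filtered = isTRUE(thickness_filtered),
                 seed = seed,
                 save_stages = isTRUE(save_stages),
                 save_thickness_map = isTRUE(save_thickness_map)),
            class = "run_config")
}

config_lines <- function(config) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
    character(1))
  c(sprintf("# canmorph %s",
            as.character(utils::packageVersion("canmorph"))),
    sprintf("# config: %s", paste(names(vals), vals, sep = "=",
                                  collapse = " ")))
}

# CSV with a provenance header of '#' comment lines; deterministic byte
# output for fixed input.
write_csv_provenance <- function(df, path, config) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(config_lines(config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Read a pipeline output CSV (skipping the provenance header)
#' @param path CSV written by the pipeline.
#' @return `data.frame`.
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

empty_roi_table <- function() {
  tab <- measure_roi(cbind(1L, 1L), matrix(0L, 1, 1), 1)[0, ]
  cbind(roi_id = integer(0), tab, threshold_used = integer(0))
}

#' Measure one calibrated field
#'
#' The per-field chain: stain extraction, 8-bit conversion, thresholding,
#' labeling, artefact filtering, ROI measurement, and whole-image local
#' thickness. Thickness is computed on the unfiltered mask by default (the
#' whole-image convention); set `thickness_filtered` in the config to apply
#' the artefact filter first.
#'
#' @param field a [calibrated_field].
#' @param config a [run_config()].
#' @return `list(rois = <per-ROI data.frame>, summary = <one-row per-field
#'   data.frame>, mask = <stain_mask>, thickness = <thickness_map>)`.
#' @export
measure_field <- function(field, config = run_config()) {
  stopifnot(inherits(field, "calibrated_field"),
            inherits(config, "run_config"))
  extracted <- extract_dab(field)
  gray <- to_8bit(extracted)
  sm <- threshold_mask(gray, config$threshold)
  comps <- label_rois(sm)
  if (config$exclude_border) {
    H <- nrow(sm$mask); W <- ncol(sm$mask)
    comps <- Filter(function(px)
      !any(px[, 1] == 1L | px[, 1] == H | px[, 2] == 1L | px[, 2] == W),
      comps)
  }
  kept <- filter_artefacts(comps, config$min_pixels)$kept
  rois <- if (length(kept)) {
    tab <- do.call(rbind, lapply(kept, measure_roi, gray_8bit = sm$dab_8bit,
                                 scale = field$scale,
                                 feret_mode = config$feret_mode))
    cbind(roi_id = seq_len(nrow(tab)), tab,
          threshold_used = sm$threshold_used)
  } else {
    empty_roi_table()
  }
  th_mask <- sm$mask
  if (config$thickness_filtered) {
    th_mask <- matrix(FALSE, nrow(sm$mask), ncol(sm$mask))
    for (px in kept) th_mask[px] <- TRUE
  }
  th <- suppressWarnings(local_thickness(th_mask, field$scale))
  summary <- cbind(
    data.frame(sample_id = field$sample_id, field_index = field$field_index,
               group_label = field$group_label, subgroup = field$subgroup,
               scale_um_per_px = field$scale,
               threshold_used = sm$threshold_used),
    summarize_field_quiet(rois),
    data.frame(mean_thickness = th$mean_thickness))
  meta <- data.frame(sample_id = field$sample_id,
                     field_index = field$field_index)
  rois <- if (nrow(rois)) cbind(meta, rois, row.names = NULL) else
    cbind(meta[0, ], rois)
  list(rois = rois, summary = summary, mask = sm, thickness = th)
}

summarize_field_quiet <- function(rois) {
  if (nrow(rois) == 0L) suppressWarnings(summarize_field(rois))
  else summarize_field(rois)
}

#' Measure a batch of fields
#'
#' Applies [measure_field()] to every field; a field that fails is logged
#' and skipped rather than aborting the batch.
#'
#' @param fields list of [calibrated_field] objects (e.g. [load_batch()]).
#' @param config a [run_config()].
#' @return `list(rois = <stacked per-ROI table>, fields = <stacked per-field
#'   table>, n_failed = <integer>)`.
#' @export
measure_batch <- function(fields, config = run_config()) {
  rois <- list(); summaries <- list(); n_failed <- 0L
  for (f in fields) {
    res <- tryCatch(measure_field(f, config), error = function(e) {
      warning(sprintf("field %s/%d failed: %s", f$sample_id, f$field_index,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    rois[[length(rois) + 1L]] <- res$rois
    summaries[[length(summaries) + 1L]] <- res$summary
  }
  list(rois = if (length(rois)) do.call(rbind, rois) else NULL,
       fields = if (length(summaries)) do.call(rbind, summaries) else NULL,
       n_failed = n_failed)
}

#' Measure a manifest end-to-end and write the result CSVs
#'
#' The `measure` pipeline entry point: loads the manifest, measures every
#' field, and writes `rois.csv` (one row per kept ROI) and `fields.csv` (one
#' row per field, including mean thickness), both with provenance headers.
#' Missing image files are skipped with a warning.
#'
#' @param manifest manifest CSV path (see [load_batch()]).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return Invisibly, the [measure_batch()] result.
#' @export
run_measure <- function(manifest, out_dir, config = run_config()) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                         comment.char = "#")
  base_dir <- dirname(normalizePath(manifest))
  if (nrow(tab)) {
    paths <- ifelse(file.exists(tab$path), tab$path,
                    file.path(base_dir, tab$path))
    exists_ok <- file.exists(paths)
    if (any(!exists_ok))
      warning(sprintf("skipping %d missing file(s): %s", sum(!exists_ok),
                      paste(utils::head(tab$path[!exists_ok], 3),
                            collapse = ", ")), call. = FALSE)
  } else exists_ok <- logical(0)
  if (is.null(tab$subgroup)) tab$subgroup <- "none"
  tab$subgroup[is.na(tab$subgroup) | tab$subgroup == ""] <- "none"
  fields <- lapply(which(exists_ok), function(i)
    load_field(paths[i], scale = tab$scale_um_per_px[i],
               sample_id = tab$sample_id[i],
               field_index = tab$field_index[i],
               group_label = tab$group_label[i],
               subgroup = tab$subgroup[i]))
  res <- measure_batch(fields, config)
  if (length(fields) > 0 && res$n_failed == length(fields))
    stop("all fields failed to measure", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty_rois <- data.frame(sample_id = character(0),
                           field_index = integer(0))
  write_csv_provenance(res$rois %||% empty_rois,
                       file.path(out_dir, "rois.csv"), config)
  write_csv_provenance(res$fields %||% empty_rois,
                       file.path(out_dir, "fields.csv"), config)
  if (is.null(res$rois) || nrow(res$rois) == 0L)
    warning("no ROIs found in any field", call. = FALSE)
  if (config$save_stages || config$save_thickness_map) {
    for (f in fields) {
      res1 <- tryCatch(measure_field(f, config), error = function(e) NULL)
      if (is.null(res1)) next
      stem <- file.path(out_dir, sprintf("%s_f%02d", f$sample_id,
                                         f$field_index))
      if (config$save_stages)
        write_stage_panel(f, paste0(stem, "_stages.png"))
      if (config$save_thickness_map)
        write_thickness_png(res1$thickness, paste0(stem, "_thickness.png"))
    }
  }
  invisible(res)
}

#' Compare groups from a per-field CSV and write report tables
#'
#' The `compare` pipeline entry point: aggregates the per-field table to the
#' configured analysis unit, runs the two-group comparison per parameter,
#' builds the subgroup descriptive table, and writes `comparison.csv`
#' (wide report layout with p-values) plus `comparison.json` (full test
#' detail). With a single group present, descriptives are written and tests
#' skipped with a warning.
#'
#' @param fields_csv per-field CSV from [run_measure()] (or a data frame).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return Invisibly, `list(comparison = ..., subgroups = ...)`.
#' @export
run_compare <- function(fields_csv, out_dir, config = run_config()) {
  tab <- if (is.data.frame(fields_csv)) fields_csv else
    read_result_csv(fields_csv)
  units <- aggregate_units(tab, config$aggregation_level)
  sub <- subgroup_table(units)
  comp <- NULL
  if (length(unique(units$group_label)) >= 2) {
    comp <- compare_groups(units, var_equal = config$test == "student")
  } else {
    warning("only one group present: writing descriptives, no tests",
            call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_provenance(format_report_table(sub, comp),
                       file.path(out_dir, "comparison.csv"), config)
  detail <- list(config = config[setdiff(names(config), "seed")],
                 subgroups = sub)
  if (!is.null(comp)) detail$tests <- as.data.frame(comp)
  jsonlite::write_json(detail, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(comparison = comp, subgroups = sub))
}

#' Simulate a two-group study fixture on disk
#'
#' The `simulate` pipeline entry point: renders a two-group batch of
#' synthetic fields, writes each field as an 8-bit TIFF, a manifest CSV
#' referencing them, and the ground truth as JSON. The disease group can
#' differ from the control group in any generator parameter via
#' `disease_spec` overrides. Deterministic for a fixed `seed`.
#'
#' @param out_dir fixture directory (created).
#' @param n_disease,n_control samples per group.
#' @param fields_per_sample fields (images) per sample; the sampling design
#'   uses 6 random high-power fields per slide.
#' @param base_spec named list of [synthetic_spec()] overrides shared by
#'   both groups.
#' @param disease_spec named list of additional overrides for the disease
#'   group only (e.g. `list(branch_count = 0)` for a hypo-branched group).
#' @param seed master seed; per-field seeds are derived from it.
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(out_dir, n_disease = 5L, n_control = 7L,
                         fields_per_sample = 6L, base_spec = list(),
                         disease_spec = list(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  truths <- list()
  k <- 0L
  for (g in c("disease", "control")) {
    n <- if (g == "disease") n_disease else n_control
    for (s in seq_len(n)) {
      sid <- sprintf("%s%02d", if (g == "disease") "gd" else "ct", s)
      for (f in seq_len(fields_per_sample)) {
        k <- k + 1L
        args <- base_spec
        if (g == "disease") args[names(disease_spec)] <- disease_spec
        args$seed <- (seed * 10007L + k) %% .Machine$integer.max
        sp <- do.call(synthetic_spec, args)
        gen <- suppressMessages(
          generate_field(sp, sample_id = sid, field_index = f,
                         group_label = g))
        fname <- sprintf("%s_f%02d.tiff", sid, f)
        write_field(gen$field, file.path(out_dir, fname))
        rows[[k]] <- data.frame(path = fname, sample_id = sid,
                                field_index = f, group_label = g,
                                subgroup = "none",
                                scale_um_per_px = sp$scale)
        truths[[sprintf("%s_f%02d", sid, f)]] <- list(
          seed = sp$seed,
          n_canaliculi = sp$n_canaliculi,
          branch_count = sp$branch_count,
          tube_width = sp$tube_width,
          n_dab_pixels = length(gen$truth$dab_pixels))
      }
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# -- optional debug imagery ---------------------------------------------------

#' Write the 4-panel stage image for one field
#'
#' Original RGB / extracted DAB / 8-bit channel / binary mask, tiled 2 x 2
#' into one PNG — the visual audit trail of the extraction chain.
#'
#' @param field a [calibrated_field].
#' @param path output PNG path.
#' @param config a [run_config()] (threshold is taken from it).
#' @return `path`, invisibly.
#' @export
write_stage_panel <- function(field, path, config = run_config()) {
  extracted <- extract_dab(field)
  gray <- to_8bit(extracted)
  sm <- threshold_mask(gray, config$threshold)
  H <- dim(field$pixels)[1]; W <- dim(field$pixels)[2]
  panel <- array(1, dim = c(2 * H + 3, 2 * W + 3, 3))
  put <- function(img, r0, c0) {
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    panel[r0:(r0 + H - 1), c0:(c0 + W - 1), ] <<- img / 255
  }
  put(field$pixels, 2, 2)
  put(extracted, 2, W + 3)
  put(gray, H + 3, 2)
  put((!sm$mask) * 255, H + 3, W + 3)
  png::writePNG(panel, path)
  invisible(path)
}

#' Write a thickness map as a color-mapped PNG
#' @param thickness a `thickness_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_thickness_png <- function(thickness, path) {
  t <- thickness$local_thickness
  mx <- max(t)
  v <- if (mx > 0) t / mx else t
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(255L, as.integer(floor(v * 255))) + 1L
  rgbcol <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, dim = c(nrow(t), ncol(t), 3))
  img[, , 1] <- matrix(rgbcol[1, ], nrow(t))
  img[, , 2] <- matrix(rgbcol[2, ], nrow(t))
  img[, , 3] <- matrix(rgbcol[3, ], nrow(t))
  img[array(rep(t == 0, 3), dim = dim(img))] <- 0
  png::writePNG(img, path)
  invisible(path)
}
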