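#' Label canalicular regions of interest
#'
#' Connected components of the positive mask under 8-connectivity, so that
#' one-pixel-wide canaliculi remain connected across diagonal steps.
#' Components are returned in deterministic order: sorted by their
#' top-left-most pixel in row-major scan order, and the pixels inside each
#' component are sorted the same way.
#'
#' @param mask a `stain_mask` (see [threshold_mask()]) or a logical matrix.
#' @return A list of two-column integer matrices (`row`, `col`, 1-based);
#'   empty list for an empty mask.
#' @export
label_rois <- function(mask) {
  m <- if (inherits(mask, "stain_mask")) mask$mask else mask
  if (!is.matrix(m)) stop_validation("mask must be a matrix")
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  fg <- which(m)                       # linear (column-major) indices
  if (length(fg) == 0L) return(list())
  id <- integer(H * W); id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% H) + 1L
  c <- ((fg - 1L) %/% H) + 1L
  # Undirected 8-neighbour edges via four directed shifts: E, S, SE, SW.
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    rr <- r + s[1]; cc <- c + s[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    if (!any(ok)) next
    nb <- (cc[ok] - 1L) * H + rr[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        cbind(id[fg[ok]][hit], id[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  key <- scan_key(r, c, W)
  comp_min <- tapply(key, memb, min)
  ord <- rank(comp_min)                # deterministic relabel by scan order
  out <- vector("list", length(comp_min))
  for (k in seq_along(comp_min)) {
    sel <- which(memb == k)
    sel <- sel[order(key[sel])]
    out[[ord[k]]] <- cbind(row = r[sel], col = c[sel])
  }
  out
}

#' Remove artefactual (sub-threshold) components
#'
#' Components smaller than `min_pixels` are treated as staining artefacts and
#' excluded before measurement; the default of 10 pixels removes components
#' of 9 pixels or fewer and keeps those of exactly 10.
#'
#' @param components list of pixel-set matrices from [label_rois()].
#' @param min_pixels minimum pixel count to keep (default 10).
#' @return `list(kept = <components>, n_removed = <integer>)`.
#' @export
filter_artefacts <- function(components, min_pixels = 10L) {
  if (!is_count(min_pixels) || min_pixels < 1)
    stop_validation("min_pixels must be a positive integer")
  if (length(components) == 0L)
    return(list(kept = list(), n_removed = 0L))
  sizes <- vapply(components, nrow, integer(1))
  keep <- sizes >= min_pixels
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(sprintf("removed %d artefactual component(s) (< %d px)",
                    n_removed, min_pixels))
  list(kept = components[keep], n_removed = as.integer(n_removed))
}

# Corner-corrected boundary length of a pixel region, in pixel units.
# The crack (pixel-edge) boundary is measured with every 90-degree corner
# cut: straight unit steps weigh 1 and each cut corner replaces two
# half-edges by a diagonal of length sqrt(2)/2, i.e.
#   P = E - C * (1 - sqrt(2)/2)
# with E the crack-edge count and C the corner count, both obtained from
# 2 x 2 pixel configurations (a diagonal pixel pair contributes two corners).
# Calibration: axis-aligned rectangles are measured near-exactly and a
# digitized disk's P/F ratio falls within 5% of pi.
region_perimeter <- function(m) {
  p <- pad_matrix(m != 0)
  E <- sum(p[-1, ] != p[-nrow(p), ]) + sum(p[, -1] != p[, -ncol(p)])
  a <- p[-nrow(p), -ncol(p)]; b <- p[-nrow(p), -1]
  cc <- p[-1, -ncol(p)];      d <- p[-1, -1]
  s <- a + b + cc + d
  C <- sum(s == 1) + sum(s == 3) +
    2 * sum(s == 2 & ((a & d) | (b & cc)))
  E - C * (1 - sqrt(2) / 2)
}

# Convex hull area over the outer corners of the region's pixels, in pixel
# units. Using pixel corners (not centers) makes a convex digitized region
# (e.g. any filled rectangle) score solidity exactly 1.
hull_area <- function(px) {
  r <- px[, 1]; c <- px[, 2]
  xs <- c(c - 0.5, c + 0.5, c + 0.5, c - 0.5)
  ys <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- grDevices::chull(xs, ys)
  shoelace_area(xs[h], ys[h])
}

#' Measure one canalicular ROI
#'
#' Computes the per-canaliculus parameter set on a single connected pixel
#' region:
#' * `area`: pixel count times `scale^2` (um^2);
#' * `perimeter`: corner-corrected boundary length times `scale` (um);
#' * `feret_x`, `feret_y`: widths of the region's projections onto the image
#'   x (columns) and y (rows) axes, in um;
#' * `feret`: the arithmetic mean of the two projections;
#' * `pf_ratio`: perimeter / Feret, the dimensionless branching index —
#'   side branches inflate the boundary much faster than the projection
#'   extent, so more-branched canaliculi score higher;
#' * `solidity`: pixel area over convex-hull area (hull taken over pixel
#'   corners; convex digitized regions score exactly 1);
#' * `mgv`: mean gray value of the ROI on the extracted 8-bit stain channel;
#' * `cmgv`: `255 - mgv`, an absorbance-like intensity (higher = darker,
#'   i.e. stronger staining).
#'
#' The Feret diameter used here is the axis-projection mean, which is
#' orientation dependent (rotating a square by 45 degrees changes it by
#' sqrt(2)); `feret_mode = "caliper"` substitutes the conventional rotational
#' maximum caliper for comparison, leaving all other columns unchanged.
#'
#' @param pixels two-column matrix of (row, col) pixel coordinates.
#' @param gray_8bit the 8-bit stain channel the mask was cut from.
#' @param scale um per pixel.
#' @param feret_mode `"projection"` (default) or `"caliper"`.
#' @return A one-row `data.frame` (an `RoiRecord`).
#' @export
measure_roi <- function(pixels, gray_8bit, scale,
                        feret_mode = c("projection", "caliper")) {
  feret_mode <- match.arg(feret_mode)
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  npx <- nrow(pixels)
  if (npx < 1L) stop_validation("empty pixel set")
  r <- pixels[, 1]; c <- pixels[, 2]
  # measure on a padded mini-mask so cost scales with the ROI, not the field
  r0 <- min(r); c0 <- min(c)
  mm <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
  mm[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  per_px <- region_perimeter(mm)
  fx <- (max(c) - c0 + 1)
  fy <- (max(r) - r0 + 1)
  if (feret_mode == "caliper") {
    feret_px <- max_caliper(pixels)
  } else {
    feret_px <- (fx + fy) / 2
  }
  mgv <- mean(gray_8bit[cbind(r, c)])
  data.frame(
    pixel_count = npx,
    area = npx * scale^2,
    perimeter = per_px * scale,
    feret_x = fx * scale,
    feret_y = fy * scale,
    feret = feret_px * scale,
    pf_ratio = per_px / feret_px,
    solidity = npx / hull_area(pixels),
    mgv = mgv,
    cmgv = 255 - mgv)
}

# Rotational maximum Feret (caliper) over the pixel-corner hull, px units.
max_caliper <- function(pixels) {
  r <- pixels[, 1]; c <- pixels[, 2]
  xs <- c(c - 0.5, c + 0.5, c + 0.5, c - 0.5)
  ys <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
}

#' Label, filter and measure every ROI of a mask
#'
#' Convenience chain: [label_rois()] then [filter_artefacts()] then
#' [measure_roi()] on every surviving component.
#'
#' @param mask a `stain_mask`.
#' @param scale um per pixel.
#' @param min_pixels artefact filter threshold (default 10).
#' @param feret_mode passed to [measure_roi()].
#' @return A `data.frame` with one row per kept ROI (`roi_id` in
#'   deterministic scan order) plus `threshold_used`; zero rows if nothing
#'   survives.
#' @export
measure_rois <- function(mask, scale, min_pixels = 10L,
                         feret_mode = c("projection", "caliper")) {
  stopifnot(inherits(mask, "stain_mask"))
  feret_mode <- match.arg(feret_mode)
  comps <- filter_artefacts(label_rois(mask), min_pixels)$kept
  if (length(comps) == 0L) {
    out <- measure_roi(cbind(1L, 1L), matrix(0L, 1, 1), scale)[0, ]
    out <- cbind(roi_id = integer(0), out, threshold_used = integer(0))
    return(out)
  }
  rows <- lapply(comps, measure_roi, gray_8bit = mask$dab_8bit,
                 scale = scale, feret_mode = feret_mode)
  out <- do.call(rbind, rows)
  cbind(roi_id = seq_len(nrow(out)), out,
        threshold_used = mask$threshold_used)
}

#' Per-field summary of ROI measurements
#'
#' Arithmetic mean of each measured parameter over the field's ROIs, plus the
#' ROI count. A field with no surviving ROIs is flagged (`n_roi = 0`, all
#' parameter means `NA`) and should be excluded from aggregation, which
#' [aggregate_units()] does with a warning.
#'
#' @param records ROI table from [measure_rois()].
#' @return One-row `data.frame` of means plus `n_roi`.
#' @export
summarize_field <- function(records) {
  params <- c("pixel_count", "area", "perimeter", "feret_x", "feret_y",
              "feret", "pf_ratio", "solidity", "mgv", "cmgv")
  if (is.null(records) || nrow(records) == 0L) {
    warning("field has no ROIs after filtering; flagged empty", call. = FALSE)
    out <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(params)),
                                                 params)))
    return(cbind(n_roi = 0L, out))
  }
  out <- as.data.frame(lapply(records[params], mean))
  cbind(n_roi = nrow(records), out)
}
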