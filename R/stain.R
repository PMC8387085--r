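#' Hematoxylin / DAB stain basis
#'
#' Returns the 3 x 3 matrix of unit optical-density vectors used for color
#' deconvolution of hematoxylin-counterstained DAB immunohistochemistry.
#' Rows are stains (`hematoxylin`, `dab`, `residual`), columns are the R, G, B
#' optical-density components. The hematoxylin and DAB rows are the published
#' Ruifrok-Johnston H-DAB vectors; the residual row is their unit cross
#' product, completing an invertible basis.
#'
#' @return A numeric 3 x 3 matrix with unit-norm rows.
#' @export
hdab_basis <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab         = d / sqrt(sum(d^2)),
             residual    = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

# Transmitted intensity -> optical density, per channel. Intensities are
# floored at 1/255 of full scale so OD stays finite on black pixels.
rgb_to_od <- function(rgb255) {
  -log10(pmax(rgb255, 1) / 255)
}

od_to_rgb <- function(od) {
  255 * 10^(-od)
}

#' Per-stain optical densities of a field
#'
#' Unmixes the RGB optical densities of every pixel into contributions along
#' the stain basis (Beer-Lambert model, Ruifrok-Johnston deconvolution).
#'
#' @param field a [calibrated_field] or an `H x W x 3` RGB array in `[0,255]`.
#' @param stain_vectors 3 x 3 stain basis, rows = stains; see [hdab_basis()].
#' @return `H x W x 3` array; slice `k` is the optical density attributed to
#'   stain `k` (can be slightly negative where the pixel color lies outside
#'   the basis cone).
#' @export
stain_od <- function(field, stain_vectors = hdab_basis()) {
  px <- if (inherits(field, "calibrated_field")) field$pixels else field
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop_validation("expected an H x W x 3 RGB array")
  if (abs(det(stain_vectors)) < 1e-8)
    stop_validation("stain basis is singular or near-singular")
  d <- dim(px)
  od <- matrix(rgb_to_od(as.numeric(px)), ncol = 3L)   # N x 3 channel OD
  conc <- od %*% solve(stain_vectors)                  # N x 3 per-stain OD
  array(conc, dim = d,
        dimnames = list(NULL, NULL, rownames(stain_vectors)))
}

#' Isolate the DAB (IHC-positive) signal of a field
#'
#' Classifies every pixel as DAB-stained or not from its deconvolved stain
#' optical densities, then reconstructs the image with all non-DAB content
#' replaced by pure white and DAB pixels re-rendered from their DAB component
#' alone. A pixel counts as DAB-positive when the DAB share of its total
#' (non-negative) stain density is at least `dab_fraction` and its total
#' density is above the background floor `od_floor`.
#'
#' The returned pixels are doubles (not rounded), so re-applying the
#' extraction leaves the image unchanged to floating-point precision.
#'
#' @inheritParams stain_od
#' @param dab_fraction minimum DAB fraction of total stain OD (default 0.5).
#' @param od_floor minimum total stain OD; pixels below are background
#'   (default 0.05).
#' @return `H x W x 3` double array in `[0, 255]`: white everywhere except
#'   reconstructed DAB pixels.
#' @export
extract_dab <- function(field, stain_vectors = hdab_basis(),
                        dab_fraction = 0.5, od_floor = 0.05) {
  px <- if (inherits(field, "calibrated_field")) field$pixels else field
  conc <- stain_od(px, stain_vectors)
  d <- dim(px)
  n <- d[1] * d[2]
  cmat <- pmax(matrix(conc, ncol = 3L), 0)
  total <- rowSums(cmat)
  frac <- ifelse(total > 0, cmat[, 2] / total, 0)
  keep <- total >= od_floor & frac >= dab_fraction
  out <- matrix(255, n, 3L)
  if (any(keep)) {
    cd <- cmat[keep, 2]
    out[keep, ] <- od_to_rgb(cd %o% stain_vectors[2, ])
  }
  array(out, dim = d)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Default conversion is the unweighted channel mean, the convention of the
#' reference desktop workflow; ITU-R BT.601 luma weights are available via
#' `weights = "luma"`. Values are rounded half-up and clipped to `[0, 255]`.
#'
#' @param rgb `H x W x 3` array in `[0, 255]`.
#' @param weights `"mean"` (default), `"luma"`, or a numeric length-3 vector
#'   of channel weights summing to 1.
#' @return Integer `H x W` matrix in `[0, 255]`.
#' @export
to_8bit <- function(rgb, weights = c("mean", "luma")) {
  if (is.character(weights)) {
    weights <- switch(match.arg(weights),
                      mean = rep(1 / 3, 3),
                      luma = c(0.299, 0.587, 0.114))
  }
  stopifnot(length(weights) == 3L, abs(sum(weights) - 1) < 1e-9)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_validation("expected an H x W x 3 RGB array")
  g <- rgb[, , 1] * weights[1] + rgb[, , 2] * weights[2] + rgb[, , 3] * weights[3]
  g <- pmin(pmax(floor(g + 0.5), 0), 255)
  dim(g) <- dim(rgb)[1:2]
  storage.mode(g) <- "integer"
  g
}

# Otsu's threshold restricted to the sub-255 histogram: background pixels of
# the extracted channel are exactly 255 and must not influence the cut.
# Returns the gray level t maximizing between-class variance of the rule
# value <= t, searched over all 256 candidate cuts.
otsu_sub255 <- function(gray) {
  v <- gray[gray < 255]
  if (length(v) == 0L)
    stop("no foreground signal: image is entirely 255", call. = FALSE)
  h <- tabulate(v + 1L, nbins = 255L)  # counts for levels 0..254
  lev <- 0:254
  n <- sum(h)
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mu <- m0[255]
  w1 <- n - w0
  between <- ifelse(w0 > 0 & w1 > 0,
                    (mu * w0 - m0 * n)^2 / (as.numeric(w0) * w1), 0)
  # all-equal foreground: zero variance everywhere; take the unique level so
  # the mask covers the whole foreground
  if (all(between == 0)) return(as.integer(v[1]))
  as.integer(lev[which.max(between)])
}

#' Threshold the 8-bit stain channel into a canalicular mask
#'
#' Positive pixels are *darker or equal to* the threshold (stained = dark
#' convention; the absorbance-like corrected mean gray value depends on it).
#' `threshold = "auto"` computes Otsu's threshold on the sub-255 pixels only
#' — background in the extracted channel is exactly white — and records the
#' value chosen.
#'
#' @param gray_8bit integer `H x W` matrix in `[0, 255]`, background = 255.
#' @param threshold integer in `[0, 255]`, or `"auto"`.
#' @param method_tag provenance label stored with the mask.
#' @return A `stain_mask`: list with `dab_8bit`, logical `mask`,
#'   `threshold_used`, `method_tag`.
#' @export
threshold_mask <- function(gray_8bit, threshold = "auto",
                           method_tag = NULL) {
  if (!is.matrix(gray_8bit))
    stop_validation("gray_8bit must be an H x W matrix")
  if (identical(threshold, "auto")) {
    thr <- otsu_sub255(gray_8bit)
    message(sprintf("auto (Otsu, sub-255) threshold: %d", thr))
    tag <- method_tag %||% "hdab-deconvolution/otsu-sub255"
  } else {
    if (!is_count(threshold) || threshold < 0 || threshold > 255)
      stop_validation("threshold must be an integer in [0, 255] or \"auto\"")
    thr <- as.integer(threshold)
    tag <- method_tag %||% "hdab-deconvolution/manual"
  }
  structure(list(dab_8bit = gray_8bit,
                 mask = gray_8bit <= thr,
                 threshold_used = thr,
                 method_tag = tag),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("<stain_mask> %d x %d px, %d positive (%.2f%%), threshold %d [%s]\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_used, x$method_tag))
  invisible(x)
}
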