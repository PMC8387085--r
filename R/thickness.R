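#' Local thickness of the canalicular mask
#'
#' Two-dimensional local thickness in the largest-inscribed-disk sense: the
#' thickness at a foreground pixel is the diameter of the largest disk that
#' contains the pixel and lies entirely within the foreground. The field
#' value reported alongside is the mean over all foreground pixels — one
#' mean canalicular thickness per whole image, the trabecular-style measure
#' used for bone microarchitecture, applied here because canalicular networks
#' tile a field much as trabeculae do.
#'
#' Implementation: exact Euclidean distance transform (outside-image counts
#' as background), inscribed-disk radius `r(c) = EDT(c) - 1/2` at every
#' foreground pixel (disk membership by pixel-center containment, so a tube
#' spanning `w` pixel rows has thickness `w`), domination pruning to the
#' distance ridge, then disk painting in decreasing radius order.
#'
#' @param mask a `stain_mask` or logical matrix.
#' @param scale um per pixel.
#' @return A `thickness_map`: list with `local_thickness` (`H x W` matrix in
#'   um, 0 on background), `mean_thickness` (um; `NA` with a warning for an
#'   empty mask), and `scale`.
#' @export
local_thickness <- function(mask, scale = 1) {
  m <- if (inherits(mask, "stain_mask")) mask$mask else mask
  if (!is.matrix(m)) stop_validation("mask must be a matrix")
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  th <- matrix(0, H, W)
  if (!any(m)) {
    warning("empty mask: mean thickness is undefined", call. = FALSE)
    return(structure(list(local_thickness = th, mean_thickness = NA_real_,
                          scale = scale), class = "thickness_map"))
  }
  edt <- as.matrix(EBImage::distmap(pad_matrix(m), metric = "euclidean"))
  edt <- edt[2:(H + 1L), 2:(W + 1L)]
  R <- edt - 0.5                      # inscribed radius at each pixel
  fg <- which(m)
  r <- ((fg - 1L) %% H) + 1L
  c <- ((fg - 1L) %/% H) + 1L
  Rf <- R[fg]
  # Domination pruning: a center c is redundant if an 8-neighbour n has
  # R(n) >= R(c) + |c - n| (its disk then contains c's disk entirely).
  dominated <- rep(FALSE, length(fg))
  Rpad <- matrix(-Inf, H + 2L, W + 2L)
  Rpad[cbind(r + 1L, c + 1L)] <- Rf
  for (s in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    d <- sqrt(sum(s^2))
    nbR <- Rpad[cbind(r + 1L + s[1], c + 1L + s[2])]
    dominated <- dominated | (nbR >= Rf + d - 1e-9)
  }
  keep <- which(!dominated)
  ord <- keep[order(Rf[keep], decreasing = TRUE)]
  # Precompute disk offsets per distinct radius.
  radii <- unique(Rf[ord])
  offsets <- lapply(radii, function(rr) {
    k <- floor(rr + 1e-9)
    dd <- expand.grid(di = -k:k, dj = -k:k)
    dd <- dd[dd$di^2 + dd$dj^2 <= rr^2 + 1e-9, , drop = FALSE]
    as.integer(dd$dj) * H + as.integer(dd$di)   # linear-index offsets
  })
  for (i in ord) {
    off <- offsets[[match(Rf[i], radii)]]
    idx <- fg[i] + off                # disk pixels are foreground => in-bounds
    val <- 2 * Rf[i]
    upd <- th[idx] < val
    if (any(upd)) th[idx[upd]] <- val
  }
  structure(list(local_thickness = th * scale,
                 mean_thickness = mean(th[fg]) * scale,
                 scale = scale),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d px, mean thickness %.3f um\n",
              nrow(x$local_thickness), ncol(x$local_thickness),
              x$mean_thickness))
  invisible(x)
}
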