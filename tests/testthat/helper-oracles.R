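# Shape rasterizers and independent brute-force oracles used across tests.

# Filled digitized disk: pixels with center distance <= r from the center of
# an (2r+3)^2 canvas.
make_disk <- function(r, n = 2 * r + 3) {
  ctr <- r + 2
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix((idx$row - ctr)^2 + (idx$col - ctr)^2 <= r^2, n, n)
  m
}

make_square <- function(side, pad = 2) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# Diagonal cross (X): two 45-degree bars of half-width `hw` spanning an
# extent x extent box. Same axis projections as the filled box.
make_xcross <- function(extent = 31, hw = 1.5, pad = 2) {
  n <- extent + 2 * pad
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  r <- idx$row - pad; c <- idx$col - pad
  inside <- r >= 1 & r <= extent & c >= 1 & c <= extent
  d1 <- abs(r - c) / sqrt(2)                 # distance to main diagonal
  d2 <- abs(r + c - (extent + 1)) / sqrt(2)  # distance to anti-diagonal
  matrix(inside & (d1 <= hw | d2 <= hw), n, n)
}

mask_pixels <- function(m) which(m, arr.ind = TRUE)[, c(1, 2), drop = FALSE]

uniform_gray <- function(m, value = 0L) {
  g <- matrix(255L, nrow(m), ncol(m))
  g[m] <- as.integer(value)
  g
}

# Brute-force Otsu oracle: minimize the weighted within-class variance over
# every cut point of the sub-255 values (independent of the between-class
# maximization in the package).
oracle_otsu_sub255 <- function(gray) {
  v <- as.numeric(gray[gray < 255])
  wvar <- vapply(0:254, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    s <- 0
    if (length(lo) >= 1) s <- s + length(lo) * mean((lo - mean(lo))^2)
    if (length(hi) >= 1) s <- s + length(hi) * mean((hi - mean(hi))^2)
    s
  }, numeric(1))
  (0:254)[which.min(wvar)]
}

# Brute-force local thickness oracle: exhaustive largest-inscribed-disk per
# pixel, with its own brute-force Euclidean distance transform (outside the
# image counts as background). Containment rule matches the definition:
# pixel-center containment, radius EDT - 1/2.
oracle_local_thickness <- function(m, scale = 1) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- m
  fg <- which(m, arr.ind = TRUE)
  bg <- which(!p, arr.ind = TRUE)
  if (nrow(fg) == 0) return(matrix(0, H, W))
  D2 <- outer(fg[, 1] + 1, bg[, 1], "-")^2 +
    outer(fg[, 2] + 1, bg[, 2], "-")^2
  R <- sqrt(apply(D2, 1, min)) - 0.5
  C2 <- outer(fg[, 1], fg[, 1], "-")^2 + outer(fg[, 2], fg[, 2], "-")^2
  th <- vapply(seq_len(nrow(fg)), function(i) {
    inside <- C2[i, ] <= R^2 + 1e-9
    2 * max(R[inside])
  }, numeric(1))
  out <- matrix(0, H, W)
  out[fg] <- th * scale
  out
}

# Hand-computed pooled two-sample t-test (textbook formula).
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Dilate a mask by a disk of radius r (independent of package code).
dilate_disk <- function(m, r = 1) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  off <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  off <- off[off$di^2 + off$dj^2 <= r^2 + 1e-9, ]
  fg <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    rr <- fg[, 1] + off$di[k]; cc <- fg[, 2] + off$dj[k]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

# Random blob mask for property tests: union of random disks, fixed seed
# handled by the caller.
random_blob_mask <- function(H = 64, W = 64, n_blobs = 5, rmax = 9) {
  m <- matrix(FALSE, H, W)
  idx <- expand.grid(row = seq_len(H), col = seq_len(W))
  for (b in seq_len(n_blobs)) {
    r0 <- sample(seq_len(H), 1); c0 <- sample(seq_len(W), 1)
    rad <- sample(seq_len(rmax), 1)
    m[(idx$row - r0)^2 + (idx$col - c0)^2 <= rad^2] <- TRUE
  }
  m
}

# Forward-render a DAB optical-density map through the stain basis to an
# RGB transmittance image (no quantization), for round-trip tests.
render_od <- function(od_dab, od_hem = NULL, basis = hdab_basis()) {
  H <- nrow(od_dab); W <- ncol(od_dab)
  od <- cbind(as.numeric(od_dab)) %*% basis["dab", , drop = FALSE]
  if (!is.null(od_hem))
    od <- od + cbind(as.numeric(od_hem)) %*% basis["hematoxylin", , drop = FALSE]
  array(255 * 10^(-od), dim = c(H, W, 3))
}

make_field_table <- function() {
  # small synthetic per-field summary table for stats tests
  data.frame(
    sample_id = rep(c("a1", "a2", "b1", "b2"), each = 3),
    field_index = rep(1:3, 4),
    group_label = rep(c("disease", "disease", "control", "control"), each = 3),
    subgroup = rep(c("clinical_liver_disease", "none", "none", "none"),
                   each = 3),
    n_roi = 5L,
    area = c(6, 7, 8, 9, 10, 11, 4, 5, 6, 7, 8, 9),
    pf_ratio = c(3.0, 3.1, 3.2, 2.9, 3.0, 3.1, 2.5, 2.6, 2.7, 2.4, 2.5, 2.6))
}
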