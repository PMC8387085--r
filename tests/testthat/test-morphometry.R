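test_that("labeling is 8-connected with deterministic ordering", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE       # diagonal touch: one component
  expect_length(label_rois(m), 1L)

  m2 <- matrix(FALSE, 8, 8)
  m2[2:3, 2:3] <- TRUE
  m2[6:7, 6:7] <- TRUE                   # separated by background
  comps <- label_rois(m2)
  expect_length(comps, 2L)
  # ordered by top-left-most pixel, row-major; pixels row-major within
  expect_equal(comps[[1]][1, ], c(row = 2L, col = 2L))
  expect_equal(comps[[2]][1, ], c(row = 6L, col = 6L))
  expect_equal(comps[[1]][, "row"], c(2L, 2L, 3L, 3L))

  expect_length(label_rois(matrix(FALSE, 4, 4)), 0L)
})

test_that("artefact filter drops components below 10 pixels exclusively", {
  m <- matrix(FALSE, 12, 30)
  m[2:4, 2:4] <- TRUE                    # 9 px: artefact
  m[2:3, 10:14] <- TRUE                  # 10 px: kept
  res <- suppressMessages(filter_artefacts(label_rois(m)))
  expect_equal(res$n_removed, 1L)
  expect_length(res$kept, 1L)
  expect_equal(nrow(res$kept[[1]]), 10L)
  expect_equal(filter_artefacts(list()), list(kept = list(), n_removed = 0L))
  expect_error(filter_artefacts(list(), min_pixels = 0), "positive")
})

test_that("a filled square measures its analytic values", {
  m <- make_square(5)
  g <- uniform_gray(m, 55)
  rec <- measure_roi(mask_pixels(m), g, scale = 1)
  expect_equal(rec$pixel_count, 25L)
  expect_equal(rec$area, 25)
  expect_equal(rec$feret_x, 5)
  expect_equal(rec$feret_y, 5)
  expect_equal(rec$feret, 5)
  expect_identical(rec$solidity, 1)      # convex digitized region: exact
  expect_equal(rec$mgv, 55)
  expect_equal(rec$cmgv, 200)
  # corner-cut crack boundary of an n x n square: 4n - 4(1 - sqrt(2)/2)
  expect_equal(rec$perimeter, 20 - 4 * (1 - sqrt(2) / 2))
})

test_that("a thin bar uses the axis-projection Feret definition", {
  m <- matrix(FALSE, 5, 24); m[3, 3:22] <- TRUE
  rec <- measure_roi(mask_pixels(m), uniform_gray(m, 10), 1)
  expect_equal(rec$feret_x, 20)
  expect_equal(rec$feret_y, 1)
  expect_equal(rec$feret, 10.5)
  expect_equal(rec$pf_ratio, rec$perimeter / 10.5)
  # caliper mode reports the rotational maximum instead (here the diagonal
  # of the 20 x 1 pixel rectangle)
  rec2 <- measure_roi(mask_pixels(m), uniform_gray(m, 10), 1,
                      feret_mode = "caliper")
  expect_equal(rec2$feret, sqrt(20^2 + 1), tolerance = 1e-12)
  expect_equal(rec2$perimeter, rec$perimeter)
})

test_that("a digitized disk calibrates the perimeter estimator to pi", {
  m <- make_disk(40)
  rec <- measure_roi(mask_pixels(m), uniform_gray(m), 1)
  expect_lt(abs(rec$pf_ratio - pi) / pi, 0.05)
})

test_that("angled branches raise the perimeter-to-Feret ratio", {
  # a diagonal cross and its bounding square share projections (equal F),
  # but the cross boundary is much longer
  xc <- make_xcross(31, hw = 1.5)
  sq <- make_square(31)
  rx <- measure_roi(mask_pixels(xc), uniform_gray(xc), 1)
  rs <- measure_roi(mask_pixels(sq), uniform_gray(sq), 1)
  expect_equal(rx$feret, rs$feret)
  expect_gt(rx$pf_ratio, rs$pf_ratio)
})

test_that("measurements are scale-equivariant and translation-invariant", {
  set.seed(3)
  m <- random_blob_mask(40, 40, n_blobs = 3, rmax = 6)
  comps <- label_rois(m)
  px <- comps[[which.max(vapply(comps, nrow, integer(1)))]]
  g <- uniform_gray(m, 80)
  r1 <- measure_roi(px, g, 1)
  r2 <- measure_roi(px, g, 2.5)
  expect_equal(r2$area, r1$area * 2.5^2)
  expect_equal(r2$perimeter, r1$perimeter * 2.5)
  expect_equal(r2$feret, r1$feret * 2.5)
  expect_equal(r2$pf_ratio, r1$pf_ratio)    # scale-free
  expect_equal(r2$solidity, r1$solidity)    # scale-free

  shifted <- cbind(px[, 1] + 7L, px[, 2] + 5L)
  gbig <- matrix(80L, 60, 60)
  r3 <- measure_roi(shifted, gbig, 1)
  expect_equal(r3[, c("area", "perimeter", "feret", "pf_ratio", "solidity")],
               r1[, c("area", "perimeter", "feret", "pf_ratio", "solidity")])
})

test_that("pf_ratio and solidity are invariant under 90-degree rotation", {
  set.seed(9)
  m <- random_blob_mask(30, 30, n_blobs = 2, rmax = 7)
  mr <- t(m[nrow(m):1, ])                   # rotate 90 degrees
  p1 <- mask_pixels(m); p2 <- mask_pixels(mr)
  r1 <- measure_roi(p1, uniform_gray(m), 1)
  r2 <- measure_roi(p2, uniform_gray(mr), 1)
  expect_equal(r2$pf_ratio, r1$pf_ratio)
  expect_equal(r2$solidity, r1$solidity)
  expect_equal(r2$feret, r1$feret)          # X/Y mean is symmetric
})

test_that("solidity is 1 for convex regions and drops with a concavity", {
  rect <- make_square(8)
  expect_identical(measure_roi(mask_pixels(rect), uniform_gray(rect), 1)$solidity,
                   1)
  notched <- rect
  notched[5:8, 5:8] <- FALSE               # bite a corner region out
  sol <- measure_roi(mask_pixels(notched), uniform_gray(notched), 1)$solidity
  expect_lt(sol, 1)
})

test_that("field summaries average ROI parameters and flag empty fields", {
  m <- matrix(FALSE, 20, 40)
  m[2:5, 2:6] <- TRUE          # 20 px
  m[10:14, 20:25] <- TRUE      # 30 px
  sm <- threshold_mask(uniform_gray(m, 50), 200)
  tab <- measure_rois(sm, scale = 1)
  expect_equal(nrow(tab), 2L)
  s <- summarize_field(tab)
  expect_equal(s$n_roi, 2L)
  expect_equal(s$area, mean(tab$area))
  one <- summarize_field(tab[1, ])
  expect_equal(one$area, tab$area[1])
  expect_warning(empty <- summarize_field(tab[0, ]), "empty")
  expect_equal(empty$n_roi, 0L)
  expect_true(is.na(empty$area))
})
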