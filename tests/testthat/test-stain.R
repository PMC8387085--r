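test_that("pure white stays white and pure hematoxylin is suppressed", {
  white <- array(255, c(8, 8, 3))
  expect_true(all(extract_dab(white) == 255))

  hem <- render_od(od_dab = matrix(0, 10, 10),
                   od_hem = matrix(runif(100, 0.2, 0.8), 10, 10))
  expect_true(all(extract_dab(hem) == 255))
})

test_that("forward-rendered DAB is recovered with sub-1e-6 OD error", {
  od <- matrix(0, 20, 20)
  disk <- make_disk(6, 20)
  od[disk] <- 0.7
  img <- render_od(od)
  conc <- stain_od(img)
  expect_lt(max(abs(conc[, , "dab"] - od)), 1e-6)
  expect_lt(max(abs(conc[, , "hematoxylin"])), 1e-6)

  out <- extract_dab(img)
  # disk retained (non-white), background exactly white
  gray <- to_8bit(out)
  expect_true(all(gray[disk] < 255))
  expect_true(all(gray[!disk] == 255))
})

test_that("extraction is idempotent on its own output", {
  sp <- synthetic_spec(image_size = c(64, 64), n_canaliculi = 2, seed = 11)
  g <- suppressMessages(generate_field(sp))
  once <- extract_dab(g$field)
  twice <- extract_dab(once)
  expect_equal(twice, once, tolerance = 1e-9)
})

test_that("8-bit conversion is the rounded unweighted channel mean", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)
  px[1, 2, ] <- c(0, 0, 0)
  px[1, 3, ] <- c(100, 110, 120)
  expect_identical(as.integer(to_8bit(px)), c(255L, 0L, 110L))
  # luma variant differs in general
  expect_equal(to_8bit(px, "luma")[1, 3], 108L)
})

test_that("manual thresholding selects darker-or-equal pixels only", {
  g <- matrix(255L, 10, 10)
  blob <- make_disk(2, 10)
  g[blob] <- 50L
  expect_true(all(!threshold_mask(g, 40)$mask))
  sm <- threshold_mask(g, 200)
  expect_identical(sm$mask, blob)
  expect_identical(sm$threshold_used, 200L)
  # mask true => value <= threshold (dark-positive convention)
  expect_true(all(sm$dab_8bit[sm$mask] <= sm$threshold_used))
  expect_error(threshold_mask(g, 300), "\\[0, 255\\]")
})

test_that("raising the threshold never shrinks the mask", {
  set.seed(42)
  g <- matrix(sample(c(sample(0:254, 60, TRUE), rep(255L, 40))), 10, 10)
  prev <- threshold_mask(g, 0)$mask
  for (t in seq(20, 255, by = 40)) {
    cur <- threshold_mask(g, t)$mask
    expect_true(all(cur[prev]))   # set inclusion
    prev <- cur
  }
})

test_that("auto threshold matches the brute-force sub-255 Otsu oracle", {
  set.seed(7)
  g <- matrix(255L, 20, 20)
  fgpix <- sample(400, 120)
  g[fgpix] <- as.integer(c(rep(60, 70), rep(180, 50)) +
                           sample(-3:3, 120, TRUE))
  sm <- suppressMessages(threshold_mask(g, "auto"))
  expect_identical(sm$threshold_used, oracle_otsu_sub255(g))
  # cut falls strictly between the two foreground modes (60 +/- 3, 180 +/- 3)
  expect_gte(sm$threshold_used, 63)
  expect_lt(sm$threshold_used, 177)
  # mask covers exactly the dark mode
  expect_true(all(g[sm$mask] < 100))
  expect_true(all(g[g < 100] <= sm$threshold_used))

  expect_error(threshold_mask(matrix(255L, 4, 4), "auto"), "no foreground")
})
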