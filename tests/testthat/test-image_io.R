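test_that("TIFF round-trip preserves pixels bit-exactly and scale", {
  px <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  storage.mode(px) <- "integer"
  f <- calibrated_field(px, 0.1, "s1", 1, "control")
  path <- withr::local_tempfile(fileext = ".tiff")
  write_field(f, path)
  f2 <- load_field(path, 0.1, "s1", 1, "control")
  expect_identical(f2$pixels, px)
  expect_identical(f2$scale, 0.1)
  expect_equal(dim(f2$pixels), c(16L, 16L, 3L))
})

test_that("field validation rejects bad scale and non-RGB input", {
  px <- array(255L, c(16, 16, 3))
  expect_error(calibrated_field(px, -1, "s", 1), "positive")
  expect_error(calibrated_field(px, 0, "s", 1), "positive")
  expect_error(calibrated_field(array(300, c(4, 4, 3)), 1, "s", 1),
               "\\[0, 255\\]")
  gray <- matrix(runif(64), 8, 8)
  gpath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, gpath)
  expect_error(load_field(gpath, 1, "s", 1), "1 channel")
})

test_that("alpha channel is dropped with a warning", {
  rgba <- array(runif(16 * 16 * 4), c(16, 16, 4))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, path)
  expect_warning(f <- load_field(path, 0.5, "s", 2, "disease"),
                 "alpha")
  expect_equal(dim(f$pixels)[3], 3L)
})

write_tiny_batch <- function(dir, samples = c("p1", "p2"), n_fields = 6) {
  rows <- list()
  for (s in samples) for (i in seq_len(n_fields)) {
    px <- array(200L, c(8, 8, 3))
    f <- calibrated_field(px, 0.2, s, i, "control")
    name <- sprintf("%s_%d.tiff", s, i)
    write_field(f, file.path(dir, name))
    rows[[length(rows) + 1]] <- data.frame(
      path = name, sample_id = s, field_index = i,
      group_label = "control", subgroup = "none", scale_um_per_px = 0.2)
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

test_that("batch loading follows the manifest and validates it", {
  dir <- withr::local_tempdir()
  manifest <- write_tiny_batch(dir)
  batch <- load_batch(manifest)
  expect_length(batch, 12L)
  # deterministic manifest order
  expect_equal(vapply(batch, `[[`, character(1), "sample_id"),
               rep(c("p1", "p2"), each = 6))
  expect_equal(vapply(batch, `[[`, integer(1), "field_index"),
               rep(1:6, 2))

  tab <- read.csv(manifest)
  tab$field_index[2] <- 1L   # duplicate (sample, field)
  m2 <- file.path(dir, "dup.csv"); write.csv(tab, m2, row.names = FALSE)
  expect_error(load_batch(m2), "duplicate")

  tab <- read.csv(manifest)
  tab$scale_um_per_px[3] <- 0.5   # inconsistent within-sample scale
  m3 <- file.path(dir, "scale.csv"); write.csv(tab, m3, row.names = FALSE)
  expect_error(load_batch(m3), "inconsistent scale")

  m4 <- file.path(dir, "empty.csv")
  write.csv(read.csv(manifest)[0, ], m4, row.names = FALSE)
  expect_warning(empty <- load_batch(m4), "no rows")
  expect_length(empty, 0L)
})
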