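# Field-map container and coordinate grid.

test_that("a constructed 2-channel 4x4x4 set reads back with correct counts", {
  gs <- c(4L, 4L, 4L)
  maps <- fieldmap_set(array(1 + 2i, c(2L, gs)), array(0, gs),
                       array(TRUE, gs), 3.5e-3)
  path <- withr::local_tempfile(fileext = ".mat")
  write_fieldmap_file(maps, path)
  back <- read_fieldmap_file(path)
  expect_identical(dim(back$b1)[1L], 2L)
  expect_identical(sum(back$mask), 64L)
  expect_identical(back$b1, maps$b1)
  expect_identical(back$b0, maps$b0)
  expect_identical(back$resolution, 3.5e-3)
})

test_that("missing arrays and shape mismatches are structured errors", {
  path <- withr::local_tempfile(fileext = ".mat")
  gs <- c(3L, 3L, 3L)
  mat_write(list(B1 = array(1 + 0i, c(2L, gs)), B0 = array(0, gs)), path)
  expect_error(read_fieldmap_file(path), "mask")
  mat_write(list(B1 = array(1 + 0i, c(2L, 4L, 3L, 3L)), B0 = array(0, gs),
                 mask = array(1, gs)), path)
  expect_error(read_fieldmap_file(path), "shape mismatch")
  expect_error(fieldmap_set(array(1 + 0i, c(2L, gs)), array(0, c(4L, 3L, 3L)),
                            array(TRUE, gs), 1e-3), "shape mismatch")
  expect_error(fieldmap_set(array(1 + 0i, c(2L, gs)), array(0, gs),
                            array(FALSE, gs), 1e-3), "no true voxel")
})

test_that("only isotropic resolution is supported", {
  gs <- c(3L, 3L, 3L)
  expect_error(fieldmap_set(array(1 + 0i, c(1L, gs)), array(0, gs),
                            array(TRUE, gs), c(1e-3, 2e-3, 1e-3)),
               "isotropic")
})

test_that("channel-last on-disk layout is auto-detected", {
  gs <- c(4L, 5L, 6L)
  b1 <- array(complex(real = rnorm(prod(gs) * 3L),
                      imaginary = rnorm(prod(gs) * 3L)), c(3L, gs))
  path <- withr::local_tempfile(fileext = ".mat")
  mat_write(list(B1 = aperm(b1, c(2L, 3L, 4L, 1L)), B0 = array(0, gs),
                 mask = array(1, gs)), path)
  back <- read_fieldmap_file(path)
  expect_identical(back$b1, b1)
})

test_that("coordinate grid is centered with the documented spacing", {
  co <- build_coords(c(64L, 64L, 64L), 3.5e-3)
  for (ax in 1:3)
    expect_equal(max(co[, ax]) - min(co[, ax]), 0.2205, tolerance = 1e-12)
  expect_equal(build_coords(c(1L, 1L, 1L), 1), matrix(0, 1L, 3L),
               ignore_attr = TRUE)
  co3 <- build_coords(c(3L, 1L, 1L), 1)
  expect_equal(co3[, 1L], c(-1, 0, 1))
  # symmetric under negation for odd dims
  co5 <- build_coords(c(5L, 5L, 5L), 2e-3)
  expect_equal(sort(unique(co5[, 1L])), -rev(sort(unique(co5[, 1L]))))
})
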