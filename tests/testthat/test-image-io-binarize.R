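test_that("load_image decodes PNG, TIFF and BMP identically", {
  set.seed(5)
  img <- array(sample(0:255, 10 * 8 * 3, replace = TRUE), c(10L, 8L, 3L))
  png_path <- withr::local_tempfile(fileext = ".png")
  tif_path <- withr::local_tempfile(fileext = ".tif")
  bmp_path <- withr::local_tempfile(fileext = ".bmp")
  png::writePNG(img / 255, png_path)
  tiff::writeTIFF(img / 255, tif_path)
  write_bmp24(img, bmp_path)
  expect_identical(load_image(png_path), img)
  expect_identical(load_image(tif_path), img)
  expect_identical(load_image(bmp_path), img)
})

test_that("grayscale input is replicated across channels", {
  g <- matrix(seq(0, 1, length.out = 12), 3, 4)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(g, path)
  img <- load_image(path)
  expect_equal(dim(img), c(3L, 4L, 3L))
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
})

test_that("unreadable inputs raise input errors naming the path", {
  expect_error(load_image("no/such/file.png"), "no/such/file.png")
  bad <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:10), bad)
  expect_error(load_image(bad), "unreadable")
  txt <- withr::local_tempfile(fileext = ".xyz")
  writeLines("hi", txt)
  expect_error(load_image(txt), "unsupported")
})

test_that("blank mask implements the min-channel rule", {
  white <- solid_rgb(6, 6, c(255, 255, 255))
  expect_true(all(blank_mask(white)))

  stained <- solid_rgb(6, 6, c(100, 50, 150))
  expect_false(any(blank_mask(stained)))

  # half white, half eosin-pink at the default level: non-blank ratio 0.5
  half <- solid_rgb(6, 6, c(255, 255, 255))
  half[, 4:6, ] <- rep(c(230, 180, 190), each = 18)
  bm <- blank_mask(half, blank_level = 220)
  expect_equal(1 - mean(bm), 0.5)
})

test_that("lowering blank_level never increases the non-blank ratio", {
  set.seed(11)
  img <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20L, 20L, 3L))
  ratios <- sapply(c(255, 240, 220, 180, 120, 0),
                   function(lv) 1 - mean(blank_mask(img, lv)))
  expect_true(all(diff(ratios) <= 0))
})

test_that("binarize separates a two-population darkness histogram exactly", {
  # half the pixels darkness 40, half darkness 200: intensity 255-d on all
  # channels makes the luminance complement equal d exactly
  img <- solid_rgb(10, 10, c(215, 215, 215))
  img[6:10, , ] <- 55
  fg <- binarize(img, blanks = matrix(FALSE, 10, 10))
  expect_equal(attr(fg, "threshold"), otsu_exhaustive(as.vector(darkness(img))))
  expect_true(all(fg[6:10, ]))
  expect_false(any(fg[1:5, ]))
})

test_that("otsu threshold equals the exhaustive-sweep optimum", {
  set.seed(3)
  for (i in 1:30) {
    x <- c(sample(0:120, sample(5:50, 1), replace = TRUE),
           sample(121:255, sample(5:50, 1), replace = TRUE))
    expect_identical(otsu_threshold(x), otsu_exhaustive(x))
  }
  # two-delta histograms: the sweep plateau starts at the lower level
  expect_identical(otsu_threshold(c(rep(40L, 50), rep(200L, 50))), 40L)
})

test_that("degenerate and all-blank images yield empty foregrounds", {
  white <- solid_rgb(5, 5, c(255, 255, 255))
  fg <- binarize(white)
  expect_false(any(fg))
  expect_true(is.na(attr(fg, "threshold")))

  uniform <- solid_rgb(5, 5, c(100, 100, 100))
  fg <- binarize(uniform, blanks = matrix(FALSE, 5, 5))
  expect_false(any(fg))                    # strict > at the fallback median
  expect_equal(attr(fg, "threshold"), 155L)
})

test_that("blank pixels and binarized foreground are always disjoint", {
  set.seed(9)
  for (i in 1:10) {
    img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16L, 16L, 3L))
    bm <- blank_mask(img)
    fg <- binarize(img, bm)
    expect_false(any(bm & fg))
  }
})

test_that("masks round-trip through the debug PNG convention", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(m, path)
  back <- load_image(path)
  expect_identical(back[, , 1] == 255L, m)
})
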