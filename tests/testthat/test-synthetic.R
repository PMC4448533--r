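test_that("tile generation is deterministic and leaves the RNG alone", {
  a <- generate_tile("normal_mucosa", seed = 42)
  set.seed(999); before <- runif(3)
  b <- generate_tile("normal_mucosa", seed = 42)
  set.seed(999); after <- runif(3)
  expect_identical(a$image, b$image)
  expect_identical(before, after)      # generator restored the global state
  c <- generate_tile("normal_mucosa", seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("phenotypes carry the right labels", {
  expect_equal(generate_tile("adenocarcinoma", seed = 1)$label, "cancer")
  for (ph in c("normal_mucosa", "inflammation", "blank_margin",
               "folded_artifact"))
    expect_equal(generate_tile(ph, seed = 1)$label, "benign")
  expect_false(generate_tile("blank_margin", seed = 1)$roi)
  expect_true(generate_tile("inflammation", seed = 1)$roi)
  expect_error(generate_tile("weird_tissue"), "phenotype")
  expect_error(synthetic_tissue_spec("normal_mucosa", width = 32), "64")
})

test_that("generated patterns match their declared Betti pairs", {
  kinds <- c("disks", "rings", "ring_lattice", "checkerboard", "random")
  for (seed in 1:25) {
    for (kind in kinds) {
      p <- generate_pattern(kind, n = sample(1:8, 1), nx = sample(1:5, 1),
                            ny = sample(1:5, 1), p = runif(1, 0.2, 0.7),
                            width = 72L, height = 72L, seed = seed)
      expect_identical(unclass(betti_numbers(p$mask)), p$expected,
                       label = sprintf("%s (seed %d)", kind, seed))
    }
  }
})

test_that("infeasible packings are rejected up front", {
  expect_error(generate_pattern("disks", n = 500, width = 64, height = 64),
               "infeasible")
})

test_that("blank-margin tiles are mostly glass", {
  tile <- generate_tile("blank_margin", seed = 1)
  scr <- screen_tile(tile$image, keep_image = FALSE)
  ratios <- scr$segments$nonblank_ratio
  expect_gt(mean(ratios < 0.2), 0.5)   # most segments nearly tissue-free
})

test_that("tumor sheets out-flag normal mucosa at matched nucleus counts", {
  seeds <- 1:20
  normal <- sapply(seeds, function(s) {
    t <- generate_tile("normal_mucosa", seed = s)
    c(n = t$n_nuclei,
      f = screen_tile(t$image, keep_image = FALSE)$verdict$n_flagged)
  })
  # a focal tumor sheet holding about as many nuclei as a whole normal
  # tile: scale the default coverage by the target/actual nucleus ratio
  n_full <- generate_tile("adenocarcinoma", seed = 1)$n_nuclei
  dens <- 0.85 * mean(normal["n", ]) / n_full
  tumor <- sapply(seeds, function(s) {
    t <- generate_tile("adenocarcinoma", seed = s, nucleus_density = dens)
    c(n = t$n_nuclei,
      f = screen_tile(t$image, keep_image = FALSE)$verdict$n_flagged)
  })
  expect_lt(abs(mean(tumor["n", ]) / mean(normal["n", ]) - 1), 0.15)
  expect_gt(mean(tumor["f", ]), mean(normal["f", ]))
})

test_that("cohort generation writes tiles and labels compatible with evaluation", {
  dir <- withr::local_tempdir()
  manifest <- generate_cohort(n_per_phenotype = 1,
                              phenotypes = c("normal_mucosa", "adenocarcinoma"),
                              seed = 3, dir = dir, width = 140, height = 140)
  expect_equal(nrow(manifest), 2L)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_length(list.files(dir, pattern = "\\.png$"), 2L)
  labels <- read.csv(file.path(dir, "labels.csv"))
  expect_setequal(names(labels), c("image_id", "condition", "roi"))
})
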