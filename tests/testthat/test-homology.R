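test_that("known shapes give their constructed Betti pairs", {
  expect_equal(unclass(betti_numbers(matrix(FALSE, 4, 4))), c(b0 = 0L, b1 = 0L))
  expect_equal(unclass(betti_numbers(matrix(c(TRUE), 1, 1))), c(b0 = 1L, b1 = 0L))

  ring <- matrix(TRUE, 3, 3); ring[2, 2] <- FALSE
  expect_equal(unclass(betti_numbers(ring)), c(b0 = 1L, b1 = 1L))

  # diagonal neighbours share a vertex of the cubical complex: one component
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(unclass(betti_numbers(diag2)), c(b0 = 1L, b1 = 0L))

  two_rings <- matrix(FALSE, 3, 8)
  two_rings[1:3, 1:3] <- ring; two_rings[1:3, 6:8] <- ring
  expect_equal(unclass(betti_numbers(two_rings)), c(b0 = 2L, b1 = 2L))
})

test_that("cell counts enumerate the complex and give chi = b0 - b1", {
  expect_equal(cell_counts(matrix(TRUE, 1, 1)),
               c(V = 4L, E = 4L, F = 1L, chi = 1L))
  expect_equal(cell_counts(matrix(TRUE, 1, 2)),
               c(V = 6L, E = 7L, F = 2L, chi = 1L))
  ring <- matrix(TRUE, 3, 3); ring[2, 2] <- FALSE
  expect_equal(cell_counts(ring), c(V = 16L, E = 24L, F = 8L, chi = 0L))
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(cell_counts(diag2)[["chi"]], 1L)
  expect_equal(cell_counts(diag2)[["V"]], 7L)  # shared corner counted once
})

test_that("chi identity and oracle agreement hold on all 512 3x3 masks", {
  skip_if_not_installed("igraph")
  for (m in all_3x3_masks()) {
    bp <- betti_numbers(m)
    cc <- cell_counts(m)
    expect_identical(bp[["b0"]] - bp[["b1"]], cc[["chi"]])
    expect_identical(unclass(bp), betti_igraph(m))
    expect_identical(unclass(bp), betti_numbers_reference(m))
  }
})

test_that("chi identity and oracles hold on random masks of varied density", {
  skip_if_not_installed("igraph")
  set.seed(20)
  for (i in 1:150) {
    m <- random_mask(sample(2:24, 1), sample(2:24, 1))
    bp <- betti_numbers(m)
    expect_identical(bp[["b0"]] - bp[["b1"]],
                     cell_counts(m)[["chi"]])
    expect_identical(unclass(bp), betti_igraph(m))
  }
})

test_that("padding with background changes neither Betti number", {
  set.seed(7)
  for (i in 1:25) {
    m <- random_mask(10, 12)
    padded <- matrix(FALSE, 16, 20)
    padded[4:13, 5:16] <- m
    expect_identical(unclass(betti_numbers(padded)),
                     unclass(betti_numbers(m)))
  }
})

test_that("Betti numbers add over masks placed in non-adjacent regions", {
  set.seed(8)
  for (i in 1:25) {
    a <- random_mask(8, 8); b <- random_mask(8, 8)
    both <- matrix(FALSE, 8, 20)
    both[, 1:8] <- a; both[, 13:20] <- b
    expect_identical(unclass(betti_numbers(both)),
                     unclass(betti_numbers(a)) + unclass(betti_numbers(b)))
  }
})

test_that("merging isolated nuclei into a fenestrated ring trades b0 for b1", {
  # the tumorigenesis signature: contact converts components into windows
  sparse <- matrix(FALSE, 9, 9)
  sparse[cbind(c(2, 2, 2, 5, 8, 8, 8, 5), c(2, 5, 8, 8, 8, 5, 2, 2))] <- TRUE
  before <- betti_numbers(sparse)
  expect_equal(unclass(before), c(b0 = 8L, b1 = 0L))

  fused <- matrix(FALSE, 9, 9)
  fused[2:8, 2:8] <- TRUE; fused[3:7, 3:7] <- FALSE
  after <- betti_numbers(fused)
  expect_lt(after[["b0"]], before[["b0"]])
  expect_gt(after[["b1"]], before[["b1"]])
})

test_that("labeling respects the requested connectivity", {
  diag2 <- matrix(FALSE, 2, 2); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2, 8)), 1L)
  expect_equal(max(label_components(diag2, 4)), 2L)
  expect_error(label_components(diag2, 6), "connectivity")
})
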