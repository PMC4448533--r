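test_that("grid boundaries follow the rounded proportional rule", {
  g <- make_grid(28, 28, 14, 14)
  expect_equal(nrow(g), 196L)
  expect_true(all(g$x1 - g$x0 == 2L) && all(g$y1 - g$y0 == 2L))

  g <- make_grid(10, 10, 2, 2)
  expect_equal(sort(unique(c(g$x0, g$x1))), c(0L, 5L, 10L))
  expect_equal(sort(unique(c(g$y0, g$y1))), c(0L, 5L, 10L))

  g <- make_grid(15, 10, rows = 2, cols = 4)
  expect_equal(sort(unique(c(g$x0, g$x1))), c(0L, 4L, 8L, 11L, 15L))
})

test_that("segments tile the image exactly for awkward sizes", {
  set.seed(2)
  for (i in 1:20) {
    w <- sample(20:150, 1); h <- sample(20:150, 1)
    rows <- sample(1:14, 1); cols <- sample(1:14, 1)
    g <- make_grid(w, h, rows, cols)
    expect_equal(sum((g$x1 - g$x0) * (g$y1 - g$y0)), w * h)
    # no overlaps: each pixel covered exactly once
    cover <- matrix(0L, h, w)
    for (k in seq_len(nrow(g)))
      cover[(g$y0[k] + 1):g$y1[k], (g$x0[k] + 1):g$x1[k]] <-
        cover[(g$y0[k] + 1):g$y1[k], (g$x0[k] + 1):g$x1[k]] + 1L
    expect_true(all(cover == 1L))
  }
  expect_error(make_grid(10, 10, rows = 11, cols = 2), "finer")
})

test_that("segment scores divide b1 by the non-blank ratio", {
  # one segment fully tissue with a known ring; another half blank
  fg <- matrix(FALSE, 10, 20)
  fg[2:4, 2:4] <- TRUE; fg[3, 3] <- FALSE           # ring in left segment
  fg[2:4, 12:14] <- TRUE; fg[3, 13] <- FALSE        # ring in right segment
  blanks <- matrix(FALSE, 10, 20)
  blanks[6:10, 11:20] <- TRUE                       # right segment half blank
  g <- make_grid(20, 10, 1, 2)
  rec <- score_segments(fg, blanks, g)
  expect_equal(rec$b1, c(1L, 1L))
  expect_equal(rec$nonblank_ratio, c(1, 0.5))
  expect_equal(rec$b1_normalized, c(1, 2))
  expect_equal(rec$status, c("unflagged", "unflagged"))
})

test_that("windows are evaluated within the segment's own border", {
  # a ring straddling the segment boundary encloses nothing in either half
  fg <- matrix(FALSE, 8, 16)
  fg[3:5, 7:10] <- TRUE; fg[4, 8:9] <- FALSE
  g <- make_grid(16, 8, 1, 2)
  rec <- score_segments(fg, matrix(FALSE, 8, 16), g)
  expect_equal(sum(rec$b1), 0L)
  expect_equal(unname(betti_numbers(fg)[["b1"]]), 1L)   # whole-image view
})

test_that("the minimum-tissue guard reports artifacts as insufficient", {
  fg <- matrix(FALSE, 10, 10)
  fg[4:6, 4:6] <- TRUE; fg[5, 5] <- FALSE
  blanks <- matrix(TRUE, 10, 10)
  blanks[fg] <- FALSE                                # ratio = 8/100
  g <- make_grid(10, 10, 1, 1)

  rec <- score_segments(fg, blanks, g, min_tissue = 0.05)
  expect_equal(rec$status, "unflagged")
  expect_equal(rec$b1_normalized, 1 / 0.08)

  rec <- score_segments(fg, blanks, g, min_tissue = 0.1)
  expect_equal(rec$status, "insufficient_tissue")
  expect_equal(rec$b1_normalized, 0)                 # reported as zero
  expect_equal(rec$b1, 1L)                           # raw value retained
  expect_equal(flag_segments(rec, 0)$status, "insufficient_tissue")
})

test_that("flagging uses a strict inequality at the threshold", {
  rec <- data.frame(b1_normalized = c(30, 30.0001, 31, 0),
                    status = "unflagged")
  out <- flag_segments(rec, threshold = 30)
  expect_equal(out$status, c("unflagged", "flagged", "flagged", "unflagged"))
})

test_that("raising the threshold never increases the flagged count", {
  set.seed(4)
  rec <- data.frame(b1_normalized = runif(300, 0, 60),
                    status = sample(c("unflagged", "insufficient_tissue"),
                                    300, TRUE, prob = c(0.9, 0.1)))
  counts <- sapply(seq(0, 60, by = 5), function(th)
    sum(flag_segments(rec, th)$status == "flagged"))
  expect_true(all(diff(counts) <= 0))
})

test_that("image verdict counts flags and rejects empty input", {
  rec <- data.frame(status = c("unflagged", "flagged", "flagged",
                               "insufficient_tissue"))
  v <- image_verdict(rec)
  expect_true(v$positive)
  expect_equal(v$n_flagged, 2L)
  expect_equal(v$n_insufficient, 1L)
  expect_false(image_verdict(data.frame(status = "unflagged"))$positive)
  expect_error(image_verdict(data.frame()), "empty")
})

test_that("segment records are local: outside pixels never matter", {
  set.seed(13)
  fg <- random_mask(40, 40, 0.4)
  blanks <- random_mask(40, 40, 0.2) & !fg
  g <- make_grid(40, 40, 4, 4)
  base <- score_segments(fg, blanks, g)
  # scramble everything outside segment (row 1, col 2)
  k <- which(base$row == 1 & base$col == 2)
  keep_r <- (base$y0[k] + 1):base$y1[k]; keep_c <- (base$x0[k] + 1):base$x1[k]
  fg2 <- random_mask(40, 40, 0.7); blanks2 <- random_mask(40, 40, 0.5) & !fg2
  fg2[keep_r, keep_c] <- fg[keep_r, keep_c]
  blanks2[keep_r, keep_c] <- blanks[keep_r, keep_c]
  after <- score_segments(fg2, blanks2, g)
  expect_equal(after[k, ], base[k, ])
})
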