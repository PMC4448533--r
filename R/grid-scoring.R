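#' Segment grid over an image
#'
#' Partitions a \code{width x height} pixel raster into a \code{rows x cols}
#' grid of half-open, 0-based pixel ranges. Boundary \code{j} of the column
#' partition is \code{round(j * width / cols)} (half-up), and likewise for
#' rows, so the segments tile the image exactly with no gaps or overlaps
#' even when the dimensions do not divide evenly.
#'
#' @param width,height image size in pixels.
#' @param rows,cols grid shape; defaults 14 x 14 (the screening default:
#'   196 segments per tile).
#' @return data.frame with columns \code{row}, \code{col} (0-based grid
#'   indices) and bounds \code{x0}, \code{x1}, \code{y0}, \code{y1}
#'   (half-open: pixels \code{x0 <= x < x1}).
#' @examples
#' make_grid(15, 10, rows = 2, cols = 4)
#' @export
make_grid <- function(width, height, rows = 14L, cols = 14L) {
  stopifnot(width >= 1L, height >= 1L, rows >= 1L, cols >= 1L)
  if (rows > height || cols > width)
    stop("grid is finer than the image (rows > height or cols > width)",
         call. = FALSE)
  half_up <- function(x) floor(x + 0.5)
  xb <- as.integer(half_up((0:cols) * width / cols))
  yb <- as.integer(half_up((0:rows) * height / rows))
  g <- expand.grid(col = 0:(cols - 1L), row = 0:(rows - 1L))
  data.frame(row = g$row, col = g$col,
             x0 = xb[g$col + 1L], x1 = xb[g$col + 2L],
             y0 = yb[g$row + 1L], y1 = yb[g$row + 2L])
}

#' Score the segments of a binarized tile
#'
#' For each grid segment, computes the Betti numbers of the stained
#' foreground restricted to the segment (windows are evaluated within the
#' segment's own border: a complement region leaking over the segment edge
#' is not a window), the non-blank tissue ratio, and the normalized score
#' \code{b1_normalized = b1 / nonblank_ratio}.
#'
#' Dividing by the tissue fraction makes scores comparable between full and
#' partially blank segments, but explodes when almost no tissue is present:
#' a sliver with one window and 2\% tissue scores 50. The
#' \code{min_tissue} guard neutralizes this known numerical artifact:
#' segments below the cutoff get status \code{"insufficient_tissue"} and a
#' reported score of 0 while retaining their raw \code{b0}/\code{b1}. Set
#' \code{min_tissue = 0} to reproduce the unguarded behaviour.
#'
#' @param fg logical foreground mask from [binarize()].
#' @param blanks logical blank mask from [blank_mask()].
#' @param grid segment bounds from [make_grid()].
#' @param min_tissue minimum non-blank ratio for a segment to be scored;
#'   default 0.05.
#' @param normalize divide \code{b1} by the non-blank ratio (default
#'   \code{TRUE}); with \code{FALSE}, \code{b1_normalized} is the raw
#'   \code{b1}.
#' @return data.frame of segment records: the grid columns plus \code{b0},
#'   \code{b1}, \code{nonblank_ratio}, \code{b1_normalized} and
#'   \code{status} (\code{"unflagged"} or \code{"insufficient_tissue"};
#'   [flag_segments()] applies the threshold).
#' @export
score_segments <- function(fg, blanks, grid, min_tissue = 0.05,
                           normalize = TRUE) {
  stopifnot(is.matrix(fg), identical(dim(fg), dim(blanks)),
            min_tissue >= 0, min_tissue < 1)
  n <- nrow(grid)
  b0 <- b1 <- integer(n)
  ratio <- numeric(n)
  for (k in seq_len(n)) {
    ri <- (grid$y0[k] + 1L):grid$y1[k]
    ci <- (grid$x0[k] + 1L):grid$x1[k]
    bp <- betti_numbers(fg[ri, ci, drop = FALSE])
    b0[k] <- bp[["b0"]]; b1[k] <- bp[["b1"]]
    ratio[k] <- 1 - mean(blanks[ri, ci])
  }
  insufficient <- ratio < min_tissue
  score <- ifelse(insufficient, 0,
                  if (normalize) ifelse(ratio > 0, b1 / ratio, 0) else b1)
  out <- grid
  out$b0 <- b0
  out$b1 <- b1
  out$nonblank_ratio <- ratio
  out$b1_normalized <- score
  out$status <- ifelse(insufficient, "insufficient_tissue", "unflagged")
  out
}

#' Apply the flagging threshold to segment records
#'
#' A segment is flagged when its normalized score strictly exceeds the
#' threshold (\code{b1_normalized > threshold}); segments with status
#' \code{"insufficient_tissue"} are never flagged. All other fields are
#' left unchanged, so re-flagging at a different threshold is cheap.
#'
#' @param records segment data.frame from [score_segments()].
#' @param threshold non-negative score cutoff; default 30, the published
#'   operating point of the screening rule.
#' @return the records with \code{status} updated to \code{"flagged"} /
#'   \code{"unflagged"}.
#' @export
flag_segments <- function(records, threshold = 30) {
  stopifnot(threshold >= 0, is.data.frame(records))
  keep <- records$status == "insufficient_tissue"
  records$status <- ifelse(keep, "insufficient_tissue",
                           ifelse(records$b1_normalized > threshold,
                                  "flagged", "unflagged"))
  records
}

#' Image-level verdict from segment records
#'
#' An image is screen-positive when at least one of its segments is
#' flagged.
#'
#' @param records segment data.frame covering one image's grid, after
#'   [flag_segments()].
#' @return list with \code{positive} (logical), \code{n_flagged} and
#'   \code{n_insufficient} (integer counts).
#' @export
image_verdict <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty segment record list", call. = FALSE)
  n_flagged <- sum(records$status == "flagged")
  list(positive = n_flagged >= 1L,
       n_flagged = as.integer(n_flagged),
       n_insufficient = as.integer(sum(records$status == "insufficient_tissue")))
}
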