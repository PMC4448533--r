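#' Screen one H&E tile for high-contact regions
#'
#' Runs the full per-tile pipeline: blank-glass masking, automatic
#' binarization of the hematoxylin-dark foreground, segment-grid Betti
#' scoring, tissue-fraction normalization, and threshold flagging. The
#' result carries every segment record plus the image-level verdict.
#'
#' @param img an RGB array \code{[h, w, 3]} in \code{[0, 255]}, or a path
#'   to an image readable by [load_image()].
#' @param grid_rows,grid_cols segment grid shape; default 14 x 14.
#' @param threshold flagging cutoff on the normalized segment score;
#'   default 30.
#' @param blank_level glass-white intensity cutoff; default 220.
#' @param min_tissue minimum non-blank ratio per segment; default 0.05.
#' @param normalize divide segment b1 by its non-blank ratio; default
#'   \code{TRUE}.
#' @param keep_image keep the pixel data in the result so that
#'   \code{plot()} can draw the overlay; default \code{TRUE}.
#' @param image_id identifier stored with the result; defaults to the file
#'   name when \code{img} is a path.
#' @return An object of class \code{roi_screen}: a list with
#'   \code{segments} (the record data.frame), \code{verdict} (from
#'   [image_verdict()]), \code{config}, \code{dim}, \code{threshold_used}
#'   (the automatic darkness cut), \code{image_id}, and optionally
#'   \code{image}.
#' @examples
#' tile <- generate_tile("adenocarcinoma", seed = 1)
#' scr <- screen_tile(tile$image)
#' scr
#' @export
screen_tile <- function(img, grid_rows = 14L, grid_cols = 14L,
                        threshold = 30, blank_level = 220,
                        min_tissue = 0.05, normalize = TRUE,
                        keep_image = TRUE, image_id = NULL) {
  if (is.character(img)) {
    if (is.null(image_id)) image_id <- basename(img)
    img <- load_image(img)
  }
  if (is.null(image_id)) image_id <- "image"
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  blanks <- blank_mask(img, blank_level)
  fg <- binarize(img, blanks)
  grid <- make_grid(w, h, grid_rows, grid_cols)
  seg <- score_segments(fg, blanks, grid, min_tissue, normalize)
  seg <- flag_segments(seg, threshold)
  out <- list(
    segments = seg,
    verdict = image_verdict(seg),
    config = list(grid_rows = grid_rows, grid_cols = grid_cols,
                  threshold = threshold, blank_level = blank_level,
                  min_tissue = min_tissue, normalize = normalize),
    dim = c(height = h, width = w),
    threshold_used = attr(fg, "threshold"),
    image_id = image_id
  )
  if (keep_image) out$image <- img
  class(out) <- "roi_screen"
  out
}

#' @export
print.roi_screen <- function(x, ...) {
  v <- x$verdict
  cat(sprintf("Homology ROI screen of '%s' (%d x %d px, %d x %d grid)\n",
              x$image_id, x$dim[["width"]], x$dim[["height"]],
              x$config$grid_rows, x$config$grid_cols))
  cat(sprintf("  verdict: %s  (%d flagged, %d insufficient-tissue of %d segments)\n",
              if (v$positive) "POSITIVE" else "negative",
              v$n_flagged, v$n_insufficient, nrow(x$segments)))
  cat(sprintf("  score threshold %g on %s b1; darkness cut %s\n",
              x$config$threshold,
              if (x$config$normalize) "normalized" else "raw",
              if (is.na(x$threshold_used)) "NA (all blank)" else x$threshold_used))
  invisible(x)
}

#' @export
summary.roi_screen <- function(object, ...) {
  s <- object$segments
  scored <- s[s$status != "insufficient_tissue", , drop = FALSE]
  out <- list(
    image_id = object$image_id,
    verdict = object$verdict,
    n_segments = nrow(s),
    b1_total = sum(s$b1),
    score_quartiles = stats::quantile(scored$b1_normalized,
                                      names = FALSE, na.rm = TRUE),
    top_segments = utils::head(s[order(-s$b1_normalized), ], 5L),
    config = object$config
  )
  class(out) <- "summary.roi_screen"
  out
}

#' @export
print.summary.roi_screen <- function(x, ...) {
  cat(sprintf("'%s': %s, %d/%d segments flagged, total b1 = %d\n",
              x$image_id,
              if (x$verdict$positive) "POSITIVE" else "negative",
              x$verdict$n_flagged, x$n_segments, x$b1_total))
  q <- x$score_quartiles
  cat(sprintf("  normalized b1 quartiles: %.1f / %.1f / %.1f / %.1f / %.1f\n",
              q[1], q[2], q[3], q[4], q[5]))
  cat("  highest-scoring segments:\n")
  print(x$top_segments[, c("row", "col", "b0", "b1", "nonblank_ratio",
                           "b1_normalized", "status")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.roi_screen <- function(x, ...) {
  cbind(image_id = x$image_id, x$segments)
}

#' Plot the screening overlay
#'
#' Draws the tile with one colored dot per segment at its left edge; green
#' dots mark flagged segments, gray marks insufficient tissue, and the
#' remaining dots encode the normalized score through the color scale.
#'
#' @param x a \code{roi_screen} object created with \code{keep_image = TRUE}.
#' @param scale a [color_scale()]; defaults to one spanning
#'   \code{[0, threshold]}.
#' @param ... passed to [render_overlay()].
#' @return invisibly, the overlay RGB array.
#' @export
plot.roi_screen <- function(x, scale = NULL, ...) {
  if (is.null(x[["image"]]))
    stop("screen_tile() was run with keep_image = FALSE; no pixels to plot",
         call. = FALSE)
  if (is.null(scale)) scale <- color_scale(max_score = x$config$threshold)
  ov <- render_overlay(x[["image"]], x$segments, scale, ...)
  op <- par(mar = c(0.5, 0.5, 1.5, 0.5)); on.exit(par(op))
  plot(NA, xlim = c(0, ncol(ov)), ylim = c(0, nrow(ov)), asp = 1,
       axes = FALSE, xlab = "", ylab = "", main = x$image_id)
  rasterImage(ov / 255, 0, 0, ncol(ov), nrow(ov))
  invisible(ov)
}
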