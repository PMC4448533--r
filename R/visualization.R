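#' Segment score color scale
#'
#' A piecewise-linear RGB ramp over score breakpoints, with a reserved
#' flag color for segments above the last breakpoint. The default ramp
#' runs blue (0) through yellow to red at \code{max_score}, with green
#' reserved for flagged segments, so "green dot = very high b1" survives
#' any rescaling of the ramp.
#'
#' @param breakpoints data.frame with columns \code{score}, \code{r},
#'   \code{g}, \code{b} (strictly increasing scores, channels in 0..255).
#'   Default: blue -> yellow -> red over \code{[0, max_score]}.
#' @param flag_color RGB triple for flagged segments; default green.
#' @param max_score upper end of the default ramp; default 30.
#' @return object of class \code{color_scale}.
#' @export
color_scale <- function(breakpoints = NULL, flag_color = c(0L, 255L, 0L),
                        max_score = 30) {
  if (is.null(breakpoints)) {
    breakpoints <- data.frame(
      score = c(0, max_score / 2, max_score),
      r = c(40L, 250L, 255L),
      g = c(60L, 200L, 40L),
      b = c(220L, 60L, 30L))
  }
  stopifnot(is.data.frame(breakpoints),
            all(c("score", "r", "g", "b") %in% names(breakpoints)),
            nrow(breakpoints) >= 2L,
            all(diff(breakpoints$score) > 0))
  structure(list(breakpoints = breakpoints,
                 flag_color = as.integer(flag_color)),
            class = "color_scale")
}

#' Map scores to colors through a scale
#'
#' Linear interpolation between breakpoints; scores at or below the first
#' breakpoint take its color, scores above the last clamp to the flag
#' color.
#'
#' @param scale a [color_scale()].
#' @param score numeric vector of segment scores.
#' @return integer matrix \code{length(score) x 3} of RGB values.
#' @export
scale_color <- function(scale, score) {
  bp <- scale$breakpoints
  lo <- bp$score[1L]; hi <- bp$score[nrow(bp)]
  out <- matrix(0L, length(score), 3L)
  over <- score > hi
  s <- pmin(pmax(score, lo), hi)
  for (k in 1:3) {
    ch <- c("r", "g", "b")[k]
    out[, k] <- as.integer(round(approx(bp$score, bp[[ch]], xout = s)$y))
  }
  if (any(over))
    out[over, ] <- matrix(scale$flag_color, sum(over), 3L, byrow = TRUE)
  out
}

#' Render the segment-score overlay
#'
#' Copies the tile and draws one filled dot per segment, vertically
#' centered at the segment's left edge. Flagged segments get the scale's
#' flag color (green by default); insufficient-tissue segments get a
#' neutral gray marker; other segments are colored by their normalized
#' score.
#'
#' @param img integer RGB array \code{[h, w, 3]}.
#' @param records segment data.frame from [flag_segments()].
#' @param scale a [color_scale()].
#' @param dot_radius dot radius in pixels; default
#'   \code{max(2, segment_height / 6)}.
#' @return RGB array of the same dimensions as \code{img}.
#' @export
render_overlay <- function(img, records, scale = color_scale(),
                           dot_radius = NULL) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  seg_h <- records$y1 - records$y0
  if (is.null(dot_radius)) dot_radius <- max(2, floor(min(seg_h) / 6))
  if (dot_radius < 1) stop("dot_radius must be >= 1", call. = FALSE)
  if (2 * dot_radius + 1 > min(seg_h))
    warning("dot larger than segment; dots will be clipped to the image")
  cols <- scale_color(scale, records$b1_normalized)
  gray <- c(128L, 128L, 128L)
  out <- img
  for (k in seq_len(nrow(records))) {
    col3 <- switch(records$status[k],
                   flagged = scale$flag_color,
                   insufficient_tissue = gray,
                   cols[k, ])
    cx <- records$x0[k] + dot_radius                  # 0-based center
    cy <- (records$y0[k] + records$y1[k]) / 2
    xs <- max(0L, floor(cx - dot_radius)):min(w - 1L, ceiling(cx + dot_radius))
    ys <- max(0L, floor(cy - dot_radius)):min(h - 1L, ceiling(cy + dot_radius))
    dd <- outer((ys - cy)^2, (xs - cx)^2, "+") <= dot_radius^2
    ri <- ys + 1L; ci <- xs + 1L
    for (ch in 1:3) {
      sub <- out[ri, ci, ch, drop = FALSE]
      sub[dd] <- col3[ch]
      out[ri, ci, ch] <- sub
    }
  }
  out
}

#' Render a vertical color bar for a scale
#'
#' A gradient strip sampling the scale from its minimum (bottom) to above
#' its last breakpoint, so the top rows show the flag color.
#'
#' @param scale a [color_scale()].
#' @param height,width strip size in pixels; \code{height >= 10}.
#' @return RGB array \code{[height, width, 3]}.
#' @export
render_colorbar <- function(scale, height = 128L, width = 16L) {
  stopifnot(height >= 10L, width >= 1L)
  bp <- scale$breakpoints
  lo <- bp$score[1L]; hi <- bp$score[nrow(bp)]
  # top 10% of rows sample above the clamp -> flag color
  scores <- seq(hi + (hi - lo) * 0.1, lo, length.out = height)
  cols <- scale_color(scale, scores)
  out <- array(0L, c(height, width, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(cols[, ch], height, width)
  out
}
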