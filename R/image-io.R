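#' Load an RGB tile image
#'
#' Reads a PNG, TIFF or BMP raster into an integer array of shape
#' \code{height x width x 3} with intensities in \code{[0, 255]}. Grayscale
#' inputs are replicated across the three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG (.png), TIFF (.tif/.tiff) or uncompressed
#'   24/32-bit BMP (.bmp) file. The format is chosen by file extension.
#' @return integer array \code{[height, width, 3]} in \code{[0, 255]}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG: ", path, call. = FALSE)),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("unreadable TIFF: ", path, call. = FALSE)),
    bmp  = return(read_bmp(path)),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[1] < 1L || dim(arr)[2] < 1L)
    stop("zero-area image: ", path, call. = FALSE)
  nc <- dim(arr)[3]
  if (nc == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  else if (nc == 2L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
  else arr <- arr[, , 1:3, drop = FALSE]
  out <- array(as.integer(round(arr * 255)), dim(arr))
  out[out < 0L] <- 0L; out[out > 255L] <- 255L
  out
}

# Minimal reader for uncompressed 24/32-bit BMP (BITMAPINFOHEADER); no
# installed package reads BMP, so this is done by hand.
read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (length(magic) < 2L || !identical(rawToChar(magic), "BM"))
    stop("unreadable BMP (bad magic): ", path, call. = FALSE)
  readBin(con, "integer", 2L, size = 4L)              # file size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  hdrsize <- readBin(con, "integer", 1L, size = 4L)
  if (hdrsize < 40L) stop("unsupported BMP header: ", path, call. = FALSE)
  w <- readBin(con, "integer", 1L, size = 4L)
  hraw <- readBin(con, "integer", 1L, size = 4L)
  h <- abs(hraw); topdown <- hraw < 0L
  readBin(con, "integer", 1L, size = 2L)              # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  compression <- readBin(con, "integer", 1L, size = 4L)
  if (w < 1L || h < 1L) stop("zero-area image: ", path, call. = FALSE)
  if (!(bpp %in% c(24L, 32L)) || compression != 0L)
    stop("unsupported BMP variant (need uncompressed 24/32-bit): ", path,
         call. = FALSE)
  seek(con, offset)
  bytes_pp <- bpp %/% 8L
  stride <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  data <- readBin(con, "raw", stride * h)
  if (length(data) < stride * h) stop("truncated BMP: ", path, call. = FALSE)
  rows <- matrix(as.integer(data), nrow = stride)[seq_len(w * bytes_pp), , drop = FALSE]
  px <- array(rows, c(bytes_pp, w, h))                # BGR(A), bottom-up rows
  img <- array(0L, c(h, w, 3L))
  rowidx <- if (topdown) seq_len(h) else rev(seq_len(h))
  for (k in 1:3) img[, , k] <- t(px[4L - k, , rowidx])
  img
}

#' Write an RGB array or binary mask as PNG
#'
#' Masks are written as 8-bit grayscale with 0 = \code{FALSE},
#' 255 = \code{TRUE}, which makes debug masks viewable in any image viewer.
#'
#' @param x integer RGB array \code{[h, w, 3]} in \code{[0,255]}, or a
#'   logical matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.integer(x) * 255L, nrow(x), ncol(x))
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Mask of blank (glass) pixels
#'
#' A pixel is blank when all three channels are near white:
#' \code{min(R, G, B) >= blank_level}. Unstained glass on H&E slides scans
#' as near-white; everything else (eosin-pink stroma, hematoxylin-dark
#' nuclei) is tissue. The non-blank ratio of any region is
#' \code{1 - mean(blank)}, the divisor used when normalizing segment
#' scores.
#'
#' @param img integer RGB array \code{[h, w, 3]} in \code{[0,255]}.
#' @param blank_level intensity threshold in \code{[0, 255]}; default 220.
#'   Scanner white points vary, so this is tunable.
#' @return logical matrix, \code{TRUE} = blank glass.
#' @export
blank_mask <- function(img, blank_level = 220) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L,
            blank_level >= 0, blank_level <= 255)
  pmin(img[, , 1], img[, , 2], img[, , 3]) >= blank_level
}

#' Automatic binarization of the stained foreground
#'
#' Extracts the hematoxylin-dark tissue mask with a per-image threshold
#' derived from the image itself, so no global tuning parameter is needed:
#' \enumerate{
#'   \item per-pixel darkness \code{d = 255 - round(0.299 R + 0.587 G +
#'     0.114 B)} (Rec.601 luminance complement);
#'   \item threshold \code{t} maximizing the between-class variance of the
#'     darkness histogram restricted to non-blank pixels (Otsu's rule);
#'   \item foreground iff non-blank and \code{d > t} (strictly darker side).
#' }
#' If every pixel is blank the mask is empty. If the darkness histogram is
#' degenerate (a single value, so all splits have zero between-class
#' variance), \code{t} falls back to the median darkness; the strict
#' inequality then yields an empty foreground.
#'
#' @param img integer RGB array \code{[h, w, 3]} in \code{[0,255]}.
#' @param blanks logical blank mask from [blank_mask()]; recomputed with
#'   default settings when omitted.
#' @return logical foreground matrix with attribute \code{"threshold"}
#'   (the darkness cut actually used, \code{NA} for an all-blank image).
#' @export
binarize <- function(img, blanks = blank_mask(img)) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (!identical(dim(blanks), dim(img)[1:2]))
    stop("blank mask dimensions do not match the image", call. = FALSE)
  d <- darkness(img)
  nb <- d[!blanks]
  if (length(nb) == 0L) {
    out <- matrix(FALSE, nrow(d), ncol(d))
    attr(out, "threshold") <- NA_integer_
    return(out)
  }
  t <- otsu_threshold(nb)
  if (is.na(t)) t <- as.integer(median(nb))
  out <- !blanks & d > t
  attr(out, "threshold") <- t
  out
}

#' Per-pixel darkness channel
#'
#' \code{255 - round(0.299 R + 0.587 G + 0.114 B)}: the complement of the
#' Rec.601 luminance, so hematoxylin-dark nuclei score high.
#'
#' @inheritParams blank_mask
#' @return integer matrix in \code{[0, 255]}.
#' @export
darkness <- function(img) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(255L - as.integer(round(lum)), nrow(lum), ncol(lum))
}

#' Otsu threshold of an integer sample
#'
#' Maximizes the between-class variance \code{w0 w1 (mu0 - mu1)^2} of the
#' two-class split \code{x <= t} vs \code{x > t} over all integer cuts,
#' via cumulative histogram sums. Ties take the smallest cut.
#'
#' @param x integer vector of values in \code{[0, 255]}.
#' @return integer threshold, or \code{NA} when no split has positive
#'   between-class variance (degenerate one-level histogram).
#' @export
otsu_threshold <- function(x) {
  stopifnot(length(x) >= 1L)
  counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                 # pixels with value <= t
  s0 <- cumsum(counts * lev)
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s0[256L] - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  best <- max(bcv)
  if (best <= 0) return(NA_integer_)
  as.integer(lev[which.max(bcv)])
}
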