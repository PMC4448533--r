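# Independent oracles used across the test files.

# Betti numbers via igraph connected components: foreground components under
# 8-connectivity, holes as 4-connected complement components away from the
# border. Shares nothing with the package's compiled labeling.
betti_igraph <- function(mask) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  h <- nrow(mask); w <- ncol(mask)
  idx <- matrix(seq_len(h * w), h, w)
  n_components <- function(m, diag) {
    ids <- idx[m]
    if (length(ids) == 0L) return(0L)
    shifts <- list(c(1L, 0L), c(0L, 1L))
    if (diag) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
    edges <- NULL
    for (s in shifts) {
      ri <- seq_len(h - abs(s[1])); ci <- seq_len(w - s[2])
      a <- as.vector(idx[ri + max(0L, s[1]), ci, drop = FALSE])
      b <- as.vector(idx[ri + max(0L, -s[1]), ci + s[2], drop = FALSE])
      both <- m[a] & m[b]
      edges <- rbind(edges, cbind(a[both], b[both]))
    }
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(edges[, 1]),
                     to = as.character(edges[, 2])),
      directed = FALSE, vertices = data.frame(name = as.character(ids)))
    igraph::count_components(g)
  }
  b0 <- n_components(mask, diag = TRUE)
  # holes: complement components minus those touching the border, counted
  # by adding a frame of TRUE complement pixels that absorbs all unbounded
  # regions into a single component
  framed <- matrix(TRUE, h + 2L, w + 2L)
  framed[2:(h + 1L), 2:(w + 1L)] <- !mask
  hh <- h + 2L; ww <- w + 2L
  idx <- matrix(seq_len(hh * ww), hh, ww)
  h <- hh; w <- ww
  b1 <- n_components(framed, diag = FALSE) - 1L
  c(b0 = as.integer(b0), b1 = as.integer(b1))
}

# Exhaustive between-class-variance sweep (the slow Otsu oracle).
otsu_exhaustive <- function(x) {
  n <- length(x)
  best_t <- NA_integer_; best <- 0
  for (t in 0:255) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

all_3x3_masks <- function() {
  lapply(0:511, function(code) {
    matrix(bitwAnd(bitwShiftR(code, 0:8), 1L) == 1L, 3L, 3L)
  })
}

random_mask <- function(h, w, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.15, 0.85)
  matrix(runif(h * w) < p, h, w)
}

# A flat-color RGB array.
solid_rgb <- function(h, w, color) {
  array(rep(as.numeric(color), each = h * w), c(h, w, 3L))
}

# Minimal uncompressed 24-bit BMP writer (tests the package's BMP reader
# against independently constructed bytes).
write_bmp24 <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  data_size <- stride * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(14L + 40L + data_size, 0L, 54L)), con, size = 4)
  writeBin(as.integer(c(40L, w, h)), con, size = 4)
  writeBin(as.integer(c(1L, 24L)), con, size = 2)
  writeBin(as.integer(c(0L, data_size, 2835L, 2835L, 0L, 0L)), con, size = 4)
  for (i in h:1) {                                    # bottom-up rows
    row <- as.vector(rbind(img[i, , 3], img[i, , 2], img[i, , 1]))
    writeBin(as.raw(c(row, rep(0L, stride - 3 * w))), con)
  }
  invisible(path)
}
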