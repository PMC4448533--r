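#' Binary test patterns with known Betti numbers
#'
#' Constructs binary masks whose Betti pair is certain by construction, for
#' exercising the homology engine:
#' \describe{
#'   \item{disks}{\code{n} disjoint filled disks: expected \code{(n, 0)}.}
#'   \item{rings}{\code{n} disjoint annuli: expected \code{(n, n)}.}
#'   \item{ring_lattice}{an \code{nx x ny} lattice of square rings sharing
#'     walls (one fused component): expected \code{(1, nx * ny)}.}
#'   \item{checkerboard}{alternating pixels starting \code{TRUE} at (0,0);
#'     diagonal contacts join all \code{TRUE} pixels into one component
#'     (when both dimensions exceed 1) and every interior \code{FALSE}
#'     pixel is an isolated window.}
#'   \item{random}{i.i.d. Bernoulli pixels; the expected pair comes from
#'     the plain-R reference labeling in [betti_numbers_reference()],
#'     independent of the compiled engine.}
#' }
#' Disjointness for \code{disks}/\code{rings} is enforced by placing shapes
#' on a spaced grid, so the expected values are certain rather than checked
#' after the fact.
#'
#' @param kind one of \code{"disks"}, \code{"rings"}, \code{"ring_lattice"},
#'   \code{"checkerboard"}, \code{"random"}.
#' @param n number of shapes (disks/rings).
#' @param nx,ny ring-lattice shape.
#' @param width,height canvas size; checkerboard/random use these directly.
#' @param radius outer shape radius in pixels (disks/rings).
#' @param p foreground probability for \code{random}.
#' @param seed integer seed for the randomized placements.
#' @return list with \code{mask} (logical matrix) and \code{expected}
#'   (named integer vector \code{b0}, \code{b1}).
#' @examples
#' p <- generate_pattern("rings", n = 3)
#' p$expected
#' @export
generate_pattern <- function(kind = c("disks", "rings", "ring_lattice",
                                      "checkerboard", "random"),
                             n = 5L, nx = 4L, ny = 4L,
                             width = 96L, height = 96L,
                             radius = 6, p = 0.4, seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    disks = pattern_shapes(n, width, height, radius, ring = FALSE),
    rings = pattern_shapes(n, width, height, radius, ring = TRUE),
    ring_lattice = pattern_ring_lattice(nx, ny),
    checkerboard = pattern_checkerboard(height, width),
    random = pattern_random(height, width, p)))
}

pattern_shapes <- function(n, width, height, radius, ring) {
  cell <- 2 * radius + 3                   # >= 1 px of guaranteed clearance
  nx <- floor(width / cell); ny <- floor(height / cell)
  if (n > nx * ny)
    stop("infeasible packing: ", n, " shapes of radius ", radius,
         " do not fit a ", width, "x", height, " canvas", call. = FALSE)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g <- g[sample.int(nrow(g), n), , drop = FALSE]
  mask <- matrix(FALSE, height, width)
  for (k in seq_len(n)) {
    cx <- (g$ix[k] - 0.5) * cell
    cy <- (g$iy[k] - 0.5) * cell
    xs <- pmax(1L, floor(cx - radius)):pmin(width, ceiling(cx + radius))
    ys <- pmax(1L, floor(cy - radius)):pmin(height, ceiling(cy + radius))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    inside <- if (ring) d2 <= radius^2 & d2 > (radius - 2.2)^2 else d2 <= radius^2
    sub <- mask[ys, xs]; sub[inside] <- TRUE; mask[ys, xs] <- sub
  }
  list(mask = mask,
       expected = c(b0 = as.integer(n), b1 = as.integer(if (ring) n else 0L)))
}

pattern_ring_lattice <- function(nx, ny, cell = 6L) {
  h <- ny * cell + 1L; w <- nx * cell + 1L
  mask <- matrix(FALSE, h, w)
  mask[seq(1L, h, by = cell), ] <- TRUE
  mask[, seq(1L, w, by = cell)] <- TRUE
  list(mask = mask, expected = c(b0 = 1L, b1 = as.integer(nx * ny)))
}

pattern_checkerboard <- function(h, w) {
  idx <- outer(0:(h - 1L), 0:(w - 1L), "+")
  mask <- idx %% 2L == 0L
  if (min(h, w) == 1L) {
    expected <- c(b0 = as.integer(sum(mask)), b1 = 0L)
  } else {
    interior <- idx[2:(h - 1L), 2:(w - 1L), drop = FALSE]
    expected <- c(b0 = 1L, b1 = as.integer(sum(interior %% 2L == 1L)))
  }
  list(mask = mask, expected = expected)
}

pattern_random <- function(h, w, p) {
  mask <- matrix(runif(h * w) < p, h, w)
  list(mask = mask, expected = betti_numbers_reference(mask))
}

#' Reference Betti numbers by iterative label propagation
#'
#' A slow, dependency-free reimplementation of [betti_numbers()] used as an
#' independent oracle: every foreground pixel starts with its own label and
#' repeatedly takes the minimum label over its neighbours until a fixed
#' point; the number of surviving labels is the component count. Holes are
#' counted the same way on the complement (4-connectivity, border
#' components excluded). Shares no code with the compiled engine.
#'
#' @inheritParams betti_numbers
#' @return named integer vector \code{b0}, \code{b1}.
#' @export
betti_numbers_reference <- function(mask) {
  mask <- as_mask(mask)
  b0 <- length(prop_components(mask, diag = TRUE))
  h <- nrow(mask); w <- ncol(mask)
  comp_labels <- prop_label_matrix(!mask, diag = FALSE)
  labs <- unique(comp_labels[!mask])
  border <- unique(c(comp_labels[1L, ], comp_labels[h, ],
                     comp_labels[, 1L], comp_labels[, w]))
  b1 <- length(setdiff(labs, border))
  c(b0 = as.integer(b0), b1 = as.integer(b1))
}

prop_label_matrix <- function(mask, diag) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h + 2L, w + 2L)
  core <- cbind(rep(2:(h + 1L), w), rep(2:(w + 1L), each = h))
  fg <- as.vector(mask)
  lab[core[fg, , drop = FALSE]] <- which(fg)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (diag) shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    old <- lab
    for (s in shifts) {
      shifted <- lab[(2:(h + 1L)) + s[1], (2:(w + 1L)) + s[2]]
      cur <- lab[2:(h + 1L), 2:(w + 1L)]
      upd <- pmin(cur, shifted)
      upd[!mask] <- Inf
      lab[2:(h + 1L), 2:(w + 1L)] <- upd
    }
    if (identical(old, lab)) break
  }
  out <- lab[2:(h + 1L), 2:(w + 1L)]
  out[!mask] <- NA
  out
}

prop_components <- function(mask, diag) {
  lab <- prop_label_matrix(mask, diag)
  unique(lab[mask])
}
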