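#' Betti numbers of a binary image
#'
#' Treats the foreground of a binary image as a full cubical complex: every
#' \code{TRUE} pixel contributes a filled unit square together with its four
#' edges and four vertices, and cells shared between adjacent pixels are
#' counted once. In this complex two diagonally adjacent pixels share a
#' vertex, so the foreground is connected under 8-connectivity, and planar
#' duality then forces 4-connectivity for the complement.
#'
#' \code{b0} counts the connected solid components of the foreground (for
#' tissue masks: isolated nuclei or fused nuclear clusters). \code{b1}
#' counts the enclosed windows -- bounded complement regions completely
#' surrounded by foreground, i.e. 4-connected components of the \code{FALSE}
#' pixels that do not touch the image border. Rising nuclear contact turns
#' isolated components into fenestrated sheets, trading \code{b0} for
#' \code{b1}; that exchange is the tumorigenesis signature this package
#' screens for.
#'
#' @param mask logical matrix (rows = image rows). Numeric 0/1 matrices are
#'   accepted; \code{NA} counts as background.
#' @return An object of class \code{betti_pair}: a named integer vector with
#'   elements \code{b0} and \code{b1}.
#' @examples
#' ring <- matrix(TRUE, 3, 3); ring[2, 2] <- FALSE
#' betti_numbers(ring)        # one component enclosing one window
#' @seealso [cell_counts()] for the Euler-characteristic cross-check
#'   (`b0 - b1 == V - E + F` for every planar mask).
#' @export
betti_numbers <- function(mask) {
  mask <- as_mask(mask)
  fg <- .cc_label(mask, 8L)
  b0 <- max(fg)
  comp <- .cc_label(!mask, 4L)
  h <- nrow(comp); w <- ncol(comp)
  border <- unique(c(comp[1L, ], comp[h, ], comp[, 1L], comp[, w]))
  n_comp <- max(comp)
  b1 <- if (n_comp == 0L) 0L else n_comp - length(setdiff(border, 0L))
  structure(c(b0 = as.integer(b0), b1 = as.integer(b1)), class = "betti_pair")
}

#' @export
print.betti_pair <- function(x, ...) {
  cat(sprintf("Betti numbers: b0 = %d (components), b1 = %d (windows)\n",
              x[["b0"]], x[["b1"]]))
  invisible(x)
}

#' Cell counts of the full cubical complex
#'
#' Counts the distinct vertices, edges and faces of the cubical complex
#' built from the foreground pixels (each shared cell once). The Euler
#' characteristic \code{chi = V - E + F} equals \code{b0 - b1} for any
#' planar complex, which makes these counts an exact independent oracle for
#' [betti_numbers()].
#'
#' @inheritParams betti_numbers
#' @return Named integer vector with elements \code{V}, \code{E}, \code{F}
#'   and \code{chi}.
#' @examples
#' cell_counts(matrix(TRUE, 1, 2))  # V=6, E=7, F=2, chi=1
#' @export
cell_counts <- function(mask) {
  mask <- as_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  # pad with a background frame so every pixel has all 4 pixel-neighbours
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  ph <- h + 2L; pw <- w + 2L
  # vertex (i,j) of the (h+1)x(w+1) lattice is present iff any of the 4
  # incident pixels is foreground
  vert <- p[1:(ph - 1L), 1:(pw - 1L)] | p[2:ph, 1:(pw - 1L)] |
          p[1:(ph - 1L), 2:pw]        | p[2:ph, 2:pw]
  # horizontal edge between vertex columns j,j+1 on vertex row i: present
  # iff the pixel above or below it is foreground
  eh <- p[1:(ph - 1L), 2:(pw - 1L)] | p[2:ph, 2:(pw - 1L)]
  # vertical edge analogously
  ev <- p[2:(ph - 1L), 1:(pw - 1L)] | p[2:(ph - 1L), 2:pw]
  V <- sum(vert); E <- sum(eh) + sum(ev); F <- sum(mask)
  c(V = as.integer(V), E = as.integer(E), F = as.integer(F),
    chi = as.integer(V - E + F))
}

#' Euler characteristic of a binary image
#'
#' Convenience wrapper returning \code{V - E + F} from [cell_counts()].
#'
#' @inheritParams betti_numbers
#' @return integer scalar.
#' @export
euler_characteristic <- function(mask) {
  unname(cell_counts(mask)[["chi"]])
}

#' Label connected components of a binary mask
#'
#' Exposes the labeling primitive underlying [betti_numbers()], mainly for
#' debugging overlays and tests.
#'
#' @inheritParams betti_numbers
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  .cc_label(as_mask(mask), as.integer(connectivity))
}
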