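# Synthetic H&E-like tiles.
#
# The generator emulates, at the morphological level the screen actually
# measures, the low-power appearance of colonic tissue: white glass
# background, eosin-pink stroma, hematoxylin-dark nuclei. Phenotypes differ
# in how nuclei contact each other: normal mucosa keeps well-spaced nuclei
# ringed around gland lumina (low contact, b1 ~ 0 per segment), while
# adenocarcinoma packs overlapping nuclei into fenestrated sheets whose
# interstitial gaps are the windows b1 counts (high contact).

# Run code with an explicit seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

solid_canvas <- function(h, w, color) {
  array(rep(as.numeric(color), each = h * w), c(h, w, 3L))
}

# Shape primitives are collected first and rasterized in a single pass:
# painting thousands of nuclei one by one onto the full canvas would copy
# the canvas at every call.
prim_ellipse <- function(cx, cy, rx, ry, color) {
  list(ring = FALSE, cx = cx, cy = cy, rx = rx, ry = ry, rin = 0,
       color = color)
}

prim_ring <- function(cx, cy, r_out, r_in, color) {
  list(ring = TRUE, cx = cx, cy = cy, rx = r_out, ry = r_out, rin = r_in,
       color = color)
}

# Paint primitives onto an RGB array in order; coordinates are continuous,
# 1-based pixel centers. The three channel matrices stay local, so the
# per-primitive sub-assignments happen in place.
rasterize <- function(base, prims) {
  h <- dim(base)[1]; w <- dim(base)[2]
  Rm <- base[, , 1]; Gm <- base[, , 2]; Bm <- base[, , 3]
  for (p in prims) {
    if (p$cx + p$rx < 1 || p$cx - p$rx > w ||
        p$cy + p$ry < 1 || p$cy - p$ry > h) next
    xs <- max(1L, floor(p$cx - p$rx)):min(w, ceiling(p$cx + p$rx))
    ys <- max(1L, floor(p$cy - p$ry)):min(h, ceiling(p$cy + p$ry))
    if (p$ring) {
      d2 <- outer((ys - p$cy)^2, (xs - p$cx)^2, "+")
      inside <- d2 <= p$rx^2 & d2 > p$rin^2
    } else {
      inside <- outer(((ys - p$cy) / p$ry)^2, ((xs - p$cx) / p$rx)^2,
                      "+") <= 1
    }
    sub <- Rm[ys, xs]; sub[inside] <- p$color[1]; Rm[ys, xs] <- sub
    sub <- Gm[ys, xs]; sub[inside] <- p$color[2]; Gm[ys, xs] <- sub
    sub <- Bm[ys, xs]; sub[inside] <- p$color[3]; Bm[ys, xs] <- sub
  }
  base[, , 1] <- Rm; base[, , 2] <- Gm; base[, , 3] <- Bm
  base
}

jitter_color <- function(color, amount = 12) {
  pmin(255, pmax(0, color + round(runif(3, -amount, amount))))
}

# Hexagonal lattice points inside a disk region, spacing s, jittered.
hex_points <- function(cx, cy, radius, spacing, jitter_sd) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(cy - radius, cy + radius, by = dy)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    x <- seq(cx - radius + off, cx + radius, by = spacing)
    cbind(x, rows[i])
  }))
  keep <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= radius^2
  pts <- pts[keep, , drop = FALSE]
  pts + matrix(rnorm(length(pts), 0, jitter_sd), nrow(pts), 2L)
}

#' Specification of a synthetic tissue tile
#'
#' Collects the phenotype and morphology parameters of one generated tile.
#' Sizes are in pixels at roughly 1 micron per pixel (a low-power overview
#' magnification), so the defaults -- nuclei of radius 2.5-3.5 px, gland
#' lumina of radius 7-12 px, a 560 px tile holding a 14 x 14 grid of
#' 40 x 40 px segments -- are on the scale of real colonic mucosa.
#'
#' @param phenotype one of \code{"normal_mucosa"}, \code{"adenocarcinoma"},
#'   \code{"inflammation"}, \code{"blank_margin"}, \code{"folded_artifact"}.
#' @param width,height tile size in pixels (>= 64).
#' @param seed integer seed; all randomness in [generate_tile()] flows from
#'   it and the caller's RNG state is left untouched.
#' @param n_glands gland count for gland-bearing phenotypes (default 70).
#' @param nucleus_density fraction of the tile covered by the cellular
#'   region in sheet-growing phenotypes (default 0.85 for adenocarcinoma).
#' @param nucleus_radius_range nuclear radius range in px (default 2.5-3.5).
#' @param contact_prob in \code{[0, 1]}: how tightly nuclei pack. It sets
#'   the cell-to-cell lattice spacing as a multiple of the nuclear
#'   diameter, \code{2 - 1.15 * contact_prob}, so 0.9 (the adenocarcinoma
#'   default) gives overlapping, mutually touching nuclei and 0.15 (the
#'   normal default) gives clearly separated ones.
#' @param stain_colors list with RGB triples \code{nucleus},
#'   \code{cytoplasm}, \code{background}.
#' @param noise_sd per-pixel Gaussian channel noise, default 3.
#' @return object of class \code{synthetic_tissue_spec}.
#' @export
synthetic_tissue_spec <- function(phenotype, width = 560L, height = 560L,
                                  seed = 1L, n_glands = NULL,
                                  nucleus_density = NULL,
                                  nucleus_radius_range = c(2.5, 3.5),
                                  contact_prob = NULL,
                                  stain_colors = list(
                                    nucleus = c(64, 32, 128),
                                    cytoplasm = c(230, 170, 190),
                                    background = c(250, 250, 250)),
                                  noise_sd = 3) {
  phenotypes <- c("normal_mucosa", "adenocarcinoma", "inflammation",
                  "blank_margin", "folded_artifact")
  if (!is.character(phenotype) || !(phenotype %in% phenotypes))
    stop("invalid phenotype; must be one of: ",
         paste(phenotypes, collapse = ", "), call. = FALSE)
  if (width < 64L || height < 64L)
    stop("tile must be at least 64 x 64 pixels", call. = FALSE)
  if (is.null(contact_prob))
    contact_prob <- switch(phenotype, adenocarcinoma = 0.9,
                           inflammation = 0.65, 0.15)
  if (is.null(n_glands)) n_glands <- 70L
  if (is.null(nucleus_density))
    nucleus_density <- switch(phenotype, adenocarcinoma = 0.85,
                              inflammation = 0.25, 0)
  stopifnot(contact_prob >= 0, contact_prob <= 1)
  structure(list(phenotype = phenotype, width = as.integer(width),
                 height = as.integer(height), seed = as.integer(seed),
                 n_glands = n_glands, nucleus_density = nucleus_density,
                 nucleus_radius_range = nucleus_radius_range,
                 contact_prob = contact_prob, stain_colors = stain_colors,
                 noise_sd = noise_sd),
            class = "synthetic_tissue_spec")
}

lattice_spacing <- function(spec) {
  2 * mean(spec$nucleus_radius_range) * (2 - 1.15 * spec$contact_prob)
}

# One colonic gland: a near-white lumen ringed by well-spaced dark nuclei.
# Returns its primitives and the number of nuclei.
gland_prims <- function(cx, cy, spec, spacing_factor = 1.6) {
  rr <- spec$nucleus_radius_range
  lumen_r <- runif(1, 7, 12)
  ring_r <- lumen_r + mean(rr)
  prims <- list(prim_ellipse(cx, cy, lumen_r, lumen_r, c(246, 246, 246)))
  n <- max(3L, floor(2 * pi * ring_r / (2 * mean(rr) * spacing_factor)))
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-1] + runif(1, 0, 2 * pi)
  for (a in ang) {
    r <- runif(1, rr[1], rr[2])
    prims[[length(prims) + 1L]] <-
      prim_ellipse(cx + ring_r * cos(a), cy + ring_r * sin(a),
                   r, r * runif(1, 1.1, 1.5),
                   jitter_color(spec$stain_colors$nucleus))
  }
  list(prims = prims, n = n)
}

# Jittered-grid gland centers guaranteeing non-overlap.
gland_centers <- function(w, h, n, min_cell = 52) {
  nx <- max(1L, floor(w / min_cell)); ny <- max(1L, floor(h / min_cell))
  if (n > nx * ny) n <- nx * ny
  cx <- (seq_len(nx) - 0.5) * w / nx
  cy <- (seq_len(ny) - 0.5) * h / ny
  g <- expand.grid(x = cx, y = cy)
  g <- g[sample.int(nrow(g), n), , drop = FALSE]
  g$x <- g$x + runif(n, -6, 6)
  g$y <- g$y + runif(n, -6, 6)
  g
}

normal_prims <- function(spec, w = spec$width, h = spec$height) {
  ctr <- gland_centers(w, h, spec$n_glands)
  prims <- list()
  n_nuclei <- 0L
  for (i in seq_len(nrow(ctr))) {
    g <- gland_prims(ctr$x[i], ctr$y[i], spec)
    prims <- c(prims, g$prims)
    n_nuclei <- n_nuclei + g$n
  }
  list(prims = prims, n = n_nuclei)
}

render_normal <- function(spec) {
  canvas <- solid_canvas(spec$height, spec$width, spec$stain_colors$cytoplasm)
  np <- normal_prims(spec)
  list(img = rasterize(canvas, np$prims), n_nuclei = np$n)
}

# Crowded nuclei on a jittered hexagonal lattice inside a disk region: the
# fenestrated-sheet morphology of adenocarcinoma (or, with small cells, a
# lymphocyte aggregate).
sheet_prims <- function(cx, cy, region_r, spec) {
  rr <- spec$nucleus_radius_range
  s <- lattice_spacing(spec)
  pts <- hex_points(cx, cy, region_r, s, jitter_sd = s * 0.12)
  prims <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    r <- runif(1, rr[1], rr[2])
    prims[[i]] <- prim_ellipse(pts[i, 1], pts[i, 2], r, r * runif(1, 1, 1.3),
                               jitter_color(spec$stain_colors$nucleus))
  }
  list(prims = prims, n = nrow(pts))
}

render_adenocarcinoma <- function(spec) {
  w <- spec$width; h <- spec$height
  canvas <- solid_canvas(h, w, spec$stain_colors$cytoplasm)
  region_r <- sqrt(spec$nucleus_density * w * h / pi)
  cx <- w / 2 + runif(1, -w / 12, w / 12)
  cy <- h / 2 + runif(1, -h / 12, h / 12)
  sh <- sheet_prims(cx, cy, region_r, spec)
  list(img = rasterize(canvas, sh$prims), n_nuclei = sh$n)
}

render_inflammation <- function(spec) {
  w <- spec$width; h <- spec$height
  canvas <- solid_canvas(h, w, spec$stain_colors$cytoplasm)
  lspec <- spec
  lspec$nucleus_radius_range <- c(2, 2.8)             # small round lymphocytes
  lspec$contact_prob <- 0.85     # cells in a follicle touch their neighbours
  n_agg <- sample(2:4, 1L)
  prims <- list()
  n_nuclei <- 0L
  for (k in seq_len(n_agg)) {
    sh <- sheet_prims(runif(1, 0.2 * w, 0.8 * w), runif(1, 0.2 * h, 0.8 * h),
                      runif(1, 13, 26), lspec)
    prims <- c(prims, sh$prims)
    n_nuclei <- n_nuclei + sh$n
  }
  # sparse scattered infiltrate between aggregates
  n_scatter <- round(0.02 * w * h / 16)
  for (k in seq_len(n_scatter)) {
    r <- runif(1, 2, 2.8)
    prims[[length(prims) + 1L]] <-
      prim_ellipse(runif(1, 1, w), runif(1, 1, h), r, r,
                   jitter_color(spec$stain_colors$nucleus))
  }
  list(img = rasterize(canvas, prims), n_nuclei = n_nuclei + n_scatter)
}

render_blank_margin <- function(spec) {
  w <- spec$width; h <- spec$height
  canvas <- solid_canvas(h, w, spec$stain_colors$background)
  # tissue strip along the left edge, normal-mucosa-like
  strip_w <- round(0.14 * w)
  for (ch in 1:3)
    canvas[, seq_len(strip_w), ch] <- spec$stain_colors$cytoplasm[ch]
  sspec <- spec
  sspec$n_glands <- max(2L, round(spec$n_glands * strip_w / w))
  np <- normal_prims(sspec, w = strip_w, h = h)
  prims <- np$prims
  # detached debris specks on the glass: tiny closed rings of stained
  # mucus/cell remnants -- almost no tissue, but one window each, the
  # classic numerical-artifact trigger under non-blank normalization
  n_debris <- 5L
  placed <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_debris)) {
    for (try in 1:50) {
      px <- runif(1, strip_w + 40, w - 12)
      py <- runif(1, 12, h - 12)
      if (nrow(placed) == 0 ||
          min((placed[, 1] - px)^2 + (placed[, 2] - py)^2) > 80^2) break
    }
    placed <- rbind(placed, c(px, py))
    prims[[length(prims) + 1L]] <-
      prim_ring(px, py, 4.5, 2.5, jitter_color(spec$stain_colors$nucleus))
  }
  list(img = rasterize(canvas, prims), n_nuclei = np$n)
}

render_folded <- function(spec) {
  w <- spec$width; h <- spec$height
  canvas <- solid_canvas(h, w, spec$stain_colors$cytoplasm)
  np <- normal_prims(spec)
  # fold: an elliptical region where the section doubled over. Both
  # layers' nuclei project into one plane, so the region reads as a
  # crowded, mutually touching nuclear jumble on stroma that is mildly
  # darkened by the doubled optical density.
  cx <- runif(1, 0.3 * w, 0.7 * w); cy <- runif(1, 0.3 * h, 0.7 * h)
  rx <- runif(1, 0.18, 0.28) * w; ry <- runif(1, 0.18, 0.28) * h
  fspec <- spec
  fspec$contact_prob <- 0.85
  sh <- sheet_prims(cx, cy, min(rx, ry), fspec)
  canvas <- rasterize(canvas, c(np$prims, sh$prims))
  xs <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
  ys <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
  inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  for (ch in 1:3) {
    sub <- canvas[ys, xs, ch, drop = FALSE]
    sub[inside] <- sub[inside] * 0.8
    canvas[ys, xs, ch] <- sub
  }
  list(img = canvas, n_nuclei = np$n + sh$n)
}

#' Generate a synthetic H&E tile with ground-truth labels
#'
#' Deterministic given the spec's seed. Phenotypes: \code{normal_mucosa}
#' (well-spaced nuclear rings around gland lumina on pink stroma),
#' \code{adenocarcinoma} (a sheet of crowded, mutually touching nuclei
#' whose interstices form windows), \code{inflammation} (dense aggregates
#' of small round cells plus scattered infiltrate -- an intended
#' false-positive phenotype), \code{blank_margin} (mostly bare glass with a
#' thin tissue strip and detached debris specks), and
#' \code{folded_artifact} (normal tissue with a darkened fold where the
#' section doubled over).
#'
#' Labels: \code{adenocarcinoma} is \code{"cancer"}, everything else
#' \code{"benign"}; every phenotype except \code{blank_margin} counts as
#' ROI (it contains tissue a pathologist would want to inspect).
#'
#' @param spec a [synthetic_tissue_spec()], or a phenotype string.
#' @param seed overrides the spec's seed when given.
#' @param ... when \code{spec} is a phenotype string, further arguments to
#'   [synthetic_tissue_spec()].
#' @return list with \code{image} (integer RGB array), \code{label}
#'   (\code{"cancer"}/\code{"benign"}), \code{roi} (logical),
#'   \code{phenotype}, \code{n_nuclei} and \code{spec}.
#' @examples
#' tile <- generate_tile("normal_mucosa", seed = 7)
#' dim(tile$image)
#' @export
generate_tile <- function(spec, seed = NULL, ...) {
  if (is.character(spec)) spec <- synthetic_tissue_spec(spec, ...)
  if (!inherits(spec, "synthetic_tissue_spec"))
    stop("spec must be a synthetic_tissue_spec or a phenotype name",
         call. = FALSE)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  with_seed(spec$seed, {
    res <- switch(spec$phenotype,
      normal_mucosa = render_normal(spec),
      adenocarcinoma = render_adenocarcinoma(spec),
      inflammation = render_inflammation(spec),
      blank_margin = render_blank_margin(spec),
      folded_artifact = render_folded(spec))
    img <- res$img
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim(img))
    list(image = img,
         label = if (spec$phenotype == "adenocarcinoma") "cancer" else "benign",
         roi = spec$phenotype != "blank_margin",
         phenotype = spec$phenotype,
         n_nuclei = res$n_nuclei,
         spec = spec)
  })
}

#' Generate a labeled cohort of synthetic tiles
#'
#' One tile per phenotype per replicate, with seeds derived as
#' \code{seed * 1000 + replicate} so cohorts with different base seeds do
#' not share tiles.
#'
#' @param n_per_phenotype replicates per phenotype.
#' @param phenotypes character vector of phenotypes to include.
#' @param seed base seed.
#' @param dir optional directory; when given, tiles are written as PNG and
#'   a \code{labels.csv} (image_id, condition, roi) is written alongside.
#' @param ... further arguments to [synthetic_tissue_spec()].
#' @return invisibly, a data.frame with \code{image_id}, \code{phenotype},
#'   \code{condition}, \code{roi}, \code{seed} and (in memory) a
#'   \code{tiles} attribute: the list of generated tiles.
#' @export
generate_cohort <- function(n_per_phenotype = 20L,
                            phenotypes = c("normal_mucosa", "adenocarcinoma",
                                           "inflammation", "blank_margin",
                                           "folded_artifact"),
                            seed = 1L, dir = NULL, ...) {
  rows <- list(); tiles <- list()
  for (ph in phenotypes) {
    for (i in seq_len(n_per_phenotype)) {
      s <- as.integer(seed) * 1000L + i
      tile <- generate_tile(ph, seed = s, ...)
      id <- sprintf("%s_%03d", ph, i)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, phenotype = ph, condition = tile$label,
        roi = tile$roi, seed = s)
      tiles[[id]] <- tile
      if (!is.null(dir))
        write_image_png(tile$image, file.path(dir, paste0(id, ".png")))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(out[, c("image_id", "condition", "roi")],
              file.path(dir, "labels.csv"), row.names = FALSE)
  attr(out, "tiles") <- tiles
  invisible(out)
}
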