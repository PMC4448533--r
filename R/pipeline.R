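#' Batch-score a set of tile images
#'
#' Runs [screen_tile()] over every input sequentially and writes, per
#' image, a segment CSV (\code{<id>_segments.csv}) and a verdict JSON
#' (\code{<id>_verdict.json}) embedding the full effective configuration;
#' optionally an overlay PNG. Results are deterministic and per-image
#' independent, so the order of inputs never changes any output.
#'
#' @param inputs character vector of image paths.
#' @param out_dir output directory (created if needed).
#' @param overlay also write \code{<id>_overlay.png}; default \code{FALSE}.
#' @param quiet suppress the one-line-per-image log; default \code{FALSE}.
#' @inheritParams screen_tile
#' @return invisibly, a data.frame with one row per image:
#'   \code{image_id}, \code{positive}, \code{n_flagged},
#'   \code{n_insufficient}, \code{ok}.
#' @export
run_score <- function(inputs, out_dir = ".", grid_rows = 14L, grid_cols = 14L,
                      threshold = 30, blank_level = 220, min_tissue = 0.05,
                      normalize = TRUE, overlay = FALSE, quiet = FALSE) {
  if (length(inputs) == 0L) stop("no input images given", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (path in inputs) {
    id <- tools::file_path_sans_ext(basename(path))
    scr <- tryCatch(
      screen_tile(path, grid_rows = grid_rows, grid_cols = grid_cols,
                  threshold = threshold, blank_level = blank_level,
                  min_tissue = min_tissue, normalize = normalize,
                  keep_image = overlay, image_id = id),
      error = function(e) e)
    if (inherits(scr, "error")) {
      message("skipping ", path, ": ", conditionMessage(scr))
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, positive = NA, n_flagged = NA_integer_,
        n_insufficient = NA_integer_, ok = FALSE)
      next
    }
    seg <- scr$segments
    write.csv(cbind(image_id = id,
                    seg[, c("row", "col", "x0", "y0", "x1", "y1", "b0", "b1",
                            "nonblank_ratio", "b1_normalized", "status")]),
              file.path(out_dir, paste0(id, "_segments.csv")),
              row.names = FALSE)
    v <- scr$verdict
    jsonlite::write_json(
      list(image_id = id, positive = v$positive, n_flagged = v$n_flagged,
           n_insufficient = v$n_insufficient, params = scr$config),
      file.path(out_dir, paste0(id, "_verdict.json")), auto_unbox = TRUE)
    if (overlay)
      write_image_png(render_overlay(scr[["image"]], seg,
                                     color_scale(max_score = threshold)),
                      file.path(out_dir, paste0(id, "_overlay.png")))
    if (!quiet)
      message(sprintf("%s: %s (%d flagged, %d insufficient of %d segments)",
                      id, if (v$positive) "POSITIVE" else "negative",
                      v$n_flagged, v$n_insufficient, nrow(seg)))
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, positive = v$positive, n_flagged = v$n_flagged,
      n_insufficient = v$n_insufficient, ok = TRUE)
  }
  out <- do.call(rbind, rows)
  if (!any(out$ok)) stop("all inputs failed to process", call. = FALSE)
  invisible(out)
}

#' Evaluate verdicts against a label file
#'
#' Reads the verdict JSONs produced by [run_score()] and a label CSV
#' (\code{image_id,condition}; condition \code{cancer}/\code{roi} vs
#' \code{benign}), builds the contingency table, and writes a metrics JSON.
#'
#' @param verdict_dir directory containing \code{*_verdict.json} files, or
#'   a character vector of JSON paths.
#' @param labels_csv path to the label CSV.
#' @param out path for the metrics JSON, or \code{NULL} to skip writing.
#' @return list with \code{table} (the [contingency()]) and \code{metrics}
#'   (raw and rounded), invisibly.
#' @export
run_evaluate <- function(verdict_dir, labels_csv, out = NULL) {
  paths <- if (length(verdict_dir) == 1L && dir.exists(verdict_dir))
    list.files(verdict_dir, pattern = "_verdict\\.json$", full.names = TRUE)
  else verdict_dir
  if (length(paths) == 0L) stop("no verdict files found", call. = FALSE)
  vs <- lapply(paths, jsonlite::read_json)
  verdicts <- data.frame(
    image_id = vapply(vs, function(v) v$image_id, ""),
    positive = vapply(vs, function(v) isTRUE(v$positive), NA))
  labels <- read.csv(labels_csv, stringsAsFactors = FALSE)
  tab <- build_contingency(verdicts, labels)
  mt <- screen_metrics(tab)
  if (!is.null(out))
    jsonlite::write_json(
      list(table = as.list(unclass(tab)),
           metrics = as.list(mt$rounded), metrics_raw = as.list(mt$raw)),
      out, auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, metrics = mt))
}

#' Generate a synthetic cohort on disk
#'
#' Thin wrapper over [generate_cohort()] for the command line: writes PNG
#' tiles and \code{labels.csv} into \code{out_dir}.
#'
#' @param phenotype phenotypes to generate (default: all five).
#' @param n tiles per phenotype.
#' @param seed base seed.
#' @param out_dir output directory.
#' @param ... further arguments to [synthetic_tissue_spec()].
#' @return invisibly, the cohort manifest data.frame.
#' @export
run_synth <- function(phenotype = c("normal_mucosa", "adenocarcinoma",
                                    "inflammation", "blank_margin",
                                    "folded_artifact"),
                      n = 5L, seed = 1L, out_dir = ".", ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  generate_cohort(n_per_phenotype = n, phenotypes = phenotype, seed = seed,
                  dir = out_dir, ...)
}
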