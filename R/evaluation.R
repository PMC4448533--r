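#' Image-level contingency table
#'
#' Cross-tabulates screening verdicts against reference (pathologist)
#' labels at the image level.
#'
#' @param verdicts data.frame with columns \code{image_id} and
#'   \code{positive} (logical screen verdict).
#' @param labels data.frame with columns \code{image_id} and
#'   \code{condition} (logical, or one of \code{"cancer"}/\code{"roi"} vs
#'   \code{"benign"}).
#' @return object of class \code{contingency}: named integer vector
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @examples
#' v <- data.frame(image_id = c("a", "b"), positive = c(TRUE, FALSE))
#' l <- data.frame(image_id = c("a", "b"), condition = c("cancer", "benign"))
#' build_contingency(v, l)
#' @export
build_contingency <- function(verdicts, labels) {
  if (!is.data.frame(verdicts) || nrow(verdicts) == 0L ||
      !is.data.frame(labels) || nrow(labels) == 0L)
    stop("verdicts and labels must be non-empty data frames", call. = FALSE)
  dup <- unique(labels$image_id[duplicated(labels$image_id)])
  if (length(dup))
    stop("duplicate labels for image(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(verdicts$image_id, labels$image_id)
  if (length(miss))
    stop("missing labels for image(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cond <- labels$condition
  if (!is.logical(cond)) cond <- tolower(as.character(cond)) %in% c("cancer", "roi", "true", "1")
  cond <- cond[match(verdicts$image_id, labels$image_id)]
  pos <- as.logical(verdicts$positive)
  contingency(tp = sum(pos & cond), fp = sum(pos & !cond),
              fn = sum(!pos & cond), tn = sum(!pos & !cond))
}

#' Construct a contingency table from its four cells
#'
#' @param tp,fp,fn,tn non-negative counts: condition-positive/negative
#'   crossed with screen-positive/negative.
#' @return object of class \code{contingency}.
#' @export
contingency <- function(tp, fp, fn, tn) {
  x <- c(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn))
  if (any(x < 0)) stop("contingency counts must be non-negative", call. = FALSE)
  structure(x, class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x[["tp"]], x[["fn"]], x[["fp"]], x[["tn"]]), 2, 2,
              dimnames = list(c("Positive", "Negative"),
                              c("Condition+", "Condition-")))
  print(m)
  mt <- screen_metrics(x)
  cat(sprintf("Sensitivity %.1f  Specificity %.1f  False positive %.1f  False negative %.1f\n",
              mt$rounded[["sensitivity"]], mt$rounded[["specificity"]],
              mt$rounded[["false_positive_rate"]],
              mt$rounded[["false_negative_rate"]]))
  invisible(x)
}

# Half-up decimal rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 1L) floor(x * 10^digits + 0.5) / 10^digits

#' Screening metrics from a contingency table
#'
#' Sensitivity \code{100 tp/(tp+fn)}, specificity \code{100 tn/(fp+tn)},
#' false-positive rate \code{100 fp/(fp+tn)} and false-negative rate
#' \code{100 fn/(tp+fn)}, as percentages. By construction
#' \code{sensitivity + false_negative_rate == 100} and
#' \code{specificity + false_positive_rate == 100} exactly.
#'
#' @param t a [contingency()] table (or anything coercible to the four
#'   named counts).
#' @return list with \code{raw} (unrounded percentages) and \code{rounded}
#'   (half-up to one decimal, the conventional reporting precision).
#' @examples
#' screen_metrics(contingency(1284, 422, 1, 118))$rounded
#' @export
screen_metrics <- function(t) {
  tp <- t[["tp"]]; fp <- t[["fp"]]; fn <- t[["fn"]]; tn <- t[["tn"]]
  if (tp + fn < 1L) stop("undefined metric: no condition-positive images (tp+fn = 0)",
                         call. = FALSE)
  if (fp + tn < 1L) stop("undefined metric: no condition-negative images (fp+tn = 0)",
                         call. = FALSE)
  raw <- c(sensitivity = 100 * tp / (tp + fn),
           specificity = 100 * tn / (fp + tn),
           false_positive_rate = 100 * fp / (fp + tn),
           false_negative_rate = 100 * fn / (tp + fn))
  list(raw = raw, rounded = round_half_up(raw, 1L))
}

#' False-positive annotation vocabulary
#'
#' The closed vocabulary used when pathologists itemize the benign images
#' that screened positive, split into ROI categories (tissue that genuinely
#' carries diagnostic information, so detecting it is desirable) and
#' non-ROI categories (gland geometry and artifacts that should not have
#' been flagged). Assignment to a category is manual annotation input,
#' never computed.
#'
#' @return data.frame with columns \code{category} and \code{roi_class}
#'   (\code{"ROI"} or \code{"non-ROI"}).
#' @export
fp_categories <- function() {
  data.frame(
    category = c("mild atypia", "mucosal inflammation", "hyperplastic polyps",
                 "inflammatory cells", "regenerative change", "necrosis",
                 "lymphoid follicles", "lymphocyte aggregation",
                 "cross sections of inclined glands", "numerical artifact",
                 "specimen artifact"),
    roi_class = c(rep("ROI", 8L), rep("non-ROI", 3L)))
}

#' Record a manually annotated false positive
#'
#' @param image_id image identifier.
#' @param category one of the labels in [fp_categories()].
#' @return data.frame row with \code{image_id}, \code{category} and the
#'   \code{roi_class} the category implies.
#' @export
fp_record <- function(image_id, category) {
  voc <- fp_categories()
  i <- match(category, voc$category)
  if (is.na(i))
    stop("unknown false-positive category: ", category, call. = FALSE)
  data.frame(image_id = image_id, category = category,
             roi_class = voc$roi_class[i])
}

#' Reference screening results on the 1825-image colonic cohort
#'
#' The image-level results of the homology screen on a cohort of 1825
#' colonic H&E images read against pathologist diagnosis, used here as
#' reference values: the contingency table with cancer as the condition,
#' the table with ROI (any diagnostically informative tissue) as the
#' condition, and the itemized manual annotation of the 422 benign images
#' that screened positive. The itemization ties the two tables together:
#' its ROI-class counts move from the false-positive to the true-positive
#' cell when the condition widens from cancer to ROI.
#'
#' @return list with elements \code{cancer} and \code{roi} (both
#'   [contingency()] tables) and \code{false_positives} (data.frame of
#'   \code{category}, \code{roi_class}, \code{count}).
#' @export
colon_screening_results <- function() {
  fp <- fp_categories()
  fp$count <- c(156L, 99L, 34L, 16L, 12L, 6L, 4L, 4L,   # ROI categories
                73L, 16L, 2L)                           # non-ROI categories
  list(cancer = contingency(tp = 1284L, fp = 422L, fn = 1L, tn = 118L),
       roi = contingency(tp = 1615L, fp = 91L, fn = 1L, tn = 118L),
       false_positives = fp)
}
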