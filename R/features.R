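# Image-level glandular aberrance features: the BAM histogram, its entropy,
# the Regularity Index, and the normal-image feature postprocessing.

#' Histogram of BAM values
#'
#' Fixed-step histogram with half-open bins `[e_k, e_{k+1})`; the last bin is
#' right-closed and absorbs any value at or beyond the last edge. The default
#' edges (`start = 0`, `step = 0.015`, `n_bins = 7`) cover `[0, 0.105)`,
#' matching the observed range of gland aberrance values (about 0 to 0.1).
#'
#' @param values nonnegative aberrance values.
#' @param step bin width (default 0.015).
#' @param start first edge (default 0).
#' @param n_bins number of bins (default 7, minimum 2).
#' @return list of class `bam_histogram` with `edges` (length `n_bins + 1`)
#'   and integer `counts` (length `n_bins`).
#' @export
bam_histogram <- function(values, step = 0.015, start = 0, n_bins = 7L) {
  if (step <= 0) gb_stop("glandbam_invalid_parameter", "step must be positive")
  if (n_bins < 2) gb_stop("glandbam_invalid_parameter", "need at least 2 bins")
  values <- values[!is.na(values)]
  if (any(values < 0))
    gb_stop("glandbam_invalid_input", "negative BAM values are impossible")
  edges <- start + (0:n_bins) * step
  idx <- pmin(pmax(floor((values - start) / step), 0) + 1L, n_bins)
  structure(list(edges = edges,
                 counts = tabulate(idx, nbins = n_bins)),
            class = "bam_histogram")
}

#' Shannon entropy of a BAM histogram
#'
#' `-sum p_b log(p_b)` over non-empty bins, natural logarithm, with
#' `p_b = count_b / total`. Zero when all mass falls in one bin; at most
#' `log(n_bins)`.
#'
#' @param hist a [bam_histogram()].
#' @return nonnegative entropy (nats).
#' @export
bam_entropy <- function(hist) {
  total <- sum(hist$counts)
  if (total < 1)
    gb_stop("glandbam_undefined_feature", "entropy of an empty histogram is undefined")
  p <- hist$counts[hist$counts > 0] / total
  -sum(p * log(p))
}

#' Regularity Index
#'
#' The fraction of glands whose BAM values fall in the first two histogram
#' bins — near-elliptical glands under the default edges. High values are
#' characteristic of normal tissue.
#'
#' @param hist a [bam_histogram()].
#' @return value in `[0, 1]`.
#' @export
regularity_index <- function(hist) {
  total <- sum(hist$counts)
  if (total < 1)
    gb_stop("glandbam_undefined_feature", "Regularity Index of an empty histogram is undefined")
  sum(hist$counts[1:2]) / total
}

included_aberrances <- function(records) {
  vals <- vapply(records, `[[`, 1, "aberrance")
  excl <- vapply(records, `[[`, TRUE, "excluded")
  vals[!excl & !is.na(vals)]
}

#' Image-level aberrance features
#'
#' Computes the per-image feature vector from gland records: mean BAM value,
#' BAM entropy and Regularity Index over all included glands with a defined
#' aberrance, plus (optionally) per-image means of the five baseline shape
#' features.
#'
#' @param records a `gland_records` object with aberrance values.
#' @param step,start,n_bins histogram parameters, see [bam_histogram()].
#' @param include_baseline average the per-gland baseline features
#'   (requires records computed with `baseline = TRUE`).
#' @param label grade label to attach (`normal`, `low_grade`, `high_grade`
#'   or `unknown`).
#' @return one-row data frame: `image_id`, `n_glands`, `mean_bam`,
#'   `bam_entropy`, `regularity_index`, baseline columns if requested,
#'   `label`, `postprocessed`.
#' @export
compute_image_features <- function(records, step = 0.015, start = 0,
                                   n_bins = 7L, include_baseline = FALSE,
                                   label = "unknown") {
  vals <- included_aberrances(records)
  if (!length(vals))
    gb_stop("glandbam_undefined_feature", "no usable glands in image %s",
            if (length(records)) records[[1L]]$image_id else "<empty>")
  hist <- bam_histogram(vals, step = step, start = start, n_bins = n_bins)
  out <- data.frame(
    image_id = records[[1L]]$image_id,
    n_glands = length(vals),
    mean_bam = mean(vals),
    bam_entropy = bam_entropy(hist),
    regularity_index = regularity_index(hist),
    stringsAsFactors = FALSE
  )
  if (include_baseline) {
    excl <- vapply(records, `[[`, TRUE, "excluded")
    bl <- lapply(records[!excl], `[[`, "baseline")
    bl <- bl[!vapply(bl, is.null, TRUE)]
    if (length(bl)) {
      for (f in c("roundness", "aspect_ratio", "elongation", "solidity", "convexity"))
        out[[f]] <- mean(vapply(bl, `[[`, 1, f))
    }
  }
  out$label <- label
  out$postprocessed <- FALSE
  out
}

#' Feature postprocessing configuration
#'
#' @param ri_threshold images with Regularity Index above this are treated as
#'   normal and postprocessed (default 0.5).
#' @param area_threshold glands smaller than this many pixels in a
#'   normal-classified image are excluded as tangential crypt sections
#'   (default 3000).
#' @param apply_border_removal also exclude border-touching glands of
#'   normal-classified images (default TRUE).
#' @return list of class `postprocess_config`.
#' @export
postprocess_config <- function(ri_threshold = 0.5, area_threshold = 3000,
                               apply_border_removal = TRUE) {
  stopifnot(ri_threshold >= 0, ri_threshold <= 1, area_threshold >= 0)
  structure(list(ri_threshold = ri_threshold, area_threshold = area_threshold,
                 apply_border_removal = isTRUE(apply_border_removal)),
            class = "postprocess_config")
}

#' Postprocess features of a normal-classified image
#'
#' Tangential crypt sections (small area) and glands clipped by the image
#' border carry spuriously high BAM values that inflate a normal image's
#' features. If the image's pre-postprocessing Regularity Index exceeds
#' `cfg$ri_threshold` (i.e. the image is classified as normal), glands with
#' `area < cfg$area_threshold` are excluded with reason `tangential_area`,
#' border-touching glands with reason `border`, and the features are
#' recomputed from the survivors. Otherwise records and features are returned
#' unchanged.
#'
#' @param records a `gland_records` object.
#' @param features the matching [compute_image_features()] row.
#' @param cfg a [postprocess_config()].
#' @param step,start,n_bins histogram parameters used for recomputation.
#' @return list with updated `records` and `features`.
#' @export
postprocess_features <- function(records, features, cfg = postprocess_config(),
                                 step = 0.015, start = 0, n_bins = 7L) {
  if (features$regularity_index <= cfg$ri_threshold)
    return(list(records = records, features = features))
  for (i in seq_along(records)) {
    if (records[[i]]$excluded) next
    if (records[[i]]$area < cfg$area_threshold) {
      records[[i]]$excluded <- TRUE
      records[[i]]$exclusion_reason <- "tangential_area"
    } else if (cfg$apply_border_removal && records[[i]]$touches_border) {
      records[[i]]$excluded <- TRUE
      records[[i]]$exclusion_reason <- "border"
    }
  }
  include_baseline <- !is.null(features$roundness)
  new_features <- compute_image_features(records, step = step, start = start,
                                         n_bins = n_bins,
                                         include_baseline = include_baseline,
                                         label = features$label)
  new_features$postprocessed <- TRUE
  list(records = records, features = new_features)
}
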