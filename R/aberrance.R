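#' Aberrance pipeline configuration
#'
#' Collects the tunables of the per-gland aberrance computation and of
#' probability-map postprocessing.
#'
#' @param N sampling points per curve for the BAM computation (power of two
#'   recommended for the FFT; default 128, minimum 8).
#' @param mvee_tol containment tolerance of the minimum-area enclosing
#'   ellipse (default 1e-4; the aberrance value is insensitive to ellipse
#'   slack far below the 1e-3 scale of interest, and tighter tolerances
#'   converge very slowly on smooth rasterized hulls).
#' @param mvee_maxit iteration cap for the ellipse fit (default 20000).
#' @param mvee_max_points convex-hull vertices are uniformly decimated to at
#'   most this many before the ellipse fit (default 100; shifts the aberrance
#'   of dense smooth contours by under 2e-5 while cutting the fit cost
#'   roughly threefold).
#' @param prob_threshold threshold turning a probability map into a binary
#'   map (default 0.5).
#' @param min_object_area objects smaller than this many pixels are removed
#'   during mask postprocessing (default 300).
#' @param fill_holes fill interior holes during mask postprocessing
#'   (default TRUE).
#' @param open_radius disk radius (px) of the single binary opening used to
#'   separate slightly merged objects (default 3).
#' @param smooth_sigma contour-extraction smoothing, see
#'   [extract_gland_contours()] (default 2).
#' @param min_vertices minimum boundary vertices per gland (default 8).
#' @param border_margin border-touch margin in px (default 2).
#' @param baseline also compute the five baseline shape features per gland
#'   (default FALSE).
#' @return list of class `aberrance_config`.
#' @export
aberrance_config <- function(N = 128L, mvee_tol = 1e-4, mvee_maxit = 20000L,
                             prob_threshold = 0.5,
                             min_object_area = 300L, fill_holes = TRUE,
                             open_radius = 3L, smooth_sigma = 2,
                             min_vertices = 8L, border_margin = 2L,
                             mvee_max_points = 100L, baseline = FALSE) {
  if (N < 8) gb_stop("glandbam_invalid_parameter", "N must be >= 8")
  if (prob_threshold <= 0 || prob_threshold >= 1)
    gb_stop("glandbam_invalid_parameter", "prob_threshold must be in (0,1)")
  structure(list(N = as.integer(N), mvee_tol = mvee_tol,
                 mvee_maxit = as.integer(mvee_maxit),
                 prob_threshold = prob_threshold,
                 min_object_area = as.integer(min_object_area),
                 fill_holes = isTRUE(fill_holes),
                 open_radius = as.integer(open_radius),
                 smooth_sigma = smooth_sigma,
                 min_vertices = as.integer(min_vertices),
                 border_margin = as.integer(border_margin),
                 mvee_max_points = as.integer(mvee_max_points),
                 baseline = isTRUE(baseline)),
            class = "aberrance_config")
}

#' Glandular aberrance of a boundary curve
#'
#' The BAM value of a gland: (1) fit the minimum-area enclosing ellipse of
#' the contour and apply its whitening transform to both the contour and the
#' ellipse boundary (the ellipse becomes a circle, removing the anisotropy of
#' an oblique cut through the tubular gland); (2) normalize both curves to
#' `N` equally spaced points, unit perimeter, zero mean; (3) return the BAM
#' distance between the two normalized shapes. By construction the value is
#' invariant under rotation, translation and isotropic scaling of the input,
#' and (near-)zero for any ellipse.
#'
#' @param contour curve matrix (gland boundary).
#' @param config an [aberrance_config()].
#' @return nonnegative aberrance, or `NA` (with a warning) if the contour is
#'   degenerate or the ellipse fit fails.
#' @export
gland_aberrance <- function(contour, config = aberrance_config()) {
  tryCatch({
    hull <- contour[grDevices::chull(contour), , drop = FALSE]
    if (nrow(hull) > config$mvee_max_points)
      hull <- hull[unique(round(seq(1, nrow(hull),
                                    length.out = config$mvee_max_points))), ,
                   drop = FALSE]
    ell <- min_area_enclosing_ellipse(hull, tol = config$mvee_tol,
                                      maxit = config$mvee_maxit)
    tf <- ellipse_whitening(ell)
    uw <- apply_transform(contour, tf)
    vw <- apply_transform(ellipse_boundary(ell, n = max(512L, 4L * config$N)), tf)
    bam_distance(normalize_shape(uw, config$N), normalize_shape(vw, config$N))
  }, glandbam_error = function(e) {
    warning(sprintf("aberrance undefined: %s", conditionMessage(e)))
    NA_real_
  })
}

#' Per-gland aberrance table of a label mask
#'
#' Extracts every gland contour and computes its aberrance. Per-gland
#' failures are flagged (`aberrance = NA`), never fatal for the image.
#'
#' @param mask integer label mask.
#' @param image_id identifier for the records.
#' @param config an [aberrance_config()].
#' @return a `gland_records` object (see [extract_gland_contours()]); each
#'   record gains an `aberrance` value and, if `config$baseline` is set, a
#'   `baseline` list of the five reference shape features.
#' @export
image_aberrance_table <- function(mask, image_id = "image",
                                  config = aberrance_config()) {
  records <- extract_gland_contours(mask, image_id,
                                    min_vertices = config$min_vertices,
                                    border_margin = config$border_margin,
                                    smooth_sigma = config$smooth_sigma)
  for (i in seq_along(records)) {
    records[[i]]$aberrance <- gland_aberrance(records[[i]]$contour, config)
    if (config$baseline) {
      records[[i]]$baseline <- tryCatch(
        baseline_shape_features(records[[i]]$contour, records[[i]]$area),
        glandbam_error = function(e) NULL)
    }
  }
  records
}

#' Convert a gland probability map into a clean label mask
#'
#' Thresholds the map, optionally fills holes, removes small objects,
#' separates slightly merged objects by one binary opening with a small disk,
#' and labels the result by 8-connected components.
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @param config an [aberrance_config()] supplying `prob_threshold`,
#'   `min_object_area`, `fill_holes` and `open_radius`.
#' @return integer label matrix.
#' @export
postprocess_probability_map <- function(prob, config = aberrance_config()) {
  if (!is.matrix(prob) || !is.numeric(prob))
    gb_stop("glandbam_invalid_input", "probability map must be a numeric matrix")
  if (any(prob < 0 | prob > 1, na.rm = TRUE) || anyNA(prob))
    gb_stop("glandbam_invalid_input", "probability values must lie in [0, 1]")
  bin <- matrix(as.numeric(prob >= config$prob_threshold), nrow(prob), ncol(prob))
  if (!any(bin > 0)) return(matrix(0L, nrow(prob), ncol(prob)))
  if (config$fill_holes)
    bin <- EBImage::imageData(EBImage::fillHull(bin))
  if (config$open_radius > 0) {
    brush <- EBImage::makeBrush(2L * config$open_radius + 1L, shape = "disc")
    bin <- EBImage::imageData(EBImage::opening(bin, brush))
  }
  lab <- label_components(bin > 0)
  if (config$min_object_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= config$min_object_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    fg <- lab > 0
    lab[fg] <- relab[lab[fg]]
  }
  lab
}
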