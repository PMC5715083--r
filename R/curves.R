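#' @useDynLib glandbam, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm fft var sd predict runif setNames
#' @importFrom utils head tail modifyList read.csv write.csv
#' @keywords internal
"_PACKAGE"

# classed condition helper: every error the package raises carries a class a
# caller (or test) can match on, in addition to the message.
gb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "glandbam_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Validate a closed planar curve
#'
#' A curve is an `n x 2` numeric matrix of vertices (columns `x`, `y`,
#' x rightward, y downward, 0-based pixel units unless normalized) read as a
#' cyclic sequence: the closing segment from the last vertex back to the first
#' is implied. Valid curves have at least 3 finite vertices, no two
#' *consecutive* vertices identical (including last-to-first), and positive
#' perimeter.
#'
#' @param points numeric matrix with 2 columns.
#' @return the validated matrix, invisibly.
#' @export
validate_curve <- function(points) {
  if (!is.matrix(points) || !is.numeric(points) || ncol(points) != 2L)
    gb_stop("glandbam_invalid_input", "a curve must be a numeric n x 2 matrix")
  if (nrow(points) < 3L)
    gb_stop("glandbam_invalid_input", "a curve needs at least 3 vertices")
  if (!all(is.finite(points)))
    gb_stop("glandbam_invalid_input", "curve vertices must be finite")
  seg <- segment_lengths(points)
  if (any(seg == 0))
    gb_stop("glandbam_invalid_input", "curve has identical consecutive vertices")
  invisible(points)
}

segment_lengths <- function(points) {
  n <- nrow(points)
  j <- c(2:n, 1L)
  sqrt((points[j, 1L] - points[, 1L])^2 + (points[j, 2L] - points[, 2L])^2)
}

#' Perimeter of a closed polyline
#' @param points curve matrix (see [validate_curve()]).
#' @return total length including the closing segment.
#' @export
curve_perimeter <- function(points) sum(segment_lengths(points))

#' Signed polygon area (shoelace)
#'
#' Positive area defines the package's canonical counter-clockwise orientation
#' in the image frame (x = column, y = row increasing downward).
#'
#' @param points curve matrix.
#' @return signed area.
#' @export
shoelace_area <- function(points) {
  n <- nrow(points)
  j <- c(2:n, 1L)
  sum(points[, 1L] * points[j, 2L] - points[j, 1L] * points[, 2L]) / 2
}

#' Canonicalize traversal orientation
#'
#' Returns the same vertex set traversed so that the shoelace area is
#' positive. The BAM minimization covers cyclic shift and rotation but not
#' traversal reversal, so both curves entering a distance computation must be
#' canonically oriented.
#'
#' @param points curve matrix.
#' @return curve matrix, possibly with row order reversed.
#' @export
canonical_orientation <- function(points) {
  validate_curve(points)
  a <- shoelace_area(points)
  if (abs(a) <= 1e-12 * curve_perimeter(points)^2)
    gb_stop("glandbam_degenerate_curve", "curve has (near-)zero signed area")
  if (a < 0) points[rev(seq_len(nrow(points))), , drop = FALSE] else points
}

#' Resample a closed curve at equal arc-length spacing
#'
#' Places exactly `N` points on the closed polyline at arc-length positions
#' `k * L / N` (k = 0, ..., N-1) measured from the first input vertex, where
#' `L` is the input perimeter. Resampling an already equally-spaced curve at
#' its own point count reproduces it.
#'
#' @param points curve matrix.
#' @param N number of output points (>= 3).
#' @return `N x 2` matrix.
#' @export
resample_closed_curve <- function(points, N) {
  if (length(N) != 1L || !is.finite(N) || N < 3)
    gb_stop("glandbam_invalid_parameter", "N must be a single integer >= 3")
  N <- as.integer(N)
  validate_curve(points)
  n <- nrow(points)
  j <- c(2:n, 1L)
  seg <- segment_lengths(points)
  cs <- c(0, cumsum(seg))
  L <- cs[n + 1L]
  s <- (seq_len(N) - 1L) * L / N
  k <- findInterval(s, cs, rightmost.closed = TRUE)
  t <- (s - cs[k]) / seg[k]
  points[k, , drop = FALSE] + t * (points[j[k], , drop = FALSE] - points[k, , drop = FALSE])
}

#' Normalize a curve to its shape representative
#'
#' Produces the discrete representative used by the BAM distance: the curve is
#' canonically oriented, resampled to `N` equally spaced points, scaled so the
#' closed `N`-gon has unit perimeter, and translated so the point mean is the
#' origin. The discrete representation requires *equal consecutive chord
#' lengths*, which a single arc-length resampling pass only approximates on
#' curved inputs; the resampling is therefore iterated to its fixed point
#' (relative chord spread below 5e-4, usually 1-3 extra passes).
#'
#' @param points curve matrix.
#' @param N number of sampling points (default 128).
#' @return `N x 2` matrix of class `normalized_shape`.
#' @export
normalize_shape <- function(points, N = 128L) {
  q <- resample_closed_curve(canonical_orientation(points), N)
  for (i in 1:20) {
    seg <- segment_lengths(q)
    if (max(abs(seg - mean(seg))) / mean(seg) <= 5e-4) break
    q <- resample_closed_curve(q, N)
  }
  q <- q / curve_perimeter(q)
  q <- sweep(q, 2L, colMeans(q))
  structure(q, class = c("normalized_shape", class(q)))
}

#' Affine whitening transform
#'
#' A transform `x -> linear %*% (x + offset)`. [ellipse_whitening()] builds the
#' one mapping a given ellipse onto a circle.
#'
#' @param linear 2 x 2 matrix.
#' @param offset length-2 numeric, added before the linear map.
#' @return object of class `whitening_transform`.
#' @export
whitening_transform <- function(linear, offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2L, 2L)
  stopifnot(length(offset) == 2L, all(is.finite(linear)), all(is.finite(offset)))
  structure(list(linear = linear, offset = as.numeric(offset)),
            class = "whitening_transform")
}

#' Apply a whitening transform to a curve
#'
#' Each point is mapped offset-then-linear. A positive-determinant linear part
#' preserves the curve's orientation; a singular one is rejected.
#'
#' @param points curve matrix.
#' @param transform a [whitening_transform()].
#' @return transformed curve matrix.
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(transform, "whitening_transform"))
  if (abs(det(transform$linear)) < .Machine$double.eps * 100)
    gb_stop("glandbam_invalid_transform", "transform has a singular linear part")
  validate_curve(points)
  sweep(points, 2L, -transform$offset) %*% t(transform$linear)
}

#' Baseline morphological shape features
#'
#' The five standard descriptors used as a reference feature set alongside the
#' aberrance features: roundness `4*pi*A/P^2`, aspect ratio `a/b` of the
#' minimum-area enclosing ellipse, elongation `1 - b/a`, solidity
#' `A / convex hull area`, and convexity `hull perimeter / P`.
#'
#' @param contour curve matrix.
#' @param area region area; defaults to the polygon area of the contour.
#'   For glands extracted from masks pass the labeled pixel count.
#' @return named list with elements `roundness`, `aspect_ratio`, `elongation`,
#'   `solidity`, `convexity`.
#' @export
baseline_shape_features <- function(contour, area = NULL) {
  contour <- canonical_orientation(contour)
  P <- curve_perimeter(contour)
  if (is.null(area)) area <- abs(shoelace_area(contour))
  if (!is.finite(area) || area <= 0)
    gb_stop("glandbam_degenerate_curve", "contour encloses no area")
  h <- grDevices::chull(contour)
  hull <- contour[h, , drop = FALSE]
  hull_area <- abs(shoelace_area(hull))
  hull_perim <- curve_perimeter(hull)
  ell <- min_area_enclosing_ellipse(contour)
  list(
    roundness = 4 * pi * area / P^2,
    aspect_ratio = ell$a / ell$b,
    elongation = 1 - ell$b / ell$a,
    solidity = area / hull_area,
    convexity = hull_perim / P
  )
}
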