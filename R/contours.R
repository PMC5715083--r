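# Mask handling and gland contour extraction.
#
# Masks are integer matrices indexed [row, col]; coordinates reported to the
# rest of the package are 0-based with x = column and y = row (y increases
# downward). Background is 0; each positive label is one gland.

#' Read a label mask from PNG or TIFF
#'
#' 8/16-bit PNG and 8/16/32-bit integer TIFF are supported. A binary mask
#' (exactly two distinct values) is relabeled by 8-connected components.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param relabel_binary relabel two-valued masks by connected components
#'   (default TRUE).
#' @return integer matrix `[row, col]`.
#' @export
read_mask <- function(path, relabel_binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of grey+alpha
    m <- matrix(round(img * (2^depth - 1)), nrow(img), ncol(img))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- img
  } else {
    gb_stop("glandbam_invalid_input", "unsupported mask format: %s", ext)
  }
  storage.mode(m) <- "integer"
  validate_mask(m)
  vals <- unique(as.vector(m))
  if (relabel_binary && length(vals) == 2L && 0L %in% vals)
    m <- label_components(m > 0L)
  m
}

#' Write a label mask
#'
#' PNG output is 8-bit (up to 255 labels); use a `.tif`/`.tiff` path for
#' 16-bit masks with more labels.
#'
#' @param mask integer matrix.
#' @param path output path ending in .png, .tif or .tiff.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(mask) > 255L)
      gb_stop("glandbam_invalid_input",
              "more than 255 labels: write a 16-bit TIFF instead")
    png::writePNG(mask / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535L)
      gb_stop("glandbam_invalid_input", "more than 65535 labels")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else {
    gb_stop("glandbam_invalid_input", "unsupported mask format: %s", ext)
  }
  invisible(path)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || length(dim(mask)) != 2L)
    gb_stop("glandbam_invalid_input", "mask must be a 2-D matrix")
  if (any(mask < 0))
    gb_stop("glandbam_invalid_input", "mask values must be nonnegative integers")
  invisible(mask)
}

#' 8-connected component labeling
#'
#' Labels the foreground of a binary matrix with consecutive positive
#' integers, treating diagonally adjacent pixels as connected (so thin
#' diagonal structures are not split).
#'
#' @param binary logical or 0/1 matrix.
#' @return integer label matrix.
#' @export
label_components <- function(binary) {
  m <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  lab <- EBImage::imageData(EBImage::bwlabel(m))  # 4-connected
  nlab <- max(lab)
  if (nlab <= 1) { storage.mode(lab) <- "integer"; return(lab) }
  # merge labels that touch diagonally (union-find over label ids)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # NW-SE neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # NE-SW neighbours
  pick <- function(a, b) { s <- a > 0 & b > 0 & a != b; cbind(a[s], b[s]) }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  fg <- lab > 0
  out[fg] <- relab[lab[fg]]
  out
}

# separable Gaussian blur of a small matrix (kernel truncated at 3 sigma,
# renormalized at the borders)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- ceiling(3 * sigma)
  g <- dnorm(seq(-k, k), sd = sigma)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -k:k) {
      idx <- seq_len(n - abs(o))
      if (o >= 0) K[cbind(idx, idx + o)] <- g[o + k + 1L]
      else K[cbind(idx - o, idx)] <- g[o + k + 1L]
    }
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# sub-pixel outer boundary of one label's indicator, cropped to its bounding
# box. Marching-squares iso-contour at level 0.5 of the (optionally
# Gaussian-smoothed) indicator; the longest closed loop is the outer boundary,
# shorter loops are interior holes and are ignored.
trace_label_contour <- function(mask, label, smooth_sigma) {
  idx <- which(mask == label, arr.ind = TRUE)
  pad <- ceiling(3 * max(smooth_sigma, 1)) + 2L
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  z <- matrix(0, h + 2L * pad, w + 2L * pad)
  z[cbind(idx[, 1L] - r0 + 1L + pad, idx[, 2L] - c0 + 1L + pad)] <- 1
  z <- gaussian_blur(z, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) return(NULL)
  len <- vapply(cl, function(co) {
    sum(sqrt(diff(co$x)^2 + diff(co$y)^2))
  }, numeric(1L))
  co <- cl[[which.max(len)]]
  # contourLines: first coordinate runs along rows -> y; second along cols -> x
  y <- co$x - pad - 1 + (r0 - 1L)
  x <- co$y - pad - 1 + (c0 - 1L)
  n <- length(x)
  if (n > 1L && x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n] }
  cbind(x = x, y = y)
}

#' Extract gland boundary contours from a label mask
#'
#' For every positive label, traces the sub-pixel outer boundary (interior
#' holes such as lumina are ignored) and records the gland's pixel area,
#' centroid, and whether it touches the image border.
#'
#' @param mask integer label mask (0 = background). A binary 0/1 (or 0/255)
#'   mask is first relabeled by 8-connected components.
#' @param image_id identifier stored with each record.
#' @param min_vertices labels whose boundary has fewer vertices are skipped
#'   with a warning (default 8).
#' @param border_margin a gland touches the border if any of its pixels lies
#'   within this many pixels of the image edge (default 2).
#' @param smooth_sigma Gaussian smoothing (in px) of the label indicator
#'   before contouring; gives sub-pixel boundaries free of staircase artifacts
#'   (default 2).
#' @return a `gland_records` object: list of per-gland records, each with
#'   `gland_id`, `image_id`, `contour` (matrix of 0-based x,y), `area`,
#'   `centroid`, `touches_border`, `aberrance` (NA until computed),
#'   `excluded`, `exclusion_reason`.
#' @export
extract_gland_contours <- function(mask, image_id = "image", min_vertices = 8L,
                                   border_margin = 2L, smooth_sigma = 2) {
  validate_mask(mask)
  vals <- sort(unique(as.vector(mask)))
  vals <- vals[vals > 0L]
  if (length(vals) == 1L) {
    # two-valued (binary) mask: relabel by 8-connected components
    mask <- label_components(mask > 0L)
    vals <- seq_len(max(mask))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  records <- list()
  for (lab in vals) {
    idx <- which(mask == lab, arr.ind = TRUE)
    contour <- trace_label_contour(mask, lab, smooth_sigma)
    if (is.null(contour) || nrow(contour) < min_vertices) {
      warning(sprintf("label %d in %s: boundary has < %d vertices, skipped",
                      lab, image_id, min_vertices))
      next
    }
    near <- border_margin + 1L
    records[[length(records) + 1L]] <- list(
      gland_id = as.integer(lab),
      image_id = image_id,
      contour = contour,
      area = nrow(idx),
      centroid = c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1),
      touches_border = any(idx[, 1L] <= near | idx[, 1L] > nr - near |
                           idx[, 2L] <= near | idx[, 2L] > nc - near),
      aberrance = NA_real_,
      excluded = FALSE,
      exclusion_reason = "none"
    )
  }
  structure(records, class = "gland_records")
}

#' Tabulate gland records
#'
#' Flattens a `gland_records` list into a data frame (contours dropped).
#'
#' @param x a `gland_records` object.
#' @param ... unused.
#' @return data frame with one row per gland.
#' @export
as.data.frame.gland_records <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(image_id = character(), gland_id = integer(),
                      area = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), touches_border = logical(),
                      aberrance = numeric(), excluded = logical(),
                      exclusion_reason = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    image_id = vapply(x, `[[`, "", "image_id"),
    gland_id = vapply(x, `[[`, 1L, "gland_id"),
    area = vapply(x, `[[`, 1, "area"),
    centroid_x = vapply(x, function(r) r$centroid[["x"]], 1),
    centroid_y = vapply(x, function(r) r$centroid[["y"]], 1),
    touches_border = vapply(x, `[[`, TRUE, "touches_border"),
    aberrance = vapply(x, `[[`, 1, "aberrance"),
    excluded = vapply(x, `[[`, TRUE, "excluded"),
    exclusion_reason = vapply(x, `[[`, "", "exclusion_reason"),
    stringsAsFactors = FALSE
  )
}
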