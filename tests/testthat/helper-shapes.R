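# Shape builders shared across tests. All fixtures are generated in code.

regular_polygon <- function(n, r = 1, phase = 0, center = c(0, 0)) {
  phi <- (seq_len(n) - 1L) * 2 * pi / n + phase
  cbind(center[1] + r * cos(phi), center[2] + r * sin(phi))
}

rotate_points <- function(p, theta) {
  p %*% t(matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2))
}

# smooth random star-shaped closed curve: unit base radius plus two cosine
# harmonics (uses the current RNG state)
random_smooth_curve <- function(n = 200) {
  k <- sample(2:6, 2)
  a <- runif(2, 0.05, 0.2)
  p <- runif(2, 0, 2 * pi)
  phi <- (seq_len(n) - 1L) * 2 * pi / n
  r <- 1 + a[1] * cos(k[1] * phi + p[1]) + a[2] * cos(k[2] * phi + p[2])
  cbind(r * cos(phi), r * sin(phi))
}

random_normalized_shape <- function(N) normalize_shape(random_smooth_curve(), N)

# binary [row, col] mask of a rasterized ellipse (pixel-center test)
rasterized_ellipse_mask <- function(a, b, phi = 0, pad = 20) {
  half <- ceiling(a) + pad
  n <- 2L * half + 1L
  cc <- half  # 0-based center
  xs <- matrix(rep(0:(n - 1L), each = n), n)   # x = col index
  ys <- matrix(rep(0:(n - 1L), n), n)          # y = row index
  xr <- (xs - cc) * cos(phi) + (ys - cc) * sin(phi)
  yr <- -(xs - cc) * sin(phi) + (ys - cc) * cos(phi)
  m <- matrix(0L, n, n)
  m[(xr / a)^2 + (yr / b)^2 <= 1] <- 1L
  t(m)  # -> [row, col] with x along columns
}

# filled disk painted into an existing [row, col] mask (1-based center row/col)
paint_disk <- function(mask, row, col, r, label) {
  rows <- max(1, floor(row - r)):min(nrow(mask), ceiling(row + r))
  cols <- max(1, floor(col - r)):min(ncol(mask), ceiling(col + r))
  for (i in rows) for (j in cols)
    if ((i - row)^2 + (j - col)^2 <= r^2) mask[i, j] <- label
  mask
}

# analytic samples of an ellipse boundary at uniform parameter angle
analytic_ellipse <- function(a, b, phi = 0, n = 512, center = c(0, 0)) {
  t <- (seq_len(n) - 1L) * 2 * pi / n
  sweep(cbind(a * cos(t), b * sin(t)) %*%
          t(matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)),
        2, center, `+`)
}

# three-lobed polar test curve used in several aberrance checks
three_lobe_curve <- function(n = 512, amp = 0.25) {
  phi <- (seq_len(n) - 1L) * 2 * pi / n
  r <- 1 + amp * cos(3 * phi)
  cbind(r * cos(phi), r * sin(phi))
}

# minimal gland_records builder for feature tests
make_records <- function(aberrance, area = 5000, touches_border = FALSE,
                         image_id = "img") {
  n <- length(aberrance)
  area <- rep_len(area, n)
  touches_border <- rep_len(touches_border, n)
  structure(lapply(seq_len(n), function(i) list(
    gland_id = i, image_id = image_id, contour = NULL, area = area[i],
    centroid = c(x = 0, y = 0), touches_border = touches_border[i],
    aberrance = aberrance[i], excluded = FALSE, exclusion_reason = "none"
  )), class = "gland_records")
}
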