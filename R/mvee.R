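#' Minimum-area enclosing ellipse
#'
#' Computes the minimum-area ellipse enclosing a planar point set by
#' Khachiyan-style iterative reweighting with away steps (compiled kernel),
#' after reducing the input to its convex hull. The returned ellipse satisfies
#' the quadratic form `(x - center)' A (x - center) <= 1 + tol` for every
#' input point.
#'
#' @param points `n x 2` numeric matrix, `n >= 3`, not all collinear.
#' @param tol containment slack tolerance (default 1e-7).
#' @param maxit iteration cap (default 10000).
#' @return object of class `mvee_ellipse`: list with `center` (length 2),
#'   semi-axes `a >= b > 0`, major-axis angle `phi` in `[0, pi)` from +x, the
#'   quadratic-form matrix `A`, and the iteration count `iter`.
#' @export
min_area_enclosing_ellipse <- function(points, tol = 1e-7, maxit = 10000L) {
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) < 3L)
    gb_stop("glandbam_invalid_input", "need an n x 2 matrix with n >= 3")
  if (!all(is.finite(points)))
    gb_stop("glandbam_invalid_input", "points must be finite")
  storage.mode(points) <- "double"
  h <- grDevices::chull(points)
  hp <- points[h, , drop = FALSE]
  if (nrow(hp) < 3L || abs(shoelace_area(hp)) <=
      .Machine$double.eps * 100 * max(1, sum(hp^2)))
    gb_stop("glandbam_degenerate_input", "points are (near-)collinear")
  # center and scale for numerical conditioning of the moment matrix
  mu <- colMeans(hp)
  sc <- max(abs(sweep(hp, 2L, mu)))
  fit <- mvee_khachiyan(sweep(hp, 2L, mu) / sc, tol, as.integer(maxit))
  if (!isTRUE(fit$ok))
    gb_stop("glandbam_degenerate_input", "ellipse fit degenerated (collinear points?)")
  if (fit$eps > tol)
    gb_stop("glandbam_convergence",
            "MVEE did not reach tol %g within %d iterations (achieved slack %g)",
            tol, as.integer(maxit), fit$eps)
  fit$center <- fit$center * sc + mu
  fit$S <- fit$S * sc^2
  S2 <- 2 * fit$S  # ellipse: (x-c)' solve(S2) (x-c) <= 1
  e <- eigen(S2, symmetric = TRUE)
  ax <- sqrt(pmax(e$values, 0))
  vmaj <- e$vectors[, which.max(e$values)]
  structure(list(
    center = as.numeric(fit$center),
    a = max(ax), b = min(ax),
    phi = atan2(vmaj[2L], vmaj[1L]) %% pi,
    A = solve(S2),
    iter = fit$iter
  ), class = "mvee_ellipse")
}

#' @export
print.mvee_ellipse <- function(x, ...) {
  cat(sprintf("minimum-area enclosing ellipse\n  center (%.4g, %.4g)  a = %.6g  b = %.6g  phi = %.4f rad\n",
              x$center[1L], x$center[2L], x$a, x$b, x$phi))
  invisible(x)
}

#' Points on an ellipse boundary
#'
#' Samples `n` points at uniform parameter angle, traversed counter-clockwise
#' (positive shoelace area) starting at the major-axis end.
#'
#' @param ellipse an `mvee_ellipse` (or list with `center`, `a`, `b`, `phi`).
#' @param n number of points.
#' @return `n x 2` matrix.
#' @export
ellipse_boundary <- function(ellipse, n = 512L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  R <- rotation_matrix(ellipse$phi)
  sweep(cbind(ellipse$a * cos(t), ellipse$b * sin(t)) %*% t(R),
        2L, ellipse$center, `+`)
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Whitening transform of an ellipse
#'
#' Builds the affine map that turns the given ellipse into a circle of radius
#' `sqrt(a * b)` (geometric-mean target, area-preserving): translate the
#' center to the origin, rotate the major axis onto +x, then scale x by
#' `sqrt(b/a)` and y by `sqrt(a/b)`. The linear part has determinant +1, so
#' curve orientation is preserved.
#'
#' @param ellipse an `mvee_ellipse`.
#' @return a [whitening_transform()].
#' @export
ellipse_whitening <- function(ellipse) {
  stopifnot(is.numeric(ellipse$a), is.numeric(ellipse$b), ellipse$b > 0)
  S <- diag(c(sqrt(ellipse$b / ellipse$a), sqrt(ellipse$a / ellipse$b)))
  whitening_transform(S %*% rotation_matrix(-ellipse$phi), -ellipse$center)
}

#' Quadratic-form values of points against an ellipse
#'
#' `<= 1` means inside or on the ellipse. Used to verify containment.
#'
#' @param ellipse an `mvee_ellipse`.
#' @param points `n x 2` matrix.
#' @return numeric vector of quadratic-form values.
#' @export
ellipse_qform <- function(ellipse, points) {
  ctr <- sweep(points, 2L, ellipse$center)
  rowSums((ctr %*% ellipse$A) * ctr)
}
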