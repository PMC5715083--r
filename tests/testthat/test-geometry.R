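test_that("orientation canonicalization fixes traversal direction and rejects degenerate curves", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))  # positive shoelace
  expect_equal(canonical_orientation(sq), sq)
  expect_equal(canonical_orientation(sq[4:1, ]), sq)  # reversal restores CCW
  expect_gt(shoelace_area(canonical_orientation(sq[4:1, ])), 0)
  expect_error(canonical_orientation(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "glandbam_degenerate_curve")
})

test_that("curve validation catches malformed input", {
  expect_error(validate_curve(rbind(c(0, 0), c(1, 0))), class = "glandbam_invalid_input")
  expect_error(validate_curve(rbind(c(0, 0), c(0, 0), c(1, 0))),
               class = "glandbam_invalid_input")
  expect_silent(validate_curve(regular_polygon(5)))
})

test_that("arc-length resampling places points at k*L/N and is idempotent", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r8 <- resample_closed_curve(sq, 8L)
  expect_equal(r8, rbind(c(0, 0), c(.5, 0), c(1, 0), c(1, .5),
                         c(1, 1), c(.5, 1), c(0, 1), c(0, .5)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # circle sampled at non-uniform angles resamples to uniform angular gaps
  set.seed(1)
  ang <- sort(runif(100, 0, 2 * pi))
  circ <- cbind(cos(ang), sin(ang))
  r64 <- resample_closed_curve(circ, 64L)
  gaps <- diff(c(atan2(r64[, 2], r64[, 1])))
  gaps <- (gaps + 2 * pi) %% (2 * pi)
  expect_lt(max(abs(gaps - 2 * pi / 64)), 1e-2)
  # idempotence at fixed N
  expect_equal(resample_closed_curve(r8, 8L), r8, tolerance = 1e-9)
  expect_error(resample_closed_curve(sq, 2L), class = "glandbam_invalid_parameter")
})

test_that("shape normalization yields unit perimeter, zero mean, equal spacing", {
  u <- normalize_shape(analytic_ellipse(5, 5, center = c(100, 200)), 128L)
  rad <- sqrt(rowSums(u^2))
  expect_lt(max(abs(rad - 1 / (2 * pi))), 1e-4)
  expect_equal(normalize_shape(u, 128L), u, tolerance = 1e-9, ignore_attr = TRUE)
  sq3 <- 3 * rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  nsq <- normalize_shape(sq3, 4L)
  expect_equal(sort(abs(as.vector(nsq))), rep(1 / 8, 8), tolerance = 1e-12)
  # invariants hold over many random smooth curves
  set.seed(11)
  for (i in 1:200) {
    s <- normalize_shape(random_smooth_curve(), 64L)
    expect_lt(max(abs(colMeans(s))), 1e-9)
    expect_lt(abs(curve_perimeter(s) - 1), 1e-6)
    seg <- sqrt(rowSums((s[c(2:64, 1), ] - s)^2))
    expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-3)
    expect_gt(shoelace_area(s), 0)
  }
})

test_that("minimum-area enclosing ellipse reproduces analytic cases", {
  # points on a circle enclose themselves
  e1 <- min_area_enclosing_ellipse(regular_polygon(64))
  expect_equal(e1$center, c(0, 0), tolerance = 1e-4)
  expect_equal(e1$a, 1, tolerance = 1e-4)
  expect_equal(e1$b, 1, tolerance = 1e-4)
  # rectangle corners: the affine image of a square's circumcircle
  e2 <- min_area_enclosing_ellipse(rbind(c(1, .5), c(1, -.5), c(-1, .5), c(-1, -.5)))
  expect_equal(e2$a, sqrt(2), tolerance = 1e-3)
  expect_equal(e2$b, sqrt(2) / 2, tolerance = 1e-3)
  expect_lt(min(e2$phi, pi - e2$phi), 1e-3)
  # points sampled on an ellipse recover it
  e3 <- min_area_enclosing_ellipse(analytic_ellipse(2, 1, n = 128))
  expect_equal(e3$a, 2, tolerance = 1e-3)
  expect_equal(e3$b, 1, tolerance = 1e-3)
  expect_lt(min(e3$phi, pi - e3$phi), 1e-3)
  expect_error(min_area_enclosing_ellipse(cbind(1:5, 2 * (1:5))),
               class = "glandbam_degenerate_input")
})

test_that("MVEE contains its inputs and is affine-equivariant", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:500, 1)
    P <- cbind(rnorm(n), rnorm(n))
    if (abs(shoelace_area(P[grDevices::chull(P), , drop = FALSE])) < 1e-6) next
    E <- min_area_enclosing_ellipse(P)
    expect_lt(max(ellipse_qform(E, P)), 1 + 1e-7)
    # affine equivariance, compared via quadratic forms of mapped points
    A <- matrix(rnorm(4), 2)
    while (abs(det(A)) < 0.3) A <- matrix(rnorm(4), 2)
    EA <- min_area_enclosing_ellipse(P %*% t(A))
    bnd <- ellipse_boundary(E, 64L) %*% t(A)  # image of the original MVEE
    expect_lt(max(abs(ellipse_qform(EA, bnd) - 1)), 1e-3)
  }
})

test_that("MVEE agrees with an independent compiled implementation", {
  skip_if_not_installed("cluster")
  set.seed(6)
  for (i in 1:10) {
    P <- cbind(rnorm(40), 2 * rnorm(40))
    E <- min_area_enclosing_ellipse(P)
    eh <- cluster::ellipsoidhull(P, tol = 1e-9, maxit = 100000)
    ax <- sort(sqrt(eigen(eh$cov * eh$d2, symmetric = TRUE)$values))
    expect_equal(c(E$b, E$a), ax, tolerance = 1e-4)
    expect_equal(E$center, as.numeric(eh$loc), tolerance = 1e-4)
  }
})

test_that("whitening maps the ellipse onto a circle and preserves orientation", {
  # analytic example: a = 2, b = 1, axis-aligned
  tf <- ellipse_whitening(structure(list(center = c(0, 0), a = 2, b = 1, phi = 0),
                                    class = "mvee_ellipse"))
  expect_equal(drop(apply_transform(rbind(c(2, 0), c(0, 1), c(-2, 0)), tf)),
               rbind(c(sqrt(2), 0), c(0, sqrt(2)), c(-sqrt(2), 0)),
               tolerance = 1e-12)
  # rotated ellipse: image boundary is a circle of radius sqrt(ab)
  ell <- structure(list(center = c(3, -1), a = 2, b = 1, phi = pi / 2),
                   class = "mvee_ellipse")
  img <- apply_transform(ellipse_boundary(ell, 256L), ellipse_whitening(ell))
  rad <- sqrt(rowSums(sweep(img, 2, colMeans(img))^2))
  expect_lt(max(rad) / min(rad) - 1, 1e-9)
  expect_equal(mean(rad), sqrt(2), tolerance = 1e-3)
  # circle: rigid motion only
  circ <- structure(list(center = c(5, 5), a = 3, b = 3, phi = 0),
                    class = "mvee_ellipse")
  img2 <- apply_transform(ellipse_boundary(circ, 64L), ellipse_whitening(circ))
  expect_equal(max(sqrt(rowSums(img2^2))), 3, tolerance = 1e-9)
})

test_that("applying a curve's own MVEE whitening makes its MVEE a circle", {
  set.seed(9)
  cur <- 40 * random_smooth_curve()
  E <- min_area_enclosing_ellipse(cur, maxit = 100000L)
  img <- apply_transform(cur, ellipse_whitening(E))
  E2 <- min_area_enclosing_ellipse(img, maxit = 100000L)
  expect_lt(E2$a / E2$b - 1, 1e-4)
  # identity and anisotropic scaling behave as expected
  idt <- whitening_transform(diag(2), c(0, 0))
  expect_equal(apply_transform(cur, idt), cur)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(apply_transform(sq, whitening_transform(diag(c(2, 1)), c(0, 0))),
               rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_error(apply_transform(sq, whitening_transform(matrix(c(1, 1, 1, 1), 2), c(0, 0))),
               class = "glandbam_invalid_transform")
})

test_that("gland contours are extracted with area, centroid and border flags", {
  expect_length(extract_gland_contours(matrix(0L, 50, 50)), 0)
  # two disks, one tangent to the top edge
  m <- matrix(0L, 120, 120)
  m <- paint_disk(m, 21, 60, 20, 1L)   # touches row 1
  m <- paint_disk(m, 80, 60, 20, 2L)
  recs <- extract_gland_contours(m, "disks")
  expect_length(recs, 2)
  borders <- vapply(recs, `[[`, TRUE, "touches_border")
  expect_equal(sum(borders), 1L)
  for (r in recs) expect_lt(abs(r$area - pi * 400) / (pi * 400), 0.05)
  # interior rectangle: exact pixel count, no border contact
  m2 <- matrix(0L, 60, 60)
  m2[25:34, 20:39] <- 1L  # 10 x 20
  recs2 <- extract_gland_contours(m2, "rect")
  expect_length(recs2, 1)
  expect_equal(recs2[[1]]$area, 200)
  expect_false(recs2[[1]]$touches_border)
  expect_error(extract_gland_contours(array(0L, c(2, 2, 2))),
               class = "glandbam_invalid_input")
  expect_error(extract_gland_contours(matrix(-1L, 5, 5)),
               class = "glandbam_invalid_input")
})

test_that("tiny labels are skipped with a warning", {
  m <- matrix(0L, 30, 30)
  m[15, 15] <- 1L
  m <- paint_disk(m, 10, 10, 5, 2L)
  expect_warning(recs <- extract_gland_contours(m, "tiny", min_vertices = 8L),
                 "skipped")
  expect_length(recs, 1)
})

test_that("binary label images are relabeled with 8-connectivity", {
  m <- matrix(0L, 20, 20)
  m[2:4, 2:4] <- 1L
  m[5:7, 5:7] <- 1L  # diagonally touching block
  m[12:15, 12:15] <- 1L
  lab <- label_components(m)
  expect_equal(max(lab), 2L)  # diagonal neighbours merge
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
})

test_that("baseline shape features hit their analytic extremes", {
  f <- baseline_shape_features(analytic_ellipse(50, 50, n = 720))
  expect_equal(f$roundness, 1, tolerance = 1e-3)
  expect_equal(f$aspect_ratio, 1, tolerance = 1e-3)
  expect_equal(f$elongation, 0, tolerance = 1e-3)
  expect_equal(f$solidity, 1, tolerance = 1e-3)
  expect_equal(f$convexity, 1, tolerance = 1e-3)
  # 4 x 1 rectangle: MVEE aspect ratio equals the side ratio; convex
  rect <- rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 1))
  fr <- baseline_shape_features(rect)
  expect_equal(fr$aspect_ratio, 4, tolerance = 1e-3)
  expect_equal(fr$solidity, 1, tolerance = 1e-9)
  # concave star: solidity and convexity drop below 1
  phi <- (0:255) * 2 * pi / 256
  star <- cbind((1 + .5 * cos(5 * phi)) * cos(phi), (1 + .5 * cos(5 * phi)) * sin(phi))
  fs <- baseline_shape_features(star)
  expect_lt(fs$solidity, 1)
  expect_lt(fs$convexity, 1)
})
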