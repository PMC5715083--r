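# Synthetic gland-mask generator. Emulates the structure of graded colorectal
# tissue images: fields of near-elliptical gland sections whose boundary
# deformation grows with tumour grade, plus the two artifact types seen in
# real normal images — small tangential crypt sections and glands clipped by
# the image border.

#' Synthetic dataset configuration
#'
#' The boundary model is polar: an ellipse base radius modulated by a small
#' number of radial cosine harmonics, `r(phi) = r_e(phi) * (1 + sum_k a_k
#' cos(k phi + psi_k))`. Total harmonic amplitude is drawn from the grade's
#' range; since all amplitudes are < 1 the curve is star-shaped and therefore
#' simple.
#'
#' @param image_size height and width in pixels (default `c(1024, 1024)`).
#' @param n_glands inclusive range of glands per image (default `c(40, 60)`).
#' @param base_radius range of the gland mean radius in px (default
#'   `c(32, 48)`; keeps every undeformed gland's area above the default
#'   3000 px2 tangential-area threshold).
#' @param eccentricity range of the base-ellipse eccentricity (default
#'   `c(0, 0.9)`).
#' @param deformation named list of per-grade total-amplitude ranges
#'   (defaults: normal `[0, 0.03]`, low_grade `[0.08, 0.18]`, high_grade
#'   `[0.2, 0.45]`).
#' @param harmonics candidate harmonic orders (default `2:8`).
#' @param tangential_fraction fraction of glands in a *normal* image replaced
#'   by small, strongly deformed tangential crypt sections (default 0.05).
#' @param tangential_radius mean-radius range of tangential sections
#'   (default `c(14, 26)`; keeps their area below the 3000 px2 threshold).
#' @param border_fraction fraction of glands placed so they clip the image
#'   border (default 0.05).
#' @param min_separation minimum gap in px between placed glands (default 5).
#' @param n_vertices boundary vertices per gland (default 256).
#' @param seed base RNG seed for [generate_dataset()] (default 0).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = c(1024L, 1024L),
                             n_glands = c(40L, 60L),
                             base_radius = c(32, 48),
                             eccentricity = c(0, 0.9),
                             deformation = list(normal = c(0, 0.03),
                                                low_grade = c(0.08, 0.18),
                                                high_grade = c(0.2, 0.45)),
                             harmonics = 2:8,
                             tangential_fraction = 0.05,
                             tangential_radius = c(14, 26),
                             border_fraction = 0.05,
                             min_separation = 5,
                             n_vertices = 256L,
                             seed = 0L) {
  stopifnot(all(c("normal", "low_grade", "high_grade") %in% names(deformation)))
  lo <- vapply(deformation[GRADES], min, 1)
  hi <- vapply(deformation[GRADES], max, 1)
  if (any(diff(lo) <= 0) || any(hi[-3] > lo[-1]))
    gb_stop("glandbam_invalid_parameter",
            "deformation amplitude ranges must be non-overlapping and increasing with grade")
  if (tangential_fraction < 0 || tangential_fraction > 1 ||
      border_fraction < 0 || border_fraction > 1)
    gb_stop("glandbam_invalid_parameter", "fractions must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size), n_glands = as.integer(n_glands),
                 base_radius = base_radius, eccentricity = eccentricity,
                 deformation = deformation, harmonics = as.integer(harmonics),
                 tangential_fraction = tangential_fraction,
                 tangential_radius = tangential_radius,
                 border_fraction = border_fraction,
                 min_separation = min_separation,
                 n_vertices = as.integer(n_vertices), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic gland boundary
#'
#' Draws ellipse parameters and radial harmonics from the configured ranges
#' (using the current RNG state) and returns the boundary centered at the
#' origin.
#'
#' @param grade `"normal"`, `"low_grade"` or `"high_grade"`.
#' @param cfg a [synthetic_config()].
#' @param amplitude override the total harmonic amplitude (default: drawn
#'   from the grade's range).
#' @param radius override the mean-radius range (length-2).
#' @return list with `points` (`n_vertices x 2`), `amplitude`, `max_radius`.
#' @export
generate_gland_boundary <- function(grade = "normal", cfg = synthetic_config(),
                                    amplitude = NULL, radius = NULL) {
  grade <- match.arg(grade, GRADES)
  rng <- if (is.null(radius)) cfg$base_radius else radius
  m <- runif(1, rng[1], rng[2])
  e <- runif(1, cfg$eccentricity[1], cfg$eccentricity[2])
  psi <- runif(1, 0, pi)
  if (is.null(amplitude)) {
    ar <- cfg$deformation[[grade]]
    amplitude <- runif(1, ar[1], ar[2])
  }
  n_h <- sample(2:3, 1)
  orders <- sample(cfg$harmonics, n_h)
  w <- runif(n_h); w <- w / sum(w)
  phases <- runif(n_h, 0, 2 * pi)
  A <- m / (1 - e^2)^0.25
  B <- m * (1 - e^2)^0.25
  phi <- (seq_len(cfg$n_vertices) - 1L) * 2 * pi / cfg$n_vertices
  t <- phi - psi
  r_e <- A * B / sqrt((B * cos(t))^2 + (A * sin(t))^2)
  mod <- 1 + Reduce(`+`, Map(function(a, k, p) a * cos(k * phi + p),
                             amplitude * w, orders, phases))
  r <- r_e * mod
  if (min(r) <= 0)
    gb_stop("glandbam_generation", "degenerate boundary (amplitude too large)")
  list(points = cbind(x = r * cos(phi), y = r * sin(phi)),
       amplitude = amplitude, max_radius = max(r))
}

# exact point-in-polygon for a star-shaped polygon given in polar form with
# equally spaced vertex angles: a pixel is inside iff its radius does not
# exceed the chord radius of the boundary segment covering its angle
# (polar line equation through (r1,phi1) and (r2,phi2)).
rasterize_star <- function(mask, boundary, cx, cy, label) {
  r_v <- sqrt(rowSums(boundary^2))
  n <- length(r_v)
  dphi <- 2 * pi / n
  rmax <- max(r_v)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- max(1L, floor(cy + 1 - rmax)):min(nr, ceiling(cy + 1 + rmax))
  cols <- max(1L, floor(cx + 1 - rmax)):min(nc, ceiling(cx + 1 + rmax))
  dy <- rows - 1 - cy
  dx <- cols - 1 - cx
  DX <- matrix(rep(dx, each = length(dy)), length(dy))
  DY <- matrix(rep(dy, length(dx)), length(dy))
  rad <- sqrt(DX^2 + DY^2)
  ang <- atan2(DY, DX) %% (2 * pi)
  i1 <- pmin(floor(ang / dphi) + 1L, n)
  i2 <- ifelse(i1 == n, 1L, i1 + 1L)
  r1 <- r_v[i1]; r2 <- r_v[i2]
  t1 <- ang - (i1 - 1L) * dphi
  rb <- r1 * r2 * sin(dphi) / (r2 * sin(dphi - t1) + r1 * sin(t1))
  inside <- rad <= rb
  sub <- mask[rows, cols]
  sub[inside & sub == 0L] <- label
  mask[rows, cols] <- sub
  mask
}

#' Generate one synthetic label image
#'
#' Samples the gland count, assigns artifact roles (tangential sections in
#' normal images; border-clipped glands in all grades), places glands by
#' rejection sampling with a minimum separation (largest first), and
#' rasterizes each as one label. Placement failures drop the gland after a
#' retry cap.
#'
#' @param grade image grade.
#' @param cfg a [synthetic_config()].
#' @param image_id identifier for the manifest.
#' @return list with `mask` (integer label matrix), `glands` (data frame:
#'   `gland_id`, `role`, `cx`, `cy`, `amplitude`), `grade`, `image_id`.
#' @export
generate_image_mask <- function(grade = "normal", cfg = synthetic_config(),
                                image_id = grade) {
  grade <- match.arg(grade, GRADES)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  n <- sample(cfg$n_glands[1]:cfg$n_glands[2], 1)
  n_tang <- if (grade == "normal") round(cfg$tangential_fraction * n) else 0L
  n_border <- round(cfg$border_fraction * n)
  roles <- c(rep("tangential", n_tang), rep("border", n_border),
             rep("regular", n - n_tang - n_border))
  shapes <- lapply(roles, function(role) {
    b <- if (role == "tangential")
      generate_gland_boundary(grade, cfg,
                              amplitude = runif(1, cfg$deformation$high_grade[1],
                                                cfg$deformation$high_grade[2]),
                              radius = cfg$tangential_radius)
    else generate_gland_boundary(grade, cfg)
    b$role <- role
    b
  })
  ord <- order(vapply(shapes, `[[`, 1, "max_radius"), decreasing = TRUE)
  shapes <- shapes[ord]
  mask <- matrix(0L, H, W)
  placed <- NULL  # rows: cx, cy, rmax
  glands <- list()
  clearance <- 4  # interior glands stay clear of the border-touch margin
  for (s in shapes) {
    rmax <- s$max_radius
    ok <- FALSE
    for (try in 1:500) {
      if (s$role == "border") {
        edge <- sample(4L, 1)
        ext <- switch(edge,
                      max(-s$points[, 1]),  # left: extent in -x
                      max(s$points[, 1]),   # right
                      max(-s$points[, 2]),  # top: extent in -y
                      max(s$points[, 2]))   # bottom
        off <- runif(1, 0.2, 0.7) * ext
        cx <- switch(edge, off, W - 1 - off, runif(1, rmax, W - 1 - rmax),
                     runif(1, rmax, W - 1 - rmax))
        cy <- switch(edge, runif(1, rmax, H - 1 - rmax),
                     runif(1, rmax, H - 1 - rmax), off, H - 1 - off)
      } else {
        if (W - 1 - rmax - clearance <= rmax + clearance) break
        cx <- runif(1, rmax + clearance, W - 1 - rmax - clearance)
        cy <- runif(1, rmax + clearance, H - 1 - rmax - clearance)
      }
      if (is.null(placed) ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >=
              placed[, 3] + rmax + cfg$min_separation)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    label <- length(glands) + 1L
    mask <- rasterize_star(mask, s$points, cx, cy, label)
    placed <- rbind(placed, c(cx, cy, rmax))
    glands[[label]] <- data.frame(gland_id = label, role = s$role,
                                  cx = cx, cy = cy, amplitude = s$amplitude,
                                  stringsAsFactors = FALSE)
  }
  list(mask = mask, glands = do.call(rbind, glands), grade = grade,
       image_id = image_id)
}

#' Generate a synthetic graded dataset
#'
#' Generates `n_per_grade` images for each grade, each from its own seed
#' derived from `cfg$seed`, so any image is reproducible in isolation. With
#' `out_dir` set, masks are written as 16-bit PNG next to a `manifest.csv`
#' (image_id, grade, seed, gland/artifact counts); otherwise the images are
#' returned in memory.
#'
#' @param cfg a [synthetic_config()].
#' @param n_per_grade integer vector of length 1 or 3 (normal, low, high).
#' @param out_dir optional output directory.
#' @return with `out_dir`: the manifest data frame (invisibly, after
#'   writing). Without: list with `images` (list of [generate_image_mask()]
#'   results) and `manifest`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), n_per_grade = 10L,
                             out_dir = NULL) {
  n_per_grade <- rep_len(as.integer(n_per_grade), 3L)
  if (any(n_per_grade < 1))
    gb_stop("glandbam_invalid_parameter", "n_per_grade must be >= 1")
  images <- list()
  manifest <- list()
  for (gi in seq_along(GRADES)) {
    grade <- GRADES[gi]
    for (i in seq_len(n_per_grade[gi])) {
      image_seed <- (cfg$seed * 13L + gi * 1000L + i) %% .Machine$integer.max
      set.seed(image_seed)
      image_id <- sprintf("%s_%03d", grade, i)
      img <- generate_image_mask(grade, cfg, image_id = image_id)
      manifest[[length(manifest) + 1L]] <- data.frame(
        image_id = image_id, grade = grade, seed = image_seed,
        n_glands = nrow(img$glands),
        n_tangential = sum(img$glands$role == "tangential"),
        n_border = sum(img$glands$role == "border"),
        stringsAsFactors = FALSE)
      if (is.null(out_dir)) {
        images[[image_id]] <- img
      } else {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        write_mask(img$mask, file.path(out_dir, paste0(image_id, ".png")))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (is.null(out_dir)) return(list(images = images, manifest = manifest))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  labels <- data.frame(image_id = manifest$image_id, label = manifest$grade)
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}
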