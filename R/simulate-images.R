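#' Simulate a two-channel puncta image pair with known colocalization
#'
#' Generates two single-plane images of Gaussian puncta emulating
#' pre-/post-synaptic marker channels. Exactly
#' `round(coloc_fraction * min(n1, n2))` channel-2 puncta are placed
#' concentric with channel-1 puncta; all remaining puncta of either channel
#' are kept farther than `2 * punctum_radius_px` from every punctum of the
#' other channel, and same-channel puncta keep a minimum separation of
#' `4 * punctum_radius_px` so that connected components remain countable.
#'
#' @param n1,n2 Number of puncta in channel 1 and channel 2.
#' @param coloc_fraction Fraction of `min(n1, n2)` that is colocalized,
#'   in `[0, 1]`.
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param punctum_radius_px Punctum radius (pixels); the rendered spot is a
#'   Gaussian of sigma `punctum_radius_px / 2` truncated at the radius x 2.
#' @param amplitude Mean peak intensity of a punctum (images are in
#'   arbitrary units with background 0).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional seed; identical seeds give identical images.
#' @return List with `ch1`, `ch2` (numeric matrices) and `truth`: a list of
#'   `centers_ch1`, `centers_ch2` (tibbles `row`, `col`, `colocalized`) and
#'   `n_colocalized`.
#' @export
simulate_puncta <- function(n1 = 2000, n2 = 2000, coloc_fraction = 0.15,
                            image_shape = c(1024, 1024),
                            punctum_radius_px = 2, amplitude = 1,
                            noise_sd = 0.02, seed = NULL) {
  check_proportion(coloc_fraction, "coloc_fraction")
  check_positive(punctum_radius_px, "punctum_radius_px")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (!is.null(seed)) set.seed(seed)

  H <- image_shape[1]; W <- image_shape[2]
  r <- punctum_radius_px
  margin <- ceiling(2 * r) + 1
  n_coloc <- round(coloc_fraction * min(n1, n2))

  same_sep <- 4 * r     # same-channel separation (components stay distinct)
  cross_sep <- 2 * r    # non-colocalized cross-channel exclusion

  # channel-1 centers: mutual separation only
  c1 <- place_centers(n1, H, W, margin, same_sep)

  # channel-2: first the colocalized ones (concentric with a random subset of
  # channel 1), then the rest, excluded from both channel-2 neighbours and
  # all channel-1 puncta
  coloc_idx <- if (n_coloc > 0) sample(n1, n_coloc) else integer()
  c2 <- c1[coloc_idx, , drop = FALSE]
  n_free <- n2 - n_coloc
  if (n_free > 0) {
    free <- matrix(NA_real_, n_free, 2)
    placed <- 0L; tries <- 0L; max_tries <- 2000L * n_free
    while (placed < n_free && tries < max_tries) {
      tries <- tries + 1L
      rr <- runif(1, 1 + margin, H - margin)
      cc <- runif(1, 1 + margin, W - margin)
      ok_cross <- min((c1[, 1] - rr)^2 + (c1[, 2] - cc)^2) > cross_sep^2
      ok_same <- TRUE
      if (nrow(c2) > 0 || placed > 0) {
        prev <- rbind(c2, free[seq_len(placed), , drop = FALSE])
        ok_same <- min((prev[, 1] - rr)^2 + (prev[, 2] - cc)^2) >= same_sep^2
      }
      if (ok_cross && ok_same) {
        placed <- placed + 1L
        free[placed, ] <- c(round(rr), round(cc))
      }
    }
    if (placed < n_free) {
      abort(sprintf("puncta density too high: placed %d of %d channel-2 puncta",
                    placed + n_coloc, n2))
    }
    c2 <- rbind(c2, free)
  }

  render <- function(centers) {
    img <- if (noise_sd > 0) {
      matrix(rnorm(H * W, 0, noise_sd), H, W)
    } else matrix(0, H, W)
    sigma <- r / 2
    R <- ceiling(2 * r)
    off <- -R:R
    d2 <- outer(off^2, off^2, `+`)
    spot <- exp(-d2 / (2 * sigma^2))
    spot[d2 > (2 * r)^2] <- 0
    for (i in seq_len(nrow(centers))) {
      amp <- amplitude * exp(rnorm(1, 0, 0.2))
      rows <- (centers[i, 1] - R):(centers[i, 1] + R)
      cols <- (centers[i, 2] - R):(centers[i, 2] + R)
      img[rows, cols] <- img[rows, cols] + amp * spot
    }
    img
  }

  ch1 <- render(c1)
  ch2 <- render(c2)

  truth <- list(
    centers_ch1 = tibble(row = c1[, 1], col = c1[, 2],
                         colocalized = seq_len(n1) %in% coloc_idx),
    centers_ch2 = tibble(row = c2[, 1], col = c2[, 2],
                         colocalized = seq_len(nrow(c2)) <= n_coloc),
    n_colocalized = n_coloc
  )
  list(ch1 = ch1, ch2 = ch2, truth = truth)
}

#' Simulate a binary organoid mask with analytic geometry
#'
#' Rasterizes a filled circle, ellipse or square into a binary mask and
#' returns the exact analytic maximum diameter, perimeter and area of the
#' generating shape (the oracle for morphometry). The ellipse perimeter is
#' computed by numeric quadrature of the arc-length integral.
#'
#' @param shape One of `"circle"`, `"ellipse"`, `"square"`.
#' @param radius_px Circle radius (pixels).
#' @param semi_axes_px Length-2 vector `c(a, b)` of ellipse semi-axes
#'   (pixels), a along image columns.
#' @param side_px Square side (pixels).
#' @param pixel_size_um Pixel size (micron), used for the analytic truth in
#'   physical units.
#' @param image_shape `c(height, width)` of the mask.
#' @param center Optional `c(row, col)` center; defaults to the image center.
#' @return List with `mask` (0/1 integer matrix) and `truth` (tibble:
#'   `shape`, `max_diameter_px`, `perimeter_px`, `area_px2`,
#'   `max_diameter_mm`, `perimeter_mm`, `area_mm2`).
#' @export
simulate_organoid_mask <- function(shape = c("circle", "ellipse", "square"),
                                   radius_px = 50, semi_axes_px = c(60, 30),
                                   side_px = 80, pixel_size_um = 10,
                                   image_shape = c(256, 256), center = NULL) {
  shape <- match.arg(shape)
  check_positive(pixel_size_um, "pixel_size_um")
  H <- image_shape[1]; W <- image_shape[2]
  ctr <- center %||% c((H + 1) / 2, (W + 1) / 2)

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rows - ctr[1]; dx <- cols - ctr[2]

  geom <- switch(shape,
    circle = {
      if (radius_px > min(ctr[1], ctr[2], H - ctr[1], W - ctr[2])) {
        abort("circle exceeds image bounds")
      }
      inside <- dy^2 + dx^2 <= radius_px^2
      c(d = 2 * radius_px, p = 2 * pi * radius_px, A = pi * radius_px^2,
        inside = list(inside))
    },
    ellipse = {
      a <- semi_axes_px[1]; b <- semi_axes_px[2]
      check_positive(c(a, b), "semi_axes_px")
      if (b > min(ctr[1], H - ctr[1]) || a > min(ctr[2], W - ctr[2])) {
        abort("ellipse exceeds image bounds")
      }
      inside <- (dx / a)^2 + (dy / b)^2 <= 1
      per <- 4 * integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                           0, pi / 2, rel.tol = 1e-10)$value
      c(d = 2 * max(a, b), p = per, A = pi * a * b, inside = list(inside))
    },
    square = {
      s <- side_px
      check_positive(s, "side_px")
      if (s / 2 > min(ctr[1], ctr[2], H - ctr[1], W - ctr[2])) {
        abort("square exceeds image bounds")
      }
      inside <- abs(dy) <= s / 2 & abs(dx) <= s / 2
      c(d = s * sqrt(2), p = 4 * s, A = s^2, inside = list(inside))
    }
  )

  mask <- matrix(0L, H, W)
  mask[geom$inside] <- 1L
  um_to_mm <- pixel_size_um / 1000
  truth <- tibble(
    shape = shape,
    max_diameter_px = geom$d, perimeter_px = geom$p, area_px2 = geom$A,
    max_diameter_mm = geom$d * um_to_mm,
    perimeter_mm = geom$p * um_to_mm,
    area_mm2 = geom$A * um_to_mm^2
  )
  list(mask = mask, truth = truth)
}
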