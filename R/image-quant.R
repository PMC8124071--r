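#' Puncta segmentation configuration
#'
#' @param threshold `"otsu"` for an automatic per-channel Otsu threshold
#'   (computed after background removal), or a single absolute intensity.
#' @param background_radius_px Radius of the disc structuring element used
#'   for morphological (top-hat) background removal; 0 disables it.
#' @param min_area_px,max_area_px Connected-component area filter (px^2).
#' @return List of class `puncta_config`.
#' @export
puncta_config <- function(threshold = "otsu", background_radius_px = 10,
                          min_area_px = 2, max_area_px = 400) {
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1L && threshold > 0))) {
    abort("`threshold` must be \"otsu\" or a positive number")
  }
  check_positive(background_radius_px, "background_radius_px", strict = FALSE)
  if (min_area_px < 1) abort("`min_area_px` must be >= 1")
  structure(list(threshold = threshold,
                 background_radius_px = background_radius_px,
                 min_area_px = min_area_px, max_area_px = max_area_px),
            class = "puncta_config")
}

# 8-connected labelling: 4-connected labels merged across diagonal contacts
label_components8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- EBImage::imageData(lab)
  nl <- max(lab)
  if (nl < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment puncta in one channel
#'
#' Re-implementation of the standard puncta-counting workflow: maximum
#' intensity Z-projection, morphological top-hat background removal (the
#' image minus its grayscale opening with a disc larger than a punctum),
#' thresholding (Otsu by default), binarization, and 8-connected component
#' labelling with an area filter.
#'
#' @param stack A 2D matrix or 3D array `[H, W, Z]` (single channel).
#' @param cfg A [puncta_config()].
#' @return List of class `puncta_seg`: `mask` (binary matrix), `labels`
#'   (integer label matrix), `count`, `threshold` (value applied),
#'   `areas_px` (component areas).
#' @export
segment_puncta <- function(stack, cfg = puncta_config()) {
  img <- if (length(dim(stack)) == 3L) apply(stack, c(1, 2), max) else stack
  if (!all(is.finite(img))) abort("image must be finite")

  if (cfg$background_radius_px > 0) {
    sz <- 2 * ceiling(cfg$background_radius_px) + 1
    brush <- EBImage::makeBrush(sz, shape = "disc")
    bg <- EBImage::opening(EBImage::Image(img), brush)
    img <- img - EBImage::imageData(bg)
    img[img < 0] <- 0
  }

  thr <- if (identical(cfg$threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) <= 0) Inf else {
      norm <- (img - rng[1]) / diff(rng)
      rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
    }
  } else cfg$threshold

  bin <- (img > thr) * 1
  labels <- label_components8(bin)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    bad <- which(areas < cfg$min_area_px | areas > cfg$max_area_px)
    if (length(bad) > 0) {
      labels[labels %in% bad] <- 0L
      keep <- setdiff(seq_along(areas), bad)
      labels[labels > 0] <- match(labels[labels > 0], keep)
      areas <- areas[keep]
    }
  } else areas <- integer()

  structure(list(mask = (labels > 0) * 1L, labels = labels,
                 count = max(labels), threshold = thr,
                 areas_px = areas),
            class = "puncta_seg")
}

#' @export
print.puncta_seg <- function(x, ...) {
  cat(sprintf("<puncta_seg> %d puncta (threshold %.4g, median area %.0f px)\n",
              x$count, x$threshold,
              if (length(x$areas_px)) median(x$areas_px) else NA))
  invisible(x)
}

#' Count colocalized puncta
#'
#' A channel-1 punctum is colocalized when at least `overlap_frac` of its
#' pixels overlap channel-2 foreground. The count can never exceed the
#' punctum count of either channel.
#'
#' @param seg1 Channel-1 segmentation ([segment_puncta()]) or a binary
#'   matrix.
#' @param seg2 Channel-2 segmentation or binary matrix.
#' @param overlap_frac Minimum pixel-overlap fraction, default 0.25.
#' @return Integer count of colocalized puncta.
#' @export
count_colocalized <- function(seg1, seg2, overlap_frac = 0.25) {
  check_proportion(overlap_frac, "overlap_frac")
  lab1 <- if (inherits(seg1, "puncta_seg")) seg1$labels else label_components8((seg1 > 0) * 1)
  fg2 <- if (inherits(seg2, "puncta_seg")) seg2$mask > 0 else seg2 > 0
  if (!all(dim(lab1) == dim(fg2))) abort("channel images must have the same shape")
  n1 <- max(lab1)
  if (n1 == 0L) return(0L)
  idx <- lab1 > 0
  sizes <- tabulate(lab1[idx], nbins = n1)
  overlap <- tabulate(lab1[idx & fg2], nbins = n1)
  n2 <- if (inherits(seg2, "puncta_seg")) seg2$count else max(label_components8(fg2 * 1))
  min(sum(overlap / sizes >= overlap_frac), n2)
}

#' Two-channel puncta analysis
#'
#' Per-channel puncta counts and the colocalized count from a pair of
#' stacks or images (e.g. pre-synaptic marker in channel 1, post-synaptic
#' in channel 2).
#'
#' @param ch1,ch2 Single-channel stacks or images.
#' @param cfg A [puncta_config()] (applied to both channels).
#' @param overlap_frac Colocalization overlap fraction.
#' @return Tibble with `count_ch1`, `count_ch2`, `count_colocalized`,
#'   `coloc_fraction_ch1` (colocalized / channel-1 count).
#' @export
puncta_analysis <- function(ch1, ch2, cfg = puncta_config(),
                            overlap_frac = 0.25) {
  s1 <- segment_puncta(ch1, cfg)
  s2 <- segment_puncta(ch2, cfg)
  nc <- count_colocalized(s1, s2, overlap_frac)
  tibble(count_ch1 = s1$count, count_ch2 = s2$count,
         count_colocalized = as.integer(nc),
         coloc_fraction_ch1 = if (s1$count > 0) nc / s1$count else NA_real_)
}

#' Background-corrected mean fluorescence per area
#'
#' The field-of-view intensity measure
#' `[integrated density - (FOV area x mean background)] / FOV area`,
#' i.e. the mean above-background fluorescence per square micron. Linear in
#' the integrated density and affine in the background, exactly.
#'
#' @param integrated_density Summed signal intensity over the field.
#' @param fov_area_um2 Field-of-view area (um^2), > 0.
#' @param mean_background Mean background intensity.
#' @return Mean background-corrected fluorescence per um^2.
#' @export
mean_fluorescence_per_area <- function(integrated_density, fov_area_um2,
                                       mean_background) {
  check_positive(fov_area_um2, "fov_area_um2")
  (integrated_density - fov_area_um2 * mean_background) / fov_area_um2
}

#' Intensity inputs from an image
#'
#' Convenience helper producing the three inputs of
#' [mean_fluorescence_per_area()] from a single-channel image: integrated
#' density is the sum of above-threshold pixel intensities, the mean
#' background is the mean of below-threshold pixels, and the field area is
#' the full image area in um^2.
#'
#' @param img Numeric matrix.
#' @param threshold Intensity threshold separating signal from background;
#'   `"otsu"` for automatic.
#' @param pixel_size_um Pixel size (um).
#' @return Tibble with `integrated_density`, `fov_area_um2`,
#'   `mean_background`, `mean_fluorescence_per_um2`.
#' @export
intensity_inputs <- function(img, threshold = "otsu", pixel_size_um = 1) {
  check_positive(pixel_size_um, "pixel_size_um")
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) <= 0) Inf
    else rng[1] + EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng))) * diff(rng)
  } else threshold
  sig <- img > thr
  integrated <- sum(img[sig])
  bgm <- if (all(sig)) 0 else mean(img[!sig])
  area <- length(img) * pixel_size_um^2
  tibble(integrated_density = integrated, fov_area_um2 = area,
         mean_background = bgm,
         mean_fluorescence_per_um2 =
           mean_fluorescence_per_area(integrated, area, bgm))
}

#' Organoid morphometry from a binary mask
#'
#' Measures the largest foreground component of a binary mask: surface area
#' (pixel count x pixel area), perimeter (length of the marching-squares
#' half-level contour, which reduces rasterization bias relative to
#' counting pixel edges) and maximum Feret diameter (largest caliper
#' distance across the contour points). Before contouring, the mask is
#' lightly Gaussian-smoothed (`contour_smooth_sigma`, default 1 px): the
#' 0.5-level set of the smoothed mask tracks the true boundary of a smooth
#' shape and removes the systematic staircase over-estimate (~5 percent on
#' a rasterized circle) of the raw binary contour. All results are reported
#' in mm / mm^2. Doubling the pixel size doubles diameter and perimeter and
#' quadruples the area, exactly.
#'
#' @param mask Binary matrix (non-zero = organoid). If several components
#'   are present the largest is kept with a warning.
#' @param pixel_size_um Pixel size (um).
#' @param contour_smooth_sigma Gaussian sigma (px) applied to the mask
#'   before contour tracing; 0 uses the raw binary contour.
#' @return Tibble with `area_mm2`, `perimeter_mm`, `max_diameter_mm` plus
#'   the pixel-unit columns `area_px2`, `perimeter_px`, `max_diameter_px`.
#' @export
organoid_morphometry <- function(mask, pixel_size_um,
                                 contour_smooth_sigma = 1) {
  check_positive(pixel_size_um, "pixel_size_um")
  bin <- (mask > 0) * 1
  if (sum(bin) == 0) abort("empty mask: no foreground component")
  labels <- label_components8(bin)
  if (max(labels) > 1L) {
    warn(sprintf("%d foreground components; keeping the largest", max(labels)))
    areas <- tabulate(labels[labels > 0])
    bin <- (labels == which.max(areas)) * 1
  }
  area_px2 <- sum(bin)

  # marching-squares contour at the 0.5 level; pad so boundary shapes close
  H <- nrow(bin); W <- ncol(bin)
  m <- max(2L, ceiling(3 * contour_smooth_sigma))
  pad <- matrix(0, H + 2 * m, W + 2 * m)
  pad[(m + 1):(H + m), (m + 1):(W + m)] <- bin
  if (contour_smooth_sigma > 0) {
    pad <- EBImage::imageData(EBImage::gblur(EBImage::Image(pad),
                                             contour_smooth_sigma))
  }
  cl <- grDevices::contourLines(x = seq_len(H + 2 * m) - m,
                                y = seq_len(W + 2 * m) - m,
                                z = pad, levels = 0.5)
  if (length(cl) == 0L) abort("could not trace the mask contour")
  len <- vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1))
  main <- cl[[which.max(len)]]
  perimeter_px <- max(len)

  pts <- cbind(main$x, main$y)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  max_diameter_px <- max(d2)

  um_to_mm <- pixel_size_um / 1000
  tibble(area_px2 = area_px2, perimeter_px = perimeter_px,
         max_diameter_px = max_diameter_px,
         area_mm2 = area_px2 * um_to_mm^2,
         perimeter_mm = perimeter_px * um_to_mm,
         max_diameter_mm = max_diameter_px * um_to_mm)
}
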