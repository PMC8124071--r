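# isotropic low-pass in the 2D frequency domain; cutoff as a fraction of the
# spatial Nyquist frequency (0.5 cycles/px). cutoff_frac >= 1 passes
# everything unchanged (the corner frequencies above Nyquist included).
lowpass2d <- function(m, cutoff_frac) {
  if (cutoff_frac >= 1) return(m)
  H <- nrow(m); W <- ncol(m)
  fy <- (seq_len(H) - 1) / H; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(W) - 1) / W; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  keep <- outer(fy^2, fx^2, `+`) <= (cutoff_frac * 0.5)^2
  Re(fft(fft(m) * keep, inverse = TRUE)) / (H * W)
}

#' Cumulative-difference activity map
#'
#' Collapses a movie into a per-pixel activity map: the per-pixel signal is
#' smoothed with a temporal moving average of `smooth_window_s`, the
#' absolute differences of the smoothed signal between frames one window
#' apart are summed over the recording, and the resulting map is low-pass
#' filtered in the 2D Fourier domain to remove pixel-scale noise and
#' clipped at zero. With `smooth_window_s` equal to one frame this is
#' exactly the cumulative absolute first difference between consecutive
#' frames; the default one-second window makes slow-rising transients
#' (whose per-frame increments are below the pixel noise) contribute to the
#' map as well. Active somata appear as smooth bumps on a uniform noise
#' floor; the map is invariant to adding a constant to all frames.
#'
#' @param movie A [ca_movie()].
#' @param cutoff_frac Isotropic low-pass cutoff as a fraction of the spatial
#'   Nyquist frequency, in (0, 1]. Values >= 1 disable filtering.
#' @param smooth_window_s Temporal moving-average window (s); the
#'   difference lag equals the window. Values below one frame disable
#'   smoothing.
#' @return An object of class `activity_map`: list with `values` (H x W
#'   non-negative matrix), `cutoff_frac`, `pixel_size_um`.
#' @export
compute_activity_map <- function(movie, cutoff_frac = 0.2,
                                 smooth_window_s = 1) {
  stopifnot(inherits(movie, "ca_movie"))
  if (!is.numeric(cutoff_frac) || cutoff_frac <= 0) {
    abort("`cutoff_frac` must be > 0")
  }
  d <- dim(movie$frames)
  Tn <- d[3]
  if (Tn < 2L) abort("activity map needs at least 2 frames")
  w <- max(1L, min(round(smooth_window_s * movie$sampling_rate_hz),
                   floor(Tn / 2)))
  acc <- matrix(0, d[1], d[2])
  # running window sums Wa = sum over [t, t+w-1], Wb = sum over [t+w, t+2w-1]
  Wa <- matrix(0, d[1], d[2]); Wb <- matrix(0, d[1], d[2])
  for (t in 1:w) Wa <- Wa + movie$frames[, , t]
  for (t in (w + 1):(2 * w)) Wb <- Wb + movie$frames[, , t]
  acc <- acc + abs(Wb - Wa)
  if (Tn >= 2L * w + 1L) {
    for (t in 1:(Tn - 2L * w)) {
      # shift both windows forward one frame
      Wa <- Wa - movie$frames[, , t] + movie$frames[, , t + w]
      Wb <- Wb - movie$frames[, , t + w] + movie$frames[, , t + 2L * w]
      acc <- acc + abs(Wb - Wa)
    }
  }
  acc <- acc / w
  vals <- lowpass2d(acc, cutoff_frac)
  vals[vals < 0] <- 0
  structure(list(values = vals, cutoff_frac = cutoff_frac,
                 pixel_size_um = movie$pixel_size_um),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %d x %d px, cutoff %.2f x Nyquist, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$cutoff_frac,
              min(x$values), max(x$values)))
  invisible(x)
}

# 8-neighbourhood local maxima (>= all neighbours); returns a logical matrix
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  res <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & m >= pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  res
}

new_roi_set <- function(df, image_dim, radius_px, min_separation_px, max_cells) {
  structure(df, class = c("roi_set", class(tibble())),
            image_dim = image_dim, radius_px = radius_px,
            min_separation_px = min_separation_px, max_cells = max_cells)
}

#' Detect ROIs as local maxima of the activity map
#'
#' Selects local maxima of the activity map above a threshold, keeps them
#' greedily in descending map value with a minimum-separation exclusion
#' (non-maximum suppression; exact ties broken in row-major order), and
#' truncates the set to at most `max_cells` ROIs.
#'
#' The threshold is `median(map) + threshold_frac * (max(map) - median(map))`:
#' relative to the map's dynamic range above its floor, because the
#' cumulative-difference map of a noisy recording sits on a uniform noise
#' floor that grows with recording length (the median estimates that floor;
#' on a clean map with a zero floor this reduces to a fraction of the
#' maximum).
#'
#' @param map An [compute_activity_map()] result (or a plain matrix).
#' @param min_separation_px Minimum center-to-center distance (pixels).
#' @param threshold_frac Detection threshold as a fraction of the map's
#'   dynamic range, in `[0, 1]`.
#' @param max_cells Hard cap on the number of ROIs (default 200 per field
#'   of view).
#' @param radius_px ROI disc radius used later for trace extraction.
#' @return A `roi_set`: tibble with columns `cell_id`, `row`, `col`,
#'   `radius_px`, ordered by descending map value.
#' @export
detect_rois <- function(map, min_separation_px = 12, threshold_frac = 0.10,
                        max_cells = 200, radius_px = 3) {
  vals <- if (inherits(map, "activity_map")) map$values else map
  if (!all(is.finite(vals))) abort("activity map must be finite")
  check_proportion(threshold_frac, "threshold_frac")
  check_positive(max_cells, "max_cells")

  lo <- median(vals); hi <- max(vals)
  empty <- tibble(cell_id = integer(), row = integer(), col = integer(),
                  radius_px = numeric())
  if (hi <= min(vals)) {
    return(new_roi_set(empty, dim(vals), radius_px, min_separation_px, max_cells))
  }
  thr <- lo + threshold_frac * (hi - lo)
  cand <- which(local_maxima(vals) & vals >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(new_roi_set(empty, dim(vals), radius_px, min_separation_px, max_cells))
  }
  v <- vals[cand]
  # descending value; row-major order breaks exact ties
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]

  keep_r <- numeric(0); keep_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    if (length(keep_r) == 0L ||
        min((keep_r - r)^2 + (keep_c - cc)^2) >= min_separation_px^2) {
      keep_r <- c(keep_r, r); keep_c <- c(keep_c, cc)
      if (length(keep_r) >= max_cells) break
    }
  }
  df <- tibble(cell_id = seq_along(keep_r), row = as.integer(keep_r),
               col = as.integer(keep_c), radius_px = radius_px)
  new_roi_set(df, dim(vals), radius_px, min_separation_px, max_cells)
}

#' Manually adjust an ROI set
#'
#' Mirrors the interactive correction step of the original workflow: add
#' missed cells and remove false detections. Removals are matched to the
#' nearest existing center within `tolerance_px`; unmatched removals are
#' reported (warning plus an `edit_errors` attribute), never silently
#' dropped. Additions beyond the `max_cells` cap are rejected with an error.
#'
#' @param rois A `roi_set` from [detect_rois()].
#' @param add Optional tibble/matrix of centers (`row`, `col`) to append.
#' @param remove Optional tibble/matrix of centers to remove.
#' @param tolerance_px Matching tolerance for removals; defaults to the ROI
#'   set's minimum separation.
#' @return The edited `roi_set` (cell ids renumbered).
#' @export
edit_rois <- function(rois, add = NULL, remove = NULL, tolerance_px = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  tol <- tolerance_px %||% attr(rois, "min_separation_px")
  dimg <- attr(rois, "image_dim")
  max_cells <- attr(rois, "max_cells")
  df <- as_tibble(rois)
  errors <- list()

  as_centers <- function(x) {
    m <- as.matrix(as.data.frame(x))
    if (ncol(m) < 2) abort("centers need `row` and `col`")
    colnames(m)[1:2] <- c("row", "col")
    m[, c("row", "col"), drop = FALSE]
  }

  if (!is.null(remove)) {
    for (i in seq_len(nrow(as_centers(remove)))) {
      p <- as_centers(remove)[i, ]
      if (nrow(df) == 0L) {
        errors[[length(errors) + 1L]] <- tibble(op = "remove", row = p[1],
                                                col = p[2], reason = "set is empty")
        next
      }
      d2 <- (df$row - p[1])^2 + (df$col - p[2])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) {
        df <- df[-j, ]
      } else {
        errors[[length(errors) + 1L]] <- tibble(
          op = "remove", row = p[1], col = p[2],
          reason = sprintf("no ROI within %.1f px", tol))
      }
    }
  }
  if (!is.null(add)) {
    ac <- as_centers(add)
    if (any(ac[, 1] < 1 | ac[, 1] > dimg[1] | ac[, 2] < 1 | ac[, 2] > dimg[2])) {
      abort("added centers must lie within image bounds")
    }
    if (nrow(df) + nrow(ac) > max_cells) {
      abort(sprintf("adding %d ROIs would exceed the %d-cell cap", nrow(ac), max_cells))
    }
    df <- dplyr::bind_rows(df, tibble(row = as.integer(ac[, 1]),
                                      col = as.integer(ac[, 2]),
                                      radius_px = attr(rois, "radius_px")))
  }
  df$cell_id <- seq_len(nrow(df))
  df <- df[, c("cell_id", "row", "col", "radius_px")]
  out <- new_roi_set(df, dimg, attr(rois, "radius_px"), tol, max_cells)
  if (length(errors) > 0) {
    err <- dplyr::bind_rows(errors)
    attr(out, "edit_errors") <- err
    warn(sprintf("%d ROI edit(s) could not be applied; see attr(x, 'edit_errors')",
                 nrow(err)))
  }
  out
}

#' Extract per-ROI fluorescence traces
#'
#' For each ROI, the trace is the mean intensity over a fixed-radius disc
#' around its center at every frame. Discs extending past the image edge are
#' clipped with a warning.
#'
#' @param movie A [ca_movie()].
#' @param rois A `roi_set` (or tibble with `cell_id`, `row`, `col`,
#'   `radius_px`).
#' @return A long tibble with columns `cell_id`, `frame`, `time_s`, `f`
#'   (raw fluorescence); attributes `sampling_rate_hz` and `n_frames`.
#'   An empty ROI set yields an empty tibble.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  fs <- movie$sampling_rate_hz
  df <- as_tibble(rois)

  out_tpl <- tibble(cell_id = integer(), frame = integer(),
                    time_s = numeric(), f = numeric())
  if (nrow(df) == 0L) {
    return(structure(out_tpl, sampling_rate_hz = fs, n_frames = Tn))
  }

  fr <- movie$frames
  dim(fr) <- c(H * W, Tn)
  clipped <- FALSE
  traces <- vector("list", nrow(df))
  time_s <- (seq_len(Tn) - 1) / fs
  for (i in seq_len(nrow(df))) {
    r0 <- df$row[i]; c0 <- df$col[i]; rad <- df$radius_px[i]
    R <- floor(rad)
    rr <- (r0 - R):(r0 + R); cc <- (c0 - R):(c0 + R)
    if (any(rr < 1 | rr > H | cc < 1 | cc > W)) clipped <- TRUE
    rr_ok <- rr[rr >= 1 & rr <= H]; cc_ok <- cc[cc >= 1 & cc <= W]
    grid <- expand.grid(r = rr_ok, c = cc_ok)
    grid <- grid[(grid$r - r0)^2 + (grid$c - c0)^2 <= rad^2, ]
    idx <- grid$r + (grid$c - 1L) * H
    tr <- if (length(idx) == 1L) fr[idx, ] else colMeans(fr[idx, , drop = FALSE])
    traces[[i]] <- tibble(cell_id = df$cell_id[i], frame = seq_len(Tn),
                          time_s = time_s, f = tr)
  }
  if (clipped) warn("some ROI discs extend past the image edge and were clipped")
  structure(dplyr::bind_rows(traces), sampling_rate_hz = fs, n_frames = Tn)
}
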