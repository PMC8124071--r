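#' Movie container
#'
#' Lightweight container for a fluorescence time-lapse recording stored as a
#' 3D array (height x width x frames) with its sampling rate and pixel size.
#'
#' @param frames 3D numeric array `[H, W, T]` of intensities.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param pixel_size_um Pixel size (micron per pixel).
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, sampling_rate_hz, pixel_size_um = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3D array [height, width, frames]")
  }
  if (!all(is.finite(frames))) abort("movie intensities must all be finite")
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(frames = frames, sampling_rate_hz = sampling_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %d x %d px, %d frames @ %g Hz (%.1f s), %g um/px\n",
              d[1], d[2], d[3], x$sampling_rate_hz, d[3] / x$sampling_rate_hz,
              x$pixel_size_um))
  invisible(x)
}

#' Simulation configuration for a spontaneous-activity movie
#'
#' Defaults emulate the study conditions the analysis is designed for: a
#' 5-minute recording at 4 Hz of a ~260 x 200 micron field of view, with a
#' mixed population of fast-kinetics cells (neuron-like, onset constant
#' below 2 s), slow-kinetics cells (glia-like, onset constant above 2 s) and
#' silent cells. Per-class parameters (`event_rate_hz`, `tau_on_s`,
#' `tau_off_s`, `amplitude_dff`) are named vectors with entries `fast` and
#' `slow`; `tau_on_s` entries may also be length-2 ranges (per-cell uniform
#' draw) supplied as a list.
#'
#' @param fov_height_px,fov_width_px Field of view size in pixels.
#' @param pixel_size_um Pixel size (micron).
#' @param sampling_rate_hz Sampling rate (Hz), default 4.
#' @param duration_s Duration (s), default 300.
#' @param n_fast_cells,n_slow_cells,n_silent_cells Population counts.
#' @param cell_radius_px Gaussian footprint sigma in pixels (footprint is
#'   truncated at 3 sigma).
#' @param event_rate_hz Per-class mean Poisson event rates (Hz).
#' @param tau_on_s Per-class onset constants (s); fast must stay < 2 s and
#'   slow > 2 s. Scalar per class, or a list of length-2 ranges.
#' @param tau_off_s Per-class mean decay constants (s).
#' @param amplitude_dff Per-class mean peak amplitudes (dF/F0).
#' @param baseline_level Baseline intensity (arbitrary units).
#' @param baseline_drift Fractional slow drift amplitude.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param sync_fraction Fraction of events moved onto shared network-burst
#'   onset frames, in `[0, 1]`.
#' @param min_separation_px Minimum distance between cell centers; default
#'   4 x `cell_radius_px`.
#' @param seed Integer seed for the movie draw.
#' @return A validated list of class `sim_movie_config`.
#' @export
sim_movie_config <- function(fov_height_px = 200, fov_width_px = 256,
                             pixel_size_um = 1,
                             sampling_rate_hz = 4, duration_s = 300,
                             n_fast_cells = 28, n_slow_cells = 56,
                             n_silent_cells = 60, cell_radius_px = 3,
                             event_rate_hz = c(fast = 0.035, slow = 0.025),
                             tau_on_s = c(fast = 1.3, slow = 5.2),
                             tau_off_s = c(fast = 3, slow = 8),
                             amplitude_dff = c(fast = 0.2, slow = 0.3),
                             baseline_level = 100, baseline_drift = 0.05,
                             noise_sd = 2, sync_fraction = 0.4,
                             min_separation_px = 4 * cell_radius_px,
                             seed = NULL) {
  cfg <- list(
    fov_height_px = fov_height_px, fov_width_px = fov_width_px,
    pixel_size_um = pixel_size_um,
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    n_fast_cells = n_fast_cells, n_slow_cells = n_slow_cells,
    n_silent_cells = n_silent_cells, cell_radius_px = cell_radius_px,
    event_rate_hz = event_rate_hz, tau_on_s = tau_on_s,
    tau_off_s = tau_off_s, amplitude_dff = amplitude_dff,
    baseline_level = baseline_level, baseline_drift = baseline_drift,
    noise_sd = noise_sd, sync_fraction = sync_fraction,
    min_separation_px = min_separation_px, seed = seed
  )
  validate_sim_movie_config(cfg)
  structure(cfg, class = "sim_movie_config")
}

class_param <- function(x, class) {
  v <- if (is.list(x)) x[[class]] else unname(x[class])
  if (is.null(v) || anyNA(v)) abort(sprintf("missing '%s' entry in per-class parameter", class))
  v
}

validate_sim_movie_config <- function(cfg) {
  for (f in c("fov_height_px", "fov_width_px", "pixel_size_um",
              "sampling_rate_hz", "duration_s", "cell_radius_px",
              "baseline_level", "min_separation_px")) {
    check_positive(cfg[[f]], f)
  }
  for (f in c("n_fast_cells", "n_slow_cells", "n_silent_cells", "noise_sd",
              "baseline_drift")) {
    check_positive(cfg[[f]], f, strict = FALSE)
  }
  check_proportion(cfg$sync_fraction, "sync_fraction")
  for (f in c("event_rate_hz", "tau_off_s", "amplitude_dff")) {
    check_positive(class_param(cfg[[f]], "fast"), paste0(f, "[fast]"))
    check_positive(class_param(cfg[[f]], "slow"), paste0(f, "[slow]"))
  }
  fast_tau <- class_param(cfg$tau_on_s, "fast")
  slow_tau <- class_param(cfg$tau_on_s, "slow")
  check_positive(fast_tau, "tau_on_s[fast]")
  check_positive(slow_tau, "tau_on_s[slow]")
  if (any(fast_tau >= 2)) abort("fast-class tau_on_s must be < 2 s")
  if (any(slow_tau <= 2)) abort("slow-class tau_on_s must be > 2 s")
  invisible(cfg)
}

# rejection-sample n centers with pairwise min separation and an edge margin
place_centers <- function(n, height, width, margin, min_sep,
                          max_tries_per_cell = 500) {
  if (n == 0L) return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  # 1-based pixel coordinates throughout (R convention)
  lo_r <- 1 + margin; hi_r <- height - margin
  lo_c <- 1 + margin; hi_c <- width - margin
  if (hi_r <= lo_r || hi_c <= lo_c) abort("field of view too small for the cell footprint margin")
  rows <- numeric(n); cols <- numeric(n); placed <- 0L
  tries <- 0L; max_tries <- max_tries_per_cell * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    r <- runif(1, lo_r, hi_r); cc <- runif(1, lo_c, hi_c)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - cc)^2) >= min_sep^2) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- cc
    }
  }
  if (placed < n) {
    abort(sprintf(
      "could not place %d cells at min separation %.1f px in a %d x %d field (placed %d)",
      n, min_sep, height, width, placed))
  }
  cbind(row = round(rows), col = round(cols))
}

# Gaussian soma footprint truncated at 3 sigma, normalised so its mean over
# the ROI-extraction disc (radius = norm_radius) is 1; ROI disc-averaged
# traces are then directly comparable to ground-truth dF/F0 amplitudes
cell_footprint <- function(sigma_px, norm_radius = sigma_px) {
  R <- ceiling(3 * sigma_px)
  off <- -R:R
  d2 <- outer(off^2, off^2, `+`)
  w <- exp(-d2 / (2 * sigma_px^2))
  w[d2 > (3 * sigma_px)^2] <- 0
  roi <- d2 <= norm_radius^2 + 1e-9
  w / mean(w[roi])
}

#' Simulate per-cell event sets with optional synchronized firing
#'
#' Draws Poisson event trains for `n_cells` cells and then moves each event,
#' independently with probability `sync_fraction`, onto one of a small set of
#' shared network-burst onset frames (snapped to the sampling grid). This is
#' the machinery behind [simulate_movie()]'s synchrony ground truth, exposed
#' so the synchrony statistic can be tested without rendering movies.
#'
#' @inheritParams simulate_trace
#' @param n_cells Number of cells.
#' @param sync_fraction Probability that an event is moved to a shared onset
#'   frame.
#' @param burst_rate_hz Rate of the shared network-burst time process (Hz).
#' @param seed Optional seed.
#' @return Tibble with columns `cell_id`, `t0_s`, `tau_on_s`, `tau_off_s`,
#'   `amplitude_dff`, `a`, `synced` (logical).
#' @export
simulate_event_sets <- function(n_cells, duration_s = 300,
                                sampling_rate_hz = 4, event_rate_hz = 0.035,
                                tau_on_s = 1.3, tau_off_s = 3,
                                amplitude_dff = 0.2, sync_fraction = 0,
                                burst_rate_hz = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_proportion(sync_fraction, "sync_fraction")
  per_cell <- purrr::map(seq_len(n_cells), function(i) {
    ev <- draw_events(event_rate_hz, duration_s, tau_on_s, tau_off_s, amplitude_dff)
    ev$synced <- FALSE
    ev$cell_id <- i
    ev
  })
  # the burst-time pool is large enough for every cell's full event train,
  # so sync_fraction = 1 really synchronizes every event
  n_burst <- max(1L, rpois(1L, burst_rate_hz * duration_s),
                 if (n_cells > 0) vapply(per_cell, nrow, integer(1)) else 0L)
  burst_t <- round(runif(n_burst, 0, duration_s) * sampling_rate_hz) / sampling_rate_hz
  per_cell <- purrr::map(per_cell, function(ev) {
    if (nrow(ev) > 0 && sync_fraction > 0) {
      mv <- which(runif(nrow(ev)) < sync_fraction)
      if (length(mv) > 0) {
        # a cell joins each network burst at most once: distinct burst times
        ev$t0_s[mv] <- sample(burst_t, length(mv), replace = FALSE)
        ev$synced[mv] <- TRUE
        ev <- ev[order(ev$t0_s), ]
      }
    }
    ev
  })
  dplyr::bind_rows(per_cell)[, c("cell_id", "t0_s", "tau_on_s", "tau_off_s",
                                 "amplitude_dff", "a", "synced")]
}

# draw a per-cell mean onset constant for one class; spec: scalar mean with
# modest lognormal spread, or an explicit [min, max] range
draw_cell_tau_on <- function(n, spec, side) {
  if (length(spec) == 2L) {
    runif(n, spec[1], spec[2])
  } else {
    v <- spec * exp(rnorm(n, 0, 0.15))
    if (side == "fast") pmin(v, 1.9) else pmax(v, 2.1)
  }
}

#' Simulate a spontaneous-activity movie with full ground truth
#'
#' Renders each cell as an isotropic Gaussian-profile disc (truncated at
#' 3 sigma) whose temporal signal is a superposition of elementary calcium
#' transients on a shared drifting baseline, plus additive Gaussian pixel
#' noise:
#' `F(p, t) = B(t) * (1 + sum_c w_c(p) s_c(t)) + noise`.
#' Silent cells appear in the ground truth but emit no signal (activity-based
#' detection should not find them). Identical `config` and seed give
#' bit-identical movies.
#'
#' @param config A [sim_movie_config()] object.
#' @return A list with `movie` (a [ca_movie()]) and `truth`, itself a list of
#'   `cells` (tibble: `cell_id`, `row`, `col`, `class`, `tau_on_mean_s`,
#'   `n_events`, `event_rate_hz`, `mean_amplitude_dff`) and `events` (per-event
#'   ground truth as in [simulate_event_sets()]).
#' @export
simulate_movie <- function(config = sim_movie_config()) {
  validate_sim_movie_config(config)
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  H <- cfg$fov_height_px; W <- cfg$fov_width_px
  Tn <- floor(cfg$duration_s * cfg$sampling_rate_hz)
  time_s <- (seq_len(Tn) - 1) / cfg$sampling_rate_hz
  n_total <- cfg$n_fast_cells + cfg$n_slow_cells + cfg$n_silent_cells

  sigma <- cfg$cell_radius_px
  margin <- ceiling(3 * sigma)
  centers <- place_centers(n_total, H, W, margin, cfg$min_separation_px)
  classes <- rep(c("FAST", "SLOW", "SILENT"),
                 c(cfg$n_fast_cells, cfg$n_slow_cells, cfg$n_silent_cells))

  tau_on_mean <- rep(NA_real_, n_total)
  fast_idx <- which(classes == "FAST"); slow_idx <- which(classes == "SLOW")
  tau_on_mean[fast_idx] <- draw_cell_tau_on(length(fast_idx),
                                            class_param(cfg$tau_on_s, "fast"), "fast")
  tau_on_mean[slow_idx] <- draw_cell_tau_on(length(slow_idx),
                                            class_param(cfg$tau_on_s, "slow"), "slow")

  drift <- if (cfg$baseline_drift > 0) draw_drift_shape(time_s) else numeric(Tn)
  B_t <- cfg$baseline_level * (1 + cfg$baseline_drift * drift)

  # draw every cell's event train first, so the shared network-burst pool
  # can cover the largest train (sync_fraction = 1 synchronizes everything)
  all_events <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    if (classes[i] == "SILENT") {
      all_events[[i]] <- tibble(t0_s = numeric(), tau_on_s = numeric(),
                                tau_off_s = numeric(),
                                amplitude_dff = numeric(), a = numeric(),
                                synced = logical())
      next
    }
    cls <- tolower(classes[i])
    ev <- draw_events(class_param(cfg$event_rate_hz, cls), cfg$duration_s,
                      tau_on_mean[i], class_param(cfg$tau_off_s, cls),
                      class_param(cfg$amplitude_dff, cls))
    ev$synced <- FALSE
    all_events[[i]] <- ev
  }
  n_burst <- max(1L, rpois(1L, 0.03 * cfg$duration_s),
                 if (n_total > 0) vapply(all_events, nrow, integer(1)) else 0L)
  burst_t <- round(runif(n_burst, 0, cfg$duration_s) * cfg$sampling_rate_hz) /
    cfg$sampling_rate_hz

  frames <- array(0, dim = c(H, W, Tn))
  if (cfg$noise_sd > 0) {
    frames[] <- rnorm(length(frames), 0, cfg$noise_sd)
  }
  frames <- frames + rep(B_t, each = H * W)

  fp <- cell_footprint(sigma)
  R <- (nrow(fp) - 1L) / 2L

  for (i in seq_len(n_total)) {
    ev <- all_events[[i]]
    if (nrow(ev) > 0 && cfg$sync_fraction > 0) {
      mv <- which(runif(nrow(ev)) < cfg$sync_fraction)
      if (length(mv) > 0) {
        # a cell joins each network burst at most once: distinct burst times
        ev$t0_s[mv] <- sample(burst_t, length(mv), replace = FALSE)
        ev$synced[mv] <- TRUE
        ev <- ev[order(ev$t0_s), ]
      }
    }
    if (nrow(ev) > 0) {
      s_t <- events_to_dff(ev, time_s)
      r0 <- centers[i, "row"]; c0 <- centers[i, "col"]
      rows <- (r0 - R):(r0 + R)
      cols <- (c0 - R):(c0 + R)
      add <- outer(as.vector(fp), B_t * s_t)
      dim(add) <- c(length(rows), length(cols), Tn)
      frames[rows, cols, ] <- frames[rows, cols, ] + add
    }
    ev$cell_id <- i
    all_events[[i]] <- ev[, c("cell_id", "t0_s", "tau_on_s", "tau_off_s",
                              "amplitude_dff", "a", "synced"), drop = FALSE]
  }
  events <- dplyr::bind_rows(all_events)

  cells <- tibble(
    cell_id = seq_len(n_total),
    row = as.integer(centers[, "row"]), col = as.integer(centers[, "col"]),
    class = classes, tau_on_mean_s = tau_on_mean,
    n_events = vapply(all_events, nrow, integer(1)),
    event_rate_hz = vapply(all_events, nrow, integer(1)) / cfg$duration_s,
    mean_amplitude_dff = vapply(all_events, function(e) {
      if (nrow(e) == 0) NA_real_ else mean(e$amplitude_dff)
    }, numeric(1))
  )

  list(movie = ca_movie(frames, cfg$sampling_rate_hz, cfg$pixel_size_um),
       truth = list(cells = cells, events = events, config = cfg))
}
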