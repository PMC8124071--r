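#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Writes a movie or image stack as a 32-bit float multi-page TIFF. Because
#' the TIFF container stores samples in `[0, 1]`, values are shifted by the
#' (negative) minimum and divided by a power-of-two scale, both recorded in
#' a `<path>.json` sidecar together with the sampling rate and pixel size;
#' power-of-two scaling is exact in binary floating point, so
#' [read_stack()] restores the data at full float32 precision.
#'
#' @param x A [ca_movie()], a 3D array `[H, W, T]`, or a matrix.
#' @param path Output TIFF path.
#' @param sampling_rate_hz,pixel_size_um Metadata for the sidecar (taken
#'   from a `ca_movie` automatically).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, sampling_rate_hz = NULL, pixel_size_um = NULL) {
  if (inherits(x, "ca_movie")) {
    sampling_rate_hz <- sampling_rate_hz %||% x$sampling_rate_hz
    pixel_size_um <- pixel_size_um %||% x$pixel_size_um
    x <- x$frames
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  offset <- min(0, min(x))
  mx <- max(x) - offset
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  pages <- lapply(seq_len(dim(x)[3]), function(t) (x[, , t] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(scale = scale, offset = offset,
                  sampling_rate_hz = sampling_rate_hz,
                  pixel_size_um = pixel_size_um,
                  n_frames = dim(x)[3])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()] (or any TIFF)
#'
#' Reads a multi-page TIFF into a [ca_movie()]. If a `<path>.json` sidecar
#' is present, the stored scale/offset and acquisition metadata are
#' applied; otherwise intensities are used as stored and the sampling rate
#' must be supplied.
#'
#' @param path TIFF path.
#' @param sampling_rate_hz,pixel_size_um Overrides / fallbacks when no
#'   sidecar exists.
#' @return A [ca_movie()] (possibly with a single frame; stages that need
#'   time series reject single-frame movies themselves).
#' @export
read_stack <- function(path, sampling_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      abort(sprintf("unreadable TIFF %s: %s", path, conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) abort(sprintf("no pages in %s", path))
  scale <- 1; offset <- 0
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    scale <- side$scale %||% 1
    offset <- side$offset %||% 0
    sampling_rate_hz <- sampling_rate_hz %||% side$sampling_rate_hz
    pixel_size_um <- pixel_size_um %||% side$pixel_size_um
  }
  if (is.null(sampling_rate_hz)) {
    abort("no sampling rate: pass `sampling_rate_hz` or provide a sidecar")
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  frames <- array(0, dim = c(H, W, length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * scale + offset
  ca_movie(frames, sampling_rate_hz, pixel_size_um %||% 1)
}

pipeline_defaults <- function() {
  list(
    sampling_rate_hz = 4, pixel_size_um = 1,
    cutoff_frac = 0.2, min_separation_px = 12, threshold_frac = 0.10,
    max_cells = 200, roi_radius_px = 3,
    baseline_method = "percentile", baseline_window_s = 60,
    baseline_prob = 0.1,
    smooth_window_s = 0.75, amplitude_threshold_frac = 0.01,
    min_event_duration_s = 0.5, slope_eps = 0.004, noise_mult = 6,
    min_event_separation_s = 1.5,
    tau_star_s = 2, sync_bin_s = 0.25,
    responder_threshold_dff = 0.05,
    puncta_threshold = "otsu", puncta_background_radius_px = 10,
    puncta_min_area_px = 2, puncta_max_area_px = 400, overlap_frac = 0.25,
    seed = NULL
  )
}

#' Pipeline configuration
#'
#' Every tunable of the analysis stages with its default: activity-map
#' cutoff, ROI detection and cap (`max_cells = 200` per field of view),
#' baseline estimation, event detection (`amplitude_threshold_frac = 0.01`,
#' the 1 percent-of-baseline rule), classification (`tau_star_s = 2`),
#' synchrony binning, evoked-response threshold and puncta settings.
#' Unknown keys are rejected; the configuration serializes losslessly to
#' JSON ([save_config()] / [load_config()]).
#'
#' @param ... Named overrides of the defaults (see [load_config()] for the
#'   full list).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  for (f in c("sampling_rate_hz", "pixel_size_um", "cutoff_frac",
              "min_separation_px", "max_cells", "roi_radius_px",
              "baseline_window_s", "smooth_window_s",
              "amplitude_threshold_frac", "min_event_duration_s",
              "slope_eps", "min_event_separation_s", "tau_star_s", "sync_bin_s",
              "responder_threshold_dff", "puncta_background_radius_px",
              "puncta_min_area_px", "puncta_max_area_px")) {
    check_positive(cfg[[f]], f)
  }
  check_positive(cfg$noise_mult, "noise_mult", strict = FALSE)
  check_proportion(cfg$threshold_frac, "threshold_frac")
  check_proportion(cfg$baseline_prob, "baseline_prob")
  check_proportion(cfg$overlap_frac, "overlap_frac")
  if (!cfg$baseline_method %in% c("percentile", "polynomial")) {
    abort("baseline_method must be 'percentile' or 'polynomial'")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from JSON (or the defaults)
#'
#' @param path JSON file of overrides, or `NULL` for the documented
#'   defaults.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, over)
}

#' Save a pipeline configuration as JSON
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Run the spontaneous-activity pipeline end to end
#'
#' Full analysis chain for one recording: activity map, ROI detection,
#' trace extraction, dF/F0 normalization, event detection and two-step
#' model fitting, per-cell summaries, FAST/SLOW classification and the
#' field-of-view summary. Deterministic given the same movie and
#' configuration (no hidden randomness in analysis stages); every
#' threshold applied and the record counts surviving each stage are
#' reported in the `log` element.
#'
#' @param movie A [ca_movie()] or a TIFF path readable by [read_stack()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, results are
#'   written via [write_results()].
#' @return A list of class `spontaneous_result`: `rois`, `traces`,
#'   `events`, `cells`, `summary` (a `fov_summary`), `config`,
#'   `config_hash`, `log` (character vector of stage messages).
#' @export
run_spontaneous_pipeline <- function(movie, config = pipeline_config(),
                                     out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(movie)) {
    movie <- read_stack(movie, config$sampling_rate_hz, config$pixel_size_um)
  }
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  if (d[3] < 2L) abort("spontaneous pipeline needs at least 2 frames")
  logline <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logline <<- c(logline, msg)
    message("[calciphen] ", msg)
  }
  duration_s <- d[3] / movie$sampling_rate_hz
  say("movie %d x %d px, %d frames (%.1f s at %g Hz)", d[1], d[2], d[3],
      duration_s, movie$sampling_rate_hz)

  amap <- compute_activity_map(movie, config$cutoff_frac)
  say("activity map computed (cutoff %.2f x Nyquist)", config$cutoff_frac)

  rois <- detect_rois(amap, config$min_separation_px, config$threshold_frac,
                      config$max_cells, config$roi_radius_px)
  say("detected %d ROIs (threshold %.2f of map range, min separation %g px, cap %d)",
      nrow(rois), config$threshold_frac, config$min_separation_px,
      config$max_cells)

  traces <- extract_traces(movie, rois)
  traces <- normalize_dff(traces, config$baseline_method,
                          config$baseline_window_s, config$baseline_prob)
  say("extracted and normalized %d traces (%s baseline)", nrow(rois),
      config$baseline_method)

  ecfg <- event_config(
    smooth_window_s = config$smooth_window_s,
    amplitude_threshold_frac = config$amplitude_threshold_frac,
    min_event_duration_s = config$min_event_duration_s,
    slope_eps = config$slope_eps, noise_mult = config$noise_mult,
    min_event_separation_s = config$min_event_separation_s)
  events <- fit_events(traces, ecfg)
  say("fitted %d events (%d converged; amplitude floor %.3g dF/F0)",
      nrow(events), sum(events$converged), config$amplitude_threshold_frac)

  cells <- summarize_cells(events, duration_s, cell_ids = rois$cell_id)
  ccfg <- class_config(config$tau_star_s, config$sync_bin_s)
  cells <- classify_fast_slow(cells, ccfg)
  summary <- summarize_fov(cells, events, ccfg)
  say("classification at tau* = %g s: %d FAST, %d SLOW, %d INACTIVE",
      config$tau_star_s, sum(cells$class == "FAST"),
      sum(cells$class == "SLOW"), sum(cells$class == "INACTIVE"))

  res <- structure(list(rois = rois, traces = traces, events = events,
                        cells = cells, summary = summary, config = config,
                        config_hash = config_hash(config), log = logline),
                   class = "spontaneous_result")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.spontaneous_result <- function(x, ...) {
  cat("<spontaneous_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes the event and cell tables as CSV and the field summary, stage
#' log and configuration echo as JSON. Every file embeds the configuration
#' hash (CSVs as a leading `#` comment line; read back with
#' `read.csv(..., comment.char = "#")`).
#'
#' @param results A `spontaneous_result` (or a named list of data frames).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  paths <- character()
  hash <- if (inherits(results, "spontaneous_result")) results$config_hash
          else config_hash(results)

  write_table <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash: %s", hash), con)
    write.csv(df, con, row.names = FALSE)
    paths <<- c(paths, p)
  }

  if (inherits(results, "spontaneous_result")) {
    write_table(as.data.frame(results$events), "events.csv")
    write_table(as.data.frame(results$cells), "cells.csv")
    write_table(as.data.frame(results$rois), "rois.csv")
    summary <- list(
      config_hash = hash,
      package_version = as.character(utils::packageVersion("calciphen")),
      counts = as.list(results$summary$counts),
      by_class = results$summary$by_class,
      log = results$log,
      config = unclass(results$config))
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    paths <- c(paths, p)
  } else {
    for (nm in names(results)) {
      write_table(as.data.frame(results[[nm]]), paste0(nm, ".csv"))
    }
  }
  invisible(paths)
}
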