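#' Classification configuration
#'
#' @param tau_star_s Rise-time threshold (s) separating FAST from SLOW
#'   active cells; 2 s distinguishes neuron-like fast onsets from
#'   glia-like slow calcium signals.
#' @param sync_bin_s Time-bin width (s) used to call two events
#'   simultaneous; defaults to one frame at 4 Hz.
#' @return List of class `class_config`.
#' @export
class_config <- function(tau_star_s = 2, sync_bin_s = 0.25) {
  check_positive(tau_star_s, "tau_star_s")
  check_positive(sync_bin_s, "sync_bin_s")
  structure(list(tau_star_s = tau_star_s, sync_bin_s = sync_bin_s),
            class = "class_config")
}

#' Classify active cells as FAST or SLOW
#'
#' Cells whose mean rise time (the mean fitted onset constant) is strictly
#' below the threshold `tau_star_s` are FAST; cells at or above the
#' threshold are SLOW. INACTIVE records are left unchanged. FAST cells are
#' interpreted as neuron-like signals, SLOW cells as glia-like or
#' store-release signals.
#'
#' @param records Cell-record tibble from [summarize_cells()].
#' @param cfg A [class_config()].
#' @return `records` with the `class` column filled with
#'   `"FAST"` / `"SLOW"` / `"INACTIVE"`.
#' @export
classify_fast_slow <- function(records, cfg = class_config()) {
  stopifnot(all(c("mean_rise_time_s", "class") %in% names(records)))
  dplyr::mutate(records, class = dplyr::case_when(
    .data$class == "INACTIVE" ~ "INACTIVE",
    !is.finite(.data$mean_rise_time_s) ~ "UNCLASSIFIED",
    .data$mean_rise_time_s < cfg$tau_star_s ~ "FAST",
    TRUE ~ "SLOW"
  ))
}

#' Network synchrony index
#'
#' Fraction of events that are simultaneous with an event of another cell:
#' all event onsets are binned at `sync_bin_s`; an event counts as
#' simultaneous if at least two distinct cells have an onset in its bin.
#' The index lies in `[0, 1]` and equals 1 when all cells fire in shared
#' bins. With fewer than two cells having at least one event the index is
#' undefined and `NA` is returned with a warning (such fields are excluded
#' from group statistics).
#'
#' @param events Tibble with `cell_id` and `t0_s` columns (fitted events or
#'   ground truth).
#' @param sync_bin_s Bin width (s).
#' @return Single numeric index in `[0, 1]`, or `NA` when undefined.
#' @export
synchrony_index <- function(events, sync_bin_s = 0.25) {
  check_positive(sync_bin_s, "sync_bin_s")
  ev <- events[!is.na(events$t0_s), , drop = FALSE]
  if (nrow(ev) == 0L || length(unique(ev$cell_id)) < 2L) {
    warn("synchrony undefined: fewer than 2 cells with events")
    return(NA_real_)
  }
  bin <- floor(ev$t0_s / sync_bin_s)
  cells_per_bin <- tapply(ev$cell_id, bin, function(x) length(unique(x)))
  shared_bins <- as.numeric(names(cells_per_bin)[cells_per_bin >= 2L])
  mean(bin %in% shared_bins)
}

#' Summarize one field of view
#'
#' Population counts and class-wise statistics for one recording: total and
#' active cell counts, FAST/SLOW counts, and per-class mean amplitude, mean
#' event rate and synchrony index (synchrony computed within each class
#' separately).
#'
#' @param records Classified cell records ([classify_fast_slow()]).
#' @param events Fitted events ([fit_events()]); used for the synchrony
#'   index.
#' @param cfg A [class_config()].
#' @param n_total Total number of cells in the field; defaults to
#'   `nrow(records)` (when detection only returns active cells, pass the
#'   independently counted total).
#' @return An object of class `fov_summary`: list with `counts`
#'   (n_total / n_active / n_fast / n_slow) and `by_class` tibble
#'   (`class`, `n`, `mean_amplitude`, `mean_event_rate_hz`, `synchrony`).
#'   Supports [tidy()] and [glance()].
#' @export
summarize_fov <- function(records, events = NULL, cfg = class_config(),
                          n_total = NULL) {
  stopifnot("class" %in% names(records))
  n_tot <- n_total %||% nrow(records)
  n_active <- sum(records$class != "INACTIVE")
  n_fast <- sum(records$class == "FAST")
  n_slow <- sum(records$class == "SLOW")
  stopifnot(n_fast + n_slow <= n_active, n_active <= n_tot)

  by_class <- purrr::map_dfr(c("FAST", "SLOW"), function(cl) {
    rec <- records[records$class == cl, , drop = FALSE]
    sync <- NA_real_
    if (!is.null(events) && nrow(rec) > 0) {
      ev <- events[events$cell_id %in% rec$cell_id & events$converged, ,
                   drop = FALSE]
      if (length(unique(ev$cell_id)) >= 2L) {
        sync <- synchrony_index(ev, cfg$sync_bin_s)
      }
    }
    tibble(class = cl, n = nrow(rec),
           mean_amplitude = if (nrow(rec)) mean(rec$mean_amplitude) else NA_real_,
           mean_event_rate_hz = if (nrow(rec)) mean(rec$event_rate_hz) else NA_real_,
           synchrony = sync)
  })
  structure(list(counts = c(n_total = n_tot, n_active = n_active,
                            n_fast = n_fast, n_slow = n_slow),
                 by_class = by_class),
            class = "fov_summary")
}

#' @export
print.fov_summary <- function(x, ...) {
  cat(sprintf("<fov_summary> total %d | active %d (FAST %d, SLOW %d)\n",
              x$counts["n_total"], x$counts["n_active"],
              x$counts["n_fast"], x$counts["n_slow"]))
  print(x$by_class)
  invisible(x)
}

#' @export
tidy.fov_summary <- function(x, ...) x$by_class

#' @export
glance.fov_summary <- function(x, ...) {
  tibble(n_total = unname(x$counts["n_total"]),
         n_active = unname(x$counts["n_active"]),
         n_fast = unname(x$counts["n_fast"]),
         n_slow = unname(x$counts["n_slow"]))
}

#' Quantify agonist-evoked responses
#'
#' For each cell, the basal fluorescence `F0` is the mean raw fluorescence
#' over the pre-puff window, and the response is `(F - F0) / F0`; the peak
#' response is taken over the post-puff window. A cell is a responder if
#' its peak response reaches `responder_threshold_dff`. The quantity is
#' invariant to rescaling the raw trace by a positive constant. Defaults
#' mirror the evoked protocol (1 Hz sampling, 15 min recording, 5 min
#' pre-puff baseline).
#'
#' @param traces Tibble with `cell_id`, `time_s`, `f` (raw fluorescence).
#' @param puff_time_s Agonist application time (s).
#' @param pre_window_s Length of the pre-puff baseline window (s),
#'   default 300 (5 min).
#' @param responder_threshold_dff Peak `(F - F0)/F0` needed to call a cell
#'   a responder.
#' @return An `evoked_result`: tibble with `cell_id`, `f0`,
#'   `peak_response`, `responder`; attribute `responder_fraction` (also via
#'   [glance()]).
#' @export
evoked_response <- function(traces, puff_time_s, pre_window_s = 300,
                            responder_threshold_dff = 0.05) {
  stopifnot(all(c("cell_id", "time_s", "f") %in% names(traces)))
  check_positive(pre_window_s, "pre_window_s")
  if (puff_time_s <= 0 || puff_time_s > max(traces$time_s)) {
    abort("`puff_time_s` must lie within the recording")
  }
  res <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      pre <- d$f[d$time_s < puff_time_s & d$time_s >= puff_time_s - pre_window_s]
      if (length(pre) == 0L) abort("empty pre-puff window")
      f0 <- mean(pre)
      if (f0 <= 0) {
        abort(sprintf("cell %s: basal fluorescence F0 <= 0", key$cell_id))
      }
      post <- d$f[d$time_s >= puff_time_s]
      tibble(f0 = f0, peak_response = max((post - f0) / f0))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(responder = .data$peak_response >= responder_threshold_dff)
  structure(res, responder_fraction = mean(res$responder),
            class = c("evoked_result", class(res)))
}

#' @export
glance.evoked_result <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_responders = sum(x$responder),
         responder_fraction = attr(x, "responder_fraction", exact = TRUE),
         mean_peak_response = mean(x$peak_response))
}

#' Compare two groups of per-FOV metrics
#'
#' Thin statistical reporting layer for genotype comparisons. For each
#' metric column present in both groups: Shapiro-Wilk normality on each
#' group; a two-sided Mann-Whitney (Wilcoxon rank-sum) test when either
#' group departs from normality (p < 0.05), otherwise Student's t test; a
#' Kolmogorov-Smirnov test on the two empirical distributions. Metrics with
#' fewer than 3 observations in either group are skipped with a notice.
#'
#' @param group_a,group_b Data frames of per-FOV (or per-cell) metric
#'   values; shared numeric columns are compared.
#' @param metrics Optional character vector restricting the metrics.
#' @param labels Length-2 group labels used in the report.
#' @return A `phenotype_comparison` object; [tidy()] returns one row per
#'   metric with `n_a`, `n_b`, means, the test used, `p_value` and `ks_p`.
#' @export
compare_groups <- function(group_a, group_b, metrics = NULL,
                           labels = c("A", "B")) {
  num_cols <- function(d) names(d)[vapply(d, is.numeric, logical(1))]
  shared <- intersect(num_cols(group_a), num_cols(group_b))
  metrics <- metrics %||% shared
  metrics <- intersect(metrics, shared)
  if (length(metrics) == 0L) abort("no shared numeric metrics to compare")

  skipped <- character()
  rows <- purrr::map(metrics, function(m) {
    a <- group_a[[m]]; b <- group_b[[m]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3L || length(b) < 3L) {
      skipped <<- c(skipped, m)
      return(NULL)
    }
    sw_a <- tryCatch(shapiro.test(a)$p.value, error = function(e) NA_real_)
    sw_b <- tryCatch(shapiro.test(b)$p.value, error = function(e) NA_real_)
    normal <- is.finite(sw_a) && is.finite(sw_b) && sw_a >= 0.05 && sw_b >= 0.05
    if (normal) {
      tst <- t.test(a, b)
      test_used <- "t"
    } else {
      tst <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      test_used <- "mann-whitney"
    }
    ks <- suppressWarnings(ks.test(a, b))
    tibble(metric = m, n_a = length(a), n_b = length(b),
           mean_a = mean(a), mean_b = mean(b),
           direction = ifelse(mean(b) > mean(a), paste(labels[2], ">", labels[1]),
                              paste(labels[2], "<=", labels[1])),
           shapiro_p_a = sw_a, shapiro_p_b = sw_b,
           test = test_used, statistic = unname(tst$statistic),
           p_value = tst$p.value, ks_statistic = unname(ks$statistic),
           ks_p = ks$p.value)
  })
  if (length(skipped) > 0) {
    warn(paste("skipped (n < 3):", paste(skipped, collapse = ", ")))
  }
  structure(list(table = dplyr::bind_rows(rows), labels = labels,
                 skipped = skipped),
            class = "phenotype_comparison")
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat(sprintf("<phenotype_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  print(x$table)
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.phenotype_comparison <- function(x, ...) x$table

#' @export
glance.phenotype_comparison <- function(x, ...) {
  tibble(n_metrics = nrow(x$table), n_skipped = length(x$skipped),
         n_significant = sum(x$table$p_value < 0.05))
}
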