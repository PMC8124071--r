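# shared fixture builders (everything generated in code at test time)

# single-cell trace as the long tibble the trace verbs expect
trace_df <- function(tr, cell_id = 1L, fs = 4) {
  df <- tibble::tibble(cell_id = cell_id, time_s = tr$time_s, f = tr$raw)
  attr(df, "sampling_rate_hz") <- fs
  df
}

# noiseless single-transient trace with fixed kinetics
single_event_trace <- function(peak, tau_on = 1, tau_off = 5, t0 = 60,
                               duration_s = 120, seed = 1) {
  simulate_trace(duration_s = duration_s, event_times_s = t0,
                 tau_on_s = tau_on, tau_off_s = tau_off, amplitude_dff = peak,
                 tau_jitter = 0, amp_jitter = 0, baseline_drift = 0,
                 noise_sd = 0, seed = seed)
}

# match each truth center to its nearest ROI; returns distances
nearest_roi_dist <- function(rois, centers) {
  vapply(seq_len(nrow(centers)), function(i) {
    sqrt(min((rois$row - centers$row[i])^2 + (rois$col - centers$col[i])^2))
  }, numeric(1))
}

# small standard movie used by several detection tests
small_movie <- function(seed = 42, noise_sd = 2) {
  cfg <- sim_movie_config(
    fov_height_px = 120, fov_width_px = 120,
    n_fast_cells = 6, n_slow_cells = 6, n_silent_cells = 4,
    duration_s = 120, noise_sd = noise_sd, seed = seed)
  simulate_movie(cfg)
}
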