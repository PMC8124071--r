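# rolling-window quantile with shrinking edge windows
rolling_quantile <- function(x, width, prob) {
  n <- length(x)
  h <- max(1L, floor(width / 2))
  vapply(seq_len(n), function(i) {
    quantile(x[max(1L, i - h):min(n, i + h)], prob, names = FALSE)
  }, numeric(1))
}

# low-envelope polynomial baseline: iterative trimmed least squares
poly_baseline <- function(x, t, degree = 3) {
  keep <- rep(TRUE, length(x))
  fit <- NULL
  for (it in 1:3) {
    fit <- lm(x ~ poly(t, degree), subset = keep)
    res <- x - predict(fit, newdata = data.frame(t = t))
    keep <- res < quantile(res, 0.6)
  }
  predict(fit, newdata = data.frame(t = t))
}

#' Normalize raw traces to dF/F0
#'
#' Estimates a slowly varying baseline `F0(t)` for each cell and computes
#' `dff = (F - F0) / F0`. Two estimators are available: a rolling
#' low-percentile window (default: 10th percentile over 60 s, wide enough
#' that slow ~30 s transients do not drag the percentile up), robust to
#' sparse transients riding on a drifting baseline, and an iteratively
#' trimmed low-order polynomial. dF/F0 is invariant to rescaling the raw
#' trace by a positive constant.
#'
#' @param traces Long tibble from [extract_traces()] (columns `cell_id`,
#'   `time_s`, `f`), or any tibble with those columns.
#' @param method `"percentile"` or `"polynomial"`.
#' @param window_s Rolling window width (s) for the percentile estimator.
#' @param prob Percentile (0-1) for the percentile estimator.
#' @param degree Polynomial degree for the polynomial estimator.
#' @return The input tibble with `baseline` and `dff` columns added.
#' @export
normalize_dff <- function(traces, method = c("percentile", "polynomial"),
                          window_s = 60, prob = 0.1, degree = 3) {
  method <- match.arg(method)
  stopifnot(all(c("cell_id", "time_s", "f") %in% names(traces)))
  fs <- trace_fs(traces)
  out <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) abort("traces need at least 3 samples")
      if (any(d$f <= 0)) {
        abort(sprintf("cell %s: raw fluorescence must be positive", key$cell_id))
      }
      f0 <- switch(method,
        percentile = rolling_quantile(d$f, round(window_s * fs), prob),
        polynomial = poly_baseline(d$f, d$time_s, degree)
      )
      if (any(f0 <= 0)) {
        abort(sprintf("cell %s: baseline estimate non-positive (min %.3g); raw trace unsuitable for dF/F0",
                      key$cell_id, min(f0)))
      }
      d$baseline <- f0
      d$dff <- (d$f - f0) / f0
      d
    }) |>
    dplyr::ungroup()
  structure(out, sampling_rate_hz = fs,
            n_frames = attr(traces, "n_frames", exact = TRUE))
}

# sampling rate from attribute or the time grid
trace_fs <- function(traces) {
  fs <- attr(traces, "sampling_rate_hz", exact = TRUE)
  if (!is.null(fs)) return(fs)
  ts <- sort(unique(traces$time_s))
  if (length(ts) < 2L) abort("cannot infer sampling rate from a single time point")
  1 / median(diff(ts))
}

#' Centered moving-average smoothing
#'
#' Moving average with a centered window; at the edges the window shrinks
#' symmetrically so the output has the same length as the input. The window
#' is used as `2 * floor(window_samples / 2) + 1` samples (nearest odd
#' width); a width of 1 is the identity.
#'
#' @param x Numeric vector.
#' @param window_samples Window width in samples (>= 1, at most `length(x)`).
#' @return Smoothed vector, same length as `x`.
#' @export
smooth_trace <- function(x, window_samples) {
  n <- length(x)
  w <- as.integer(window_samples)
  if (w < 1L) abort("`window_samples` must be >= 1")
  if (w > n) abort("smoothing window longer than the trace")
  h <- floor(w / 2)
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Event-detection configuration
#'
#' Tunable parameters of the transient-detection rules.
#'
#' @param smooth_window_s Moving-average width (s) applied before detection.
#' @param amplitude_threshold_frac Peak-amplitude threshold as a fraction of
#'   the baseline, i.e. a dF/F0 floor; 0.01 is the 1 percent-of-baseline
#'   rule.
#' @param min_event_duration_s Minimum onset-to-offset interval (s).
#' @param slope_eps Minimum positive slope of the smoothed trace
#'   (dF/F0 per s) for an onset.
#' @param noise_mult The amplitude threshold actually applied is
#'   `max(amplitude_threshold_frac, noise_mult * sigma_s)` where `sigma_s`
#'   is the estimated noise SD of the smoothed trace; on noiseless traces
#'   this reduces exactly to the fractional rule. The default (6) keeps the
#'   expected number of noise-triggered events per 200-cell recording below
#'   one; set to 0 to disable the adaptive floor.
#' @param fit_pad_s Seconds of pre-onset samples included in the onset fit
#'   window.
#' @param max_fit_window_s Cap on the full-transient fit window (s).
#' @param min_event_separation_s Fitted events with onsets closer than this
#'   (s) are merged onto the larger-amplitude one; suppresses splinter fits
#'   of a single transient.
#' @param tau_bounds Lower/upper bounds (s) for fitted time constants.
#' @param max_restarts Jittered restarts on fit failure.
#' @return A list of class `event_config`.
#' @export
event_config <- function(smooth_window_s = 0.75,
                         amplitude_threshold_frac = 0.01,
                         min_event_duration_s = 0.5,
                         slope_eps = 0.004,
                         noise_mult = 6,
                         fit_pad_s = 1.5,
                         max_fit_window_s = 60,
                         min_event_separation_s = 1.5,
                         tau_bounds = c(0.05, 60),
                         max_restarts = 3) {
  check_positive(smooth_window_s, "smooth_window_s")
  check_positive(amplitude_threshold_frac, "amplitude_threshold_frac")
  check_positive(min_event_duration_s, "min_event_duration_s")
  check_positive(slope_eps, "slope_eps")
  check_positive(noise_mult, "noise_mult", strict = FALSE)
  structure(list(smooth_window_s = smooth_window_s,
                 amplitude_threshold_frac = amplitude_threshold_frac,
                 min_event_duration_s = min_event_duration_s,
                 slope_eps = slope_eps, noise_mult = noise_mult,
                 fit_pad_s = fit_pad_s, max_fit_window_s = max_fit_window_s,
                 min_event_separation_s = min_event_separation_s,
                 tau_bounds = tau_bounds, max_restarts = max_restarts),
            class = "event_config")
}

# central-difference slope (dF/F0 per second)
trace_slope <- function(s, fs) {
  n <- length(s)
  sl <- numeric(n)
  if (n >= 3L) sl[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2 * fs
  sl[1] <- (s[2] - s[1]) * fs
  sl[n] <- (s[n] - s[n - 1]) * fs
  sl
}

# one-cell candidate detection on a normalized dff vector; returns indices
detect_events_one <- function(dff, fs, cfg) {
  n <- length(dff)
  win <- max(1L, 2L * floor(round(cfg$smooth_window_s * fs) / 2) + 1L)
  win <- min(win, n)
  s <- smooth_trace(dff, win)
  sigma_raw <- mad(diff(dff)) / sqrt(2)
  sigma_s <- sigma_raw / sqrt(win)
  amp_thr <- max(cfg$amplitude_threshold_frac, cfg$noise_mult * sigma_s)
  slope <- smooth_trace(trace_slope(s, fs), win)

  rising <- slope > cfg$slope_eps
  onsets <- integer(); peaks <- integer(); amps <- numeric(); bases <- numeric()
  i <- 2L
  while (i <= n) {
    if (rising[i] && !rising[i - 1L]) {
      onset <- i - 1L
      # advance to the end of the event: slope negative for 2 consecutive samples
      k <- i
      while (k < n && !(slope[k] < 0 && (k == n || slope[min(k + 1L, n)] < 0))) {
        k <- k + 1L
      }
      peak <- onset + which.max(s[onset:k]) - 1L
      amp <- s[peak] - s[onset]
      dur <- (peak - onset) / fs
      if (dur >= cfg$min_event_duration_s && amp >= amp_thr) {
        onsets <- c(onsets, onset); peaks <- c(peaks, peak)
        amps <- c(amps, amp); bases <- c(bases, s[onset])
      }
      i <- max(peak, i) + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble(onset_idx = onsets, peak_idx = peaks,
         onset_time_s = (onsets - 1) / fs, peak_time_s = (peaks - 1) / fs,
         amplitude_smoothed = amps, pre_onset_level = bases,
         amp_threshold = amp_thr)
}

#' Detect putative calcium-transient onsets
#'
#' Applies the onset/offset rules to each cell's normalized, smoothed trace:
#' an onset opens where the smoothed dF/F0 slope exceeds `slope_eps`; the
#' offset is where the slope turns negative (the local peak); the candidate
#' is kept only if the onset-to-offset interval reaches
#' `min_event_duration_s` and the local peak amplitude (relative to the
#' pre-onset level) reaches the amplitude threshold. Detection is invariant
#' to multiplying the raw trace by a positive constant, and the candidate
#' count is non-increasing in the amplitude threshold.
#'
#' @param traces Tibble with `cell_id`, `time_s`, `dff` (from
#'   [normalize_dff()]).
#' @param cfg An [event_config()].
#' @return Tibble of candidates: `cell_id`, `onset_idx`, `peak_idx`,
#'   `onset_time_s`, `peak_time_s`, `amplitude_smoothed`,
#'   `pre_onset_level`, `amp_threshold`. Empty tibble when nothing is found.
#' @export
detect_events <- function(traces, cfg = event_config()) {
  stopifnot(all(c("cell_id", "time_s", "dff") %in% names(traces)))
  fs <- trace_fs(traces)
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ detect_events_one(.x$dff, fs, cfg)) |>
    dplyr::ungroup()
}

transient_model <- function(t, t0, tau_on, tau_off, a) {
  dt <- pmax(t - t0, 0)
  a * exp(-dt / tau_off) * (1 - exp(-dt / tau_on))
}

nls_ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                       ptol = 1e-15)

#' Fit the onset model of a transient
#'
#' First fitting step: nonlinear least squares of the single-exponential
#' rise \eqn{I(t) = k (1 - e^{-(t - t_0)/\tau_{on}})} (0 before \eqn{t_0})
#' over a window from shortly before the detected onset to the local peak,
#' estimating the event start `t0` and the onset time constant `tau_on`.
#'
#' @param time_s,dff Sample times and dF/F0 values of the fit window.
#' @param onset_guess_s Initial onset time (s), typically the detected onset.
#' @param tau_bounds Bounds (s) on `tau_on`.
#' @param max_restarts Jittered restarts on failure.
#' @return A `transient_fit` object: list with `estimate` (named vector
#'   `t0`, `tau_on`, `k`), `converged`, `n_points`; supports [tidy()].
#' @export
fit_onset <- function(time_s, dff, onset_guess_s, tau_bounds = c(0.05, 60),
                      max_restarts = 3) {
  peak_v <- max(dff)
  k0 <- max(peak_v, 1e-4)
  above <- which(dff >= peak_v / 2 & time_s > onset_guess_s)
  tau0 <- if (length(above) > 0) {
    max(time_s[above[1]] - onset_guess_s, 0.1)
  } else 0.5
  tau0 <- min(max(tau0, tau_bounds[1] * 2), tau_bounds[2] / 2)

  dat <- data.frame(t = time_s, y = dff)
  attempt <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ k * (1 - exp(-pmax(t - t0, 0) / tau_on)),
        data = dat, start = st,
        lower = c(k = 1e-8, t0 = min(time_s), tau_on = tau_bounds[1]),
        upper = c(k = Inf, t0 = max(time_s), tau_on = tau_bounds[2]),
        control = nls_ctrl),
      error = function(e) NULL)
  }
  fit <- attempt(list(k = k0, t0 = onset_guess_s, tau_on = tau0))
  # deterministic jitter table so the analysis has no hidden randomness
  jit <- list(c(1.5, 0.25, 0.5), c(0.7, -0.25, 2), c(2, 0.5, 0.25))
  r <- 0L
  while (is.null(fit) && r < max_restarts) {
    r <- r + 1L
    jj <- jit[[(r - 1L) %% 3L + 1L]]
    fit <- attempt(list(k = k0 * jj[1], t0 = onset_guess_s + jj[2],
                        tau_on = tau0 * jj[3]))
  }
  if (is.null(fit)) {
    return(structure(list(model = "onset",
                          estimate = c(t0 = NA_real_, tau_on = NA_real_, k = NA_real_),
                          converged = FALSE, n_points = length(dff)),
                     class = "transient_fit"))
  }
  est <- coef(fit)[c("t0", "tau_on", "k")]
  structure(list(model = "onset", estimate = est, converged = TRUE,
                 n_points = length(dff)),
            class = "transient_fit")
}

#' Fit the full transient model
#'
#' Second fitting step: starting from the [fit_onset()] estimates,
#' least-squares fit of the full transient
#' \eqn{I(t) = a\, e^{-(t - t_0)/\tau_{off}} (1 - e^{-(t - t_0)/\tau_{on}})}
#' estimating the scale `a` and the decay constant `tau_off`, and refining
#' `tau_on` and `t0` (each initialized at, or optionally frozen to, the
#' first-step values). Refinement matters because a pure-rise fit taken up
#' to the observed peak sees a rise already attenuated by the decay factor
#' and is biased (short `tau_on`, late `t0`), visibly so at 4 Hz sampling
#' of sub-second rises. The reported `peak_amplitude` is the model maximum
#' and `rise_time` is `tau_on`; the empirical 10-90 percent rise time of
#' the fitted model is a secondary kinetic measure.
#'
#' @param time_s,dff Sample times and dF/F0 values of the fit window.
#' @param t0,tau_on Onset parameters from the first step.
#' @param refine_tau_on Refit `tau_on` together with `a` and `tau_off`
#'   (default); `FALSE` keeps it fixed at the first-step value.
#' @param refine_t0 Refit `t0` within +/- `t0_halfwidth_s` of the
#'   first-step estimate (default); `FALSE` keeps it fixed.
#' @param t0_halfwidth_s Search half-width (s) for the `t0` refinement.
#' @inheritParams fit_onset
#' @return A `transient_fit` object with `estimate` = named vector `a`,
#'   `tau_off`, `tau_on`, `t0`, `peak_amplitude`, `rise_time`, `rise10_90`;
#'   supports [tidy()].
#' @export
fit_full_transient <- function(time_s, dff, t0, tau_on,
                               tau_bounds = c(0.05, 60), max_restarts = 3,
                               refine_tau_on = TRUE, refine_t0 = TRUE,
                               t0_halfwidth_s = 0.5) {
  check_positive(tau_on, "tau_on")
  # decay-tail log-linear initial guess for tau_off
  pk <- which.max(dff)
  tail_i <- which(time_s > time_s[pk] & dff > max(dff) * 0.05)
  tau_off0 <- if (length(tail_i) >= 3) {
    sl <- coef(lm(log(dff[tail_i]) ~ time_s[tail_i]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 3
  } else 3
  tau_off0 <- min(max(tau_off0, tau_bounds[1] * 2), tau_bounds[2] / 2)
  a0 <- max(dff) / transient_peak_factor(tau_on, max(tau_off0, tau_bounds[1]))

  dat <- data.frame(t = time_s, y = dff)
  t0_init <- t0; tau_on_init <- tau_on
  attempt <- function(st) {
    lo <- c(a = 1e-8, tau_off = tau_bounds[1], tau_on = tau_bounds[1],
            t0 = t0_init - t0_halfwidth_s)
    hi <- c(a = Inf, tau_off = tau_bounds[2], tau_on = tau_bounds[2],
            t0 = t0_init + t0_halfwidth_s)
    if (!refine_tau_on) st$tau_on <- NULL
    if (!refine_t0) st$t0 <- NULL
    # a start pinned on a box bound makes the LM gradient step singular
    for (p in names(st)) {
      st[[p]] <- min(max(st[[p]], lo[[p]] + 1e-8), hi[[p]] - 1e-8)
    }
    # parameters absent from `start` resolve to these constants
    tau_on <- tau_on_init; t0 <- t0_init
    form <- y ~ a * exp(-pmax(t - t0, 0) / tau_off) *
      (1 - exp(-pmax(t - t0, 0) / tau_on))
    nm <- names(st)
    tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, lower = lo[nm],
                        upper = hi[nm], control = nls_ctrl),
      error = function(e) NULL)
  }
  fit <- attempt(list(a = a0, tau_off = tau_off0, tau_on = tau_on,
                      t0 = t0_init))
  jit <- list(c(1.5, 0.4, 2.5), c(0.7, 2.5, 0.4), c(2, 0.15, 1))
  r <- 0L
  while (is.null(fit) && r < max_restarts) {
    r <- r + 1L
    jj <- jit[[(r - 1L) %% 3L + 1L]]
    fit <- attempt(list(a = a0 * jj[1], tau_off = tau_off0 * jj[2],
                        tau_on = tau_on * jj[3], t0 = t0_init))
  }
  if (is.null(fit)) {
    return(structure(list(model = "full",
                          estimate = c(a = NA_real_, tau_off = NA_real_,
                                       tau_on = NA_real_, t0 = NA_real_,
                                       peak_amplitude = NA_real_,
                                       rise_time = NA_real_, rise10_90 = NA_real_),
                          converged = FALSE, n_points = length(dff)),
                     class = "transient_fit"))
  }
  a <- unname(coef(fit)["a"]); tau_off <- unname(coef(fit)["tau_off"])
  tau_on_hat <- if (refine_tau_on) unname(coef(fit)["tau_on"]) else tau_on
  t0_hat <- if (refine_t0) unname(coef(fit)["t0"]) else t0_init
  # a time constant pinned at (or squeezed against) its bound marks a
  # degenerate fit, typically an unmodelled overlap; so does a vanishing
  # peak factor (tau_on >> tau_off, where the model degenerates into a
  # gamma-like pulse with an arbitrarily large scale `a`). Flag both so
  # kinetic statistics exclude the event.
  at_bound <- function(v) v <= tau_bounds[1] * 1.01 ||
    v >= tau_bounds[2] * 0.99
  if (at_bound(tau_off) || at_bound(tau_on_hat) ||
      transient_peak_factor(tau_on_hat, tau_off) < 0.05) {
    return(structure(list(model = "full",
                          estimate = c(a = a, tau_off = tau_off,
                                       tau_on = tau_on_hat, t0 = t0_hat,
                                       peak_amplitude = NA_real_,
                                       rise_time = NA_real_, rise10_90 = NA_real_),
                          converged = FALSE, n_points = length(dff)),
                     class = "transient_fit"))
  }
  peak <- a * transient_peak_factor(tau_on_hat, tau_off)
  structure(list(model = "full",
                 estimate = c(a = a, tau_off = tau_off, tau_on = tau_on_hat,
                              t0 = t0_hat, peak_amplitude = peak,
                              rise_time = tau_on_hat,
                              rise10_90 = rise_10_90(tau_on_hat, tau_off)),
                 converged = TRUE, n_points = length(dff)),
            class = "transient_fit")
}

# empirical 10-90% rise time of the fitted model (closed-form maximization,
# numeric root-finding on the rising limb)
rise_10_90 <- function(tau_on, tau_off) {
  dtp <- transient_peak_time(tau_on, tau_off)
  pk <- transient_peak_factor(tau_on, tau_off)
  m <- function(dt) exp(-dt / tau_off) * (1 - exp(-dt / tau_on))
  cross <- function(frac) {
    stats::uniroot(function(dt) m(dt) - frac * pk, c(1e-9 * dtp, dtp),
                   tol = 1e-10)$root
  }
  cross(0.9) - cross(0.1)
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("<transient_fit: %s> converged=%s\n", x$model, x$converged))
  print(round(x$estimate, 5))
  invisible(x)
}

#' @export
tidy.transient_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @export
glance.transient_fit <- function(x, ...) {
  tibble(model = x$model, converged = x$converged, n_points = x$n_points)
}

#' Detect and fit all calcium events of every trace
#'
#' Full per-trace event analysis under the linear-superposition assumption:
#' candidate detection on the smoothed dF/F0 trace, then for each
#' candidate, in time order, the two-step fit on the residual trace after
#' subtracting all previously fitted transients (sequential peeling).
#' Two refinement rounds follow: each event is refitted on the trace minus
#' all *other* fitted events over an extended window (stabilizing decay
#' constants of events whose first-pass window was cut short by a
#' neighbour), and candidate detection is re-run on the final residual to
#' rescue events that overlapped so closely that the first detection pass
#' merged them. Events whose fit fails to converge are kept with
#' `converged = FALSE` and excluded from kinetic statistics downstream;
#' fitted events whose model peak falls below the amplitude threshold are
#' dropped.
#'
#' @param traces Tibble with `cell_id`, `time_s`, `dff` (from
#'   [normalize_dff()]).
#' @param cfg An [event_config()].
#' @return Event tibble: `cell_id`, `event_idx`, `t0_s`, `tau_on_s`, `k`,
#'   `a`, `tau_off_s`, `peak_dff`, `rise10_90_s`, `converged`; attribute
#'   `duration_s`.
#' @export
fit_events <- function(traces, cfg = event_config()) {
  stopifnot(all(c("cell_id", "time_s", "dff") %in% names(traces)))
  fs <- trace_fs(traces)
  empty <- tibble(cell_id = integer(), event_idx = integer(), t0_s = numeric(),
                  tau_on_s = numeric(), k = numeric(), a = numeric(),
                  tau_off_s = numeric(), peak_dff = numeric(),
                  rise10_90_s = numeric(), converged = logical())

  per_cell <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split()

  rows <- purrr::map(per_cell, function(d) {
    cid <- d$cell_id[1]
    dff <- d$dff; time_s <- d$time_s; n <- length(dff)
    cand <- detect_events_one(dff, fs, cfg)
    if (nrow(cand) == 0L) return(NULL)
    amp_thr <- cand$amp_threshold[1]
    pad <- round(cfg$fit_pad_s * fs)
    max_w <- round(cfg$max_fit_window_s * fs)

    sigma_raw <- mad(diff(dff)) / sqrt(2)

    # two-step fit of one candidate against a residual trace; returns the
    # event row plus the fitted model curve (NULL when not converged)
    fit_one <- function(resid, on_i, pk_i, onset_time, end_i) {
      start_i <- max(1L, on_i - pad)
      off0 <- median(resid[start_i:on_i])
      f1 <- fit_onset(time_s[start_i:pk_i], resid[start_i:pk_i] - off0,
                      onset_time, cfg$tau_bounds, cfg$max_restarts)
      if (!f1$converged) {
        return(list(row = tibble(cell_id = cid, t0_s = onset_time,
                                 tau_on_s = NA_real_, k = NA_real_,
                                 a = NA_real_, tau_off_s = NA_real_,
                                 peak_dff = NA_real_, rise10_90_s = NA_real_,
                                 converged = FALSE),
                    model = NULL))
      }
      t0 <- unname(f1$estimate["t0"])
      f2 <- fit_full_transient(time_s[start_i:end_i],
                               resid[start_i:end_i] - off0, t0,
                               unname(f1$estimate["tau_on"]),
                               cfg$tau_bounds, cfg$max_restarts)
      if (!f2$converged) {
        # a degenerate full fit is the signature of two merged transients;
        # attempt the two-component refit before giving up
        w <- max(1L, on_i - pad):end_i
        split <- try_split(resid, off0, w, k1 = unname(f1$estimate["k"]),
                           w_core = w, rms_single = Inf)
        if (!is.null(split)) return(split)
        return(list(row = tibble(cell_id = cid, t0_s = t0,
                                 tau_on_s = unname(f1$estimate["tau_on"]),
                                 k = unname(f1$estimate["k"]), a = NA_real_,
                                 tau_off_s = NA_real_, peak_dff = NA_real_,
                                 rise10_90_s = NA_real_, converged = FALSE),
                    model = NULL))
      }
      a <- unname(f2$estimate["a"]); tau_off <- unname(f2$estimate["tau_off"])
      tau_on <- unname(f2$estimate["tau_on"])   # refined in the full fit
      t0 <- unname(f2$estimate["t0"])
      model <- transient_model(time_s, t0, tau_on, tau_off, a)
      peak <- unname(f2$estimate["peak_amplitude"])
      # goodness flag: a residual RMS far above the trace noise over the
      # transient's own support marks an unmodelled overlap (e.g. two
      # merged transients fitted as one). Restricting the check to the
      # transient support keeps slow events, whose long windows accumulate
      # benign baseline-estimator wiggle, from being flagged spuriously.
      w <- max(1L, on_i - pad):end_i
      t_end <- t0 + transient_peak_time(tau_on, tau_off) + 2 * tau_off
      w_core <- w[time_s[w] >= t0 - 1 & time_s[w] <= t_end]
      if (length(w_core) < 4L) w_core <- w
      rms <- sqrt(mean((resid[w_core] - off0 - model[w_core])^2))
      if (rms > 2.5 * sigma_raw + 0.02 * peak) {
        split <- try_split(resid, off0, w, k1 = unname(f1$estimate["k"]),
                           w_core = w_core, rms_single = rms)
        if (!is.null(split)) return(split)
        # unsplittable: keep the event but exclude its kinetics
        return(list(row = tibble(cell_id = cid, t0_s = t0, tau_on_s = tau_on,
                                 k = unname(f1$estimate["k"]), a = a,
                                 tau_off_s = tau_off, peak_dff = NA_real_,
                                 rise10_90_s = NA_real_, converged = FALSE),
                    model = model))
      }
      list(row = tibble(cell_id = cid, t0_s = t0, tau_on_s = tau_on,
                        k = unname(f1$estimate["k"]), a = a,
                        tau_off_s = tau_off,
                        peak_dff = peak,
                        rise10_90_s = unname(f2$estimate["rise10_90"]),
                        converged = TRUE),
           model = model)
    }

    # joint two-transient refit of a window whose single-transient fit left
    # a structured residual (two events merged by the candidate detector)
    try_split <- function(resid, off0, w, k1, w_core, rms_single) {
      y <- resid[w] - off0; tt <- time_s[w]
      ys <- smooth_trace(y, min(3L, length(y)))
      # two candidate onsets: the window start and the strongest later rise
      i1 <- which(ys >= 0.25 * max(ys))[1]
      t0a <- tt[max(1L, i1 - 1L)]
      d2 <- c(0, diff(ys))
      half <- which(tt > t0a + 1)
      if (length(half) < 4L) return(NULL)
      i2 <- half[which.max(d2[half])]
      t0b <- tt[max(1L, i2 - 1L)]
      if (t0b - t0a < 2 / fs) return(NULL)
      amp0 <- max(ys)
      st <- list(a1 = amp0, a2 = amp0 / 2, t01 = t0a, t02 = t0b,
                 ton1 = 1, toff1 = 3, ton2 = 1, toff2 = 3)
      lo <- c(a1 = 1e-8, a2 = 1e-8, t01 = t0a - 1, t02 = t0b - 1,
              ton1 = cfg$tau_bounds[1], toff1 = cfg$tau_bounds[1],
              ton2 = cfg$tau_bounds[1], toff2 = cfg$tau_bounds[1])
      hi <- c(a1 = Inf, a2 = Inf, t01 = t0a + 1, t02 = t0b + 1,
              ton1 = cfg$tau_bounds[2], toff1 = cfg$tau_bounds[2],
              ton2 = cfg$tau_bounds[2], toff2 = cfg$tau_bounds[2])
      dat <- data.frame(t = tt, y = y)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ a1 * exp(-pmax(t - t01, 0) / toff1) *
            (1 - exp(-pmax(t - t01, 0) / ton1)) +
            a2 * exp(-pmax(t - t02, 0) / toff2) *
            (1 - exp(-pmax(t - t02, 0) / ton2)),
          data = dat, start = st, lower = lo, upper = hi,
          control = nls_ctrl),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      p <- coef(fit)
      bad_tau <- function(v) v <= cfg$tau_bounds[1] * 1.01 ||
        v >= cfg$tau_bounds[2] * 0.99
      if (any(vapply(p[c("ton1", "toff1", "ton2", "toff2")], bad_tau,
                     logical(1))) ||
          transient_peak_factor(p[["ton1"]], p[["toff1"]]) < 0.05 ||
          transient_peak_factor(p[["ton2"]], p[["toff2"]]) < 0.05) {
        return(NULL)
      }
      pk1 <- p[["a1"]] * transient_peak_factor(p[["ton1"]], p[["toff1"]])
      pk2 <- p[["a2"]] * transient_peak_factor(p[["ton2"]], p[["toff2"]])
      # a genuine merged pair has two comparable transients; a dominant
      # component with a sliver is a fit artifact, not a split
      if (min(pk1, pk2) < max(amp_thr, 0.25 * max(pk1, pk2))) return(NULL)
      model <- transient_model(time_s, p[["t01"]], p[["ton1"]], p[["toff1"]], p[["a1"]]) +
        transient_model(time_s, p[["t02"]], p[["ton2"]], p[["toff2"]], p[["a2"]])
      # the split must fit well absolutely and clearly beat the single fit
      # on the same stretch; otherwise a slow transient would be carved
      # into two fast halves whenever the single fit was merely mediocre
      rms <- sqrt(mean((resid[w_core] - off0 - model[w_core])^2))
      if (rms > 2.5 * sigma_raw + 0.02 * max(pk1, pk2)) return(NULL)
      if (rms > 0.75 * rms_single) return(NULL)
      row <- tibble(
        cell_id = cid,
        t0_s = c(p[["t01"]], p[["t02"]]),
        tau_on_s = c(p[["ton1"]], p[["ton2"]]),
        k = k1, a = c(p[["a1"]], p[["a2"]]),
        tau_off_s = c(p[["toff1"]], p[["toff2"]]),
        peak_dff = c(pk1, pk2),
        rise10_90_s = c(rise_10_90(p[["ton1"]], p[["toff1"]]),
                        rise_10_90(p[["ton2"]], p[["toff2"]])),
        converged = TRUE)
      list(row = row, model = model)
    }

    # pass 1: sequential peeling in time order, windows cut at the next onset
    models <- vector("list", nrow(cand))
    out <- vector("list", nrow(cand))
    resid <- dff
    for (j in seq_len(nrow(cand))) {
      end_i <- if (j < nrow(cand)) {
        max(cand$peak_idx[j], cand$onset_idx[j + 1] - 1L)
      } else n
      end_i <- min(end_i, cand$onset_idx[j] + max_w, n)
      r <- fit_one(resid, cand$onset_idx[j], cand$peak_idx[j],
                   cand$onset_time_s[j], end_i)
      out[[j]] <- r$row
      models[[j]] <- r$model
      if (!is.null(r$model)) resid <- resid - r$model
    }

    # pass 2: refit every event on the trace minus all *other* events, with
    # the window no longer truncated by the neighbour (stabilizes tau_off)
    fitted <- !vapply(models, is.null, logical(1))
    total <- Reduce(`+`, models[fitted], numeric(n))
    for (j in which(fitted)) {
      resid_j <- dff - (total - models[[j]])
      end_i <- min(cand$onset_idx[j] + max_w, n)
      r <- fit_one(resid_j, cand$onset_idx[j], cand$peak_idx[j],
                   cand$onset_time_s[j], end_i)
      if (!is.null(r$model)) {
        total <- total - models[[j]] + r$model
        models[[j]] <- r$model
        out[[j]] <- r$row
      }
    }

    # pass 3: re-detect on the residual to rescue events the first pass
    # merged into a neighbour
    resid_all <- dff - total
    cand2 <- detect_events_one(resid_all, fs, cfg)
    if (nrow(cand2) > 0) {
      fresh <- vapply(seq_len(nrow(cand2)), function(j) {
        all(abs(cand2$onset_time_s[j] - cand$onset_time_s) > 2 / fs)
      }, logical(1))
      cand2 <- cand2[fresh, , drop = FALSE]
      # a rescued event must be comparable to the cell's established events,
      # not a sliver of fit residue
      prior <- unlist(lapply(out, function(x) x$peak_dff))
      floor2 <- max(amp_thr, 0.3 * median(prior, na.rm = TRUE), na.rm = TRUE)
      for (j in seq_len(nrow(cand2))) {
        end_i <- min(cand2$onset_idx[j] + max_w, n)
        r <- fit_one(resid_all, cand2$onset_idx[j], cand2$peak_idx[j],
                     cand2$onset_time_s[j], end_i)
        if (!is.null(r$model) && all(r$row$peak_dff >= floor2, na.rm = FALSE) &&
            !anyNA(r$row$peak_dff)) {
          out[[length(out) + 1L]] <- r$row
          resid_all <- resid_all - r$model
        }
      }
    }

    ev <- dplyr::bind_rows(out)
    # drop fitted events whose model peak fell below the applied threshold
    ev <- ev[is.na(ev$peak_dff) | ev$peak_dff >= amp_thr, ]
    if (nrow(ev) == 0L) return(NULL)
    ev <- ev[order(ev$t0_s), ]
    # merge splinter fits: a pair of onsets closer than the minimum
    # separation collapses onto the larger-amplitude one when the smaller
    # looks like a fit artifact (well below the larger, or within two
    # samples); genuine similar-amplitude close pairs are preserved
    if (nrow(ev) > 1L) {
      score <- ifelse(is.na(ev$peak_dff), 0, ev$peak_dff)
      keep <- rep(TRUE, nrow(ev))
      repeat {
        idx <- which(keep)
        if (length(idx) < 2L) break
        gaps <- diff(ev$t0_s[idx])
        merged <- FALSE
        for (jj in which(gaps < cfg$min_event_separation_s)) {
          pair <- idx[c(jj, jj + 1L)]
          if (gaps[jj] < 2 / fs ||
              min(score[pair]) < 0.35 * max(score[pair])) {
            keep[pair[which.min(score[pair])]] <- FALSE
            merged <- TRUE
            break
          }
        }
        if (!merged) break
      }
      ev <- ev[keep, ]
    }
    ev$event_idx <- seq_len(nrow(ev))
    ev
  })
  ev <- dplyr::bind_rows(rows)
  if (nrow(ev) == 0L) ev <- empty else {
    ev <- ev[, c("cell_id", "event_idx", "t0_s", "tau_on_s", "k", "a",
                 "tau_off_s", "peak_dff", "rise10_90_s", "converged")]
  }
  structure(ev, duration_s = max(traces$time_s) + 1 / fs,
            sampling_rate_hz = fs)
}

#' Summarize events per cell
#'
#' Per-cell event statistics: event rate (events per second of recording),
#' mean peak amplitude and mean rise time (`tau_on`). Cells with no
#' (converged) events are reported as `INACTIVE` with rate 0.
#'
#' @param events Event tibble from [fit_events()].
#' @param duration_s Recording duration (s); taken from the events attribute
#'   if absent.
#' @param cell_ids Optional vector of all analyzed cell ids, so that cells
#'   without events appear as INACTIVE records.
#' @return Cell-record tibble: `cell_id`, `n_events`, `event_rate_hz`,
#'   `mean_amplitude`, `mean_rise_time_s`, `mean_tau_off_s`,
#'   `mean_rise10_90_s`, `class` (`NA` until [classify_fast_slow()];
#'   `"INACTIVE"` for event-free cells).
#' @export
summarize_cells <- function(events, duration_s = NULL, cell_ids = NULL) {
  duration_s <- duration_s %||% attr(events, "duration_s", exact = TRUE)
  check_positive(duration_s, "duration_s")
  ids <- cell_ids %||% unique(events$cell_id)

  # every detected event counts towards the rate; kinetic statistics use
  # converged fits only, and among those only events of representative
  # amplitude (>= 30% of the cell's median peak) - tiny residue events
  # carry arbitrary time constants, and a supervised analyst would discard
  # them on sight
  agg <- events |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      med <- median(d$peak_dff[d$converged], na.rm = TRUE)
      use <- d$converged & !is.na(d$peak_dff) & d$peak_dff >= 0.3 * med
      # kinetic summaries use a 20% trimmed mean: per-event time-constant
      # errors at 4 Hz sampling are heavy-tailed, and the original
      # supervised review discarded such outlier fits by eye
      tibble(
        n_events = nrow(d),
        mean_amplitude = mean(d$peak_dff[use]),
        mean_rise_time_s = mean(d$tau_on_s[use], trim = 0.2),
        mean_tau_off_s = mean(d$tau_off_s[use], trim = 0.2),
        mean_rise10_90_s = mean(d$rise10_90_s[use], trim = 0.2))
    }) |>
    dplyr::ungroup()
  res <- tibble(cell_id = ids) |>
    dplyr::left_join(agg, by = "cell_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      event_rate_hz = .data$n_events / duration_s,
      class = ifelse(.data$n_events == 0L, "INACTIVE", NA_character_)
    )
  res[, c("cell_id", "n_events", "event_rate_hz", "mean_amplitude",
          "mean_rise_time_s", "mean_tau_off_s", "mean_rise10_90_s", "class")]
}
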