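#' Elementary calcium transient model
#'
#' Closed-form model of a single calcium transient: a single-exponential rise
#' multiplied by a single-exponential decay,
#' \deqn{I(t) = a \, e^{-(t - t_0)/\tau_{off}} \left(1 - e^{-(t - t_0)/\tau_{on}}\right)}
#' for \eqn{t \ge t_0} and 0 before the onset (causality). This is the
#' elementary waveform that both the simulator and the fitting stage share;
#' recorded traces are modelled as linear superpositions of such transients
#' on a baseline.
#'
#' @param t Numeric vector of time points (seconds).
#' @param t0 Onset time (s).
#' @param tau_on Onset (rise) time constant (s), > 0.
#' @param tau_off Decay time constant (s), > 0.
#' @param a Scale of the transient (dF/F0 units). Note `a` is not the peak:
#'   the model maximum is `a * transient_peak_factor(tau_on, tau_off)`.
#' @return Numeric vector of model values, same length as `t`.
#' @seealso [transient_peak_time()], [transient_peak_factor()]
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.25)
#' y <- simulate_transient(t, t0 = 2, tau_on = 1, tau_off = 3, a = 0.2)
simulate_transient <- function(t, t0, tau_on, tau_off, a) {
  check_positive(tau_on, "tau_on")
  check_positive(tau_off, "tau_off")
  dt <- pmax(t - t0, 0)
  a * exp(-dt / tau_off) * (1 - exp(-dt / tau_on))
}

#' Time of the transient peak relative to onset
#'
#' The model \eqn{a e^{-dt/\tau_{off}}(1 - e^{-dt/\tau_{on}})} attains its
#' maximum at \eqn{dt = \tau_{on} \log(1 + \tau_{off}/\tau_{on})} (set the
#' derivative to zero).
#'
#' @inheritParams simulate_transient
#' @return Time from onset to peak (s).
#' @export
transient_peak_time <- function(tau_on, tau_off) {
  check_positive(tau_on, "tau_on")
  check_positive(tau_off, "tau_off")
  tau_on * log(1 + tau_off / tau_on)
}

#' Peak value of the unit-scale transient
#'
#' Model maximum for `a = 1`; multiply by `a` for the true peak amplitude.
#' The simulator divides requested peak amplitudes by this factor so that
#' ground-truth amplitudes are peak dF/F0 values.
#'
#' @inheritParams simulate_transient
#' @return Peak of the unit-scale model, in (0, 1).
#' @export
transient_peak_factor <- function(tau_on, tau_off) {
  dt <- transient_peak_time(tau_on, tau_off)
  exp(-dt / tau_off) * (1 - exp(-dt / tau_on))
}

# draw one cell's event list: Poisson count, uniform onset times, per-event
# kinetics jittered around the cell means but kept on the cell's side of
# `tau_split` so kinetic classes stay separated by construction
draw_events <- function(event_rate_hz, duration_s, tau_on_s, tau_off_s,
                        amplitude_dff, tau_jitter = 0.1, amp_jitter = 0.15,
                        tau_split = 2) {
  n <- rpois(1L, event_rate_hz * duration_s)
  if (n == 0L) {
    return(tibble(
      t0_s = numeric(), tau_on_s = numeric(), tau_off_s = numeric(),
      amplitude_dff = numeric(), a = numeric()
    ))
  }
  t0 <- sort(runif(n, 0, duration_s))
  tau_on <- tau_on_s * exp(rnorm(n, 0, tau_jitter))
  # keep every event on its class's side of the fast/slow split
  if (tau_on_s < tau_split) {
    tau_on <- pmin(tau_on, tau_split * 0.95)
  } else if (tau_on_s > tau_split) {
    tau_on <- pmax(tau_on, tau_split * 1.05)
  }
  tau_off <- tau_off_s * exp(rnorm(n, 0, tau_jitter))
  amp <- amplitude_dff * exp(rnorm(n, 0, amp_jitter))
  tibble(
    t0_s = t0, tau_on_s = tau_on, tau_off_s = tau_off,
    amplitude_dff = amp, a = amp / transient_peak_factor(tau_on, tau_off)
  )
}

# superpose a cell's events into a dF/F0 signal on a sample grid
events_to_dff <- function(events, time_s) {
  s <- numeric(length(time_s))
  if (nrow(events) == 0L) return(s)
  for (i in seq_len(nrow(events))) {
    s <- s + simulate_transient(time_s, events$t0_s[i], events$tau_on_s[i],
                                events$tau_off_s[i], events$a[i])
  }
  s
}

# smooth low-order polynomial drift with max |p| = 1 (deterministic given RNG
# state); degree-3 with random coefficients
draw_drift_shape <- function(time_s) {
  x <- 2 * (time_s - min(time_s)) / max(diff(range(time_s)), 1e-12) - 1
  co <- rnorm(3)
  p <- co[1] * x + co[2] * x^2 + co[3] * x^3
  m <- max(abs(p))
  if (m < 1e-12) return(p * 0)
  p / m
}

#' Simulate one fluorescence trace with known event ground truth
#'
#' Generates a raw fluorescence trace as
#' `baseline(t) * (1 + sum of transients in dF/F0) + Gaussian noise`,
#' where the baseline is a constant level modulated by a smooth low-order
#' polynomial drift. Calcium transients add linearly (superposition); events
#' are a homogeneous Poisson process with per-event kinetics jittered around
#' the supplied means. The returned ground-truth event table is the oracle
#' for downstream detection and fitting tests.
#'
#' @param duration_s Recording duration (s). Default 300 (5-minute recording).
#' @param sampling_rate_hz Sampling rate (Hz). Default 4.
#' @param event_rate_hz Mean Poisson event rate (Hz).
#' @param tau_on_s,tau_off_s Mean onset and decay time constants (s).
#' @param amplitude_dff Mean peak amplitude in dF/F0 units.
#' @param baseline_level Baseline fluorescence (arbitrary intensity units).
#' @param baseline_drift Fractional amplitude of the slow polynomial drift
#'   (0 = flat baseline).
#' @param noise_sd Additive Gaussian noise SD (intensity units); must be >= 0.
#' @param tau_jitter,amp_jitter Log-normal jitter SD for per-event kinetics
#'   and amplitudes.
#' @param event_times_s Optional fixed onset times (overrides the Poisson
#'   draw; kinetics still jittered).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list with `time_s`, `raw` (the trace), `baseline` (noise-free
#'   baseline), `dff_true` (noise-free summed dF/F0 signal), and `events`
#'   (ground-truth tibble: `t0_s`, `tau_on_s`, `tau_off_s`, `amplitude_dff`,
#'   `a`).
#' @export
simulate_trace <- function(duration_s = 300, sampling_rate_hz = 4,
                           event_rate_hz = 0.04, tau_on_s = 1, tau_off_s = 3,
                           amplitude_dff = 0.2, baseline_level = 100,
                           baseline_drift = 0.05, noise_sd = 0,
                           tau_jitter = 0.1, amp_jitter = 0.15,
                           event_times_s = NULL, seed = NULL) {
  check_positive(duration_s, "duration_s")
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(event_rate_hz, "event_rate_hz", strict = FALSE)
  check_positive(baseline_level, "baseline_level")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- floor(duration_s * sampling_rate_hz)
  time_s <- (seq_len(n) - 1) / sampling_rate_hz

  events <- draw_events(event_rate_hz, duration_s, tau_on_s, tau_off_s,
                        amplitude_dff, tau_jitter, amp_jitter)
  if (!is.null(event_times_s)) {
    k <- length(event_times_s)
    tau_on <- tau_on_s * exp(rnorm(k, 0, tau_jitter))
    tau_off <- tau_off_s * exp(rnorm(k, 0, tau_jitter))
    amp <- amplitude_dff * exp(rnorm(k, 0, amp_jitter))
    events <- tibble(
      t0_s = sort(event_times_s), tau_on_s = tau_on, tau_off_s = tau_off,
      amplitude_dff = amp, a = amp / transient_peak_factor(tau_on, tau_off)
    )
  }

  dff_true <- events_to_dff(events, time_s)
  drift <- if (baseline_drift > 0) draw_drift_shape(time_s) else numeric(n)
  baseline <- baseline_level * (1 + baseline_drift * drift)
  raw <- baseline * (1 + dff_true)
  if (noise_sd > 0) raw <- raw + rnorm(n, 0, noise_sd)

  list(time_s = time_s, raw = raw, baseline = baseline,
       dff_true = dff_true, events = events)
}
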