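test_that("dF/F0 normalization: constants, scale invariance, diagnostics", {
  df <- tibble::tibble(cell_id = 1L, time_s = (0:99) / 4, f = 50)
  nd <- normalize_dff(df)
  expect_true(all(nd$dff == 0))

  tr <- simulate_trace(duration_s = 120, event_times_s = c(30, 80),
                       amplitude_dff = 0.3, noise_sd = 0, seed = 2)
  d1 <- normalize_dff(trace_df(tr))
  d2 <- trace_df(tr); d2$f <- d2$f * 2
  expect_equal(normalize_dff(d2)$dff, d1$dff, tolerance = 1e-12)

  # the recovered dff matches the generated signal despite baseline drift
  # (peak 0.3; residual estimator error stays below ~2% of baseline)
  expect_lt(max(abs(d1$dff - tr$dff_true)), 0.05)
  quiet <- d1$dff[tr$dff_true < 1e-6]
  expect_lt(abs(mean(quiet)), 0.01)

  bad <- tibble::tibble(cell_id = 1L, time_s = (0:99) / 4,
                        f = c(rep(10, 50), rep(-1, 50)))
  expect_error(normalize_dff(bad), "positive")
})

test_that("polynomial baseline tracks a drifting noiseless trace", {
  tr <- simulate_trace(duration_s = 300, event_rate_hz = 0.02,
                       baseline_drift = 0.08, noise_sd = 0, seed = 9)
  nd <- normalize_dff(trace_df(tr), method = "polynomial")
  quiet <- nd$dff[tr$dff_true < 1e-6]
  expect_lt(abs(mean(quiet)), 0.01)
})

test_that("moving average: identity, mean preservation, variance reduction", {
  x <- rnorm(100)
  expect_identical(smooth_trace(x, 1), x)
  expect_equal(smooth_trace(rep(2, 50), 5), rep(2, 50))
  expect_error(smooth_trace(x, 200), "longer")
  set.seed(31)
  z <- rnorm(50000)
  s <- smooth_trace(z, 5)
  expect_equal(sd(s[3:49998]), 1 / sqrt(5), tolerance = 0.03)
})

test_that("event detection rules: flat traces, the 1% floor, onset accuracy", {
  flat <- tibble::tibble(cell_id = 1L, time_s = (0:499) / 4, f = 100,
                         dff = 0)
  expect_equal(nrow(detect_events(flat)), 0L)

  # peak at half the 1%-of-baseline floor -> rejected
  lo <- single_event_trace(0.005)
  expect_equal(nrow(detect_events(normalize_dff(trace_df(lo)))), 0L)
  hi <- single_event_trace(0.011)
  expect_equal(nrow(detect_events(normalize_dff(trace_df(hi)))), 1L)

  # three well-separated noiseless transients: candidate onsets found and
  # fitted onset times within 1 sample of the truth
  tr <- simulate_trace(duration_s = 300, event_times_s = c(50, 150, 250),
                       tau_on_s = 1, tau_off_s = 3, amplitude_dff = 0.3,
                       tau_jitter = 0, amp_jitter = 0, baseline_drift = 0,
                       noise_sd = 0, seed = 7)
  nd <- normalize_dff(trace_df(tr))
  cand <- detect_events(nd)
  expect_equal(nrow(cand), 3L)
  ev <- fit_events(nd)
  expect_equal(nrow(ev), 3L)
  expect_true(all(abs(ev$t0_s - c(50, 150, 250)) <= 0.25 + 1e-9))
})

test_that("detection is scale invariant and monotone in the threshold", {
  tr <- simulate_trace(duration_s = 300, event_rate_hz = 0.03,
                       amplitude_dff = 0.15, noise_sd = 1.5, seed = 17)
  nd <- normalize_dff(trace_df(tr))
  n1 <- nrow(detect_events(nd))
  scaled <- trace_df(tr); scaled$f <- scaled$f * 3.7
  expect_equal(nrow(detect_events(normalize_dff(scaled))), n1)

  counts <- vapply(c(0.005, 0.01, 0.05, 0.1, 0.2), function(thr) {
    nrow(detect_events(nd, event_config(amplitude_threshold_frac = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fitting noiseless model samples recovers the parameters exactly", {
  # onset model self-consistency
  t <- seq(0, 12, by = 0.1)
  y <- 0.1 * (1 - exp(-pmax(t - 2, 0) / 1))
  f1 <- fit_onset(t, y, onset_guess_s = 2.2)
  expect_true(f1$converged)
  expect_equal(unname(f1$estimate), c(2, 1, 0.1), tolerance = 1e-6)

  # full model self-consistency (t0 known, tau_on refined from a rough start)
  y2 <- simulate_transient(t, 2, 1, 3, 0.2)
  f2 <- fit_full_transient(t, y2, t0 = 2, tau_on = 1.3)
  expect_true(f2$converged)
  expect_equal(unname(f2$estimate[c("a", "tau_off", "tau_on")]), c(0.2, 3, 1),
               tolerance = 1e-6)
  # tidy() exposes the estimates
  td <- tidy(f2)
  expect_true(all(c("term", "estimate") %in% names(td)))
})

test_that("model peak amplitude matches the closed-form maximum", {
  # a = 1, tau_on = 1, tau_off = 2: maximum at t0 + ln 3
  t <- seq(0, 20, by = 0.05)
  y <- simulate_transient(t, 0, 1, 2, 1)
  f <- fit_full_transient(t, y, t0 = 0, tau_on = 1)
  peak_cf <- exp(-log(3) / 2) * (1 - exp(-log(3)))
  expect_equal(unname(f$estimate["peak_amplitude"]), peak_cf, tolerance = 1e-6)
})

test_that("coarse 4 Hz sampling still recovers a fast tau_on within 5%", {
  t <- seq(0, 20, by = 0.25)
  y <- simulate_transient(t, 5.1, 0.5, 3, 0.2)
  f <- fit_full_transient(t, y, t0 = 5.1, tau_on = 0.8)
  # dense-grid oracle: the same fit on 50 Hz samples, which is exact
  td <- seq(0, 20, by = 0.02)
  fd <- fit_full_transient(td, simulate_transient(td, 5.1, 0.5, 3, 0.2),
                           t0 = 5.1, tau_on = 0.8)
  expect_equal(unname(fd$estimate["tau_on"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f$estimate["tau_on"]), 0.5, tolerance = 0.05)
})

test_that("noisy replicates: median fitted tau_on within 10% of truth", {
  set.seed(202)
  taus <- vapply(1:200, function(i) {
    t <- seq(0, 15, by = 0.25)
    y <- simulate_transient(t, 3, 1, 3, 0.1 / transient_peak_factor(1, 3)) +
      rnorm(length(t), 0, 0.005)
    f <- fit_full_transient(t, y, t0 = 3, tau_on = 1.4)
    unname(f$estimate["tau_on"])
  }, numeric(1))
  expect_lt(abs(median(taus, na.rm = TRUE) - 1) / 1, 0.1)
})

test_that("sequential peeling resolves two overlapping transients", {
  # two events 2 s apart on a noiseless trace: fit the first on the window
  # up to the second onset, subtract it, fit the second on the residual
  t <- seq(0, 60, by = 0.25)
  p1 <- c(t0 = 20, tau_on = 0.8, tau_off = 4)
  p2 <- c(t0 = 22, tau_on = 0.8, tau_off = 4)
  a1 <- 0.3 / transient_peak_factor(0.8, 4)
  a2 <- 0.24 / transient_peak_factor(0.8, 4)
  y <- simulate_transient(t, p1["t0"], p1["tau_on"], p1["tau_off"], a1) +
    simulate_transient(t, p2["t0"], p2["tau_on"], p2["tau_off"], a2)

  w1 <- t >= 18 & t < 22
  f1 <- fit_onset(t[w1], y[w1], onset_guess_s = 20.1)
  full1 <- fit_full_transient(t[t >= 18 & t < 21.9], y[t >= 18 & t < 21.9],
                              t0 = unname(f1$estimate["t0"]),
                              tau_on = unname(f1$estimate["tau_on"]))
  resid <- y - transient_model(t, unname(f1$estimate["t0"]),
                               unname(full1$estimate["tau_on"]),
                               unname(full1$estimate["tau_off"]),
                               unname(full1$estimate["a"]))
  w2 <- t >= 21.5
  full2 <- fit_full_transient(t[w2], resid[w2], t0 = 22, tau_on = 1)
  # oracle: the joint truth on a dense noiseless grid is the generating pair
  expect_lt(abs(full1$estimate["peak_amplitude"] / 0.3 - 1), 0.1)
  expect_lt(abs(full2$estimate["peak_amplitude"] / 0.24 - 1), 0.1)
})

test_that("cell summaries: rates, INACTIVE records, ground-truth means", {
  ev <- tibble::tibble(cell_id = rep(1L, 18), event_idx = 1:18,
                       t0_s = seq(10, 290, length.out = 18), tau_on_s = 1.2,
                       k = 0.1, a = 0.25, tau_off_s = 3,
                       peak_dff = rep(c(0.2, 0.3), 9), rise10_90_s = 1,
                       converged = TRUE)
  rec <- summarize_cells(ev, duration_s = 300, cell_ids = 1:2)
  expect_equal(rec$event_rate_hz[1], 0.06)
  expect_equal(rec$mean_amplitude[1], 0.25)
  expect_equal(rec$mean_rise_time_s[1], 1.2)
  expect_equal(rec$n_events[2], 0L)
  expect_equal(rec$class[2], "INACTIVE")
  expect_equal(rec$event_rate_hz[2], 0)
})
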