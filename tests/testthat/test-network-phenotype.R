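make_records <- function(rise, class = NA_character_) {
  tibble::tibble(cell_id = seq_along(rise), n_events = 5,
                 event_rate_hz = 0.02, mean_amplitude = 0.2,
                 mean_rise_time_s = rise, mean_tau_off_s = 3,
                 mean_rise10_90_s = 1, class = class)
}

test_that("FAST/SLOW split uses a strict 2 s rise-time threshold", {
  rec <- classify_fast_slow(make_records(c(1.3, 1.99, 2.0, 5.2)))
  expect_equal(rec$class, c("FAST", "FAST", "SLOW", "SLOW"))
  # INACTIVE records pass through unchanged
  rec2 <- make_records(c(1, NA)); rec2$class[2] <- "INACTIVE"
  expect_equal(classify_fast_slow(rec2)$class, c("FAST", "INACTIVE"))
})

test_that("synchrony index: perfect synchrony, degenerate inputs, bounds", {
  ev <- tibble::tibble(cell_id = rep(1:5, each = 3),
                       t0_s = rep(c(10, 20, 30), 5))
  expect_equal(synchrony_index(ev), 1)
  one <- tibble::tibble(cell_id = 1L, t0_s = c(1, 2, 3))
  expect_warning(s <- synchrony_index(one), "undefined")
  expect_true(is.na(s))
  # disjoint bins across cells -> 0
  ev2 <- tibble::tibble(cell_id = rep(1:2, each = 2),
                        t0_s = c(10, 20, 100, 200))
  expect_equal(synchrony_index(ev2), 0)
})

test_that("synchrony of independent Poisson cells matches a brute-force oracle", {
  set.seed(55)
  bin <- 0.25
  ours <- numeric(200); oracle <- numeric(200)
  for (r in 1:200) {
    ev <- dplyr::bind_rows(lapply(1:50, function(cid) {
      n <- rpois(1, 0.03 * 300)
      tibble::tibble(cell_id = cid, t0_s = runif(n, 0, 300))
    }))
    ours[r] <- suppressWarnings(synchrony_index(ev, bin))
    # naive O(n^2) definition: an event is simultaneous if any event of a
    # different cell falls in its bin
    b <- floor(ev$t0_s / bin)
    oracle[r] <- mean(vapply(seq_len(nrow(ev)), function(i) {
      any(b == b[i] & ev$cell_id != ev$cell_id[i])
    }, logical(1)))
  }
  expect_equal(ours, oracle, tolerance = 1e-12)
  # chance level for ~450 events in 1200 bins is roughly 1 - exp(-n/bins)
  n_ev <- 50 * 0.03 * 300; n_bins <- 300 / bin
  approx_chance <- 1 - exp(-(n_ev - 9) / n_bins)
  expect_gt(mean(ours), approx_chance * 0.7)
  expect_lt(mean(ours), approx_chance * 1.3)
})

test_that("synchrony rises monotonically with the generator sync fraction", {
  fracs <- c(0, 0.3, 0.6, 1)
  means <- vapply(fracs, function(sf) {
    mean(vapply(1:20, function(s) {
      ev <- simulate_event_sets(n_cells = 30, duration_s = 300,
                                event_rate_hz = 0.03, sync_fraction = sf,
                                seed = 1000 + s)
      suppressWarnings(synchrony_index(ev))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[4], 0.95)   # full synchrony drives the index towards 1
})

test_that("FOV summary: count identities and additivity under merging", {
  rec <- classify_fast_slow(make_records(c(1, 1.5, 3, 4, NA)))
  rec$class[5] <- "INACTIVE"
  s <- summarize_fov(rec)
  expect_equal(unname(s$counts), c(5, 4, 2, 2))
  expect_lte(s$counts[["n_fast"]] + s$counts[["n_slow"]], s$counts[["n_active"]])
  expect_lte(s$counts[["n_active"]], s$counts[["n_total"]])
  g <- glance(s)
  expect_equal(g$n_active, 4)

  # all INACTIVE: zero active, class means flagged NA
  rec0 <- make_records(c(NA, NA)); rec0$class <- "INACTIVE"
  s0 <- summarize_fov(rec0)
  expect_equal(s0$counts[["n_active"]], 0)
  expect_true(all(is.na(s0$by_class$mean_amplitude)))

  # merging two identical FOVs doubles counts and preserves means
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, cell_id = cell_id + 10))
  s2 <- summarize_fov(rec2)
  expect_equal(unname(s2$counts), 2 * unname(s$counts))
  expect_equal(s2$by_class$mean_amplitude, s$by_class$mean_amplitude)
})

test_that("evoked responses follow (F - F0)/F0 exactly", {
  tt <- 0:899   # 1 Hz, 15 min
  base <- tibble::tibble(cell_id = 1L, time_s = tt, f = 80)
  r0 <- evoked_response(base, puff_time_s = 300)
  expect_equal(r0$peak_response, 0)
  expect_false(r0$responder)

  step <- tibble::tibble(cell_id = 1L, time_s = tt,
                         f = ifelse(tt < 300, 120, 240))
  r1 <- evoked_response(step, puff_time_s = 300)
  expect_equal(r1$peak_response, 1)
  expect_true(r1$responder)
  # scale invariance
  step2 <- dplyr::mutate(step, f = f * 5.5)
  expect_equal(evoked_response(step2, puff_time_s = 300)$peak_response, 1)
  expect_error(evoked_response(base, puff_time_s = 2000), "within")
})

test_that("a simulated responder fraction is recovered within binomial error", {
  set.seed(88)
  n <- 80; p_true <- 0.75
  responders <- runif(n) < p_true
  tt <- 0:899
  traces <- dplyr::bind_rows(lapply(1:n, function(i) {
    amp <- if (responders[i]) runif(1, 0.3, 1) else 0
    f <- 100 * (1 + amp * exp(-pmax(tt - 300, 0) / 30) *
                  (tt >= 300)) + rnorm(900, 0, 1)
    tibble::tibble(cell_id = i, time_s = tt, f = f)
  }))
  est <- glance(evoked_response(traces, puff_time_s = 300))$responder_fraction
  expect_lt(abs(est - mean(responders)), 3 * sqrt(0.75 * 0.25 / n) + 0.02)
})

test_that("group comparison picks tests per normality and reports direction", {
  set.seed(5)
  a <- tibble::tibble(amplitude = rnorm(14, 0.2, 0.02),
                      frequency = rexp(14, 10))
  # identical groups: location tests are far from significant
  same <- tidy(compare_groups(a, a))
  expect_true(all(same$p_value > 0.9))
  expect_true(all(same$ks_statistic == 0))

  # a large shift is detected (n = 14 per group)
  b <- dplyr::mutate(a, amplitude = amplitude + 1)
  cmp <- tidy(compare_groups(a, b, metrics = "amplitude",
                             labels = c("WT", "KO")))
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$direction, "KO > WT")

  # insufficient n is skipped with a notice
  expect_warning(
    cmp2 <- compare_groups(a[1:2, ], b[1:2, ], metrics = "amplitude"),
    "skipped")
  expect_equal(nrow(tidy(cmp2)), 0L)
})
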