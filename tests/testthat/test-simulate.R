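test_that("transient model is causal, scales with a, and rejects bad taus", {
  t <- seq(-5, -0.1, by = 0.1)
  expect_equal(simulate_transient(t, t0 = 0, tau_on = 1, tau_off = 2, a = 1),
               rep(0, length(t)))
  t2 <- seq(0, 20, by = 0.05)
  expect_equal(simulate_transient(t2, 0, 1, 2, a = 0), rep(0, length(t2)))
  expect_error(simulate_transient(t2, 0, -1, 2, 1), "tau_on")
  expect_error(simulate_transient(t2, 0, 1, 0, 1), "tau_off")
})

test_that("transient peak occurs at t0 + tau_on*log(1 + tau_off/tau_on)", {
  # closed form from d/dt = 0; checked against a fine-grid argmax
  expect_equal(transient_peak_time(1, 2), log(3))
  tg <- seq(0, 30, by = 1e-4)
  for (p in list(c(1, 2), c(0.5, 3), c(5, 8))) {
    y <- simulate_transient(tg, 0, p[1], p[2], 1)
    expect_equal(tg[which.max(y)], transient_peak_time(p[1], p[2]),
                 tolerance = 1e-3)
    expect_equal(max(y), transient_peak_factor(p[1], p[2]), tolerance = 1e-6)
  }
})

test_that("trace generator: zero rate and zero noise give a flat trace", {
  tr <- simulate_trace(duration_s = 60, event_rate_hz = 0, baseline_drift = 0,
                       noise_sd = 0, seed = 1)
  expect_equal(tr$raw, rep(tr$raw[1], length(tr$raw)))
  expect_equal(nrow(tr$events), 0L)
})

test_that("trace generator is deterministic given a seed", {
  a <- simulate_trace(noise_sd = 2, event_rate_hz = 0.05, seed = 99)
  b <- simulate_trace(noise_sd = 2, event_rate_hz = 0.05, seed = 99)
  expect_identical(a$raw, b$raw)
  expect_identical(a$events, b$events)
})

test_that("event counts follow the Poisson expectation", {
  # rate 0.05 Hz over 300 s: mean 15 events; 500 seeds
  counts <- vapply(1:500, function(s) {
    nrow(simulate_trace(duration_s = 300, event_rate_hz = 0.05,
                        noise_sd = 0, seed = s)$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 500))
})

test_that("noise-free trace equals the closed-form superposition exactly", {
  tr <- simulate_trace(duration_s = 120, event_times_s = c(20, 50, 90),
                       tau_on_s = 1, tau_off_s = 4, amplitude_dff = 0.3,
                       baseline_drift = 0, noise_sd = 0, seed = 3)
  manual <- rep(0, length(tr$time_s))
  for (i in seq_len(nrow(tr$events))) {
    manual <- manual + simulate_transient(tr$time_s, tr$events$t0_s[i],
                                          tr$events$tau_on_s[i],
                                          tr$events$tau_off_s[i],
                                          tr$events$a[i])
  }
  expect_equal(max(abs(tr$raw / tr$baseline - 1 - manual)), 0, tolerance = 1e-12)
})

test_that("movie with no cells and no noise is exactly the baseline image", {
  cfg <- sim_movie_config(fov_height_px = 40, fov_width_px = 40,
                          n_fast_cells = 0, n_slow_cells = 0,
                          n_silent_cells = 0, duration_s = 10,
                          noise_sd = 0, baseline_drift = 0, seed = 1)
  sim <- simulate_movie(cfg)
  expect_true(all(sim$movie$frames == cfg$baseline_level))
})

test_that("movie generation is deterministic and truth is self-consistent", {
  cfg <- sim_movie_config(fov_height_px = 60, fov_width_px = 60,
                          n_fast_cells = 3, n_slow_cells = 3,
                          n_silent_cells = 1, duration_s = 30,
                          noise_sd = 1, seed = 11)
  a <- simulate_movie(cfg); b <- simulate_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$events, b$truth$events)
  # ground-truth bookkeeping: per-cell event counts match the event table
  tab <- table(factor(a$truth$events$cell_id, levels = a$truth$cells$cell_id))
  expect_equal(as.integer(tab), a$truth$cells$n_events)
  # written TIFF is byte-identical across re-runs
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(a$movie, f1); write_stack(b$movie, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("noiseless movie peaks coincide with ground-truth centers", {
  cfg <- sim_movie_config(fov_height_px = 150, fov_width_px = 150,
                          n_fast_cells = 10, n_slow_cells = 10,
                          n_silent_cells = 0, duration_s = 60,
                          event_rate_hz = c(fast = 0.1, slow = 0.1),
                          noise_sd = 0, baseline_drift = 0, seed = 21)
  sim <- simulate_movie(cfg)
  mx <- apply(sim$movie$frames, c(1, 2), max)
  act <- sim$truth$cells[sim$truth$cells$n_events > 0, ]
  for (i in seq_len(nrow(act))) {
    # the max-projection restricted to the footprint peaks at the center
    r <- act$row[i]; cc <- act$col[i]
    block <- mx[(r - 4):(r + 4), (cc - 4):(cc + 4)]
    expect_equal(which(block == max(block), arr.ind = TRUE)[1, ],
                 c(row = 5, col = 5))
  }
})

test_that("kinetic classes are separated by construction across seeds", {
  for (s in 1:5) {
    cfg <- sim_movie_config(fov_height_px = 80, fov_width_px = 80,
                            n_fast_cells = 4, n_slow_cells = 4,
                            n_silent_cells = 0, duration_s = 60,
                            noise_sd = 0, seed = s)
    ev <- simulate_movie(cfg)$truth
    fast_ids <- ev$cells$cell_id[ev$cells$class == "FAST"]
    expect_true(all(ev$events$tau_on_s[ev$events$cell_id %in% fast_ids] < 2))
    expect_true(all(ev$events$tau_on_s[!ev$events$cell_id %in% fast_ids] > 2))
  }
  expect_error(sim_movie_config(tau_on_s = c(fast = 2.5, slow = 5)), "fast")
  expect_error(sim_movie_config(tau_on_s = c(fast = 1, slow = 1.5)), "slow")
})

test_that("puncta generator honours the colocalization bookkeeping", {
  p0 <- simulate_puncta(n1 = 100, n2 = 100, coloc_fraction = 0,
                        image_shape = c(256, 256), seed = 1)
  expect_equal(p0$truth$n_colocalized, 0)
  p1 <- simulate_puncta(n1 = 80, n2 = 80, coloc_fraction = 1,
                        image_shape = c(256, 256), seed = 2)
  expect_equal(p1$truth$n_colocalized, 80)
  p <- simulate_puncta(n1 = 300, n2 = 300, coloc_fraction = 0.15,
                       image_shape = c(512, 512), seed = 3)
  expect_equal(p$truth$n_colocalized, 45)  # round(0.15 * 300)
  expect_lte(p$truth$n_colocalized, min(300, 300))
  # determinism
  q <- simulate_puncta(n1 = 300, n2 = 300, coloc_fraction = 0.15,
                       image_shape = c(512, 512), seed = 3)
  expect_identical(p$ch1, q$ch1)
  # impossible density fails loudly
  expect_error(simulate_puncta(n1 = 500, n2 = 500, coloc_fraction = 0,
                               image_shape = c(64, 64), seed = 4),
               "density|place")
})

test_that("organoid masks carry exact analytic geometry", {
  circ <- simulate_organoid_mask("circle", radius_px = 50, pixel_size_um = 10)
  expect_equal(circ$truth$max_diameter_px, 100)
  expect_equal(circ$truth$area_px2, pi * 2500)
  expect_equal(circ$truth$max_diameter_mm, 1)

  sq <- simulate_organoid_mask("square", side_px = 80, pixel_size_um = 10)
  expect_equal(sq$truth$max_diameter_px, 80 * sqrt(2))
  expect_equal(sq$truth$perimeter_px, 320)

  ell <- simulate_organoid_mask("ellipse", semi_axes_px = c(60, 30),
                                pixel_size_um = 10)
  # independent quadrature oracle: dense arc-length sum
  th <- seq(0, 2 * pi, length.out = 2e5)
  oracle <- sum(sqrt(diff(60 * cos(th))^2 + diff(30 * sin(th))^2))
  expect_equal(ell$truth$perimeter_px, oracle, tolerance = 1e-6)
  expect_error(simulate_organoid_mask("circle", radius_px = 300,
                                      image_shape = c(256, 256)),
               "bounds")
})
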