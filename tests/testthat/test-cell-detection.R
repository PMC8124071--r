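test_that("activity map of a constant movie is identically zero", {
  mv <- ca_movie(array(7, dim = c(20, 20, 30)), 4)
  expect_true(all(compute_activity_map(mv)$values == 0))
  expect_error(compute_activity_map(ca_movie(array(1, c(5, 5, 1)), 4)),
               "2 frames")
})

test_that("unfiltered map of a flickering pixel is confined to that pixel", {
  fr <- array(0.5, dim = c(16, 16, 20))
  fr[5, 9, seq(1, 20, by = 2)] <- 1.5
  mv <- ca_movie(fr, 4)
  m <- compute_activity_map(mv, cutoff_frac = 1, smooth_window_s = 0)$values
  expect_gt(m[5, 9], 0)
  m[5, 9] <- 0
  expect_true(all(m == 0))
})

test_that("activity map is invariant to a constant intensity offset", {
  sim <- small_movie(seed = 5)
  m1 <- compute_activity_map(sim$movie)$values
  mv2 <- ca_movie(sim$movie$frames + 123.4, 4)
  m2 <- compute_activity_map(mv2)$values
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("detection recovers ground-truth centers on a noiseless movie", {
  sim <- small_movie(seed = 8, noise_sd = 0)
  rois <- detect_rois(compute_activity_map(sim$movie))
  act <- sim$truth$cells[sim$truth$cells$n_events > 0, ]
  expect_true(all(nearest_roi_dist(rois, act) <= 2))   # recall 1 within 2 px
  fp <- vapply(seq_len(nrow(rois)), function(j) {
    sqrt(min((act$row - rois$row[j])^2 + (act$col - rois$col[j])^2)) > 2
  }, logical(1))
  expect_false(any(fp))                                 # precision 1
})

test_that("ROI detection respects threshold, cap and empty maps", {
  expect_equal(nrow(detect_rois(matrix(0, 30, 30))), 0L)
  # 250 synthetic bumps, cap at 200
  set.seed(4)
  m <- matrix(0, 340, 340)
  ctr <- expand.grid(row = seq(15, 330, by = 21), col = seq(15, 330, by = 21))
  ctr <- ctr[1:250, ]
  for (i in 1:250) {
    r <- ctr$row[i]; cc <- ctr$col[i]
    m[(r - 3):(r + 3), (cc - 3):(cc + 3)] <-
      outer(exp(-(-3:3)^2 / 4), exp(-(-3:3)^2 / 4)) * runif(1, 0.5, 1)
  }
  rois <- detect_rois(m, min_separation_px = 10, threshold_frac = 0.1,
                      max_cells = 200)
  expect_equal(nrow(rois), 200L)
  # without the cap all 250 are found
  expect_equal(nrow(detect_rois(m, min_separation_px = 10,
                                threshold_frac = 0.1, max_cells = 500)), 250L)
})

test_that("ROI edits: add/remove inverse, unmatched removals reported, cap", {
  m <- matrix(0, 50, 50); m[25, 25] <- 1; m[10, 40] <- 0.8
  rois <- detect_rois(m, min_separation_px = 5, threshold_frac = 0.1,
                      max_cells = 4)
  n0 <- nrow(rois)
  r1 <- edit_rois(rois, add = data.frame(row = 40, col = 10))
  r2 <- edit_rois(r1, remove = data.frame(row = 40, col = 10))
  expect_equal(as.data.frame(r2[c("row", "col")]),
               as.data.frame(rois[c("row", "col")]))
  # removal with no match is reported, not silently ignored
  expect_warning(r3 <- edit_rois(rois, remove = data.frame(row = 1, col = 1)),
                 "edit")
  expect_equal(nrow(r3), n0)
  expect_s3_class(attr(r3, "edit_errors"), "data.frame")
  # removing from an empty set leaves it unchanged with an error record
  empty <- detect_rois(matrix(0, 20, 20))
  expect_warning(r4 <- edit_rois(empty, remove = data.frame(row = 5, col = 5)))
  expect_equal(nrow(r4), 0L)
  # additions beyond the cap are rejected outright
  expect_error(edit_rois(rois, add = data.frame(row = c(5, 6, 7, 8, 9),
                                                col = c(5, 15, 25, 35, 45))),
               "cap")
})

test_that("trace extraction: uniform movies, proportionality, empty sets", {
  mv <- ca_movie(array(3.5, dim = c(30, 30, 10)), 4)
  rois <- detect_rois(matrix(c(rep(0, 445), 1, rep(0, 454)), 30, 30),
                      threshold_frac = 0.1)
  tr <- extract_traces(mv, rois)
  expect_true(all(tr$f == 3.5))
  expect_equal(nrow(extract_traces(mv, detect_rois(matrix(0, 30, 30)))), 0L)

  # single noiseless cell: ROI trace is proportional to the generated signal
  cfg <- sim_movie_config(fov_height_px = 60, fov_width_px = 60,
                          n_fast_cells = 1, n_slow_cells = 0,
                          n_silent_cells = 0, duration_s = 60,
                          event_rate_hz = c(fast = 0.1, slow = 0.1),
                          noise_sd = 0, baseline_drift = 0, seed = 13)
  sim <- simulate_movie(cfg)
  ctr <- sim$truth$cells
  roi1 <- edit_rois(detect_rois(matrix(0, 60, 60)),
                    add = data.frame(row = ctr$row, col = ctr$col))
  tr1 <- extract_traces(sim$movie, roi1)
  time_s <- unique(tr1$time_s)
  truth_sig <- rep(0, length(time_s))
  ev <- sim$truth$events
  for (i in seq_len(nrow(ev))) {
    truth_sig <- truth_sig + simulate_transient(time_s, ev$t0_s[i],
                                                ev$tau_on_s[i], ev$tau_off_s[i],
                                                ev$a[i])
  }
  expect_gt(stats::cor(tr1$f, truth_sig), 1 - 1e-9)
})
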