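test_that("a static specification renders identical frames, deterministically", {
  spec <- synthetic_spec(seed = 30, jitter_amplitude = 0, noise_sigma = 0,
                         n_events = 0, n_frames = 40)
  gen <- generate_video(spec)
  expect_identical(gen$video$frames[[1]], gen$video$frames[[40]])
  gen2 <- generate_video(spec)
  expect_identical(gen$video$frames[[17]], gen2$video$frames[[17]])
  expect_identical(gen$truth$jitter_trajectory, gen2$truth$jitter_trajectory)
})

test_that("gap events advance at the specified speed", {
  spec <- synthetic_spec(seed = 31, n_events = 2, n_frames = 120)
  gen <- generate_video(spec)
  pos <- gen$truth$capillaries[[1]]$event_positions
  for (e in 1:2) {
    p <- pos[, e]
    p <- p[!is.na(p)]
    p <- p[p > 4 & p < max(p) - 4]   # interior, away from clamped ends
    expect_true(all(abs(diff(p) - spec$event_speed) <= 0.5))
  }
})

test_that("infeasible event schedules are rejected", {
  expect_error(synthetic_spec(n_frames = 30), "overlap the path end")
  expect_error(synthetic_spec(event_times = list(c(1, 140)), n_frames = 160),
               "overlap the path end")
  expect_error(synthetic_spec(jitter_amplitude = 30), "jitter amplitude")
})

test_that("rendered colors separate vessel and background under the color score", {
  spec <- synthetic_spec(seed = 32, noise_sigma = 0, jitter_amplitude = 0,
                         n_events = 0, n_frames = 40)
  gen <- generate_video(spec)
  f <- gen$video$frames[[1]]
  score <- 1.5 * f[, , 1] - (f[, , 2] + f[, , 3])
  m <- gen$truth$true_mask > 0
  # vessel core (strict interior) and background away from the vessel edge
  core <- m & capcount:::shift_reflect(m, 1, 0) & capcount:::shift_reflect(m, -1, 0) &
          capcount:::shift_reflect(m, 0, 1) & capcount:::shift_reflect(m, 0, -1)
  far_bg <- !(m | capcount:::shift_reflect(m, 2, 0) | capcount:::shift_reflect(m, -2, 0) |
              capcount:::shift_reflect(m, 0, 2) | capcount:::shift_reflect(m, 0, -2))
  expect_true(all(score[core] > 0))
  expect_true(all(score[far_bg] < 0))
})

test_that("the ground-truth mask is the tube neighborhood of the centerline", {
  spec <- synthetic_spec(seed = 33, n_events = 0, n_frames = 40,
                         image_size = c(96, 128), branch_length = 30,
                         jitter_amplitude = 0)
  gen <- generate_video(spec)
  cl <- gen$truth$capillaries[[1]]$centerline
  d <- matrix(Inf, 96, 128)
  for (i in seq_len(nrow(cl)))
    d <- pmin(d, sqrt(outer((seq_len(96) - cl[i, 1])^2,
                            (seq_len(128) - cl[i, 2])^2, `+`)))
  expect_equal(gen$truth$true_mask, ifelse(d <= spec$tube_radius, 255, 0))
})

test_that("with jitter on, frames equal the unjittered rendering shifted", {
  a <- generate_video(synthetic_spec(seed = 34, noise_sigma = 0,
                                     jitter_amplitude = 4, n_events = 2,
                                     n_frames = 60))
  b <- generate_video(synthetic_spec(seed = 34, noise_sigma = 0,
                                     jitter_amplitude = 0, n_events = 2,
                                     n_frames = 60))
  expect_equal(a$truth$jitter_trajectory[1, ], c(dy = 0L, dx = 0L))
  for (t in c(2, 30, 60))
    expect_identical(a$video$frames[[t]],
                     apply_translation(b$video$frames[[t]],
                                       a$truth$jitter_trajectory[t, ]))
})

test_that("ST fixtures draw the requested line geometry", {
  expect_true(all(make_st_fixture(0)$st$values == 0))
  fx <- make_st_fixture(7, angles = 30, offsets = seq(-30, 30, 10))
  expect_equal(nrow(fx$lines), 7)
  expect_equal(count_events(fx$st)$n_events, 7)
})
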