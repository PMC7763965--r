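test_that("ST maps stack per-frame vectors as columns", {
  st <- build_st_map(replicate(3, c(1, 2, 3), simplify = FALSE), fps = 30)
  expect_equal(st$values, matrix(rep(c(1, 2, 3), 3), 3, 3))
  expect_equal(st$stage, "raw")
  # a bright element advancing one row per frame traces the diagonal
  vecs <- lapply(1:5, function(t) { v <- numeric(5); v[t] <- 9; v })
  st2 <- build_st_map(vecs)
  expect_equal(which(st2$values == 9, arr.ind = TRUE),
               cbind(row = 1:5, col = 1:5), ignore_attr = TRUE)
  expect_error(build_st_map(list(1:3, 1:4)), "length")
})

test_that("an event's ST slope matches the injected velocity", {
  gen <- generate_video(synthetic_spec(seed = 13, noise_sigma = 0,
                                       jitter_amplitude = 0, n_events = 1,
                                       n_frames = 80))
  tb <- trace_boundaries(gen$truth$true_mask)
  geom <- build_intermediates(pair_coordinates(tb$internal, tb$external))
  eq <- equalize_frames(gen$video)
  st <- build_st_map(lapply(eq$frames, sample_capillary_vector, geometry = geom))
  # least squares on per-column argmax over the event's active columns
  v <- st$values
  act <- which(!is.na(gen$truth$capillaries[[1]]$event_positions[, 1]))
  act <- act[5:(length(act) - 5)]
  am <- apply(v[, act], 2, which.max)
  slope <- stats::coef(stats::lm(am ~ act))[2]
  # index advances slightly slower than arc length (inner contour < path)
  expected <- 3 * geom$n_points / gen$truth$capillaries[[1]]$path_length
  expect_lt(abs(abs(slope) - expected) / expected, 0.15)
})

test_that("ST enhancement removes static structure and flags band edges", {
  # constant map dies at the row zero-meaning step
  st <- st_map(matrix(7, 9, 30), stage = "raw")
  expect_true(all(process_st_map(st)$values == 0))
  # rectangular pulse on otherwise constant rows: Sobel leaves exactly two
  # nonzero column bands, at the pulse edges
  m <- matrix(1, 5, 40); m[, 15:24] <- 10
  proc <- process_st_map(st_map(m, stage = "raw"))
  nz <- which(colSums(proc$values) > 0)
  runs <- split(nz, cumsum(c(1, diff(nz) > 1)))
  expect_length(runs, 2)
  expect_true(all(abs(range(runs[[1]]) - 15) <= 2))
  expect_true(all(abs(range(runs[[2]]) - 24) <= 2))
  # isolated speck is removed by the median filter
  sp <- matrix(0, 9, 30); sp[5, 15] <- 100
  expect_true(all(process_st_map(st_map(sp, stage = "raw"))$values == 0))
  expect_error(process_st_map(st_map(matrix(0, 2, 2), stage = "raw"), 5),
               "kernel")
})

test_that("row zero-meaning removes constant baselines", {
  set.seed(14)
  # noisy raw map with two genuine slanted event bands
  bands <- make_st_fixture(2, angles = 30, offsets = c(-20, 20),
                           thickness = 4, shape = c(60, 80), strength = 150)
  m <- bands$st$values + matrix(runif(60 * 80) * 25, 60, 80)
  # a global constant passes through the median filter and dies at the
  # zero-meaning step: exact invariance
  p1 <- process_st_map(st_map(m, stage = "raw"))$values
  p2 <- process_st_map(st_map(m + 37, stage = "raw"))$values
  expect_equal(p1, p2, tolerance = 1e-12)
  # a smooth per-row baseline (static vessel structure) is removed up to the
  # median filter's row mixing; the detected events must be unchanged
  baseline <- 30 * sin(seq(0, pi, length.out = 60))
  p3 <- process_st_map(st_map(m + baseline, stage = "raw"))
  ev1 <- count_events(st_map(p1, stage = "processed"))
  ev3 <- count_events(p3)
  expect_equal(ev1$n_events, 2)
  expect_equal(ev3$n_events, 2)
  expect_equal(vapply(ev3$events, `[[`, 0, "theta"),
               vapply(ev1$events, `[[`, 0, "theta"), tolerance = 0.1)
})

test_that("well-separated lines survive processing as distinct ridges", {
  fx <- make_st_fixture(3, angles = 25, offsets = c(-30, 0, 30), thickness = 3)
  raw <- st_map(fx$st$values, stage = "raw")
  proc <- process_st_map(raw)$values
  # the gradient magnitude flags each line as a pair of edge ridges a line
  # width apart; closing that gap leaves one component per event
  mask <- proc > max(proc) / 2
  dil <- mask
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(-1, -1), c(1, -1), c(-1, 1)))
    dil <- dil | capcount:::shift_reflect(mask, d[1], d[2])
  expect_equal(max(capcount:::label_components(dil)), 3)
})
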