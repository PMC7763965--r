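gauss_bump <- function(m, t0, z0, amp = 1, sd = 2) {
  nt <- nrow(m); nz <- ncol(m)
  m + amp * exp(-(outer((seq_len(nt) - t0)^2, (seq_len(nz) - z0)^2, `+`)) / (2 * sd^2))
}

test_that("local maxima detection finds isolated peaks and breaks ties", {
  vals <- gauss_bump(matrix(0, 40, 60), 20, 30)
  pm <- polar_map(vals, thetas = seq_len(40), zs = seq_len(60) - 31)
  mx <- detect_local_maxima(pm, c(5, 5), 0.3)
  expect_equal(nrow(mx), 1)
  expect_equal(c(mx$theta, mx$z), c(20, pm$zs[30]))
  # two equal bumps farther apart than the window: both found, and equal
  # strengths are ordered lexicographically by (theta, z)
  v2 <- gauss_bump(gauss_bump(matrix(0, 40, 60), 10, 15), 30, 45)
  pm2 <- polar_map(v2, seq_len(40), seq_len(60) - 31)
  mx2 <- detect_local_maxima(pm2, c(5, 5), 0.3)
  expect_equal(nrow(mx2), 2)
  expect_true(mx2$theta[1] < mx2$theta[2] || mx2$strength[1] > mx2$strength[2])
  # an exactly tied plateau pair inside one window yields a single maximum
  v3 <- matrix(0, 20, 20); v3[10, 8] <- 5; v3[10, 11] <- 5
  pm3 <- polar_map(v3, seq_len(20), seq_len(20) - 11)
  expect_equal(nrow(detect_local_maxima(pm3, c(9, 9), 0.1)), 1)
  expect_equal(nrow(detect_local_maxima(polar_map(matrix(0, 5, 5),
                                                  1:5, -2:2))), 0)
})

test_that("maxima of a three-line fixture identify the injected lines", {
  fx <- make_st_fixture(3, angles = c(30, 30, 70), offsets = c(-25, 10, 30),
                        thickness = 2, shape = c(81, 101))
  pm <- radon_transform(fx$st$values)
  mx <- detect_local_maxima(pm, c(11, 15), 0.35)
  expect_gte(nrow(mx), 3)
  for (i in 1:3) {
    d_th <- abs(mx$theta - fx$lines$theta[i])
    d_z <- abs(mx$z - fx$lines$z[i])
    expect_true(any(d_th <= 2 & d_z <= 2),
                label = sprintf("line %d recovered", i))
  }
})

test_that("base events are the best-populated angle group", {
  mx <- data.frame(theta = c(62, 63, 61, 20), z = c(0, 10, -10, 5),
                   strength = c(5, 4, 3, 10))
  sel <- select_base_events(mx, 5)
  expect_setequal(sel$base$theta, c(61, 62, 63))
  expect_equal(sel$remaining$theta, 20)
  single <- data.frame(theta = 45, z = 3, strength = 1)
  sel1 <- select_base_events(single, 5)
  expect_equal(nrow(sel1$base), 1)
  expect_equal(nrow(sel1$remaining), 0)
})

test_that("deduplication keeps parallels and removes crossing lines", {
  shape <- c(61, 81)
  base <- data.frame(theta = 30, z = 0, strength = 10)
  # parallel candidate at a different offset: kept
  rem_par <- data.frame(theta = 30, z = 15, strength = 5)
  ev <- deduplicate_events(base, rem_par, shape)
  expect_equal(ev$n_events, 2)
  # candidate crossing the base line inside the map: discarded
  rem_x <- data.frame(theta = 60, z = 0, strength = 5)
  ev2 <- deduplicate_events(base, rem_x, shape)
  expect_equal(ev2$n_events, 1)
  # a coincident duplicate (same line) is removed
  rem_dup <- data.frame(theta = 30, z = 0.2, strength = 5)
  expect_equal(deduplicate_events(base, rem_dup, shape)$n_events, 1)
  expect_error(deduplicate_events(base[0, ], rem_par, shape), "empty")
})

test_that("a thick line collapses to exactly one event", {
  fx <- make_st_fixture(1, angles = 35, offsets = 0, thickness = 6,
                        shape = c(81, 101))
  ev <- count_events(fx$st)
  expect_equal(ev$n_events, 1)
  expect_noncrossing(ev)
})

test_that("count_events counts clean fixtures exactly", {
  # all-zero map: no events
  expect_equal(count_events(st_map(matrix(0, 40, 50), stage = "processed"))$n_events, 0)
  # seven well-separated parallel lines: seven events
  fx <- make_st_fixture(7, angles = 30, offsets = seq(-45, 45, length.out = 7),
                        thickness = 2, shape = c(101, 141))
  ev <- count_events(fx$st)
  expect_equal(ev$n_events, 7)
  expect_noncrossing(ev)
  # timestamps are ordered and within the video span
  tt <- vapply(ev$events, `[[`, 0, "time_s")
  expect_true(all(diff(tt) > 0))
})
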