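test_that("FFT registration matches exhaustive spatial search on random masks", {
  set.seed(5)
  for (i in 1:20) {
    ref <- matrix(runif(32 * 32), 32, 32)
    true_shift <- c(sample(-8:8, 1), sample(-8:8, 1))
    mov <- apply_translation(ref, true_shift)   # moving displaced by true_shift
    mov[mov == 0] <- runif(sum(mov == 0)) * 0.2
    got <- get_translation_vec(ref, mov)
    expect_equal(unname(got), brute_shift_search(ref, mov))
  }
})

test_that("registration recovers known displacements, including under noise", {
  u <- make_test_u()
  expect_equal(unname(get_translation_vec(u, u)), c(0L, 0L))
  # moving = reference circularly displaced by (3, -2)
  circ <- u[((seq_len(80) - 1 - 3) %% 80) + 1, ((seq_len(80) - 1 + 2) %% 80) + 1]
  expect_equal(unname(get_translation_vec(u, circ)), c(3L, -2L))
  set.seed(6)
  noisy <- pmin(pmax(apply_translation(u, c(5, 0)) + rnorm(length(u), 0, 10), 0), 255)
  expect_equal(unname(get_translation_vec(u, noisy)), c(5L, 0L))
  expect_error(get_translation_vec(u * 0, u), "all zero")
})

test_that("apply_translation shifts content and zero-fills the border", {
  img <- matrix(0, 20, 20); img[10, 10] <- 9
  expect_identical(apply_translation(img, c(0, 0)), img)
  sh <- apply_translation(img, c(5, -4))
  expect_equal(which(sh == 9, arr.ind = TRUE)[1, ], c(row = 15, col = 6))
  # near-inverse with a zeroed border band
  set.seed(7)
  a <- matrix(runif(100), 10, 10)
  back <- apply_translation(apply_translation(a, c(2, 3)), c(-2, -3))
  expect_equal(back[1:8, 1:7], a[1:8, 1:7])
  expect_true(all(back[9:10, ] == 0) && all(back[, 8:10] == 0))
  # non-border pixel multiset is conserved
  expect_equal(sort(apply_translation(a, c(1, 1))[2:10, 2:10]), sort(a[1:9, 1:9]))
  expect_error(apply_translation(a, c(10, 0)), "larger")
})

test_that("a jitter-free video is a fixed point of stabilization", {
  gen <- generate_video(synthetic_spec(seed = 8, jitter_amplitude = 0,
                                       n_frames = 80, n_events = 1))
  eq <- equalize_frames(gen$video)
  masks <- segment_video(eq, "conventional")
  st <- stabilize(eq, masks, 10)
  expect_true(all(st$trace$per_frame_vectors == 0))
  expect_identical(st$video$frames[[30]], eq$frames[[30]])
})

test_that("stabilization recovers the negated jitter trajectory exactly", {
  gen <- generate_video(synthetic_spec(seed = 9, noise_sigma = 0,
                                       jitter_amplitude = 3, n_events = 2,
                                       n_frames = 80))
  eq <- equalize_frames(gen$video)
  masks <- segment_video(eq, "conventional")
  st <- stabilize(eq, masks, 50)
  expect_equal(unname(st$trace$per_frame_vectors),
               unname(-gen$truth$jitter_trajectory))
  expect_false(any(st$trace$failed))
  expect_equal(st$trace$reference_indices, c(1L, 51L))
})

test_that("the reference-history accumulator composes exactly", {
  # rigid-shift video: per-frame vectors must not depend on the update period
  gen <- generate_video(synthetic_spec(seed = 10, noise_sigma = 0,
                                       jitter_amplitude = 4, n_events = 0,
                                       n_frames = 60))
  eq <- equalize_frames(gen$video)
  masks <- segment_video(eq, "conventional")
  v_never <- stabilize(eq, masks, 60)$trace$per_frame_vectors
  v_often <- stabilize(eq, masks, 5)$trace$per_frame_vectors
  expect_identical(v_never, v_often)
})

test_that("mask ensembling averages and thresholds per pixel", {
  u <- make_test_u()
  same <- replicate(7, u, simplify = FALSE)
  for (thr in c(1, 100, 255))
    expect_equal(ensemble_mask(same, thr)$values, u)
  # pixel present in 40% of binary masks: 0.4*255 = 102 < 150 -> excluded
  on <- matrix(255, 4, 4); off <- matrix(0, 4, 4)
  ens <- ensemble_mask(c(replicate(2, on, simplify = FALSE),
                         replicate(3, off, simplify = FALSE)), 150)
  expect_true(all(ens$values == 0))
  ens2 <- ensemble_mask(c(replicate(2, on, simplify = FALSE),
                          replicate(3, off, simplify = FALSE)), 100)
  expect_true(all(ens2$values == 255))
  # one spurious mask among 50 correct ones does not perturb the ensemble
  set.seed(11)
  junk <- matrix(sample(c(0, 255), length(u), TRUE), nrow(u))
  ens3 <- ensemble_mask(c(replicate(50, u, simplify = FALSE), list(junk)), 128)
  expect_equal(ens3$values, u)
  expect_error(ensemble_mask(list(), 100), "empty")
})
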