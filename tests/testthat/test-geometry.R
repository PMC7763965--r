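test_that("instance extraction filters by area and ranks by size", {
  big <- make_test_u(90, 90, cx = 30)                      # ~ area 700+
  small <- make_test_u(90, 90, cx = 68, spacing = 20, branch_len = 25)
  speck <- matrix(0, 90, 90); speck[85:87, 85:87] <- 255   # 9 px noise
  mask <- pmax(big, small, speck)
  inst <- extract_capillary_instances(mask, max_capillaries = 2, min_area = 200)
  expect_length(inst, 2)
  areas <- vapply(inst, function(m) sum(m > 0), numeric(1))
  expect_true(areas[1] >= areas[2])
  expect_equal(sum(areas), sum(big > 0) + sum(small > 0))
  expect_length(extract_capillary_instances(matrix(0, 10, 10)), 0)
  # diagonal touching joins under 8-connectivity
  dm <- matrix(0, 6, 6); dm[2, 2] <- 255; dm[3, 3] <- 255
  expect_length(capcount:::label_components(dm) |> max(), 1L)
})

test_that("the ROI is the margin-expanded bounding box, clipped to the image", {
  comp <- matrix(0, 100, 100); comp[10:60, 20:50] <- 255
  expect_equal(determine_roi(comp, margin = 2), c(8L, 18L, 62L, 52L))
  expect_equal(determine_roi(comp, margin = 0), c(10L, 20L, 60L, 50L))
  edge <- matrix(0, 30, 30); edge[1:10, 1:10] <- 255
  expect_warning(roi <- determine_roi(edge, margin = 3), "clipped")
  expect_equal(roi, c(1L, 1L, 13L, 13L))
})

test_that("boundary tracing splits a hairpin into internal and external contours", {
  u <- make_test_u()
  tb <- trace_boundaries(u)
  # internal length matches an independent digital inner-boundary count
  oracle_n <- inner_boundary_oracle(u)
  expect_lte(abs(nrow(tb$internal) - oracle_n), 4)
  # disjoint pixel sets
  key <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(key(tb$internal), key(tb$external)), 0)
  # simple path: each internal pixel visited exactly once
  expect_false(any(duplicated(key(tb$internal))))
  # ordered from the left branch's free end over the arch to the right
  expect_lt(tb$internal[1, 2], tb$internal[nrow(tb$internal), 2])
  expect_lt(min(tb$internal[, 1]), tb$internal[1, 1])  # passes over the arch
  # all contour pixels lie on the component
  expect_true(all(u[tb$internal] > 0) && all(u[tb$external] > 0))
})

test_that("non-hairpin topologies raise a geometry error", {
  solid <- matrix(0, 30, 30); solid[5:25, 5:25] <- 255
  expect_error(trace_boundaries(solid), "geometry error")
  blob <- matrix(0, 30, 30); blob[10:20, 10:20] <- 255; blob[12:18, 12:18] <- 255
  expect_error(trace_boundaries(blob), "geometry error")
})

test_that("external resampling pairs radially on concentric circles", {
  ang_in <- seq(0, 2 * pi, length.out = 73)[-73]
  inner <- cbind(40 + 5 * sin(ang_in), 40 + 5 * cos(ang_in))
  ang_out <- seq(0, 2 * pi, length.out = 241)[-241]
  outer <- cbind(40 + 10 * sin(ang_out), 40 + 10 * cos(ang_out))
  geom <- pair_coordinates(inner, outer, closed = TRUE)
  expect_equal(geom$n_points, nrow(inner))
  # every paired segment's line passes near the common center
  for (k in seq(1, geom$n_points, by = 6)) {
    a <- geom$internal_coords[k, ]; b <- geom$external_coords[k, ]
    d <- b - a
    dist_center <- abs(d[2] * (40 - a[1]) - d[1] * (40 - a[2])) / sqrt(sum(d^2))
    expect_lt(dist_center, 1.5)
  }
  # resampled external points are equally spaced in arc length
  difs <- sqrt(rowSums((geom$external_coords -
    rbind(geom$external_coords[-1, ], geom$external_coords[1, ]))^2))
  expect_lt(max(difs) - min(difs), 1)
})

test_that("resampling count contract and degenerate inputs", {
  inner <- cbind(c(5, 5, 6), c(5, 6, 6))
  outer <- cbind(c(3, 3, 3, 8, 8, 8), c(3, 5, 8, 8, 5, 3))
  geom <- pair_coordinates(inner, outer)
  expect_equal(nrow(geom$external_coords), 3)
  expect_error(pair_coordinates(inner[1:2, ], outer), "3 internal")
  expect_error(pair_coordinates(inner, outer[1:2, ]), "fewer")
})

test_that("intermediate coordinates are the interior pixels of digital segments", {
  g <- capillary_geometry(internal = cbind(c(1, 3, 5), c(1, 3, 5)),
                          external = cbind(c(1, 3, 5), c(5, 4, 8)))
  g <- build_intermediates(g)
  expect_equal(g$intermediate_coords[[1]], cbind(c(1, 1, 1), c(2, 3, 4)),
               ignore_attr = TRUE)                       # horizontal run
  # adjacent pair -> empty set
  g2 <- capillary_geometry(cbind(c(1, 2, 3), c(1, 1, 1)),
                           cbind(c(1, 2, 3), c(2, 2, 2)))
  g2 <- build_intermediates(g2)
  expect_equal(nrow(g2$intermediate_coords[[1]]), 0)
  # diagonal: the two interior pixels of the 8-connected digital diagonal
  g3 <- capillary_geometry(cbind(c(1, 5, 9), c(1, 1, 1)),
                           cbind(c(4, 5, 9), c(4, 4, 4)))
  g3 <- build_intermediates(g3)
  expect_equal(g3$intermediate_coords[[1]], cbind(c(2, 3), c(2, 3)),
               ignore_attr = TRUE)
})

test_that("capillary vectors average internal, external and intermediate pixels", {
  geom <- build_intermediates(capillary_geometry(
    internal = cbind(c(3, 5, 7), c(3, 3, 3)),
    external = cbind(c(3, 5, 7), c(5, 5, 5))))
  frame <- matrix(100, 10, 10)
  expect_equal(unname(sample_capillary_vector(frame, geom)), rep(100, 3),
               ignore_attr = TRUE)
  # internal = 0, external = 0, single intermediate = 255 -> mean 85
  frame2 <- matrix(0, 10, 10); frame2[3, 4] <- 255
  v <- sample_capillary_vector(frame2, geom)
  expect_equal(v[[1]], 85)
  # a bright blob at path position k is the vector argmax near k
  u <- make_test_u()
  tb <- trace_boundaries(u)
  gu <- build_intermediates(pair_coordinates(tb$internal, tb$external))
  img <- matrix(10, 80, 80)
  k_star <- 20
  ctr <- gu$internal_coords[k_star, ]
  img[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2)] <- 255
  vv <- sample_capillary_vector(img, gu)
  expect_lte(abs(which.max(vv) - k_star), 2)
})

test_that("internal traversal is monotone along the generator centerline", {
  gen <- generate_video(synthetic_spec(seed = 12, noise_sigma = 0,
                                       jitter_amplitude = 0, n_events = 0,
                                       n_frames = 40))
  tb <- trace_boundaries(gen$truth$true_mask)
  cl <- gen$truth$capillaries[[1]]$centerline
  cum <- gen$truth$capillaries[[1]]$cumlen
  pos <- apply(tb$internal, 1, function(p)
    cum[which.min((cl[, 1] - p[1])^2 + (cl[, 2] - p[2])^2)])
  # allow small local ties from pixelation, no global direction reversals
  expect_gt(mean(diff(pos) >= -1), 0.97)
  expect_gt(stats::cor(pos, seq_along(pos)), 0.99)
})
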