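# Independent oracles and small constructed fixtures shared across tests.

# Exhaustive spatial-domain circular cross-correlation search: returns the
# integer displacement of `moving` relative to `reference` (moving is
# reference shifted by the result), unwrapped to the signed half-range.
# Independent of the FFT implementation under test.
brute_shift_search <- function(reference, moving) {
  h <- nrow(reference); w <- ncol(reference)
  best <- c(0L, 0L); best_v <- -Inf
  for (dy in 0:(h - 1)) {
    rows <- ((seq_len(h) - 1 - dy) %% h) + 1     # reference shifted down by dy
    shifted_rows <- reference[rows, , drop = FALSE]
    for (dx in 0:(w - 1)) {
      cols <- ((seq_len(w) - 1 - dx) %% w) + 1
      v <- sum(moving * shifted_rows[, cols])
      if (v > best_v) { best_v <- v; best <- c(dy, dx) }
    }
  }
  if (best[1] > h %/% 2) best[1] <- best[1] - h
  if (best[2] > w %/% 2) best[2] <- best[2] - w
  best
}

# Brute-force Radon oracle: dense nearest-neighbor sampling of the
# piecewise-constant image along each line, aggregated per unit offset bin.
radon_oracle <- function(img, theta_deg, zs, zstep = 0.1, sstep = 0.05) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta_deg * pi / 180
  smax <- sqrt(h^2 + w^2) / 2 + 1
  s <- seq(-smax, smax, by = sstep)
  vapply(zs, function(z) {
    zeta <- seq(z - 0.5 + zstep / 2, z + 0.5 - zstep / 2, by = zstep)
    tot <- 0
    for (zz in zeta) {
      r <- round(cy - zz * sin(th) + s * cos(th))
      c_ <- round(cx + zz * cos(th) + s * sin(th))
      ok <- r >= 1 & r <= h & c_ >= 1 & c_ <= w
      tot <- tot + sum(img[cbind(r[ok], c_[ok])]) * sstep
    }
    tot / length(zeta)
  }, numeric(1))
}

# Clean binary U-shape (hairpin): two vertical bars joined by a semicircular
# arch, built directly from pixel distances to an analytic centerline.
make_test_u <- function(h = 80, w = 80, cx = 40, arch_row = 25,
                        spacing = 24, branch_len = 35, tube = 3) {
  rr <- spacing / 2
  s <- seq(0, 1, by = 0.005)
  up <- cbind(arch_row + branch_len * (1 - s), cx - rr)
  phi <- seq(pi, 0, length.out = 200)
  arch <- cbind(arch_row - rr * sin(phi), cx + rr * cos(phi))
  down <- cbind(arch_row + branch_len * s, cx + rr)
  pts <- rbind(up, arch, down)
  d <- matrix(Inf, h, w)
  for (i in seq_len(nrow(pts))) {
    rs <- max(1, floor(pts[i, 1] - tube - 1)):min(h, ceiling(pts[i, 1] + tube + 1))
    cs <- max(1, floor(pts[i, 2] - tube - 1)):min(w, ceiling(pts[i, 2] + tube + 1))
    d[rs, cs] <- pmin(d[rs, cs], sqrt(outer((rs - pts[i, 1])^2, (cs - pts[i, 2])^2, `+`)))
  }
  ifelse(d <= tube, 255, 0)
}

# Count the digital inner boundary of a U independently: mask pixels
# 4-adjacent to the inter-branch background region, found by flood fill from
# a seed between the branches (bounded by the component's bounding box plus
# the open bottom row).
inner_boundary_oracle <- function(mask) {
  m <- mask != 0
  idx <- which(m, arr.ind = TRUE)
  top <- min(idx[, 1]); bot <- max(idx[, 1])
  seed_col <- round(mean(range(idx[, 2])))
  seed_row <- bot
  stopifnot(!m[seed_row, seed_col])
  h <- nrow(m); w <- ncol(m)
  visited <- matrix(FALSE, h, w)
  queue <- matrix(c(seed_row, seed_col), 1)
  visited[seed_row, seed_col] <- TRUE
  while (nrow(queue)) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] < top || q[1] > bot) next
      if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w) next
      if (m[q[1], q[2]] || visited[q[1], q[2]]) next
      visited[q[1], q[2]] <- TRUE
      queue <- rbind(queue, q)
    }
  }
  cnt <- 0
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c_ <- idx[i, 2]
    nb <- rbind(c(r - 1, c_), c(r + 1, c_), c(r, c_ - 1), c(r, c_ + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, , drop = FALSE]
    if (any(visited[nb])) cnt <- cnt + 1
  }
  cnt
}

# Independent pairwise non-crossing check on a final event set: solves each
# pair of (theta, z) lines analytically and asserts no intersection strictly
# inside the ST map.
expect_noncrossing <- function(ev) {
  df <- as.data.frame(ev)
  if (nrow(df) < 2) return(invisible(TRUE))
  h <- ev$st_shape[1]; w <- ev$st_shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  for (i in seq_len(nrow(df) - 1)) for (j in (i + 1):nrow(df)) {
    t1 <- df$theta[i] * pi / 180; t2 <- df$theta[j] * pi / 180
    det <- sin(t1 - t2)
    if (abs(det) < 1e-9) next
    u <- (df$z[j] * sin(t1) - df$z[i] * sin(t2)) / det
    v <- (df$z[j] * cos(t1) - df$z[i] * cos(t2)) / det
    r <- cy + v; c_ <- cx + u
    expect_false(r > 1 && r < h && c_ > 1 && c_ < w,
                 label = sprintf("events %d and %d cross at (%.1f, %.1f)",
                                 i, j, r, c_))
  }
  invisible(TRUE)
}

# shared run of the conventional stabilized arm returning the total count
run_conventional_arm <- function(video, stabilize = TRUE) {
  res <- wbc_pipeline(video, wbc_config(method = "conventional",
                                        stabilize = stabilize))
  sum(vapply(res$event_sets, `[[`, 0L, "n_events"))
}

# deterministic draw without disturbing the ambient RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
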