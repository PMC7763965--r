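# Small raster primitives shared across the pipeline. Images are numeric
# matrices (grayscale) or H x W x 3 arrays (RGB), intensities on the 0..255
# scale, indexed (row, col) with row 1 at the top.

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Reflected (symmetric, edge-repeating) index into 1..n.
#' @keywords internal
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  clamp(i, 1L, n)
}

# Shift a matrix so content at (r, c) comes from (r - dy, c - dx), with
# reflected borders; used by the filtering kernels.
#' @keywords internal
shift_reflect <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[reflect_index(seq_len(h) - dy, h), reflect_index(seq_len(w) - dx, w), drop = FALSE]
}

# Median of 9 values held in 9 equally-shaped matrices, via a sorting
# network (fully vectorised; used by the 3x3 median filter).
#' @keywords internal
median9 <- function(p) {
  s <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network; result lands in p[[5]]
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

# k x k median filter with reflected borders; k = 3 uses the sorting
# network, larger (odd) kernels fall back to a direct per-pixel median.
#' @keywords internal
median_filter <- function(m, k = 3L) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  if (k == 1L) return(m)
  if (k > min(dim(m))) stop("median kernel larger than the map", call. = FALSE)
  offs <- seq_len(k) - (k + 1L) %/% 2L
  layers <- vector("list", k * k)
  i <- 0L
  for (dy in offs) for (dx in offs) {
    i <- i + 1L
    layers[[i]] <- shift_reflect(m, dy, dx)
  }
  if (k == 3L) return(median9(layers))
  stacked <- vapply(layers, as.vector, numeric(length(m)))
  out <- apply(stacked, 1L, stats::median)
  matrix(out, nrow(m), ncol(m))
}

# Sobel gradient images (Gx along columns/time, Gy along rows), reflect
# padded. Returns list(gx, gy, magnitude).
#' @keywords internal
sobel <- function(m) {
  sx <- function(dy, dx, wgt) wgt * shift_reflect(m, dy, dx)
  gx <- sx(-1, -1, -1) + sx(0, -1, -2) + sx(1, -1, -1) +
        sx(-1,  1,  1) + sx(0,  1,  2) + sx(1,  1,  1)
  gy <- sx(-1, -1, -1) + sx(-1, 0, -2) + sx(-1, 1, -1) +
        sx( 1, -1,  1) + sx( 1, 0,  2) + sx( 1, 1,  1)
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# Linear rescale of a non-negative map so its maximum lands on 255.
# An all-zero map stays zero.
#' @keywords internal
rescale255 <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  pmin(m * (255 / mx), 255)
}

# Bilinear resize of a matrix to (h2, w2) (pixel-center aligned).
#' @keywords internal
resize_bilinear <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  ys <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  xs <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- clamp(floor(ys), 1, h); y1 <- clamp(y0 + 1, 1, h); fy <- clamp(ys - y0, 0, 1)
  x0 <- clamp(floor(xs), 1, w); x1 <- clamp(x0 + 1, 1, w); fx <- clamp(xs - x0, 0, 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  fyM <- matrix(fy, h2, w2); fxM <- matrix(fx, h2, w2, byrow = TRUE)
  a * (1 - fyM) * (1 - fxM) + b * (1 - fyM) * fxM + c_ * fyM * (1 - fxM) + d * fyM * fxM
}

#' @keywords internal
resize_nearest <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  ys <- clamp(ceiling((seq_len(h2) - 0.5) * h / h2), 1, h)
  xs <- clamp(ceiling((seq_len(w2) - 0.5) * w / w2), 1, w)
  m[ys, xs, drop = FALSE]
}

#' @keywords internal
resize_rgb <- function(a, h2, w2) {
  out <- array(0, c(h2, w2, dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- resize_bilinear(a[, , ch], h2, w2)
  out
}

# Integer pixels on the 8-connected digital segment between two (row, col)
# points, endpoints included (Bresenham).
#' @keywords internal
bresenham <- function(p0, p1) {
  r0 <- as.integer(round(p0[1])); c0 <- as.integer(round(p0[2]))
  r1 <- as.integer(round(p1[1])); c1 <- as.integer(round(p1[2]))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(NA_integer_, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

# 8-connected labeling of a logical/binary matrix. Returns an integer
# matrix of labels (0 = background), labels in first-encounter order.
#' @keywords internal
label_components <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  # work on padded linear indices so all 8 neighbor offsets are safe
  hp <- h + 2L
  pad <- matrix(FALSE, hp, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  nbr <- c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  todo <- which(pad)
  cur <- 0L
  for (s in todo) {
    if (!pad[s]) next
    cur <- cur + 1L
    queue <- s; pad[s] <- FALSE
    members <- integer(0)
    while (length(queue)) {
      members <- c(members, queue)
      cand <- unique(as.vector(outer(queue, nbr, `+`)))
      cand <- cand[pad[cand]]
      pad[cand] <- FALSE
      queue <- cand
    }
    pr <- (members - 1L) %% hp + 1L
    pc <- (members - 1L) %/% hp + 1L
    lab[cbind(pr - 1L, pc - 1L)] <- cur
  }
  lab
}
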