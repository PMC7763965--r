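# Discrete Radon transform and line reconstruction. A line in the ST map is
# parameterized by the angle theta of its normal measured from the time
# (column) axis and its signed offset z from the map center: pixels (r, c)
# on the line satisfy  (c - cx) cos(theta) - (r - cy) sin(theta) = z,
# with (cy, cx) the map center. theta = 0 gives the central vertical line.

#' Polar map container (Radon transform output)
#'
#' @param values `length(thetas) x length(zs)` matrix of line integrals.
#' @param thetas angle grid in degrees.
#' @param zs signed offset grid in pixels (zero-centered).
#' @return An object of class `polar_map`.
#' @export
polar_map <- function(values, thetas, zs) {
  stopifnot(is.matrix(values), nrow(values) == length(thetas),
            ncol(values) == length(zs))
  structure(list(values = values, thetas = thetas, zs = zs),
            class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("<polar_map> %d angles x %d offsets, max %.3g\n",
              length(x$thetas), length(x$zs), max(x$values)))
  invisible(x)
}

#' Discrete Radon transform
#'
#' For each angle theta and signed offset z, computes the line integral of
#' the piecewise-constant (pixel-valued) image along the line with normal
#' direction theta at offset z from the image center, aggregated per unit
#' offset bin. The projection of a unit pixel onto the offset axis is the
#' trapezoid `box(|cos t|) * box(|sin t|)` (a convolution of two boxes);
#' each pixel deposits its value into the (at most three) bins its footprint
#' overlaps, weighted by the exact trapezoid CDF. Total mass per angle is
#' conserved exactly, and the projections at 0 and 90 degrees are exact
#' column/row sums (odd image sizes).
#'
#' @param image finite non-negative numeric matrix (treated as zero-centered).
#' @param thetas angle grid in degrees (default 0..179).
#' @return A [polar_map()] with integer offsets covering the image diagonal.
#' @export
radon_transform <- function(image, thetas = 0:179) {
  image <- st_values(image)
  if (length(thetas) == 0L) stop("empty angle grid", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  nz_idx <- which(image != 0)
  f <- image[nz_idx]
  v <- (nz_idx - 1L) %% h + 1L - cy          # row offset
  u <- (nz_idx - 1L) %/% h + 1L - cx         # col offset
  zmax <- ceiling(sqrt(max(abs(u), 0)^2 + max(abs(v), 0)^2)) + 1L
  zs <- seq.int(-zmax, zmax)
  nzb <- length(zs)
  out <- matrix(0, length(thetas), nzb)
  if (length(f) > 0L) {
    for (i in seq_along(thetas)) {
      th <- thetas[i] * pi / 180
      a <- max(abs(cos(th)), abs(sin(th)))
      b <- min(abs(cos(th)), abs(sin(th)))
      if (b < 1e-12) b <- 0              # degenerate trapezoid: pure box
      c1 <- (a - b) / 2; c2 <- (a + b) / 2
      # CDF of the trapezoid footprint box(a) * box(b)
      G <- function(t) {
        g <- numeric(length(t))
        g[t >= c2] <- 1
        if (b > 0) {
          ramp_lo <- t > -c2 & t < -c1
          g[ramp_lo] <- (t[ramp_lo] + c2)^2 / (2 * a * b)
          ramp_hi <- t >= c1 & t < c2
          g[ramp_hi] <- 1 - (c2 - t[ramp_hi])^2 / (2 * a * b)
        }
        mid <- t >= -c1 & t < c1
        g[mid] <- b / (2 * a) + (t[mid] + c1) / a
        g
      }
      zval <- u * cos(th) - v * sin(th)
      m0 <- round(zval)
      acc <- numeric(nzb)
      for (dm in -1:1) {
        edge_hi <- m0 + dm + 0.5 - zval
        wgt <- G(edge_hi) - G(edge_hi - 1)
        keep <- wgt > 0
        if (!any(keep)) next
        s0 <- rowsum(f[keep] * wgt[keep], m0[keep] + dm + zmax + 1L)
        ii <- as.integer(rownames(s0))
        acc[ii] <- acc[ii] + s0
      }
      out[i, ] <- acc
    }
  }
  polar_map(out, thetas, zs)
}

#' Reconstruct the image-domain line of a polar-map coordinate
#'
#' Returns the integer pixels of the line with normal angle `theta` and
#' offset `z` from the map center, clipped to the map bounds, together with
#' the event timestamp: the time (seconds) at which the line crosses the
#' map's central row. For lines parallel to the time axis the crossing is
#' undefined and the timestamp is `NA`.
#'
#' @param theta angle in degrees.
#' @param z signed offset in pixels.
#' @param st_shape `c(n_points, T)` shape of the ST map.
#' @param fps frames per second (for the timestamp).
#' @return List with `pixels` (k x 2 matrix of (row, col), possibly empty)
#'   and `time_s`.
#' @export
reconstruct_line <- function(theta, z, st_shape, fps = 30) {
  h <- st_shape[1]; w <- st_shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta * pi / 180
  smax <- ceiling(sqrt(h^2 + w^2) / 2) + 1
  s <- seq(-smax, smax, by = 0.5)
  r <- round(cy - z * sin(th) + s * cos(th))
  c_ <- round(cx + z * cos(th) + s * sin(th))
  keep <- r >= 1 & r <= h & c_ >= 1 & c_ <= w
  px <- unique(cbind(row = r[keep], col = c_[keep]))
  time_s <- if (abs(cos(th)) < 1e-9) NA_real_ else (cx + z / cos(th) - 1) / fps
  list(pixels = px, time_s = time_s)
}

# Continuous intersection of two (theta, z) lines; returns c(row, col) or
# NULL when (near-)parallel and not coincident.
#' @keywords internal
line_intersection <- function(theta1, z1, theta2, z2, st_shape) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  det <- sin(t1 - t2)
  if (abs(det) < 1e-9) {
    # parallel: coincident lines are treated as intersecting everywhere
    if (abs(z1 - z2) < 0.5) return(c((st_shape[1] + 1) / 2, (st_shape[2] + 1) / 2))
    return(NULL)
  }
  u <- (z2 * sin(t1) - z1 * sin(t2)) / det
  v <- (z2 * cos(t1) - z1 * cos(t2)) / det
  c((st_shape[1] + 1) / 2 + v, (st_shape[2] + 1) / 2 + u)
}

# TRUE when two reconstructed lines cross strictly inside the map bounds
# (meeting exactly on the border pixels does not count).
#' @keywords internal
lines_cross <- function(theta1, z1, theta2, z2, st_shape) {
  p <- line_intersection(theta1, z1, theta2, z2, st_shape)
  if (is.null(p)) return(FALSE)
  p[1] > 1 && p[1] < st_shape[1] && p[2] > 1 && p[2] < st_shape[2]
}
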