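# Capillary coordinate determination: from a binary ensemble mask to ordered
# internal / external / intermediate sampling coordinates for one U-shaped
# (hairpin) capillary. Coordinates are 1-based (row, col), row 1 at the top.

#' Capillary sampling geometry
#'
#' Ordered coordinates defining the sampling path of one capillary: the
#' internal contour (inner edge of the U facing the inter-branch gap), an
#' equal number of external coordinates resampled along the outer boundary,
#' and per pair the intermediate pixels on the connecting digital segment.
#'
#' @param internal n x 2 matrix of ordered (row, col) internal coordinates.
#' @param external n x 2 matrix of paired external coordinates (may hold
#'   continuous positions from arc-length resampling).
#' @param roi `c(top, left, bottom, right)` rectangle, or NULL.
#' @param intermediates list of length n of k x 2 integer pixel matrices, or
#'   NULL before [build_intermediates()] runs.
#' @return An object of class `capillary_geometry`.
#' @export
capillary_geometry <- function(internal, external, roi = NULL,
                               intermediates = NULL) {
  internal <- as.matrix(internal); external <- as.matrix(external)
  if (nrow(internal) < 3L) stop("geometry needs at least 3 points", call. = FALSE)
  if (nrow(internal) != nrow(external))
    stop("internal/external coordinate counts differ", call. = FALSE)
  structure(list(internal_coords = internal, external_coords = external,
                 roi = roi, intermediate_coords = intermediates,
                 n_points = nrow(internal)),
            class = "capillary_geometry")
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat(sprintf("<capillary_geometry> %d sampling points%s%s\n", x$n_points,
              if (!is.null(x$roi))
                sprintf(", roi [%d:%d, %d:%d]", x$roi[1], x$roi[3], x$roi[2], x$roi[4])
              else "",
              if (!is.null(x$intermediate_coords)) ", intermediates built" else ""))
  invisible(x)
}

#' Extract per-capillary instance masks from an ensemble mask
#'
#' 8-connected components of the binary mask with area at least `min_area`,
#' sorted by area descending and truncated to `max_capillaries`. Small
#' components are discarded as noise.
#'
#' @param mask binary mask (matrix or [capillary_mask()]).
#' @param max_capillaries maximum number of instances returned (default 2).
#' @param min_area minimum component area in pixels (default 200).
#' @return List of binary component matrices (values 0/255); empty if no
#'   component qualifies.
#' @export
extract_capillary_instances <- function(mask, max_capillaries = 2L,
                                        min_area = 200L) {
  v <- mask_values(mask)
  lab <- label_components(v != 0)
  if (max(lab) == 0L) return(list())
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  keep <- utils::head(keep, max_capillaries)
  lapply(keep, function(k) ifelse(lab == k, 255, 0))
}

#' Region of interest around a capillary component
#'
#' The component's bounding box expanded by `margin` pixels on each side,
#' clipped to the image (with a warning when clipping occurs).
#'
#' @param component binary component matrix.
#' @param margin expansion margin in pixels (default 2).
#' @return Integer `c(top, left, bottom, right)`.
#' @export
determine_roi <- function(component, margin = 2L) {
  v <- mask_values(component)
  idx <- which(v != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component", call. = FALSE)
  box <- c(top = min(idx[, 1]) - margin, left = min(idx[, 2]) - margin,
           bottom = max(idx[, 1]) + margin, right = max(idx[, 2]) + margin)
  clipped <- c(max(box[1], 1L), max(box[2], 1L),
               min(box[3], nrow(v)), min(box[4], ncol(v)))
  if (any(clipped != box))
    warning("ROI clipped at the image border", call. = FALSE)
  as.integer(clipped)
}

# Moore-neighbor boundary tracing (8-connectivity), clockwise in image
# coordinates, starting from the topmost-then-leftmost foreground pixel.
# Returns the closed contour as an n x 2 (row, col) matrix (start not
# repeated at the end). Pixels may repeat where the shape is one pixel thick.
#' @keywords internal
trace_contour <- function(mask) {
  m <- mask_values(mask) != 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  # clockwise neighbor ring: N, NE, E, SE, S, SW, W, NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  # ring index from a (dr, dc) offset
  ring_of <- matrix(0L, 3L, 3L)
  for (d in 1:8) ring_of[dr[d] + 2L, dc[d] + 2L] <- d
  idx <- which(pad, arr.ind = TRUE)
  start <- as.integer(idx[order(idx[, 1], idx[, 2])[1L], ])
  if (sum(m) == 1L) return(matrix(start - 1L, 1L, 2L))
  b0 <- c(start[1], start[2] - 1L)  # west neighbor, background by construction
  cur <- start; b <- b0
  npix <- sum(m)
  contour <- matrix(0L, 8L * npix + 8L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > nrow(contour)) contour <- rbind(contour, contour)
    contour[n, ] <- cur
    sd <- ring_of[b[1] - cur[1] + 2L, b[2] - cur[2] + 2L]
    nxt <- NULL
    for (k in 1:8) {
      d <- (sd + k - 1L) %% 8L + 1L
      nr <- cur[1] + dr[d]; nc <- cur[2] + dc[d]
      if (pad[nr, nc]) {
        dprev <- (sd + k - 2L) %% 8L + 1L
        b <- c(cur[1] + dr[dprev], cur[2] + dc[dprev])
        nxt <- c(nr, nc)
        break
      }
    }
    if (is.null(nxt)) break  # isolated pixel (cannot happen for npix > 1)
    cur <- nxt
    # Jacob's stopping criterion: back at the start with the initial backtrack
    if (all(cur == start) && all(b == b0)) break
    if (n > 8L * npix) break  # safety
  }
  contour[seq_len(n), , drop = FALSE] - 1L  # unpad
}

# Locate the inter-branch gap of a U-shaped component from its column
# profile. Returns list(left_run, right_run, gap_cols) of column indices, or
# NULL when the topology is not an open hairpin.
#' @keywords internal
find_gap_columns <- function(m) {
  cols <- which(colSums(m) > 0)
  bot <- max(which(rowSums(m) > 0))
  botrow <- vapply(cols, function(cc) max(which(m[, cc])), integer(1))
  deep <- botrow >= bot - 1L            # columns reaching the bottom (branches)
  r <- rle(deep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  deep_runs <- which(r$values)
  if (length(deep_runs) < 2L) return(NULL)
  lrun <- cols[starts[deep_runs[1]]:ends[deep_runs[1]]]
  rrun <- cols[starts[deep_runs[length(deep_runs)]]:ends[deep_runs[length(deep_runs)]]]
  gap <- cols[cols > max(lrun) & cols < min(rrun)]
  gap <- gap[botrow[match(gap, cols)] < bot - 2L]   # open at the bottom
  if (length(gap) == 0L) return(NULL)
  list(left = lrun, right = rrun, gap = gap)
}

#' Trace the internal and external boundaries of a U-shaped capillary
#'
#' The component's closed boundary is traced clockwise (Moore neighbor
#' tracing) and split at the two inner tip corners of the branches: the arc
#' facing the inter-branch gap is the internal contour, ordered from the free
#' end of the leftmost branch, over the arch, to the free end of the other
#' branch; the remaining arc (traversed in the same rotational sense and
#' ordered the same way) is the external contour. A component without an
#' identifiable inter-branch gap opening at the bottom (blob or rectangle
#' topology) raises a geometry error.
#'
#' @param component binary component matrix containing one hairpin capillary.
#' @return List with `internal` and `external`, each an n x 2 ordered
#'   (row, col) matrix; the two pixel sets are disjoint.
#' @export
trace_boundaries <- function(component) {
  m <- mask_values(component) != 0
  gp <- find_gap_columns(m)
  if (is.null(gp))
    stop("geometry error: no inter-branch gap found (not a U-shaped component)",
         call. = FALSE)
  corner <- function(cols, inner_side) {
    sub <- which(m[, cols, drop = FALSE], arr.ind = TRUE)
    sub[, 2] <- cols[sub[, 2]]
    rmax <- max(sub[, 1])
    cand <- sub[sub[, 1] == rmax, , drop = FALSE]
    if (inner_side == "right") cand[which.max(cand[, 2]), ] else cand[which.min(cand[, 2]), ]
  }
  left_corner <- corner(gp$left, "right")    # inner corner of left branch tip
  right_corner <- corner(gp$right, "left")   # inner corner of right branch tip
  contour <- trace_contour(m)
  find_idx <- function(p) {
    i <- which(contour[, 1] == p[1] & contour[, 2] == p[2])
    if (length(i) == 0L)
      stop("geometry error: branch tip corner not on the traced boundary",
           call. = FALSE)
    i[1]
  }
  iL <- find_idx(left_corner); iR <- find_idx(right_corner)
  n <- nrow(contour)
  arc <- function(from, to) {          # forward (clockwise) arc, inclusive
    if (from <= to) from:to else c(from:n, 1:to)
  }
  a1 <- arc(iL, iR); a2 <- arc(iR, iL)
  # the trace starts at the topmost-leftmost pixel (outer arch), so the arc
  # containing index 1 is the external one
  if (1L %in% a1[-c(1L, length(a1))] || a1[1] == 1L || a1[length(a1)] == 1L) {
    ext_idx <- a1; int_idx <- a2
  } else {
    ext_idx <- a2; int_idx <- a1
  }
  internal <- contour[int_idx, , drop = FALSE]
  # external arc excluding the shared corner endpoints keeps the sets disjoint
  ext_idx <- setdiff(ext_idx, c(iL, iR))
  external <- contour[ext_idx, , drop = FALSE]
  internal <- unique(internal)
  external <- unique(external)
  if (nrow(internal) < 3L)
    stop("geometry error: internal contour degenerate", call. = FALSE)
  if (internal[1, 2] > internal[nrow(internal), 2])
    internal <- internal[nrow(internal):1, , drop = FALSE]
  if (external[1, 2] > external[nrow(external), 2])
    external <- external[nrow(external):1, , drop = FALSE]
  list(internal = internal, external = external)
}

#' @keywords internal
polyline_cumlen <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# sample a polyline at arc-length positions s (vectorized)
#' @keywords internal
polyline_sample <- function(pts, cl, s) {
  s <- clamp(s, 0, cl[length(cl)])
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- clamp(seg, 1L, nrow(pts) - 1L)
  t0 <- (s - cl[seg]) / pmax(cl[seg + 1L] - cl[seg], 1e-12)
  pts[seg, , drop = FALSE] * (1 - t0) + pts[seg + 1L, , drop = FALSE] * t0
}

#' Pair internal coordinates with resampled external coordinates
#'
#' The external boundary is divided into as many coordinates as the internal
#' boundary: it is resampled at `n` positions equally spaced in cumulative arc
#' length, aligned so the first external sample is the external point nearest
#' the first internal coordinate, and oriented so corresponding samples run in
#' the same sense (the orientation minimizing total pair distance). Pairing is
#' positional: `internal[k]` with `external[k]`.
#'
#' @param internal n x 2 ordered internal coordinates (n >= 3).
#' @param external m x 2 ordered external boundary points (m >= n).
#' @param closed treat the external boundary as a closed loop (e.g. the outer
#'   boundary of an annulus) rather than an open arc.
#' @return A [capillary_geometry()] with the pairing populated (external
#'   coordinates continuous).
#' @export
pair_coordinates <- function(internal, external, closed = FALSE) {
  internal <- as.matrix(internal); external <- as.matrix(external)
  n <- nrow(internal)
  if (n < 3L) stop("geometry error: fewer than 3 internal points", call. = FALSE)
  if (nrow(external) < n)
    stop("external boundary has fewer points than the internal one", call. = FALSE)
  resample <- function(pts) {
    if (closed) {
      d0 <- rowSums((pts - matrix(internal[1, ], nrow(pts), 2, byrow = TRUE))^2)
      k <- which.min(d0)
      pts <- rbind(pts[k:nrow(pts), , drop = FALSE],
                   pts[seq_len(k - 1L), , drop = FALSE])
      pts <- rbind(pts, pts[1, ])           # close the loop
      cl <- polyline_cumlen(pts)
      s <- cl[length(cl)] * (seq_len(n) - 1L) / n
    } else {
      cl <- polyline_cumlen(pts)
      s <- cl[length(cl)] * (seq_len(n) - 1L) / (n - 1L)
    }
    polyline_sample(pts, cl, s)
  }
  cand1 <- resample(external)
  cand2 <- resample(external[nrow(external):1, , drop = FALSE])
  cost <- function(e) sum(sqrt(rowSums((e - internal)^2)))
  ext <- if (cost(cand1) <= cost(cand2)) cand1 else cand2
  capillary_geometry(internal, ext)
}

#' Build intermediate coordinates on the pairing segments
#'
#' For each internal/external pair, the intermediate coordinates are the
#' integer pixels on the 8-connected digital segment between the two
#' (endpoints excluded, duplicates removed).
#'
#' @param geometry a [capillary_geometry()] with the pairing populated.
#' @return The geometry with `intermediate_coords` populated.
#' @export
build_intermediates <- function(geometry) {
  stopifnot(inherits(geometry, "capillary_geometry"))
  n <- geometry$n_points
  ints <- vector("list", n)
  for (k in seq_len(n)) {
    a <- geometry$internal_coords[k, ]
    b <- round(geometry$external_coords[k, ])
    px <- bresenham(a, b)
    if (nrow(px) > 2L) {
      px <- px[-c(1L, nrow(px)), , drop = FALSE]
      px <- unique(px)
      keep <- !(px[, 1] == a[1] & px[, 2] == a[2]) &
              !(px[, 1] == b[1] & px[, 2] == b[2])
      px <- px[keep, , drop = FALSE]
    } else {
      px <- matrix(integer(0), 0L, 2L)
    }
    ints[[k]] <- px
  }
  geometry$intermediate_coords <- ints
  geometry
}

# Precompute linear sampling indices + group ids for fast repeated sampling.
#' @keywords internal
geometry_sampling_index <- function(geometry, h, w) {
  n <- geometry$n_points
  rows <- integer(0); cols <- integer(0); grp <- integer(0)
  ext <- round(geometry$external_coords)
  for (k in seq_len(n)) {
    px <- rbind(geometry$internal_coords[k, ], ext[k, ],
                geometry$intermediate_coords[[k]])
    rows <- c(rows, px[, 1]); cols <- c(cols, px[, 2])
    grp <- c(grp, rep.int(k, nrow(px)))
  }
  clamped <- rows < 1L | rows > h | cols < 1L | cols > w
  rows <- clamp(rows, 1L, h); cols <- clamp(cols, 1L, w)
  list(idx = (cols - 1L) * h + rows, grp = grp,
       counts = tabulate(grp, n), clamped = any(clamped))
}

#' Sample the capillary intensity vector of one frame
#'
#' Element `k` is the mean scalar intensity over the union of `internal[k]`,
#' `external[k]` and the intermediate pixels of pair `k`. The scalar intensity
#' is one color channel of the (equalized) frame; green is the conventional
#' high-contrast channel for microvascular imaging and the default.
#' Out-of-frame coordinates (possible after stabilization shifts) are clamped
#' to the frame edge and flagged via attribute `"clamped"`.
#'
#' @param frame `H x W x 3` RGB array (or a matrix used directly).
#' @param geometry a [capillary_geometry()] with intermediates built.
#' @param channel `"green"`, `"red"`, `"blue"` or `"gray"`.
#' @return Numeric vector of length `n_points`.
#' @export
sample_capillary_vector <- function(frame, geometry, channel = "green") {
  img <- frame_channel(frame, channel)
  si <- geometry_sampling_index(geometry, nrow(img), ncol(img))
  if (si$clamped)
    warning("sampling coordinates clamped to the frame edge", call. = FALSE)
  sums <- rowsum(img[si$idx], si$grp, reorder = TRUE)
  out <- as.vector(sums) / si$counts
  attr(out, "clamped") <- si$clamped
  out
}

#' @keywords internal
frame_channel <- function(frame, channel = "green") {
  if (is.matrix(frame)) return(frame)
  switch(channel,
         red = frame[, , 1], green = frame[, , 2], blue = frame[, , 3],
         gray = (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3,
         stop("unknown channel: ", channel, call. = FALSE))
}
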