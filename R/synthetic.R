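# Ground-truthed synthetic capillary videos: U-shaped (hairpin) vessels on a
# lighter skin-like background, bright visual-gap events traveling along each
# vessel, integer camera-jitter random walk, a mild multiplicative
# illumination field, and Gaussian pixel noise.

#' Specification of a synthetic capillary video
#'
#' The defaults define a desk-scale scene: one hairpin capillary in a
#' 192 x 256 frame, 160 frames at 30 fps, gaps about one vessel diameter
#' long moving at 2 px/frame, integer jitter random-walk steps up to 3 px and
#' mild sensor noise. The vessel is dark red: its red channel is comparable
#' to the background's while green and blue are strongly suppressed, so the
#' red-dominance score separates vessel from background both on raw and on
#' per-channel histogram-equalized frames.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_capillaries number of vessels.
#' @param branch_spacing center-to-center spacing of the two branches (px);
#'   the arch radius is half of it.
#' @param branch_length straight branch length (px).
#' @param tube_radius vessel half-width (px).
#' @param wiggle_amplitude,wiggle_wavelength tortuosity of the vessel: a
#'   sideways sinusoidal displacement of the centerline (px / px of arc
#'   length). Real nailfold hairpins are never perfectly straight, and the
#'   tortuosity anchors translation registration along the branch axis.
#' @param vessel_color,background_color RGB triples on 0..255.
#' @param n_events events per capillary (scalar or one per capillary).
#' @param event_speed gap speed along the centerline (px/frame).
#' @param event_length gap length along the centerline (px).
#' @param event_times optional list (per capillary) of event start frames; by
#'   default events are spread evenly over the feasible window.
#' @param jitter_amplitude per-frame random-walk step bound (px, integer).
#' @param noise_sigma Gaussian pixel noise standard deviation (intensity
#'   levels).
#' @param illum_amplitude relative amplitude of the smooth multiplicative
#'   illumination field (default 0.04).
#' @param n_frames number of frames `T`.
#' @param fps frames per second.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(192L, 256L), n_capillaries = 1L,
                           branch_spacing = 28, branch_length = 50,
                           tube_radius = 3.5, wiggle_amplitude = 3, wiggle_wavelength = 35,
                           vessel_color = c(235, 60, 70),
                           background_color = c(200, 175, 160),
                           n_events = 4L, event_speed = 3, event_length = 8,
                           event_times = NULL, jitter_amplitude = 3L,
                           noise_sigma = 5, illum_amplitude = 0.04,
                           n_frames = 160L, fps = 30, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               n_capillaries = as.integer(n_capillaries),
               branch_spacing = branch_spacing, branch_length = branch_length,
               tube_radius = tube_radius,
               wiggle_amplitude = wiggle_amplitude,
               wiggle_wavelength = wiggle_wavelength,
               vessel_color = vessel_color,
               background_color = background_color,
               n_events = rep_len(as.integer(n_events), n_capillaries),
               event_speed = event_speed, event_length = event_length,
               event_times = event_times,
               jitter_amplitude = as.integer(jitter_amplitude),
               noise_sigma = noise_sigma, illum_amplitude = illum_amplitude,
               n_frames = as.integer(n_frames), fps = fps,
               seed = as.integer(seed))
  if (spec$jitter_amplitude >= min(spec$image_size) / 8)
    stop("jitter amplitude must stay below min(H, W)/8", call. = FALSE)
  path_len <- 2 * branch_length + pi * branch_spacing / 2
  travel <- (path_len + event_length) / event_speed
  if (any(spec$n_events > 0) && travel >= spec$n_frames)
    stop("infeasible spec: events overlap the path end (video too short for ",
         "a full traversal)", call. = FALSE)
  if (!is.null(event_times)) {
    if (!is.list(event_times)) event_times <- list(event_times)
    for (tt in event_times)
      if (any(tt < 1) || any(tt + travel > spec$n_frames))
        stop("infeasible spec: events overlap the path end", call. = FALSE)
    spec$event_times <- event_times
  }
  structure(spec, class = "synthetic_spec")
}

#' Synthetic scene presets
#'
#' `"desk"` is the default batch-size scene (one capillary, 192 x 256,
#' 160 frames). `"paper"` mirrors a portable-capillaroscope acquisition
#' geometry: 640 x 480 at 30 fps with two capillaries, at reduced duration
#' (10 s) to keep a single run tractable.
#'
#' @param name `"desk"` or `"paper"`.
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(),
    paper = list(image_size = c(480L, 640L), n_capillaries = 2L,
                 branch_spacing = 44, branch_length = 90, tube_radius = 5,
                 n_events = c(4L, 3L), event_speed = 3, event_length = 12,
                 n_frames = 300L))
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

# dense centerline of one hairpin: from the left branch bottom, up, over the
# semicircular arch, down the right branch; step 0.5 px
#' @keywords internal
hairpin_centerline <- function(cx, arch_row, branch_spacing, branch_length,
                               step = 0.5, wiggle_amplitude = 0,
                               wiggle_wavelength = 55, wiggle_phase = 0) {
  rr <- branch_spacing / 2
  bottom <- arch_row + branch_length
  left <- cx - rr; right <- cx + rr
  up <- seq(bottom, arch_row, by = -step)
  phi <- seq(pi, 0, by = -step / rr)
  arch_r <- arch_row - rr * sin(phi)
  arch_c <- cx + rr * cos(phi)
  down <- seq(arch_row, bottom, by = step)
  pts <- rbind(cbind(up, left), cbind(arch_r, arch_c), cbind(down, right))
  colnames(pts) <- c("row", "col")
  if (wiggle_amplitude > 0) {
    cl <- polyline_cumlen(pts)
    pts[, 2] <- pts[, 2] +
      wiggle_amplitude * sin(2 * pi * cl / wiggle_wavelength + wiggle_phase)
  }
  pts
}

# minimum distance from every pixel in a window around a point set to that
# point set; updates `dmat` in place semantics (returns updated matrix)
#' @keywords internal
update_dist <- function(dmat, pts, radius) {
  h <- nrow(dmat); w <- ncol(dmat)
  rwin <- ceiling(radius) + 1L
  for (i in seq_len(nrow(pts))) {
    pr <- pts[i, 1]; pc <- pts[i, 2]
    rs <- max(1L, floor(pr - rwin)):min(h, ceiling(pr + rwin))
    cs <- max(1L, floor(pc - rwin)):min(w, ceiling(pc + rwin))
    dd <- sqrt(outer((rs - pr)^2, (cs - pc)^2, `+`))
    dmat[rs, cs] <- pmin(dmat[rs, cs], dd)
  }
  dmat
}

# smooth multiplicative illumination field 1 + amp * g, g in [-1, 1]
#' @keywords internal
illumination_field <- function(h, w, amp) {
  if (amp <= 0) return(matrix(1, h, w))
  ys <- seq(-1, 1, length.out = h); xs <- seq(-1, 1, length.out = w)
  g <- outer(ys, xs, function(y, x) 0.6 * stats::runif(1, -1, 1) * y +
                                     0.6 * stats::runif(1, -1, 1) * x)
  for (k in 1:2) {
    cy <- stats::runif(1, -1, 1); cx <- stats::runif(1, -1, 1)
    s <- stats::runif(1, 0.4, 0.9); a <- stats::runif(1, -1, 1)
    g <- g + a * outer(ys, xs, function(y, x) exp(-((y - cy)^2 + (x - cx)^2) / (2 * s^2)))
  }
  mx <- max(abs(g))
  if (mx > 0) g <- g / mx
  1 + amp * g
}

#' Generate a ground-truthed synthetic capillary video
#'
#' Renders, per frame: the anti-aliased dark-red hairpin vessels on the
#' background under a smooth illumination field; each active event as a
#' background-colored gap segment of length `event_length` advancing
#' `event_speed` px/frame along the centerline; then the whole frame is
#' shifted by an integer jitter random walk (reflecting bounds) and corrupted
#' with clipped Gaussian noise. Fully deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `video` (a [video_stack()]) and `truth`: `true_mask`
#'   (binary 0/255, unjittered coordinates), `jitter_trajectory` (T x 2),
#'   and per capillary (`capillaries[[k]]`) the dense `centerline` with
#'   cumulative arc length, `path_length`, ground-truth per-capillary `mask`,
#'   `event_times` (start frames) and `event_positions` (T x n_events matrix
#'   of gap-center arc-length positions, NA when inactive).
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_video_impl(spec))
}

#' @keywords internal
generate_video_impl <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  tl <- spec$n_frames
  nc <- spec$n_capillaries
  rr <- spec$branch_spacing / 2
  tube <- spec$tube_radius
  total_h <- spec$branch_length + rr + 2 * tube
  arch_row <- (h - total_h) / 2 + rr + tube
  caps <- vector("list", nc)
  illum <- illumination_field(h, w, spec$illum_amplitude)
  alpha <- matrix(0, h, w)
  for (k in seq_len(nc)) {
    cx <- w * k / (nc + 1)
    pts <- hairpin_centerline(cx, arch_row, spec$branch_spacing,
                              spec$branch_length,
                              wiggle_amplitude = spec$wiggle_amplitude,
                              wiggle_wavelength = spec$wiggle_wavelength,
                              wiggle_phase = stats::runif(1, 0, 2 * pi))
    cl <- polyline_cumlen(pts)
    dmat <- update_dist(matrix(Inf, h, w), pts, tube + 1)
    a_k <- clamp(tube + 0.5 - dmat, 0, 1)
    caps[[k]] <- list(centerline = pts, cumlen = cl,
                      path_length = cl[length(cl)],
                      mask = ifelse(dmat <= tube, 255, 0),
                      alpha = a_k)
    alpha <- pmax(alpha, a_k)
  }
  true_mask <- ifelse(Reduce(pmax, lapply(caps, `[[`, "mask")) > 0, 255, 0)
  # static base scene
  base <- array(0, c(h, w, 3))
  for (ch in 1:3)
    base[, , ch] <- illum * (spec$background_color[ch] * (1 - alpha) +
                             spec$vessel_color[ch] * alpha)
  # event schedules
  travel <- function(plen) (plen + spec$event_length) / spec$event_speed
  for (k in seq_len(nc)) {
    n_ev <- spec$n_events[k]
    if (!is.null(spec$event_times)) {
      t0 <- spec$event_times[[min(k, length(spec$event_times))]]
    } else if (n_ev > 0) {
      wmax <- floor(tl - travel(caps[[k]]$path_length)) - 1L
      t0 <- round(seq(1, wmax, length.out = n_ev))
      if (n_ev > 1) {
        jit <- round(stats::runif(n_ev, -2, 2))
        cand <- sort(clamp(t0 + jit, 1, wmax))
        # keep events well separated; fall back to even spacing otherwise
        if (all(diff(cand) >= 9)) t0 <- cand
      }
    } else t0 <- integer(0)
    caps[[k]]$event_times <- as.integer(t0)
    pos <- matrix(NA_real_, tl, length(t0))
    front <- matrix(NA_real_, tl, length(t0))
    for (e in seq_along(t0)) {
      tt <- seq_len(tl)
      p_front <- (tt - t0[e]) * spec$event_speed - spec$event_length
      active <- p_front > -spec$event_length &
                p_front < caps[[k]]$path_length
      front[active, e] <- p_front[active]
      ctr <- p_front + spec$event_length / 2
      pos[active, e] <- clamp(ctr[active], 0, caps[[k]]$path_length)
    }
    caps[[k]]$event_positions <- pos
    caps[[k]]$event_front <- front
  }
  # jitter trajectory: integer random walk with reflecting bounds
  traj <- matrix(0L, tl, 2L, dimnames = list(NULL, c("dy", "dx")))
  if (spec$jitter_amplitude > 0) {
    bound <- floor(min(h, w) / 8)
    steps <- matrix(sample(seq(-spec$jitter_amplitude, spec$jitter_amplitude),
                           2L * tl, replace = TRUE), tl, 2L)
    for (t in 2:tl) {
      p <- traj[t - 1L, ] + steps[t, ]
      p <- ifelse(abs(p) > bound, sign(p) * 2L * bound - p, p)
      traj[t, ] <- p
    }
  }
  # render frames
  frames <- vector("list", tl)
  dcol <- spec$background_color - spec$vessel_color
  for (t in seq_len(tl)) {
    f <- base
    for (k in seq_len(nc)) {
      cp <- caps[[k]]
      for (e in seq_along(cp$event_times)) {
        if (is.na(cp$event_front[t, e])) next
        lo <- cp$event_front[t, e]; hi <- lo + spec$event_length
        sel <- cp$cumlen >= lo & cp$cumlen <= hi
        if (!any(sel)) next
        pts <- cp$centerline[sel, , drop = FALSE]
        rwin <- ceiling(tube) + 2L
        rs <- max(1L, floor(min(pts[, 1]) - rwin)):min(h, ceiling(max(pts[, 1]) + rwin))
        cs <- max(1L, floor(min(pts[, 2]) - rwin)):min(w, ceiling(max(pts[, 2]) + rwin))
        dloc <- update_dist(matrix(Inf, length(rs), length(cs)),
                            cbind(pts[, 1] - rs[1] + 1, pts[, 2] - cs[1] + 1),
                            tube + 1)
        g <- pmin(alpha[rs, cs], clamp(tube + 0.5 - dloc, 0, 1))
        for (ch in 1:3)
          f[rs, cs, ch] <- f[rs, cs, ch] + illum[rs, cs] * g * dcol[ch]
      }
    }
    if (any(traj[t, ] != 0L)) f <- apply_translation(f, traj[t, ])
    if (spec$noise_sigma > 0)
      f <- f + stats::rnorm(length(f), 0, spec$noise_sigma)
    frames[[t]] <- clamp(round(f), 0, 255)
  }
  truth <- list(true_mask = true_mask, jitter_trajectory = traj,
                capillaries = lapply(caps, function(cp)
                  cp[c("centerline", "cumlen", "path_length", "mask",
                       "event_times", "event_positions")]),
                illumination = illum,
                event_times = unlist(lapply(caps, `[[`, "event_times")),
                n_events_total = sum(lengths(lapply(caps, `[[`, "event_times"))))
  list(video = video_stack(frames, fps = spec$fps,
                           source = sprintf("<synthetic seed=%d>", spec$seed)),
       truth = truth)
}

#' Build a synthetic capillary segmentation training set
#'
#' Draws frames from several short synthetic videos with varied vessel
#' geometry, illumination and jitter, paired with the exact ground-truth
#' masks (shifted by the frame's jitter vector). Suitable for training and
#' validating the U-Net segmenter.
#'
#' @param n number of frame/mask pairs.
#' @param seed RNG seed.
#' @param frames_per_video frames drawn from each generated video.
#' @param equalize histogram-equalize the drawn frames (default TRUE), so the
#'   training distribution matches the frames the pipeline feeds the
#'   segmenter.
#' @return List with `images` (RGB arrays) and `masks` (binary matrices).
#' @export
synthetic_segmentation_set <- function(n, seed = 1L, frames_per_video = 10L,
                                       equalize = TRUE) {
  n_videos <- ceiling(n / frames_per_video)
  images <- list(); masks <- list()
  for (v in seq_len(n_videos)) {
    sd <- seed * 1000L + v
    geom <- with_seed(sd, list(spacing = stats::runif(1, 24, 34),
                               blen = stats::runif(1, 40, 60),
                               tube = stats::runif(1, 3, 4.5)))
    spec <- synthetic_spec(branch_spacing = geom$spacing,
                           branch_length = geom$blen,
                           tube_radius = geom$tube,
                           n_frames = 80L, n_events = 1L, seed = sd)
    gen <- generate_video(spec)
    pick <- round(seq(1, spec$n_frames, length.out = frames_per_video))
    for (t in pick) {
      f <- gen$video$frames[[t]]
      if (equalize) for (ch in 1:3) f[, , ch] <- equalize_channel(f[, , ch])
      images[[length(images) + 1L]] <- f
      masks[[length(masks) + 1L]] <-
        apply_translation(gen$truth$true_mask, gen$truth$jitter_trajectory[t, ])
    }
  }
  list(images = images[seq_len(n)], masks = masks[seq_len(n)])
}

#' Draw a clean ST-map line fixture
#'
#' Bright straight lines of given normal angle, offset and thickness on a
#' zero background — a direct fixture for the event-detection chain.
#'
#' @param n_lines number of lines.
#' @param angles normal angles in degrees (recycled to `n_lines`).
#' @param offsets signed offsets from the map center in px.
#' @param thickness line thickness in px (default 2).
#' @param shape `c(n_points, T)` map shape.
#' @param strength line intensity (default 200).
#' @param fps frames per second recorded on the map.
#' @return List with `st` (a processed [st_map()]) and `lines`
#'   (data.frame of theta/z per line).
#' @export
make_st_fixture <- function(n_lines, angles = 30, offsets = NULL,
                            thickness = 2, shape = c(133L, 160L),
                            strength = 200, fps = 30) {
  angles <- rep_len(angles, max(n_lines, 1L))
  if (is.null(offsets))
    offsets <- seq(-5 * (n_lines - 1), 5 * (n_lines - 1), length.out = max(n_lines, 1L))
  h <- shape[1]; w <- shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  v <- matrix(rep(seq_len(h) - cy, w), h, w)
  u <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  m <- matrix(0, h, w)
  if (n_lines > 0) {
    for (i in seq_len(n_lines)) {
      th <- angles[i] * pi / 180
      d <- abs(u * cos(th) - v * sin(th) - offsets[i])
      m[d <= thickness / 2] <- strength
    }
  }
  list(st = st_map(m, fps = fps, stage = "processed"),
       lines = data.frame(theta = angles[seq_len(n_lines)],
                          z = offsets[seq_len(n_lines)]))
}
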