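# WBC event detection: local maxima of the polar map, base-event selection by
# dominant angle, and crossing-based duplicate elimination.

#' Event set container
#'
#' @param events list of events; each has `theta`, `z`, `strength`, `time_s`
#'   and `line_pixels`.
#' @param base_angle representative angle (degrees) of the dominant bin.
#' @param st_shape `c(n_points, T)` of the originating ST map.
#' @param fps frames per second.
#' @return An object of class `event_set`; `n_events` is the WBC count.
#' @export
event_set <- function(events = list(), base_angle = NA_real_,
                      st_shape = NULL, fps = 30) {
  structure(list(events = events, base_angle = base_angle,
                 n_events = length(events), st_shape = st_shape, fps = fps),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d WBC events (base angle %.0f deg)\n",
              x$n_events, x$base_angle))
  if (x$n_events > 0) {
    df <- as.data.frame(x)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.event_set <- function(x, ...) {
  if (x$n_events == 0)
    return(data.frame(event = integer(0), theta = numeric(0), z = numeric(0),
                      strength = numeric(0), time_s = numeric(0)))
  data.frame(event = seq_len(x$n_events),
             theta = vapply(x$events, `[[`, 0, "theta"),
             z = vapply(x$events, `[[`, 0, "z"),
             strength = vapply(x$events, `[[`, 0, "strength"),
             time_s = vapply(x$events, `[[`, 0, "time_s"))
}

#' Local maxima of a polar map
#'
#' Returns the polar-map points that are maxima within their
#' `neighborhood[1] x neighborhood[2]` window (angle x offset) and at least
#' `min_fraction` of the global maximum, sorted by strength descending. A tie
#' within a window is resolved in favor of the lexicographically smallest
#' (theta, z), so a symmetric pair of equal peaks yields exactly one maximum.
#'
#' @param polar a [polar_map()].
#' @param neighborhood odd window sizes `c(n_theta, n_z)`; default
#'   `c(11, 15)` (half-window of 5 degrees and 7 px). The offset half-window
#'   is sized to the parallel structure a single event produces: the paired
#'   edge ridges of its Sobel-enhanced band (about the gap length times
#'   sin(theta)) and the offset between its two branch segments caused by the
#'   shorter arch traverse of a hairpin path.
#' @param min_fraction minimum strength as a fraction of the global maximum
#'   (default 0.35).
#' @return data.frame with columns `theta`, `z`, `strength`.
#' @export
detect_local_maxima <- function(polar, neighborhood = c(11L, 15L),
                                min_fraction = 0.35) {
  stopifnot(inherits(polar, "polar_map"))
  m <- polar$values
  gmax <- max(m)
  if (gmax <= 0)
    return(data.frame(theta = numeric(0), z = numeric(0), strength = numeric(0)))
  ht <- (neighborhood[1] - 1L) %/% 2L
  hz <- (neighborhood[2] - 1L) %/% 2L
  # separable running max with -Inf border
  shift_inf <- function(mm, dy, dx) {
    hh <- nrow(mm); ww <- ncol(mm)
    out <- matrix(-Inf, hh, ww)
    rs <- max(1, 1 + dy):min(hh, hh + dy)
    cs <- max(1, 1 + dx):min(ww, ww + dx)
    out[rs, cs] <- mm[rs - dy, cs - dx, drop = FALSE]
    out
  }
  wmax <- m
  for (d in seq_len(ht)) wmax <- pmax(wmax, shift_inf(m, d, 0), shift_inf(m, -d, 0))
  wmax2 <- wmax
  for (d in seq_len(hz)) wmax2 <- pmax(wmax2, shift_inf(wmax, 0, d), shift_inf(wmax, 0, -d))
  cand <- which(m >= wmax2 & m >= min_fraction * gmax & m > 0)
  if (length(cand) == 0L)
    return(data.frame(theta = numeric(0), z = numeric(0), strength = numeric(0)))
  nt <- nrow(m); nzb <- ncol(m)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    ci <- cand[j]
    ti <- (ci - 1L) %% nt + 1L
    zi <- (ci - 1L) %/% nt + 1L
    rs <- max(1L, ti - ht):min(nt, ti + ht)
    cs <- max(1L, zi - hz):min(nzb, zi + hz)
    win <- m[rs, cs, drop = FALSE]
    val <- m[ti, zi]
    if (any(win > val)) next
    # tie-break: candidate must be the lexicographically first equal cell
    eq <- which(win == val, arr.ind = TRUE)
    eq_t <- rs[eq[, 1]]; eq_z <- cs[eq[, 2]]
    first <- order(eq_t, eq_z)[1]
    keep[j] <- (eq_t[first] == ti && eq_z[first] == zi)
  }
  cand <- cand[keep]
  ti <- (cand - 1L) %% nt + 1L
  zi <- (cand - 1L) %/% nt + 1L
  df <- data.frame(theta = polar$thetas[ti], z = polar$zs[zi],
                   strength = m[cand])
  df[order(-df$strength, df$theta, df$z), , drop = FALSE]
}

#' Select base events by dominant angle
#'
#' The angle group containing the most maxima defines the base events: a
#' window of width `angle_tolerance` is slid over the maxima angles (each
#' maximum in turn as window center, so the grouping is alignment-free) and
#' the best-populated window wins; count ties are broken toward the window
#' with higher total strength. The winning window's maxima become the initial
#' base set; the remaining maxima are candidates for crossing-based
#' deduplication.
#'
#' @param maxima data.frame from [detect_local_maxima()].
#' @param angle_tolerance window width in degrees (default 5).
#' @return List with `base` and `remaining` (both data.frames sorted by
#'   strength descending) and `base_angle` (strength-weighted mean angle of
#'   the winning group).
#' @export
select_base_events <- function(maxima, angle_tolerance = 5) {
  if (nrow(maxima) == 0L)
    return(list(base = maxima, remaining = maxima, base_angle = NA_real_))
  half <- angle_tolerance / 2
  best_in <- NULL; best_count <- -1L; best_strength <- -Inf
  for (i in seq_len(nrow(maxima))) {
    in_win <- abs(maxima$theta - maxima$theta[i]) <= half
    cnt <- sum(in_win); s <- sum(maxima$strength[in_win])
    if (cnt > best_count || (cnt == best_count && s > best_strength)) {
      best_in <- in_win; best_count <- cnt; best_strength <- s
    }
  }
  base <- maxima[best_in, , drop = FALSE]
  remaining <- maxima[!best_in, , drop = FALSE]
  ord <- function(d) d[order(-d$strength, d$theta, d$z), , drop = FALSE]
  list(base = ord(base), remaining = ord(remaining),
       base_angle = sum(base$theta * base$strength) / sum(base$strength))
}

#' Crossing-based duplicate elimination
#'
#' A thick line yields several nearby polar maxima; all but one describe the
#' same event and their reconstructed lines cross inside the ST map. Starting
#' from the strongest base event, candidates (the rest of the base set, then
#' the remaining maxima, in descending strength) are kept only if their
#' reconstructed line crosses no already-accepted line strictly inside the
#' map bounds; parallel lines at distinct offsets never cross and are kept.
#'
#' @param base data.frame of base events (non-empty), strength-descending.
#' @param remaining data.frame of other maxima, strength-descending.
#' @param st_shape `c(n_points, T)` of the ST map.
#' @param fps frames per second (for event timestamps).
#' @return An [event_set()] whose reconstructed lines are pairwise
#'   non-crossing inside the map.
#' @export
deduplicate_events <- function(base, remaining, st_shape, fps = 30) {
  if (nrow(base) == 0L) stop("empty base event set", call. = FALSE)
  cand <- rbind(base, remaining)
  acc <- cand[1, , drop = FALSE]
  for (i in seq_len(nrow(cand))[-1]) {
    crosses <- any(vapply(seq_len(nrow(acc)), function(j)
      lines_cross(cand$theta[i], cand$z[i], acc$theta[j], acc$z[j], st_shape),
      logical(1)))
    if (!crosses) acc <- rbind(acc, cand[i, , drop = FALSE])
  }
  events <- lapply(seq_len(nrow(acc)), function(i) {
    rl <- reconstruct_line(acc$theta[i], acc$z[i], st_shape, fps)
    list(theta = acc$theta[i], z = acc$z[i], strength = acc$strength[i],
         time_s = rl$time_s, line_pixels = rl$pixels)
  })
  events <- events[vapply(events, function(e) nrow(e$line_pixels) > 0, logical(1))]
  base_angle <- sum(base$theta * base$strength) / sum(base$strength)
  ord <- order(vapply(events, function(e)
    if (is.na(e$time_s)) Inf else e$time_s, numeric(1)))
  event_set(events[ord], base_angle = base_angle, st_shape = st_shape, fps = fps)
}

#' Count WBC events in a processed ST map
#'
#' Full event-detection chain: Radon transform, local-maxima detection,
#' base-event selection by dominant angle, crossing-based duplicate
#' elimination and line reconstruction. `n_events` of the returned set is the
#' WBC count for the capillary.
#'
#' @param st a processed [st_map()] (or plain non-negative matrix).
#' @param thetas angle grid in degrees.
#' @param neighborhood,min_fraction see [detect_local_maxima()].
#' @param angle_tolerance see [select_base_events()].
#' @param fps frames per second (taken from `st` when it is an [st_map()]).
#' @return An [event_set()].
#' @export
count_events <- function(st, thetas = 0:179, neighborhood = c(11L, 15L),
                         min_fraction = 0.35, angle_tolerance = 5,
                         fps = NULL) {
  v <- st_values(st)
  if (is.null(fps)) fps <- if (inherits(st, "st_map")) st$fps else 30
  if (max(v) <= 0)
    return(event_set(st_shape = dim(v), fps = fps))
  polar <- radon_transform(v, thetas)
  maxima <- detect_local_maxima(polar, neighborhood, min_fraction)
  if (nrow(maxima) == 0L)
    return(event_set(st_shape = dim(v), fps = fps))
  sel <- select_base_events(maxima, angle_tolerance)
  deduplicate_events(sel$base, sel$remaining, dim(v), fps)
}
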