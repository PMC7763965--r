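# Spatiotemporal (ST / kymograph) representation of one capillary: rows are
# positions along the sampling path, columns are frames. A WBC visual gap
# moving along the vessel traces a slanted bright line.

#' ST map container
#'
#' @param values `n_points x T` numeric matrix: rows = path position,
#'   columns = time (frames).
#' @param fps frames per second of the source video.
#' @param capillary_id index of the capillary within its video.
#' @param stage `"raw"` or `"processed"`.
#' @return An object of class `st_map`.
#' @export
st_map <- function(values, fps = 30, capillary_id = 1L,
                   stage = c("raw", "processed")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values))
  if (stage == "processed" && min(values) < 0)
    stop("processed ST maps must be non-negative", call. = FALSE)
  structure(list(values = values, fps = fps, capillary_id = capillary_id,
                 stage = stage), class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> %d path positions x %d frames (%s), %.4g fps, capillary %d\n",
              nrow(x$values), ncol(x$values), x$stage, x$fps, x$capillary_id))
  invisible(x)
}

#' @keywords internal
st_values <- function(st) if (inherits(st, "st_map")) st$values else st

#' Assemble per-frame capillary vectors into an ST map
#'
#' Column `t` of the map is the capillary intensity vector of frame `t`.
#'
#' @param vectors list of equal-length numeric vectors (one per frame), or an
#'   `n_points x T` matrix.
#' @param fps frames per second.
#' @param capillary_id capillary index recorded on the map.
#' @return A raw [st_map()].
#' @export
build_st_map <- function(vectors, fps = 30, capillary_id = 1L) {
  if (is.list(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L)
      stop("capillary vectors differ in length", call. = FALSE)
    vectors <- matrix(unlist(vectors), nrow = lens[1])
  }
  if (ncol(vectors) < 2L) stop("an ST map needs at least 2 frames", call. = FALSE)
  st_map(vectors, fps = fps, capillary_id = capillary_id, stage = "raw")
}

#' Enhance a raw ST map for line detection
#'
#' In order: (1) 2-D median filter (`median_kernel`, reflect-padded) removes
#' isolated specks; (2) each row is zero-meaned, removing static structure
#' along the path (a row's baseline intensity is constant in time); (3)
#' negative values are clipped to zero; (4) the Sobel operator sharpens the
#' event lines — by default the orientation-agnostic gradient magnitude
#' `sqrt(Gx^2 + Gy^2)`. The result is rescaled to 0..255 so downstream
#' peak-picking thresholds are scale-free.
#'
#' @param st a raw [st_map()].
#' @param median_kernel odd kernel size (default 3).
#' @param sobel_axis `"magnitude"` (default), `"time"` or `"space"` for an
#'   axis-only derivative.
#' @return A processed [st_map()].
#' @export
process_st_map <- function(st, median_kernel = 3L,
                           sobel_axis = c("magnitude", "time", "space")) {
  sobel_axis <- match.arg(sobel_axis)
  stopifnot(inherits(st, "st_map"))
  v <- st$values
  if (median_kernel > min(dim(v)))
    stop("median kernel larger than the map", call. = FALSE)
  v <- median_filter(v, as.integer(median_kernel))
  v <- v - rowMeans(v)
  v[v < 0] <- 0
  g <- sobel(v)
  v <- switch(sobel_axis,
              magnitude = g$magnitude, time = abs(g$gx), space = abs(g$gy))
  st$values <- rescale255(v)
  st$stage <- "processed"
  st
}
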