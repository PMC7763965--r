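#' Video stack container
#'
#' An ordered sequence of RGB frames sharing one geometry, the raw material of
#' the counting pipeline. Frames are stored as a list of `H x W x 3` numeric
#' arrays on the 0..255 intensity scale with fixed channel order (R, G, B);
#' rows run top to bottom.
#'
#' @param frames list of `H x W x 3` numeric arrays, all the same shape.
#' @param fps frames per second.
#' @param source provenance string.
#' @return An object of class `video_stack` with elements `frames`, `fps`,
#'   `source`.
#' @export
video_stack <- function(frames, fps = 30, source = "<memory>") {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a video stack needs at least 2 frames", call. = FALSE)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames with inconsistent geometry", call. = FALSE)
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(list(frames = frames, fps = fps, source = source),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_stack> %d frames, %d x %d px, %.4g fps (%.1f s)\n  source: %s\n",
              length(x$frames), d[1], d[2], x$fps,
              length(x$frames) / x$fps, x$source))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) {
  c(length(x$frames), dim(x$frames[[1]]))
}

#' Load a video from a directory of image frames
#'
#' Reads a directory of lexicographically ordered PNG (or TIFF) frames into a
#' [video_stack()]. File names should carry zero-padded frame numbers so that
#' lexicographic order is temporal order. Container formats (AVI/MP4) are not
#' decodable in a plain R session and raise an input error.
#'
#' @param path directory containing the frames.
#' @param fps frames per second to record on the stack (frame directories
#'   carry no timing metadata; defaults to 30).
#' @return A [video_stack()].
#' @export
load_video <- function(path, fps = 30) {
  if (!file.exists(path)) stop("unreadable path: ", path, call. = FALSE)
  if (!dir.exists(path)) {
    stop("'", path, "' is not a frame directory; container decoding (AVI/MP4) ",
         "is unavailable here - extract frames to numbered PNGs first",
         call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no frames found in ", path, call. = FALSE)
  frames <- lapply(files, read_frame)
  video_stack(frames, fps = fps, source = normalizePath(path))
}

# read one PNG/TIFF image as an H x W x 3 array on 0..255
#' @keywords internal
read_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") {
    png::readPNG(file)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF frames", call. = FALSE)
    tiff::readTIFF(file)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write a video stack (or masks) as numbered PNG frames
#'
#' @param video a [video_stack()], or a list of grayscale matrices / RGB arrays.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(video, dir, prefix = "frame") {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%05d.png", prefix, i))
    f <- frames[[i]]
    if (inherits(f, "capillary_mask")) f <- f$values
    png::writePNG(clamp(f, 0, 255) / 255, paths[i])
  }
  invisible(paths)
}

# histogram equalization of one 0..255 channel (256 bins, CDF mapping)
#' @keywords internal
equalize_channel <- function(ch) {
  v <- as.integer(round(ch))
  h <- tabulate(v + 1L, nbins = 256L)
  map <- round(255 * cumsum(h) / length(v))
  matrix(map[v + 1L], nrow(ch), ncol(ch))
}

#' Per-channel histogram equalization of every frame
#'
#' Contrast enhancement applied before segmentation: each frame's R, G and B
#' channels are independently histogram-equalized over the full frame (256
#' bins, cumulative-distribution mapping onto 0..255). The mapping is monotone
#' (pixel rank order within a channel is preserved) and idempotent.
#'
#' @param video a [video_stack()].
#' @return The equalized [video_stack()].
#' @export
equalize_frames <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  video$frames <- lapply(video$frames, function(f) {
    for (ch in 1:3) f[, , ch] <- equalize_channel(f[, , ch])
    f
  })
  video
}
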