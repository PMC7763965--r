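# Video stabilization: whole-frame translation registration in the Fourier
# domain, a periodically updated reference with an accumulated translation
# history, and temporal mask ensembling.

#' Translation between two images by FFT cross-correlation
#'
#' Returns the integer `(dy, dx)` displacement of `moving` relative to
#' `reference` — how far the content has moved, so that `moving` is
#' approximately `reference` shifted by `(dy, dx)` — found as the peak of the
#' circular cross-correlation computed via forward FFTs, an elementwise
#' conjugate product and an inverse FFT. Shifting `moving` by the negated
#' vector realigns it with `reference`. The correlation peak is unwrapped to
#' the signed range `(-H/2, H/2] x (-W/2, W/2]`.
#'
#' Registration is intended to run on capillary label masks rather than raw
#' frames: graded mask intensity gives a sharper, noise-robust peak.
#'
#' @param reference,moving single-channel images (matrices or
#'   [capillary_mask()]s) of equal shape with at least one non-zero pixel each.
#' @return Integer vector `c(dy, dx)`.
#' @export
get_translation_vec <- function(reference, moving) {
  r <- mask_values(reference); m <- mask_values(moving)
  if (!identical(dim(r), dim(m))) stop("shape mismatch", call. = FALSE)
  if (all(r == 0) || all(m == 0))
    stop("no correlation peak: an input image is all zero", call. = FALSE)
  cc <- Re(stats::fft(stats::fft(m) * Conj(stats::fft(r)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  h <- nrow(r); w <- ncol(r)
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > h %/% 2) dy <- dy - h
  if (dx > w %/% 2) dx <- dx - w
  c(dy = dy, dx = dx)
}

#' Shift an image by a translation vector
#'
#' Content moves down by `dy` rows and right by `dx` columns; vacated border
#' pixels are zero-filled (`fill = "edge"` replicates the edge instead).
#'
#' @param image matrix or `H x W x C` array.
#' @param vec integer `c(dy, dx)` with `|dy| < H`, `|dx| < W`.
#' @param fill `"zero"` (default) or `"edge"`.
#' @return The shifted image, same shape.
#' @export
apply_translation <- function(image, vec, fill = c("zero", "edge")) {
  fill <- match.arg(fill)
  dy <- as.integer(round(vec[1])); dx <- as.integer(round(vec[2]))
  d <- dim(image); h <- d[1]; w <- d[2]
  if (abs(dy) >= h || abs(dx) >= w)
    stop("translation vector larger than the image", call. = FALSE)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  if (fill == "edge") {
    src_r <- clamp(src_r, 1L, h); src_c <- clamp(src_c, 1L, w)
    ok_r <- rep(TRUE, h); ok_c <- rep(TRUE, w)
  } else {
    ok_r <- src_r >= 1L & src_r <= h; ok_c <- src_c >= 1L & src_c <= w
    src_r <- clamp(src_r, 1L, h); src_c <- clamp(src_c, 1L, w)
  }
  if (length(d) == 2L) {
    out <- image[src_r, src_c, drop = FALSE]
    out[!ok_r, ] <- 0; out[, !ok_c] <- 0
  } else {
    out <- image[src_r, src_c, , drop = FALSE]
    out[!ok_r, , ] <- 0; out[, !ok_c, ] <- 0
  }
  out
}

#' Stabilize a capillary video against camera translation
#'
#' Every frame is registered to the first frame's coordinate system using the
#' per-frame capillary masks. To keep individual displacements small, the
#' reference mask is replaced every `period_p` frames by the raw mask of the
#' current frame, and a single accumulator (the running correction mapping
#' the current reference into first-frame coordinates) keeps the history of
#' translations among reference frames: each frame's total correction is the
#' accumulator minus the frame's displacement from the current reference, so
#' the accumulation composes exactly.
#'
#' A frame whose registration fails (degenerate mask, or an implausible shift
#' beyond half the frame) inherits the previous frame's total vector and is
#' flagged in the trace.
#'
#' @param video a [video_stack()].
#' @param masks list of per-frame [capillary_mask()]s (soft masks are used
#'   as-is for correlation), aligned one-to-one with frames.
#' @param period_p reference update period in frames (default 50).
#' @return List with elements `video` (stabilized [video_stack()]), `masks`
#'   (stabilized masks, same kinds) and `trace` (class `stab_trace`:
#'   `per_frame_vectors` (T x 2), `reference_indices`,
#'   `reference_accumulator`, `period_p`, `failed`).
#' @export
stabilize <- function(video, masks, period_p = 50L) {
  stopifnot(inherits(video, "video_stack"))
  tl <- length(video$frames)
  if (length(masks) != tl)
    stop("masks must align one-to-one with frames", call. = FALSE)
  mvals <- lapply(masks, mask_values)
  ref <- mvals[[1]]
  acc <- c(0L, 0L)
  vectors <- matrix(0L, tl, 2L, dimnames = list(NULL, c("dy", "dx")))
  failed <- logical(tl)
  ref_idx <- 1L
  acc_hist <- matrix(0L, 1L, 2L, dimnames = list(NULL, c("dy", "dx")))
  h <- nrow(ref); w <- ncol(ref)
  out_frames <- vector("list", tl)
  out_masks <- vector("list", tl)
  last_total <- c(0L, 0L)
  for (i in seq_len(tl)) {
    v <- tryCatch(get_translation_vec(ref, mvals[[i]]), error = function(e) NULL)
    if (is.null(v) || abs(v[1]) > h / 2 || abs(v[2]) > w / 2) {
      failed[i] <- TRUE
      total <- last_total
      if (i > 1L)
        warning(sprintf("registration failed on frame %d; carrying last vector", i),
                call. = FALSE)
    } else {
      total <- acc - as.integer(v)
    }
    vectors[i, ] <- total
    last_total <- total
    out_frames[[i]] <- apply_translation(video$frames[[i]], total)
    mk <- masks[[i]]
    if (inherits(mk, "capillary_mask")) {
      mk$values <- apply_translation(mvals[[i]], total)
    } else {
      mk <- apply_translation(mvals[[i]], total)
    }
    out_masks[[i]] <- mk
    if (i > 1L && (i - 1L) %% period_p == 0L) {
      ref <- mvals[[i]]        # raw mask of the new reference frame
      acc <- total             # its accumulated total into frame-1 coords
      ref_idx <- c(ref_idx, i)
      acc_hist <- rbind(acc_hist, acc)
    }
  }
  video$frames <- out_frames
  trace <- structure(list(per_frame_vectors = vectors,
                          reference_indices = ref_idx,
                          reference_accumulator = acc_hist,
                          period_p = period_p,
                          failed = failed),
                     class = "stab_trace")
  list(video = video, masks = out_masks, trace = trace)
}

#' @export
print.stab_trace <- function(x, ...) {
  n2 <- sqrt(rowSums(x$per_frame_vectors^2))
  cat(sprintf("<stab_trace> %d frames, p = %d, %d reference updates, %d failures\n",
              nrow(x$per_frame_vectors), x$period_p,
              length(x$reference_indices) - 1L, sum(x$failed)))
  cat(sprintf("  translation L2 norm: median %.1f, max %.1f px\n",
              stats::median(n2), max(n2)))
  invisible(x)
}

#' Temporal ensemble of stabilized capillary masks
#'
#' Pixelwise temporal mean of the masks on the 0..255 scale, binarized at
#' `threshold`. Averaging many stabilized (co-registered) masks suppresses
#' per-frame segmentation noise.
#'
#' @param masks non-empty list of stabilized masks of equal shape.
#' @param threshold binarization threshold in \[0, 255\].
#' @return A binary [capillary_mask()].
#' @export
ensemble_mask <- function(masks, threshold) {
  if (length(masks) == 0L) stop("empty mask list", call. = FALSE)
  method <- if (inherits(masks[[1]], "capillary_mask")) masks[[1]]$method else "manual"
  avg <- Reduce(`+`, lapply(masks, mask_values)) / length(masks)
  m <- binarize(avg, threshold)
  m$method <- method
  m
}
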