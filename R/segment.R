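#' Capillary mask container
#'
#' A single-channel capillary label image: either soft scores scaled to
#' 0..255 or a binary image with values in \{0, 255\}.
#'
#' @param values numeric matrix, same H x W as the originating frame.
#' @param kind `"soft"` or `"binary"`.
#' @param method `"conventional"`, `"dnn"` or `"manual"`.
#' @return An object of class `capillary_mask`.
#' @export
capillary_mask <- function(values, kind = c("soft", "binary"),
                           method = c("conventional", "dnn", "manual")) {
  kind <- match.arg(kind); method <- match.arg(method)
  stopifnot(is.matrix(values))
  if (min(values) < 0 || max(values) > 255)
    stop("mask values must lie in [0, 255]", call. = FALSE)
  if (kind == "binary" && !all(values %in% c(0, 255)))
    stop("binary masks may contain only {0, 255}", call. = FALSE)
  structure(list(values = values, kind = kind, method = method),
            class = "capillary_mask")
}

#' @export
print.capillary_mask <- function(x, ...) {
  cat(sprintf("<capillary_mask> %d x %d, %s (%s), %.1f%% above zero\n",
              nrow(x$values), ncol(x$values), x$kind, x$method,
              100 * mean(x$values > 0)))
  invisible(x)
}

#' @keywords internal
mask_values <- function(m) if (inherits(m, "capillary_mask")) m$values else m

#' Segmentation parameters
#'
#' @param lambda_red weight of the red component in the color score
#'   (default 1.5).
#' @param threshold_conventional binarization threshold for the color-score
#'   masks (default 80, on the 0..255 normalized scale).
#' @param threshold_dnn binarization threshold for U-Net soft masks
#'   (default 150).
#' @return A validated parameter list of class `seg_params`.
#' @export
seg_params <- function(lambda_red = 1.5, threshold_conventional = 80,
                       threshold_dnn = 150) {
  if (lambda_red <= 0) stop("lambda_red must be positive", call. = FALSE)
  for (t in c(threshold_conventional, threshold_dnn))
    if (t < 0 || t > 255) stop("thresholds must lie in [0, 255]", call. = FALSE)
  structure(list(lambda_red = lambda_red,
                 threshold_conventional = threshold_conventional,
                 threshold_dnn = threshold_dnn), class = "seg_params")
}

#' Conventional color-score capillary segmentation
#'
#' Scores each pixel by red dominance, `s = max(0, lambda*R - (G + B))^2`:
#' capillaries are red regions whose green and blue components are low, and
#' squaring stretches the capillary/background contrast. The raw squared
#' scores are rescaled linearly so the frame maximum maps to 255 (an all-zero
#' map stays zero), making the downstream binarization threshold scale-free.
#'
#' @param frame `H x W x 3` RGB array on 0..255.
#' @param params a [seg_params()] list.
#' @param normalize rescale the squared score to 0..255 (default TRUE). With
#'   `FALSE` the raw squared scores are returned (not a valid mask scale).
#' @return A soft [capillary_mask()] (or a raw score matrix if
#'   `normalize = FALSE`).
#' @export
conventional_segment <- function(frame, params = seg_params(), normalize = TRUE) {
  stopifnot(length(dim(frame)) == 3L)
  s <- pmax(params$lambda_red * frame[, , 1] - (frame[, , 2] + frame[, , 3]), 0)^2
  if (!normalize) return(s)
  capillary_mask(rescale255(s), kind = "soft", method = "conventional")
}

#' Binarize a soft capillary mask
#'
#' Pixels at or above `threshold` become 255, the rest 0.
#'
#' @param mask a soft [capillary_mask()] (or plain matrix on 0..255).
#' @param threshold intensity threshold in \[0, 255\].
#' @return A binary [capillary_mask()].
#' @export
binarize <- function(mask, threshold) {
  if (threshold < 0 || threshold > 255)
    stop("threshold outside [0, 255]", call. = FALSE)
  method <- if (inherits(mask, "capillary_mask")) mask$method else "manual"
  v <- mask_values(mask)
  capillary_mask(ifelse(v >= threshold, 255, 0), kind = "binary", method = method)
}

#' Mean intersection-over-union of two binary masks
#'
#' Average over the background and capillary classes of
#' `|pred & truth| / |pred | truth|`; a class with an empty union (absent from
#' both masks) contributes 1.
#'
#' @param pred,truth binary masks (matrices or [capillary_mask()]s) of equal
#'   shape.
#' @return Mean IoU in \[0, 1\].
#' @export
mean_iou <- function(pred, truth) {
  p <- mask_values(pred) != 0
  t_ <- mask_values(truth) != 0
  if (!identical(dim(p), dim(t_))) stop("shape mismatch", call. = FALSE)
  iou <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 1 else sum(a & b) / u
  }
  (iou(p, t_) + iou(!p, !t_)) / 2
}

#' Segment every frame of a video
#'
#' @param video a [video_stack()] (typically already equalized).
#' @param method `"conventional"` or `"dnn"`.
#' @param params a [seg_params()] list.
#' @param model a trained [unet_build()] model (required for `method = "dnn"`).
#' @return List of soft [capillary_mask()]s, one per frame.
#' @export
segment_video <- function(video, method = c("conventional", "dnn"),
                          params = seg_params(), model = NULL) {
  method <- match.arg(method)
  if (method == "conventional") {
    lapply(video$frames, conventional_segment, params = params)
  } else {
    if (is.null(model)) stop("method 'dnn' needs a trained model", call. = FALSE)
    lapply(video$frames, function(f) unet_predict(model, f))
  }
}
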