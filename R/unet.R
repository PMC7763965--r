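# Compact U-Net semantic segmenter in base R. Convolutions are im2col
# matrix products; training uses Adam on pixelwise binary cross-entropy.
# Sized for small training images (default 128 x 128), which is ample for
# capillary-vs-background color/shape segmentation.

# ---- low-level layers -------------------------------------------------------

# im2col for 3x3 "same" convolution with zero padding; returns HW x 9C
#' @keywords internal
im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, ch))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  pf <- matrix(xp, (h + 2L) * (w + 2L), ch)
  rp <- rep.int(2:(h + 1L), w)
  cp <- rep(2:(w + 1L), each = h)
  out <- matrix(0, h * w, 9L * ch)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    idx <- (rp + dy) + (cp + dx - 1L) * (h + 2L)
    out[, ((k - 1L) * ch + 1L):(k * ch)] <- pf[idx, ]
  }
  out
}

# scatter-add of dP (HW x 9C) back onto the input grid (col2im)
#' @keywords internal
col2im3 <- function(dP, h, w, ch) {
  dpad <- matrix(0, (h + 2L) * (w + 2L), ch)
  rp <- rep.int(2:(h + 1L), w)
  cp <- rep(2:(w + 1L), each = h)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    idx <- (rp + dy) + (cp + dx - 1L) * (h + 2L)
    dpad[idx, ] <- dpad[idx, ] + dP[, ((k - 1L) * ch + 1L):(k * ch)]
  }
  array(dpad, c(h + 2L, w + 2L, ch))[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

#' @keywords internal
conv3_forward <- function(x, W, b) {
  d <- dim(x)
  P <- im2col3(x)
  y <- P %*% W
  y <- sweep(y, 2L, b, `+`)
  list(out = array(y, c(d[1], d[2], ncol(W))), P = P, in_dim = d)
}

#' @keywords internal
conv3_backward <- function(cache, dY) {
  d <- cache$in_dim
  co <- length(dY) / (d[1] * d[2])
  dYm <- matrix(dY, d[1] * d[2], co)
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  dP <- tcrossprod(dYm, cache$W)
  dX <- col2im3(dP, d[1], d[2], d[3])
  list(dX = dX, dW = dW, db = db)
}

#' @keywords internal
maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  ro <- seq(1L, h, 2L); co <- seq(1L, w, 2L)
  a <- x[ro, co, , drop = FALSE];      b <- x[ro + 1L, co, , drop = FALSE]
  cc <- x[ro, co + 1L, , drop = FALSE]; dd <- x[ro + 1L, co + 1L, , drop = FALSE]
  m1 <- pmax(a, b); m2 <- pmax(cc, dd); m <- pmax(m1, m2)
  which_ <- array(1L, dim(m))
  which_[b > a] <- 2L
  which_[cc > m1] <- 3L
  which_[dd > m1 & dd > cc] <- 4L
  list(out = m, which = which_, in_dim = d)
}

#' @keywords internal
maxpool_backward <- function(cache, dY) {
  d <- cache$in_dim
  dX <- array(0, d)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  for (k in 1:4) {
    sel <- (cache$which == k) * dY
    dy_off <- (k - 1L) %% 2L; dx_off <- (k - 1L) %/% 2L
    dX[ro + dy_off, co + dx_off, ] <- dX[ro + dy_off, co + dx_off, ] + sel
  }
  dX
}

#' @keywords internal
upconv_forward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]
  co <- length(b)
  z <- matrix(x, h * w, d[3]) %*% W      # HW x 4Cout
  y <- array(0, c(2L * h, 2L * w, co))
  for (di in 0:1) for (dj in 0:1) {
    cols <- (seq_len(co) - 1L) * 4L + dj * 2L + di + 1L
    y[seq(1L, 2L * h, 2L) + di, seq(1L, 2L * w, 2L) + dj, ] <-
      array(z[, cols], c(h, w, co))
  }
  sweep(y, 3L, b, `+`) -> y
  list(out = y, x = x, in_dim = d)
}

#' @keywords internal
upconv_backward <- function(cache, dY, W) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]
  co <- dim(dY)[3]
  dZ <- matrix(0, h * w, 4L * co)
  for (di in 0:1) for (dj in 0:1) {
    cols <- (seq_len(co) - 1L) * 4L + dj * 2L + di + 1L
    dZ[, cols] <- matrix(dY[seq(1L, 2L * h, 2L) + di,
                            seq(1L, 2L * w, 2L) + dj, , drop = FALSE], h * w, co)
  }
  xf <- matrix(cache$x, h * w, d[3])
  list(dX = array(dZ %*% t(W), d), dW = crossprod(xf, dZ),
       db = as.vector(apply(dY, 3L, sum)))
}

# ---- model ------------------------------------------------------------------

#' Build a compact U-Net capillary segmenter
#'
#' An encoder-decoder with, per level, two 3x3 convolution + ReLU blocks and
#' 2x2 max pooling on the contracting path; 2x2 up-convolution, concatenation
#' with the matching encoder feature map (skip connection) and two 3x3
#' convolution blocks on the expanding path; and a terminal 1x1 convolution
#' to a single-channel logit map. Channel widths double per level from
#' `base_channels`. Weights are He-initialized, deterministically given
#' `seed`.
#'
#' @param depth number of pooling levels (>= 1).
#' @param base_channels channels of the first level (default 8).
#' @param in_channels input channels (3 for RGB).
#' @param input_size training/inference image side (frames are resized
#'   bilinearly to `input_size x input_size`; predictions are upsampled
#'   back). Set `input_size = NULL` to run inference at native size with
#'   reflect padding to a multiple of `2^depth`.
#' @param seed RNG seed for the initialization.
#' @return An object of class `unet_model`.
#' @export
unet_build <- function(depth = 2L, base_channels = 8L, in_channels = 3L,
                       input_size = 128L, seed = 1L) {
  stopifnot(depth >= 1L, base_channels >= 1L)
  if (!is.null(input_size) && input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  chans <- base_channels * 2^(0:depth)
  layers <- list()
  he <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)
  add_conv <- function(name, cin, cout) {
    layers[[name]] <<- list(W = he(9L * cin, cout, 9L * cin), b = numeric(cout),
                            type = "conv3", cin = cin, cout = cout)
  }
  with_seed(seed, {
    cin <- in_channels
    for (l in seq_len(depth)) {
      add_conv(sprintf("enc%d_1", l), cin, chans[l])
      add_conv(sprintf("enc%d_2", l), chans[l], chans[l])
      cin <- chans[l]
    }
    add_conv("bot_1", chans[depth], chans[depth + 1L])
    add_conv("bot_2", chans[depth + 1L], chans[depth + 1L])
    for (l in rev(seq_len(depth))) {
      layers[[sprintf("up%d", l)]] <- list(
        W = he(chans[l + 1L], 4L * chans[l], 4L * chans[l + 1L]),
        b = numeric(chans[l]), type = "upconv",
        cin = chans[l + 1L], cout = chans[l])
      add_conv(sprintf("dec%d_1", l), 2L * chans[l], chans[l])
      add_conv(sprintf("dec%d_2", l), chans[l], chans[l])
    }
    layers[["final"]] <- list(W = he(chans[1], 1L, chans[1]), b = 0,
                              type = "conv1", cin = chans[1], cout = 1L)
  })
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = in_channels, input_size = input_size,
                 layers = layers, trained_epochs = 0L),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d channels, %s params, %d epochs trained\n",
              x$depth, x$base_channels,
              format(count_parameters(x), big.mark = ","), x$trained_epochs))
  invisible(x)
}

#' Number of trainable parameters of a U-Net model
#'
#' @param model a [unet_build()] model.
#' @return Integer parameter count (weights + biases over all layers).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# forward pass on one H x W x C input in [0, 1]; returns logits (+ caches)
#' @keywords internal
unet_forward <- function(model, x, keep_cache = FALSE) {
  L <- model$layers
  caches <- list()
  relu_fwd <- function(a) { a[a < 0] <- 0; a }
  run_conv <- function(name, x, act = TRUE) {
    cc <- conv3_forward(x, L[[name]]$W, L[[name]]$b)
    cc$W <- L[[name]]$W
    out <- if (act) relu_fwd(cc$out) else cc$out
    if (keep_cache) {
      cc$post <- out
      caches[[name]] <<- cc
    }
    out
  }
  skips <- list()
  for (l in seq_len(model$depth)) {
    x <- run_conv(sprintf("enc%d_1", l), x)
    x <- run_conv(sprintf("enc%d_2", l), x)
    skips[[l]] <- x
    mp <- maxpool_forward(x)
    if (keep_cache) caches[[sprintf("pool%d", l)]] <- mp
    x <- mp$out
  }
  x <- run_conv("bot_1", x)
  x <- run_conv("bot_2", x)
  for (l in rev(seq_len(model$depth))) {
    up <- upconv_forward(x, L[[sprintf("up%d", l)]]$W, L[[sprintf("up%d", l)]]$b)
    if (keep_cache) caches[[sprintf("up%d", l)]] <- up
    x <- array(c(skips[[l]], up$out),
               c(dim(up$out)[1], dim(up$out)[2], 2L * dim(up$out)[3]))
    x <- run_conv(sprintf("dec%d_1", l), x)
    x <- run_conv(sprintf("dec%d_2", l), x)
  }
  d <- dim(x)
  xf <- matrix(x, d[1] * d[2], d[3])
  logits <- matrix(xf %*% L$final$W + L$final$b, d[1], d[2])
  if (keep_cache) caches$final <- list(xf = xf, in_dim = d)
  list(logits = logits, caches = caches, skips = if (keep_cache) skips else NULL)
}

# full backward pass; returns gradient list aligned with model$layers
#' @keywords internal
unet_backward <- function(model, fw, dlogits) {
  L <- model$layers
  caches <- fw$caches
  grads <- list()
  relu_bwd <- function(dY, post) { dY[post <= 0] <- 0; dY }
  back_conv <- function(name, dY) {
    cc <- caches[[name]]
    dY <- relu_bwd(dY, cc$post)
    cc$W <- L[[name]]$W
    bb <- conv3_backward(cc, dY)
    grads[[name]] <<- list(dW = bb$dW, db = bb$db)
    bb$dX
  }
  fc <- caches$final
  dlf <- matrix(dlogits, fc$in_dim[1] * fc$in_dim[2], 1L)
  grads$final <- list(dW = crossprod(fc$xf, dlf), db = sum(dlf))
  dX <- array(dlf %*% t(L$final$W), fc$in_dim)
  # decoder, reversing forward order (level 1 ran last)
  d_skips <- vector("list", model$depth)
  for (l in seq_len(model$depth)) {
    dX <- back_conv(sprintf("dec%d_2", l), dX)
    dX <- back_conv(sprintf("dec%d_1", l), dX)
    cc <- dim(dX)[3] / 2L
    d_skips[[l]] <- dX[, , seq_len(cc), drop = FALSE]
    d_up <- dX[, , cc + seq_len(cc), drop = FALSE]
    ub <- upconv_backward(caches[[sprintf("up%d", l)]], d_up,
                          L[[sprintf("up%d", l)]]$W)
    grads[[sprintf("up%d", l)]] <- list(dW = ub$dW, db = ub$db)
    dX <- ub$dX
  }
  # bottleneck
  dX <- back_conv("bot_2", dX)
  dX <- back_conv("bot_1", dX)
  # encoder, deepest level first; gradient reaching each level's output is
  # the pooled-path gradient plus the skip-connection gradient
  for (l in rev(seq_len(model$depth))) {
    dX <- maxpool_backward(caches[[sprintf("pool%d", l)]], dX)
    dX <- dX + d_skips[[l]]
    dX <- back_conv(sprintf("enc%d_2", l), dX)
    dX <- back_conv(sprintf("enc%d_1", l), dX)
  }
  grads
}

#' Train the U-Net segmenter
#'
#' Adam optimization of pixelwise binary cross-entropy between the sigmoid of
#' the logit map and the binary labels, deterministic given `seed`. Training
#' images are resized bilinearly to the model's `input_size` (labels with
#' nearest-neighbor). Per-epoch mean loss and, when a validation set is
#' given, validation mean IoU (at `threshold` on the 0..255 soft-mask scale)
#' are recorded in the returned history.
#'
#' @param model a [unet_build()] model.
#' @param images list of `H x W x 3` RGB arrays (0..255).
#' @param labels list of binary masks (matrices or [capillary_mask()]s),
#'   one per image.
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 3).
#' @param seed RNG seed for shuffling (default 1).
#' @param val_images,val_labels optional held-out set evaluated each epoch.
#' @param threshold binarization threshold for validation IoU (default 150).
#' @param verbose print per-epoch progress.
#' @return List with `model` (trained) and `history` (data.frame with
#'   `epoch`, `loss`, `val_miou`).
#' @export
unet_train <- function(model, images, labels, epochs = 100L, lr = 0.001,
                       batch_size = 3L, seed = 1L,
                       val_images = NULL, val_labels = NULL,
                       threshold = 150, verbose = FALSE) {
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  if (length(images) != length(labels))
    stop("images and labels must correspond one-to-one", call. = FALSE)
  sz <- model$input_size
  if (is.null(sz)) stop("training requires a fixed input_size", call. = FALSE)
  xs <- lapply(images, function(f) resize_rgb(f, sz, sz) / 255)
  ys <- lapply(labels, function(m) resize_nearest(mask_values(m), sz, sz) / 255)
  # Adam state
  mstate <- lapply(model$layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                                  mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0L
  n <- length(xs)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_miou = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        gacc <- NULL
        bl <- 0
        for (i in bs) {
          fw <- unet_forward(model, xs[[i]], keep_cache = TRUE)
          x <- fw$logits; y <- ys[[i]]
          bl <- bl + mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
          dlog <- (1 / (1 + exp(-x)) - y) / length(x)
          g <- unet_backward(model, fw, dlog)
          if (is.null(gacc)) gacc <- g
          else for (nm in names(g)) {
            gacc[[nm]]$dW <- gacc[[nm]]$dW + g[[nm]]$dW
            gacc[[nm]]$db <- gacc[[nm]]$db + g[[nm]]$db
          }
        }
        tstep <- tstep + 1L
        corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
        for (nm in names(gacc)) {
          gW <- gacc[[nm]]$dW / length(bs); gb <- gacc[[nm]]$db / length(bs)
          st <- mstate[[nm]]
          st$mW <- beta1 * st$mW + (1 - beta1) * gW
          st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
          st$mb <- beta1 * st$mb + (1 - beta1) * gb
          st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
          mstate[[nm]] <- st
          model$layers[[nm]]$W <- model$layers[[nm]]$W -
            lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          model$layers[[nm]]$b <- model$layers[[nm]]$b -
            lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
        }
        losses <- c(losses, bl / length(bs))
      }
      vm <- NA_real_
      if (!is.null(val_images)) {
        ious <- vapply(seq_along(val_images), function(i) {
          pred <- unet_predict(model, val_images[[i]])
          mean_iou(binarize(pred, threshold), val_labels[[i]])
        }, numeric(1))
        vm <- mean(ious)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                           val_miou = vm))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val mIoU %s", ep, mean(losses),
                        ifelse(is.na(vm), "-", sprintf("%.3f", vm))))
    }
  })
  model$trained_epochs <- model$trained_epochs + epochs
  list(model = model, history = history)
}

#' Predict a soft capillary mask with a trained U-Net
#'
#' The frame is resized to the model's `input_size`, passed through the
#' network, and the sigmoid output map (scaled to 0..255) is resized back to
#' the frame geometry. With `input_size = NULL` the frame is instead
#' reflect-padded to the next multiple of `2^depth`, processed at native
#' resolution and cropped.
#'
#' @param model a trained [unet_build()] model.
#' @param frame `H x W x 3` RGB array on 0..255.
#' @return A soft [capillary_mask()].
#' @export
unet_predict <- function(model, frame) {
  d <- dim(frame)
  if (!is.null(model$input_size)) {
    x <- resize_rgb(frame, model$input_size, model$input_size) / 255
    fw <- unet_forward(model, x)
    soft <- 255 / (1 + exp(-fw$logits))
    out <- resize_bilinear(soft, d[1], d[2])
  } else {
    mult <- 2L^model$depth
    h2 <- ceiling(d[1] / mult) * mult; w2 <- ceiling(d[2] / mult) * mult
    ri <- reflect_index(seq_len(h2), d[1]); ci <- reflect_index(seq_len(w2), d[2])
    xp <- frame[ri, ci, , drop = FALSE] / 255
    fw <- unet_forward(model, xp)
    soft <- 255 / (1 + exp(-fw$logits))
    out <- soft[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  }
  capillary_mask(clamp(out, 0, 255), kind = "soft", method = "dnn")
}
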