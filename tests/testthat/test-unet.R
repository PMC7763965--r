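test_that("the model contract holds: shapes, skip wiring, parameter count", {
  m <- unet_build(depth = 1, base_channels = 8, input_size = 64, seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- capcount:::unet_forward(m, x)
  expect_equal(dim(out$logits), c(64, 64))
  # decoder convs receive the concatenation of skip and upsampled features
  expect_equal(m$layers$dec1_1$cin, 2L * 8L)
  # parameter count equals the closed-form sum over declared layers
  conv_p <- function(ci, co) (9 * ci + 1) * co
  up_p <- function(ci, co) (4 * co) * ci + co
  expected <- conv_p(3, 8) + conv_p(8, 8) +            # encoder level 1
    conv_p(8, 16) + conv_p(16, 16) +                   # bottleneck
    up_p(16, 8) + conv_p(16, 8) + conv_p(8, 8) +       # decoder level 1
    (8 + 1)                                            # 1x1 head
  expect_equal(count_parameters(m), expected)
  expect_error(unet_build(depth = 2, input_size = 62), "divisible")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(40)
  m <- unet_build(depth = 2, base_channels = 2, input_size = 8, seed = 3)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  lossfn <- function(mm) {
    lg <- capcount:::unet_forward(mm, x)$logits
    mean(pmax(lg, 0) - lg * y + log1p(exp(-abs(lg))))
  }
  fw <- capcount:::unet_forward(m, x, keep_cache = TRUE)
  dlog <- (1 / (1 + exp(-fw$logits)) - y) / length(fw$logits)
  g <- capcount:::unet_backward(m, fw, dlog)
  eps <- 1e-5
  for (nm in c("enc1_1", "bot_2", "up2", "dec1_2", "final")) {
    i <- sample(length(m$layers[[nm]]$W), 1)
    m2 <- m; m2$layers[[nm]]$W[i] <- m2$layers[[nm]]$W[i] + eps
    m3 <- m; m3$layers[[nm]]$W[i] <- m3$layers[[nm]]$W[i] - eps
    num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
    expect_equal(g[[nm]]$dW[i], num, tolerance = 1e-4,
                 label = sprintf("d/dW %s", nm))
  }
})

test_that("training is seeded-deterministic and reduces the loss", {
  set.seed(41)
  imgs <- lapply(1:6, function(i) {
    f <- array(30, c(16, 16, 3))
    r <- sample(4:12, 1)
    f[r + (-2:2), 5:12, 1] <- 220   # red bar = "vessel"
    f + array(runif(16 * 16 * 3, 0, 10), c(16, 16, 3))
  })
  labs <- lapply(imgs, function(f) ifelse(f[, , 1] > 150, 255, 0))
  m <- unet_build(depth = 1, base_channels = 4, input_size = 16, seed = 5)
  fit1 <- unet_train(m, imgs, labs, epochs = 12, batch_size = 3, seed = 9,
                     lr = 0.01)
  fit2 <- unet_train(m, imgs, labs, epochs = 12, batch_size = 3, seed = 9,
                     lr = 0.01)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_lt(utils::tail(fit1$history$loss, 1), fit1$history$loss[1] / 2)
  # smoothed (window 5) loss is non-increasing overall
  sm <- stats::filter(fit1$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(utils::tail(sm, 1), sm[1])
  pred <- unet_predict(fit1$model, imgs[[1]])
  expect_s3_class(pred, "capillary_mask")
  expect_equal(dim(pred$values), c(16, 16))
  expect_error(unet_train(m, list(), list()), "empty")
  expect_error(unet_train(m, imgs, labs[-1]), "one-to-one")
})

test_that("native-size inference pads and crops arbitrary geometries", {
  m <- unet_build(depth = 2, base_channels = 2, input_size = NULL, seed = 6)
  f <- array(runif(37 * 53 * 3, 0, 255), c(37, 53, 3))
  pred <- unet_predict(m, f)
  expect_equal(dim(pred$values), c(37, 53))
  expect_true(all(pred$values >= 0 & pred$values <= 255))
})
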