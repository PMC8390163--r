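test_that("feature_map_size floor-halves once per pool and names the minimum on error", {
  vgg <- backbone_spec("vgg16")
  expect_equal(feature_map_size(224, 224, vgg), c(14, 14))
  expect_equal(feature_map_size(19, 29, vgg), c(1, 1))   # smallest clinical ROI
  expect_equal(feature_map_size(16, 16, vgg), c(1, 1))
  expect_error(feature_map_size(15, 100, vgg), "16x16")

  tiny <- backbone_spec("tiny")
  expect_equal(tiny$n_pools, 2)
  expect_equal(feature_map_size(19, 29, tiny), c(4, 7))
})

test_that("one network processes any valid size into the same output shape", {
  net <- msp_net(backbone_spec("tiny"), msp_levels(1:3), seed = 3)
  sizes <- list(c(19, 29), c(32, 64), c(48, 160), c(134, 564))
  set.seed(5)
  for (sz in sizes) {
    img <- matrix(runif(sz[1] * sz[2]), sz[1], sz[2])
    prob <- stripnet:::net_forward(net, img)$prob
    expect_length(prob, 3)
    expect_true(all(prob >= 0))
    expect_equal(sum(prob), 1, tolerance = 1e-6)
    expect_length(extract_features(net, img), net$pooled_len)
  }
  expect_error(stripnet:::net_forward(net, matrix(0.5, 3, 50)), "minimum")
})

test_that("softmax is symmetric at zero and shift-invariant in its argmax", {
  expect_equal(stripnet:::softmax(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(8)
  for (rep in 1:20) {
    z <- rnorm(3)
    expect_equal(which.max(stripnet:::softmax(z)),
                 which.max(stripnet:::softmax(z + runif(1, -5, 5))))
  }
})

test_that("dropout masks with the retain probability", {
  y <- rep(1, 10000)
  expect_equal(dropout_apply(y, p = 1), y)
  expect_equal(dropout_apply(y, p = 0), rep(0, 10000))
  masked <- dropout_apply(y, p = 0.5, seed = 99)
  expect_true(all(masked %in% c(0, 1)))
  expect_lt(abs(mean(masked) - 0.5), 0.02)
  expect_identical(masked, dropout_apply(y, p = 0.5, seed = 99))
  expect_error(dropout_apply(y, p = 1.2), "\\[0, 1\\]")
  expect_error(dropout_apply(y, p = -0.1), "\\[0, 1\\]")
})

test_that("a single SGD step decreases the sample's cross-entropy loss", {
  cfg <- small_roi_config()
  img <- generate_plaque("echo-rich", cfg, seed = 21)
  net <- msp_net(backbone_spec("tiny"), msp_levels(1:3), p_retain = 1, seed = 4)
  loss_of <- function(n) -log(stripnet:::net_forward(n, img)$prob[1])
  before <- loss_of(net)
  fit <- fit_mspnet(net, list(a = img), "echo-rich",
                    train_config(epochs = 1, base_lr = 1e-4, seed = 1))
  expect_lt(loss_of(fit$net), before)
})

test_that("an identity backbone wires the raw image straight into the pooling head", {
  # 1 block, 1 filter, no pool; delta kernel and zero bias make the conv an
  # identity on non-negative input, so the pooled features must equal the
  # pooling module applied to the image itself.
  spec <- backbone_spec(blocks = list(c(1, 1)), include_final_pool = FALSE)
  lv <- msp_levels(1:3)
  net <- msp_net(spec, lv, seed = 1)
  params <- net$params
  params$conv[[1]]$W <- array(0, dim = c(3, 3, 1, 1))
  params$conv[[1]]$W[2, 2, 1, 1] <- 1
  params$conv[[1]]$b <- 0
  net <- set_weights(net, params)
  set.seed(12)
  img <- matrix(runif(11 * 17), 11, 17)
  expect_equal(extract_features(net, img), msp_forward(img, lv),
               tolerance = 1e-12)
})

test_that("parameter shapes are independent of the input size", {
  net <- msp_net(backbone_spec("tiny"), msp_levels(1:3), seed = 2)
  shapes <- function(fit_net) lapply(fit_net$params$conv, function(p) dim(p$W))
  cfg <- small_roi_config()
  s1 <- make_synth_set(1, cfg, seed0 = 1)
  fit <- fit_mspnet(net, s1$images, s1$labels, train_config(epochs = 1, seed = 1))
  expect_identical(shapes(fit$net), shapes(net))
  expect_identical(dim(fit$net$params$fc1$W), dim(net$params$fc1$W))
})
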