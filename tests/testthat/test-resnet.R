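test_that("forward pass yields a probability vector over the two classes", {
  spec <- resnet_spec(stem_filters = 8, stage_filters = c(8, 16),
                      blocks_per_stage = 1, input_size = 32)
  m <- build_model(spec, seed = 2)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 3), dim = c(32, 32, 3, 3))
  fw <- resnet_forward(m, x)
  expect_equal(colSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
  # arbitrary real inputs still give a valid distribution
  x2 <- array(rnorm(32 * 32 * 3 * 2, sd = 50), dim = c(32, 32, 3, 2))
  fw2 <- resnet_forward(m, x2)
  expect_equal(colSums(fw2$probs), rep(1, 2), tolerance = 1e-6)
})

test_that("weight initialization is seed-deterministic", {
  spec <- resnet_tiny_spec()
  m1 <- build_model(spec, seed = 11)
  m2 <- build_model(spec, seed = 11)
  m3 <- build_model(spec, seed = 12)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter count of the full 18-layer 2-class network matches arithmetic", {
  # independent layer-by-layer count: stem 7x7x3x64 conv + BN(2x64);
  # stage s with f filters: first block conv1 3x3x(f_prev)xf + conv2
  # 3x3xfxf + 2 BNs (+ projection 1x1xf_prev xf + BN when dimensions
  # change), second block 2 convs 3x3xfxf + 2 BNs; head 512x2 + 2.
  f <- c(64, 128, 256, 512)
  expected <- 7 * 7 * 3 * 64 + 2 * 64
  f_prev <- 64
  for (s in seq_along(f)) {
    fs <- f[s]
    proj <- if (s > 1) f_prev * fs + 2 * fs else 0  # dotted shortcut
    expected <- expected +
      (3 * 3 * f_prev * fs + 2 * fs) + (3 * 3 * fs * fs + 2 * fs) + proj +
      (3 * 3 * fs * fs + 2 * fs) + (3 * 3 * fs * fs + 2 * fs)
    f_prev <- fs
  }
  expected <- expected + 512 * 2 + 2
  m <- build_model(resnet18_spec(), seed = 1)
  expect_equal(param_count(m), expected)
})

test_that("channel count doubles exactly when spatial size halves", {
  spec <- resnet18_spec()
  expect_equal(spec$stage_filters[-1] / spec$stage_filters[-4], c(2, 2, 2))
  m <- build_model(resnet_tiny_spec(), seed = 1)
  x <- array(runif(64 * 64 * 3 * 1), dim = c(64, 64, 3, 1))
  fw <- resnet_forward(m, x, keep_cache = TRUE)
  d1 <- dim(fw$cache$blocks[["s1.b2"]]$x)
  d2 <- dim(fw$cache$blocks[["s2.b2"]]$x)
  expect_equal(d1[1] / d2[1], 2)
  expect_equal(d2[3] / d1[3], 2)
})

test_that("a zeroed residual branch with identity shortcut returns relu(x)", {
  blk <- residual_block(8, 8, stride = 1, shortcut = "identity",
                        bn_passthrough = TRUE, seed = 4)
  blk$params[["blk.conv1"]][] <- 0
  blk$params[["blk.conv2"]][] <- 0
  x <- array(rnorm(6 * 6 * 8 * 2), dim = c(6, 6, 8, 2))
  y <- residual_block_forward(blk, x)
  expect_equal(y, pmax(x, 0), tolerance = 1e-12)
})

test_that("an identity-equivalent projection with zero residual branch returns relu(x)", {
  blk <- residual_block(4, 4, stride = 1, shortcut = "projection",
                        bn_passthrough = TRUE, seed = 4)
  blk$params[["blk.conv1"]][] <- 0
  blk$params[["blk.conv2"]][] <- 0
  proj <- array(0, dim = c(1, 1, 4, 4))
  for (c in 1:4) proj[1, 1, c, c] <- 1
  blk$params[["blk.proj"]] <- proj
  x <- array(rnorm(5 * 5 * 4 * 1), dim = c(5, 5, 4, 1))
  expect_equal(residual_block_forward(blk, x), pmax(x, 0), tolerance = 1e-12)
})

test_that("block forward agrees with a brute-force convolution oracle", {
  for (case in list(list(cin = 2, cout = 2, stride = 1, sc = "identity"),
                    list(cin = 2, cout = 3, stride = 1, sc = "projection"),
                    list(cin = 2, cout = 4, stride = 2, sc = "projection"))) {
    blk <- residual_block(case$cin, case$cout, stride = case$stride,
                          shortcut = case$sc, bn_passthrough = TRUE,
                          seed = 99)
    set.seed(7)
    x <- array(rnorm(4 * 4 * case$cin), dim = c(4, 4, case$cin, 1))
    h <- pmax(naive_conv2d(x, blk$params[["blk.conv1"]],
                           stride = case$stride, pad = 1), 0)
    f <- naive_conv2d(h, blk$params[["blk.conv2"]], stride = 1, pad = 1)
    sc <- if (case$sc == "identity") x else
      naive_conv2d(x, blk$params[["blk.proj"]], stride = case$stride, pad = 0)
    expected <- pmax(f + sc, 0)
    got <- residual_block_forward(blk, x)
    expect_equal(got, expected, tolerance = 1e-5)
  }
})

test_that("identity shortcuts refuse mismatched dimensions", {
  expect_error(residual_block(4, 8, stride = 1, shortcut = "identity"),
               "identity shortcut requires")
  expect_error(residual_block(4, 4, stride = 2, shortcut = "identity"),
               "identity shortcut requires")
  blk <- residual_block(4, 4, shortcut = "identity")
  x <- array(rnorm(4 * 4 * 3 * 1), dim = c(4, 4, 3, 1))
  expect_error(residual_block_forward(blk, x), "channels")
})

test_that("zero-padding shortcuts increase dimensions without parameters", {
  blk_p <- residual_block(4, 8, stride = 2, shortcut = "projection", seed = 1)
  blk_z <- residual_block(4, 8, stride = 2, shortcut = "zero_pad", seed = 1)
  expect_false("blk.proj" %in% names(blk_z$params))
  expect_true("blk.proj" %in% names(blk_p$params))
  x <- array(rnorm(8 * 8 * 4 * 1), dim = c(8, 8, 4, 1))
  y <- residual_block_forward(blk_z, x)
  expect_equal(dim(y), c(4, 4, 8, 1))
})

test_that("gradient reaches the input through a zeroed residual branch", {
  # with the identity shortcut the block cannot block gradient flow
  spec <- resnet_spec(stem_filters = 4, stage_filters = 4,
                      blocks_per_stage = 1, input_size = 16)
  m <- build_model(spec, seed = 6)
  m$params[["s1.b1.conv1"]][] <- 0
  m$params[["s1.b1.conv2"]][] <- 0
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  fw <- resnet_forward(m, x, train = TRUE, keep_cache = TRUE)
  dlogits <- matrix(c(1, -1, 1, -1), nrow = 2)
  grads <- pvcnet:::resnet_backward(m, fw$cache, dlogits)
  expect_gt(sum(abs(grads[["stem.conv"]])), 0)
})

test_that("pretrained mode without weights fails with offline guidance", {
  expect_error(build_model(resnet_tiny_spec(), pretrained_backbone = TRUE),
               "pretrained_backbone = FALSE")
})

test_that("checkpoints round-trip spec, weights and running statistics", {
  m <- build_model(resnet_spec(stem_filters = 4, stage_filters = 4,
                               blocks_per_stage = 1, input_size = 16),
                   seed = 8)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, p)
  m2 <- restore_model(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$spec, m$spec)
  # a fresh model can consume the checkpoint as a pretrained backbone:
  # backbone weights match, head stays randomly initialized
  m3 <- build_model(m$spec, pretrained_backbone = TRUE, backbone_path = p,
                    seed = 9)
  expect_identical(m3$params[["stem.conv"]], m$params[["stem.conv"]])
  expect_false(identical(m3$params[["fc.W"]], m$params[["fc.W"]]))
})
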