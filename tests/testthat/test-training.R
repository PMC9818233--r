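test_that("class weights are the complement of the batch share", {
  w <- class_weights(rep(c("NORMAL", "PVC"), each = 16))
  expect_equal(w, c(NORMAL = 0.5, PVC = 0.5))
  w2 <- class_weights(c(rep("NORMAL", 28), rep("PVC", 4)))
  expect_equal(w2, c(NORMAL = 0.125, PVC = 0.875))
  # degenerate single-class batch: weight 0 for the present class
  w3 <- class_weights(rep("NORMAL", 32))
  expect_equal(w3[["NORMAL"]], 0)
  expect_equal(w3[["PVC"]], 1)
})

test_that("weighted binary cross-entropy satisfies its identities", {
  # perfect prediction (post-clamp) gives essentially zero loss
  y <- c(1, 0, 1, 1, 0)
  expect_lt(weighted_bce(y, y, c(NORMAL = 0.5, PVC = 0.5)), 1e-5)
  # balanced weights halve the unweighted loss
  set.seed(2)
  p <- runif(40)
  yy <- rep(0:1, 20)
  expect_equal(weighted_bce(p, yy, c(NORMAL = 0.5, PVC = 0.5)),
               0.5 * weighted_bce(p, yy, c(NORMAL = 1, PVC = 1)),
               tolerance = 1e-12)
  # two-sample hand-computed case: loss = 0.5 * ln 2 under mean reduction
  expect_equal(weighted_bce(c(0.5, 0.5), c(0, 1), c(NORMAL = 0.5, PVC = 0.5)),
               0.5 * log(2), tolerance = 1e-9)
  # non-negative everywhere, factor labels accepted
  expect_gte(weighted_bce(runif(10), rbinom(10, 1, 0.5)), 0)
  expect_equal(weighted_bce(c(0.2, 0.8), factor(c("NORMAL", "PVC"))),
               weighted_bce(c(0.2, 0.8), c(0, 1)))
  expect_error(weighted_bce(c(0.5), c(0, 1)), "length")
})

test_that("weighted sampler balances classes and is reproducible", {
  labels <- c(rep("NORMAL", 900), rep("PVC", 100))
  s <- make_weighted_sampler(labels, seed = 5)
  # expected per-class frequency 0.5; 3 standard errors for 10,000 draws
  draws <- s$draw(10000)
  frac_pvc <- mean(labels[draws] == "PVC")
  expect_lt(abs(frac_pvc - 0.5), 3 * sqrt(0.25 / 10000))
  # weights: inverse class frequency; balanced data means equal weights
  sb <- make_weighted_sampler(rep(c("NORMAL", "PVC"), 50), seed = 1)
  expect_equal(length(unique(round(sb$weights, 12))), 1)
  # identical seed, identical stream (across successive calls too)
  s1 <- make_weighted_sampler(labels, seed = 9)
  s2 <- make_weighted_sampler(labels, seed = 9)
  expect_identical(c(s1$draw(50), s1$draw(50)), c(s2$draw(50), s2$draw(50)))
  expect_error(make_weighted_sampler(rep("NORMAL", 10)), "PVC")
})

test_that("augmentation is identity when disabled and RNG-determined otherwise", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(augment_image(img, enabled = FALSE), img)
  set.seed(77); a1 <- augment_image(img)
  set.seed(77); a2 <- augment_image(img)
  expect_identical(a1, a2)
  set.seed(78); a3 <- augment_image(img)
  expect_false(identical(a1, a3))
  expect_equal(dim(a1), dim(img))
})

test_that("the early-stopping rule reproduces the worked trace", {
  # validation loss improves through epoch 59 and is flat from epoch 60
  # onwards; with patience 8 the run halts at epoch 67
  trace <- c(seq(1, 0.1, length.out = 59), rep(0.1, 141))
  res <- early_stop_epoch(trace, patience = 8)
  expect_equal(res$stop_epoch, 67)
  expect_equal(res$stop_reason, "early_stop")
  # a strictly decreasing loss runs to the epoch cap
  res2 <- early_stop_epoch(seq(1, 0.5, length.out = 10), patience = 8)
  expect_equal(res2$stop_epoch, 10)
  expect_equal(res2$stop_reason, "max_epochs")
  # patience is configurable
  expect_equal(early_stop_epoch(trace, patience = 6)$stop_epoch, 65)
})

test_that("fit refuses leakage and empty inputs", {
  ds <- small_beat_dataset()
  m <- build_model(resnet_tiny_spec(), seed = 1)
  expect_error(fit(m, ds, train_config(max_epochs = 1),
                   eval_subjects = "SYN01"), "SYN01")
  empty <- subset_dataset(ds, integer(0))
  expect_error(fit(m, empty, train_config(max_epochs = 1)), "empty")
})

test_that("training a tiny model on separable beats learns the classes", {
  ds <- small_beat_dataset(n_subjects = 4, n_beats = 40, seed = 1)
  cfg <- train_config(max_epochs = 8, seed = 1)
  m <- build_model(resnet_tiny_spec(), seed = 1)
  ft <- fit(m, ds, cfg)
  expect_lt(tail(ft$history$train_loss, 1), ft$history$train_loss[1])
  # learning-rate trace never increases and decays only by the factor
  lr <- ft$history$lr
  expect_true(all(diff(lr) <= 0))
  steps <- lr[-1] / lr[-length(lr)]
  expect_true(all(abs(steps - 1) < 1e-12 | abs(steps - 0.1) < 1e-12))
  pred <- predict_labels(ft$model, ds$images)
  acc <- mean(pred == ds$labels)
  expect_gt(acc, 0.9)
  # augmented copies of one beat classify like the original
  img <- pvcnet:::stack_images(ds$images[1])[, , , 1]
  base_lab <- as.character(predict_labels(ft$model, list(img)))
  set.seed(42)
  augs <- replicate(60, augment_image(img), simplify = FALSE)
  labs <- as.character(predict_labels(ft$model, augs))
  expect_gte(mean(labs == base_lab), 0.95)
})
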