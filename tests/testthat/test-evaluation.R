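test_that("confusion counts are exact", {
  t10 <- rep(c("NORMAL", "PVC"), 5)
  cm <- confusion(t10, t10)
  expect_equal(cm["NORMAL", "PVC"] + cm["PVC", "NORMAL"], 0)
  expect_equal(sum(cm), 10)
  # an all-NORMAL prediction on a balanced set
  cm2 <- confusion(rep(c("NORMAL", "PVC"), each = 5), rep("NORMAL", 10))
  expect_equal(cm2["PVC", "PVC"], 0)     # TP
  expect_equal(cm2["PVC", "NORMAL"], 5)  # FN
  expect_equal(cm2["NORMAL", "NORMAL"], 5)
  expect_equal(cm2["NORMAL", "PVC"], 0)
  expect_error(confusion(c("NORMAL", "APB"), c("PVC", "PVC")), "APB")
  expect_error(confusion("NORMAL", c("PVC", "PVC")), "length")
})

test_that("confusion agrees with a brute-force tally on random labels", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    t_ <- sample(c("NORMAL", "PVC"), n, replace = TRUE)
    p_ <- sample(c("NORMAL", "PVC"), n, replace = TRUE)
    cm <- confusion(t_, p_)
    for (a in c("NORMAL", "PVC")) for (b in c("NORMAL", "PVC")) {
      tally <- sum(vapply(seq_len(n), function(k) t_[k] == a && p_[k] == b,
                          logical(1)))
      expect_identical(as.integer(cm[a, b]), as.integer(tally))
    }
  }
})

test_that("metrics agree with an independent recomputation on random matrices", {
  set.seed(77)
  for (i in 1:200) {
    cnt <- sample(0:500, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    cm <- confusion_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    rep_ <- metrics(cm)
    ora <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    pc <- rep_$per_class
    expect_equal(rep_$accuracy, ora$accuracy, tolerance = 1e-10)
    expect_equal(pc$precision[pc$class == "PVC"], ora$precision_pvc,
                 tolerance = 1e-10)
    expect_equal(pc$recall[pc$class == "PVC"], ora$recall_pvc,
                 tolerance = 1e-10)
    expect_equal(pc$f1[pc$class == "PVC"], ora$f1_pvc, tolerance = 1e-10)
    expect_equal(unname(rep_$macro["f1"]), ora$macro_f1, tolerance = 1e-10)
    expect_equal(rep_$balanced_accuracy, ora$balanced_accuracy,
                 tolerance = 1e-10)
    # binary duality: specificity of one class is the recall of the other
    if (!any(is.na(pc$specificity)) && !any(is.na(pc$recall))) {
      expect_equal(pc$specificity[pc$class == "NORMAL"],
                   pc$recall[pc$class == "PVC"], tolerance = 1e-12)
      expect_equal(pc$specificity[pc$class == "PVC"],
                   pc$recall[pc$class == "NORMAL"], tolerance = 1e-12)
    }
    # balanced accuracy equals macro-average recall in the binary case
    if (!any(is.na(pc$recall))) {
      expect_equal(rep_$balanced_accuracy, unname(rep_$macro["recall"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("a perfect symmetric matrix scores 1 everywhere", {
  rep_ <- metrics(confusion_from_counts(50, 0, 0, 50))
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$balanced_accuracy, 1)
  expect_true(all(unlist(rep_$per_class[, -1]) == 1))
  expect_true(all(rep_$macro == 1))
})

test_that("zero-denominator metrics are flagged as undefined, not zeroed", {
  # no PVC beats at all: PVC precision and recall are undefined
  rep_ <- metrics(confusion_from_counts(10, 0, 0, 0))
  pc <- rep_$per_class
  expect_true(is.na(pc$precision[pc$class == "PVC"]))
  expect_true(is.na(pc$recall[pc$class == "PVC"]))
  expect_true("PVC" %in% rep_$undefined)
  expect_error(metrics(confusion_from_counts(0, 0, 0, 0)), "empty")
})

test_that("report printing rounds percentages half away from zero", {
  expect_equal(pvcnet:::round_half_up(99.125, 2), 99.13)
  expect_equal(pvcnet:::round_half_up(99.865, 2), 99.87)
  expect_equal(pvcnet:::round_half_up(-0.125, 2), -0.13)
  out <- capture.output(print(metrics(confusion_from_counts(95, 5, 2, 98))))
  expect_true(any(grepl("balanced accuracy", out)))
  tab <- report_as_table(metrics(confusion_from_counts(95, 5, 2, 98)), "demo")
  expect_true(all(c("experiment", "class", "metric", "value") %in% names(tab)))
  expect_equal(nrow(tab), 8 + 4 + 2)
})

test_that("summing fold matrices conserves the beat total", {
  cms <- list(confusion_from_counts(10, 1, 2, 7),
              confusion_from_counts(5, 0, 1, 4),
              confusion_from_counts(8, 2, 0, 6))
  agg <- sum_confusions(cms)
  expect_equal(sum(agg), sum(vapply(cms, sum, numeric(1))))
  expect_equal(agg["PVC", "PVC"], 17)
})
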