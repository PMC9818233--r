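test_that("the midpoint rule segments interior beats exactly", {
  rec <- ecg_record("r", fs = 360, samples = rnorm(1000))
  beats <- segment_beats(rec, c(200, 400, 600))
  expect_length(beats, 1)
  expect_equal(beats[[1]]$r_index, 400)
  expect_equal(beats[[1]]$start, 300)
  expect_equal(beats[[1]]$end, 500)
  expect_length(beats[[1]]$samples, 200)
  expect_warning(empty <- segment_beats(rec, c(100, 300)), "fewer than 3")
  expect_length(empty, 0)
})

test_that("windows tile the covered span without gaps or overlap", {
  set.seed(404)
  rec <- ecg_record("r", fs = 360, samples = numeric(20000))
  for (rep in 1:50) {
    n_peaks <- sample(3:40, 1)
    peaks <- cumsum(sample(2:400, n_peaks, replace = TRUE))
    beats <- segment_beats(rec, peaks)
    expect_length(beats, n_peaks - 2)
    starts <- vapply(beats, `[[`, numeric(1), "start")
    ends <- vapply(beats, `[[`, numeric(1), "end")
    expect_equal(starts[1], (peaks[1] + peaks[2]) %/% 2)
    expect_equal(ends[length(ends)],
                 (peaks[n_peaks - 1] + peaks[n_peaks]) %/% 2)
    if (length(beats) > 1) {
      expect_equal(starts[-1], ends[-length(ends)])  # exact tiling
    }
    expect_true(all(ends > starts))
    expect_true(all(starts <= vapply(beats, `[[`, numeric(1), "r_index")))
    expect_true(all(vapply(beats, `[[`, numeric(1), "r_index") < ends))
  }
})

test_that("labelling matches the nearest annotation within tolerance", {
  rec <- ecg_record("r", fs = 360, samples = rnorm(2000),
                    annotations = data.frame(sample = c(400, 800, 1200),
                                             symbol = c("N", "V", "A")))
  beats <- segment_beats(rec, c(400, 800, 1200, 1600))
  lab <- label_beats(beats, rec$annotations, rec$fs)
  # beat at the 'V' annotation is a PVC; the 'A' (OTHER) beat is dropped
  expect_length(lab, 1)
  expect_equal(lab[[1]]$r_index, 800)
  expect_equal(lab[[1]]$label, "PVC")
  expect_equal(attr(lab, "dropped")[["other"]], 1)
  # a beat 0.3 s away from every annotation is dropped at 0.15 s tolerance
  far <- segment_beats(rec, c(292, 1000, 1700))
  lab2 <- label_beats(far, rec$annotations[1, ], rec$fs, tolerance_s = 0.15)
  expect_length(lab2, 0)
  expect_equal(attr(lab2, "dropped")[["unmatched"]], 1)
})

test_that("clean synthetic record yields ground-truth count minus endpoints", {
  g <- generate_record(rhythm_spec(n_beats = 30, pvc_fraction = 0.2,
                                   noise_sd = 0, seed = 17))
  beats <- segment_beats(g$record)
  lab <- label_beats(beats, g$record$annotations, g$record$fs)
  expect_length(lab, nrow(g$truth) - 2)
  expect_equal(vapply(lab, `[[`, "", "label"),
               g$truth$label[2:(nrow(g$truth) - 1)])
})

test_that("rendering is deterministic and shape-exact", {
  cfg <- render_config(height = 64, width = 96, line_width = 2)
  x <- sin(seq(0, 6 * pi, length.out = 300))
  i1 <- render_beat_image(x, cfg)
  i2 <- render_beat_image(x, cfg)
  expect_identical(i1, i2)
  expect_equal(dim(i1), c(64, 96, 3))
  expect_true(all(i1 >= 0 & i1 <= 255))
})

test_that("a constant beat renders as a mid-height line", {
  cfg <- render_config(height = 63, width = 63, line_width = 1)
  img <- render_beat_image(rep(2.5, 100), cfg)
  nonbg <- which(img[, , 1] != cfg$bg_rgb[1], arr.ind = TRUE)
  expect_gt(nrow(nonbg), 0)
  mid <- (63 + 1) / 2
  expect_true(all(abs(nonbg[, 1] - mid) <= 1))
  expect_equal(sort(unique(nonbg[, 2])), 1:63)
})

test_that("PVC and normal morphologies survive rendering as distinct images", {
  g <- generate_record(rhythm_spec(n_beats = 20, pvc_fraction = 0.5,
                                   noise_sd = 0, seed = 31))
  beats <- label_beats(segment_beats(g$record), g$record$annotations,
                       g$record$fs)
  labels <- vapply(beats, `[[`, "", "label")
  cfg <- render_config(64, 64)
  i_n <- render_beat_image(beats[[which(labels == "NORMAL")[1]]], cfg)
  i_v <- render_beat_image(beats[[which(labels == "PVC")[1]]], cfg)
  expect_gt(sum(i_n != i_v), 0)
})

test_that("dataset building ties images, labels and subjects together", {
  gen <- generate_dataset(n_subjects = 2, n_beats = 12, pvc_fraction = 0.25,
                          seed = 3)
  ds <- build_beat_dataset(lapply(gen, `[[`, "record"), render_config(32, 32))
  expect_s3_class(ds, "beat_dataset")
  expect_equal(length(ds$images), 2 * (12 - 2))
  expect_setequal(unique(ds$subject_id), c("SYN01", "SYN02"))
  expect_true(all(ds$labels %in% c("NORMAL", "PVC")))
  d <- withr::local_tempdir()
  idx_path <- write_dataset_index(ds, file.path(d, "index.csv"))
  idx <- read.csv(idx_path)
  expect_equal(nrow(idx), length(ds$images))
  png_path <- write_beat_png(ds$images[[1]], file.path(d, "beat.png"))
  back <- png::readPNG(png_path)
  expect_equal(round(back * 255), unclass(ds$images[[1]]), ignore_attr = TRUE)
  # detector-anchored segmentation works end to end as well
  ds2 <- build_beat_dataset(lapply(gen, `[[`, "record"), render_config(32, 32),
                            anchor = "detector")
  expect_gt(length(ds2$images), 0)
})
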