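test_that("annotation symbol mapping is total and configurable", {
  expect_equal(map_annotation_symbol("V"), "PVC")
  expect_equal(map_annotation_symbol("N"), "NORMAL")
  expect_equal(map_annotation_symbol("A"), "OTHER")
  expect_equal(map_annotation_symbol(c("N", "V", "A", "L", "?", "x")),
               c("NORMAL", "PVC", "OTHER", "OTHER", "OTHER", "OTHER"))
  expect_equal(map_annotation_symbol("L", normal_symbols = c("N", "L", "R")),
               "NORMAL")
})

test_that("record construction enforces its invariants", {
  expect_error(ecg_record("r", fs = 0, samples = 1:10), "positive")
  expect_error(ecg_record("r", fs = 360, samples = numeric(0)), "non-empty")
  ann <- data.frame(sample = c(5, 12), symbol = c("N", "V"))
  expect_error(ecg_record("r", fs = 360, samples = rnorm(10), annotations = ann),
               "out of range.*12")
  ann2 <- data.frame(sample = c(5, 5), symbol = c("N", "V"))
  expect_error(ecg_record("r", fs = 360, samples = rnorm(10), annotations = ann2),
               "strictly increasing")
})

test_that("write_record / read_record round-trips samples and annotations", {
  g <- generate_record(rhythm_spec(n_beats = 10, pvc_fraction = 0.3,
                                   noise_sd = 0.02, seed = 42))
  rec <- g$record
  d <- withr::local_tempdir()
  write_record(rec, d, aux_leads = list(V1 = rev(rec$samples)))
  r1 <- read_record(file.path(d, rec$record_id), lead = "MLII")
  expect_identical(r1$annotations$sample, rec$annotations$sample)
  expect_identical(r1$annotations$symbol, rec$annotations$symbol)
  expect_equal(r1$samples, round(rec$samples * 200) / 200, tolerance = 0)
  expect_equal(r1$fs, rec$fs)
  expect_equal(r1$lead_name, "MLII")
  # second trip of the already-quantized record is bit-exact
  d2 <- withr::local_tempdir()
  write_record(r1, d2)
  r2 <- read_record(file.path(d2, rec$record_id))
  expect_identical(r2$samples, r1$samples)
  expect_identical(r2$annotations, r1$annotations)
  # fixture with 10 annotated beats comes back with all 10, as manifested
  mf <- file.path(d, "truth.csv")
  write_truth_manifest(list(g), mf)
  manifest <- read.csv(mf)
  expect_equal(nrow(r1$annotations), 10)
  expect_equal(r1$annotations$sample, manifest$sample)
  expect_equal(map_annotation_symbol(r1$annotations$symbol), manifest$label)
})

test_that("reading a missing file or absent lead fails informatively", {
  expect_error(read_record("/nonexistent/rec001"), "rec001.hea")
  g <- generate_record(rhythm_spec(n_beats = 5, seed = 1))
  d <- withr::local_tempdir()
  write_record(g$record, d)
  expect_error(read_record(file.path(d, g$record$record_id), lead = "V5"),
               "available leads.*MLII")
})

test_that("resampling preserves identity at the native rate and rescales indices", {
  g <- generate_record(rhythm_spec(n_beats = 8, seed = 5))
  expect_identical(resample_record(g$record, g$record$fs), g$record)
  # exact 360 -> 200 ratio: index 360 lands on 200
  rec <- ecg_record("r", fs = 360, samples = sin(seq_len(720) / 10),
                    annotations = data.frame(sample = 360, symbol = "N"))
  expect_equal(resample_record(rec, 200)$annotations$sample, 200L)
  expect_error(resample_record(rec, -5), "positive")
})

test_that("band-limited resampling reproduces an analytic sinusoid", {
  fs1 <- 360; fs2 <- 200; f <- 5
  t1 <- seq(0, 10, by = 1 / fs1)
  rec <- ecg_record("sine", fs = fs1, samples = sin(2 * pi * f * t1))
  out <- resample_record(rec, fs2)
  n2 <- length(out$samples)
  ref <- sin(2 * pi * f * (seq_len(n2) - 1) / fs2)
  interior <- seq(ceiling(0.05 * n2), floor(0.95 * n2))
  expect_gt(cor(out$samples[interior], ref[interior]), 0.999)
})

test_that("resampling preserves annotation count and order at any rate", {
  g <- generate_record(rhythm_spec(n_beats = 25, pvc_fraction = 0.2, seed = 9))
  for (hz in c(97.3, 200, 257, 500)) {
    out <- resample_record(g$record, hz)
    expect_equal(nrow(out$annotations), nrow(g$record$annotations))
    expect_false(is.unsorted(out$annotations$sample, strictly = TRUE))
    expect_identical(out$annotations$label, g$record$annotations$label)
  }
})

test_that("record selection drops exclusions, requires PVC, truncates deterministically", {
  mk <- function(id, pvc) {
    ann <- data.frame(sample = c(10, 50),
                      symbol = c("N", if (pvc) "V" else "N"))
    ecg_record(id, fs = 360, samples = rnorm(100), annotations = ann)
  }
  recs <- list(mk("101", TRUE), mk("102", TRUE), mk("106", TRUE))
  kept <- select_records(recs, exclude_ids = c("102", "104", "107", "217"))
  expect_equal(vapply(kept, `[[`, "", "record_id"), c("101", "106"))
  # a record without PVC beats is excluded under the PVC-required policy
  recs2 <- list(mk("100", FALSE), mk("119", TRUE))
  kept2 <- select_records(recs2, require_pvc = TRUE)
  expect_equal(vapply(kept2, `[[`, "", "record_id"), "119")
  # 61 records truncated to the first 22 in sorted id order
  many <- lapply(sprintf("I%02d", sample(61)), mk, pvc = TRUE)
  k22 <- select_records(many, keep_first = 22)
  expect_length(k22, 22)
  expect_equal(vapply(k22, `[[`, "", "record_id"), sprintf("I%02d", 1:22))
  # output is a subset of input and selection is idempotent
  again <- select_records(k22, keep_first = 22)
  expect_identical(vapply(again, `[[`, "", "record_id"),
                   vapply(k22, `[[`, "", "record_id"))
  expect_true(all(vapply(k22, `[[`, "", "record_id") %in%
                    vapply(many, `[[`, "", "record_id")))
  # empty result is legal
  expect_length(select_records(recs2, exclude_ids = c("100", "119")), 0)
})
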