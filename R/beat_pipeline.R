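# Beat segmentation by the midpoint rule, labelling against annotations,
# and deterministic rendering of each beat as an RGB raster.

#' Segment beats at RR midpoints
#'
#' A beat is the span between the midpoint to its previous R peak and the
#' midpoint to its next one: for each interior peak `R_k` the window is
#' `[floor((R_{k-1}+R_k)/2), floor((R_k+R_{k+1})/2))` (half-open, 0-based).
#' The first and last peaks have no two-sided midpoint and are dropped,
#' so the windows tile the covered span without overlap.
#'
#' @param rec an [ecg_record()].
#' @param r_peaks strictly increasing 0-based R-peak sample indices;
#'   defaults to the record's annotation positions.
#' @return list of `ecg_beat` objects (empty, with a warning, for fewer
#'   than 3 peaks).
#' @export
segment_beats <- function(rec, r_peaks = rec$annotations$sample) {
  stopifnot(inherits(rec, "ecg_record"))
  r_peaks <- as.integer(r_peaks)
  n <- length(rec$samples)
  if (length(r_peaks) > 0) {
    stopifnot(all(r_peaks >= 0), all(r_peaks < n))
    if (is.unsorted(r_peaks, strictly = TRUE)) {
      stop("r_peaks must be strictly increasing")
    }
    if (any(diff(r_peaks) < 2L)) {
      stop("r_peaks must be at least 2 samples apart ",
           "(midpoint windows need length >= 2)")
    }
  }
  if (length(r_peaks) < 3) {
    warning("fewer than 3 R peaks: no interior beat to segment")
    return(list())
  }
  k <- 2:(length(r_peaks) - 1)
  start <- (r_peaks[k - 1] + r_peaks[k]) %/% 2L
  end <- (r_peaks[k] + r_peaks[k + 1]) %/% 2L
  lapply(seq_along(k), function(j) {
    structure(list(record_id = rec$record_id, subject_id = rec$subject_id,
                   r_index = r_peaks[k[j]],
                   start = start[j], end = end[j],
                   samples = rec$samples[(start[j] + 1L):end[j]],
                   fs = rec$fs, label = NA_character_),
              class = "ecg_beat")
  })
}

#' Label beats from annotations and drop unmatched or OTHER beats
#'
#' Each beat takes the label of the nearest annotation within
#' `tolerance_s` of its R index. Beats with no annotation in tolerance,
#' or whose nearest annotation is an `OTHER` beat, are discarded; the
#' discard counts are attached as attribute `dropped`.
#'
#' @param beats list of beats from [segment_beats()].
#' @param annotations data.frame with `sample` and `label` columns.
#' @param fs sampling rate the indices refer to (Hz).
#' @param tolerance_s matching tolerance, seconds.
#' @return list of labelled beats (label `NORMAL` or `PVC`).
#' @export
label_beats <- function(beats, annotations, fs, tolerance_s = 0.15) {
  stopifnot(tolerance_s > 0)
  tol <- tolerance_s * fs
  dropped_unmatched <- 0L
  dropped_other <- 0L
  out <- list()
  for (b in beats) {
    if (nrow(annotations) == 0) { dropped_unmatched <- dropped_unmatched + 1L; next }
    d <- abs(annotations$sample - b$r_index)
    i <- which.min(d)
    if (d[i] > tol) {
      dropped_unmatched <- dropped_unmatched + 1L
    } else if (annotations$label[i] == "OTHER") {
      dropped_other <- dropped_other + 1L
    } else {
      b$label <- annotations$label[i]
      out[[length(out) + 1L]] <- b
    }
  }
  structure(out, dropped = c(unmatched = dropped_unmatched,
                             other = dropped_other))
}

#' Beat image rendering configuration
#'
#' The waveform is drawn as a connected polyline on a plain background
#' with no axes, ticks or margins; the vertical axis is min-max
#' normalized per beat (a constant beat renders as a mid-height line),
#' the horizontal axis spans the beat window, and the raster has exactly
#' the configured size. Rendering is a pure function of the samples and
#' this configuration.
#'
#' @param height,width raster size in pixels.
#' @param line_rgb,bg_rgb 0-255 RGB colours of the trace and background.
#' @param line_width trace thickness in pixels.
#' @return object of class `render_config`.
#' @export
render_config <- function(height = 224, width = 224,
                          line_rgb = c(40, 40, 140),
                          bg_rgb = c(255, 255, 255),
                          line_width = 2) {
  stopifnot(height >= 8, width >= 8, line_width >= 1,
            length(line_rgb) == 3, length(bg_rgb) == 3)
  structure(list(height = as.integer(height), width = as.integer(width),
                 line_rgb = as.integer(line_rgb),
                 bg_rgb = as.integer(bg_rgb),
                 line_width = as.integer(line_width)),
            class = "render_config")
}

#' Render a beat as a deterministic RGB image
#'
#' @param beat an `ecg_beat` (or bare numeric sample vector).
#' @param cfg a [render_config()].
#' @return `beat_image`: integer array `height x width x 3` in 0-255.
#' @export
render_beat_image <- function(beat, cfg = render_config()) {
  samples <- if (inherits(beat, "ecg_beat")) beat$samples else as.numeric(beat)
  stopifnot(length(samples) >= 1)
  H <- cfg$height; W <- cfg$width
  rng <- range(samples)
  v <- if (rng[2] - rng[1] < 1e-12) rep(0.5, length(samples)) else
    (samples - rng[1]) / (rng[2] - rng[1])
  ns <- length(samples)
  xs <- if (ns == 1) (W - 1) / 2 else (seq_len(ns) - 1) / (ns - 1) * (W - 1)
  ys <- (1 - v) * (H - 1)
  # rasterize the polyline: dense interpolation along each segment
  px <- integer(0); py <- integer(0)
  if (ns == 1) {
    px <- round(xs); py <- round(ys)
  } else {
    for (i in seq_len(ns - 1)) {
      steps <- max(abs(round(xs[i + 1]) - round(xs[i])),
                   abs(round(ys[i + 1]) - round(ys[i]))) + 1L
      tt <- seq(0, 1, length.out = steps + 1L)
      px <- c(px, round(xs[i] + tt * (xs[i + 1] - xs[i])))
      py <- c(py, round(ys[i] + tt * (ys[i + 1] - ys[i])))
    }
  }
  # thicken: line_width x line_width square footprint per point
  lw <- cfg$line_width
  off <- seq_len(lw) - 1L - (lw - 1L) %/% 2L
  grid <- expand.grid(dx = off, dy = off)
  rows <- rep(py, each = nrow(grid)) + grid$dy
  cols <- rep(px, each = nrow(grid)) + grid$dx
  keep <- rows >= 0 & rows < H & cols >= 0 & cols < W
  rows <- rows[keep]; cols <- cols[keep]
  img <- array(rep(cfg$bg_rgb, each = H * W), dim = c(H, W, 3))
  lin <- unique(rows + H * cols)  # 0-based (row, col) linear indices
  for (ch in 1:3) img[lin + 1L + (ch - 1L) * H * W] <- cfg$line_rgb[ch]
  structure(array(as.integer(img), dim = c(H, W, 3)),
            class = "beat_image",
            source = if (inherits(beat, "ecg_beat")) {
              list(record_id = beat$record_id, r_index = beat$r_index,
                   label = beat$label)
            } else NULL)
}

#' Write a beat image as PNG
#' @param img a `beat_image`.
#' @param path output PNG path.
#' @export
write_beat_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Build a labelled beat-image dataset from annotated records
#'
#' Runs the full pre-processing pipeline per record: anchor R peaks
#' either on the reference annotations (`anchor = "annotation"`, the mode
#' used with annotated archives) or on the Pan-Tompkins detector output
#' (`anchor = "detector"`), segment beats by the midpoint rule, label
#' them against the annotations, and render each beat as an RGB image.
#'
#' @param records list of [ecg_record()] objects.
#' @param cfg a [render_config()].
#' @param anchor `"annotation"` or `"detector"`.
#' @param tolerance_s labelling tolerance, seconds.
#' @return `beat_dataset`: list with `images` (list of `beat_image`),
#'   `labels` (factor NORMAL/PVC), `subject_id`, `record_id`, `r_index`.
#' @export
build_beat_dataset <- function(records, cfg = render_config(),
                               anchor = c("annotation", "detector"),
                               tolerance_s = 0.15) {
  anchor <- match.arg(anchor)
  images <- list(); labels <- character(0)
  subject <- character(0); record <- character(0); r_index <- integer(0)
  for (rec in records) {
    peaks <- if (anchor == "annotation") rec$annotations$sample else
      detect_r_peaks(rec)
    beats <- if (length(peaks) >= 3) segment_beats(rec, peaks) else list()
    beats <- label_beats(beats, rec$annotations, rec$fs, tolerance_s)
    for (b in beats) {
      images[[length(images) + 1L]] <- render_beat_image(b, cfg)
      labels <- c(labels, b$label)
      subject <- c(subject, b$subject_id)
      record <- c(record, b$record_id)
      r_index <- c(r_index, b$r_index)
    }
  }
  structure(list(images = images,
                 labels = factor(labels, levels = c("NORMAL", "PVC")),
                 subject_id = subject, record_id = record,
                 r_index = r_index),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats, %d subjects; N=%d, PVC=%d\n",
              length(x$images), length(unique(x$subject_id)),
              sum(x$labels == "NORMAL"), sum(x$labels == "PVC")))
  invisible(x)
}

#' Subset a beat dataset
#' @param ds a `beat_dataset`.
#' @param idx integer or logical index vector.
#' @export
subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[idx],
                 labels = ds$labels[idx],
                 subject_id = ds$subject_id[idx],
                 record_id = ds$record_id[idx],
                 r_index = ds$r_index[idx]),
            class = "beat_dataset")
}

#' Export a beat dataset index as CSV
#' @param ds a `beat_dataset`.
#' @param path CSV path.
#' @export
write_dataset_index <- function(ds, path) {
  write.csv(data.frame(record_id = ds$record_id, subject_id = ds$subject_id,
                       ordinal = seq_along(ds$images) - 1L,
                       label = as.character(ds$labels),
                       r_index = ds$r_index),
            path, row.names = FALSE)
  invisible(path)
}
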