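#' Beat label vocabulary
#'
#' Every annotation symbol maps to exactly one of three beat labels:
#' `"NORMAL"`, `"PVC"` or `"OTHER"`. `OTHER` beats are retained in the
#' record (raw data stay lossless) and filtered out at segmentation time.
#'
#' @format Character vector of the three labels.
#' @export
BEAT_LABELS <- c("NORMAL", "PVC", "OTHER")

#' Map annotation symbols to beat labels
#'
#' Default convention: `'N'` is a normal sinus beat, `'V'` a premature
#' ventricular contraction, and every other symbol (atrial premature
#' beats, fusion beats, paced beats, artifacts, ...) is `OTHER`. Bundle
#' branch block and escape beats (`'L','R','e','j'`) can be folded into
#' the normal class via `normal_symbols` when a broader normal definition
#' is wanted; the mapping is total either way.
#'
#' @param symbol character vector of single-character annotation symbols.
#' @param normal_symbols symbols mapped to `NORMAL`.
#' @param pvc_symbols symbols mapped to `PVC`.
#' @return character vector of labels, same length as `symbol`.
#' @examples
#' map_annotation_symbol(c("N", "V", "A"))
#' @export
map_annotation_symbol <- function(symbol,
                                  normal_symbols = "N",
                                  pvc_symbols = "V") {
  stopifnot(is.character(symbol))
  out <- rep("OTHER", length(symbol))
  out[symbol %in% normal_symbols] <- "NORMAL"
  out[symbol %in% pvc_symbols] <- "PVC"
  out
}

#' Construct an annotated single-lead ECG record
#'
#' The central container of the IO layer: a sampled voltage series in mV
#' plus beat annotations given as 0-based sample indices with a symbol
#' and its mapped label. Invariants (positive sampling rate, non-empty
#' signal, strictly increasing in-range annotation indices) are enforced
#' at construction.
#'
#' @param record_id,subject_id,lead_name identity strings; `subject_id`
#'   defaults to `record_id` (one record per subject).
#' @param fs sampling rate in Hz.
#' @param samples numeric vector of voltages (mV).
#' @param annotations data.frame with columns `sample` (0-based integer
#'   index), `symbol` (character); a `label` column is derived with
#'   [map_annotation_symbol()] if absent.
#' @param ... passed to [map_annotation_symbol()].
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, samples,
                       annotations = NULL,
                       subject_id = record_id,
                       lead_name = "MLII", ...) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("sampling rate must be a single positive number")
  }
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0), symbol = character(0),
                              label = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(annotations),
            all(c("sample", "symbol") %in% names(annotations)))
  annotations$sample <- as.integer(annotations$sample)
  if (is.null(annotations$label)) {
    annotations$label <- map_annotation_symbol(annotations$symbol, ...)
  }
  n <- length(samples)
  bad <- annotations$sample < 0L | annotations$sample >= n
  if (any(bad)) {
    stop(sprintf("annotation index out of range [0, %d): %s", n,
                 paste(annotations$sample[bad], collapse = ", ")))
  }
  if (is.unsorted(annotations$sample, strictly = TRUE)) {
    stop("annotation sample indices must be strictly increasing")
  }
  structure(list(record_id = as.character(record_id),
                 subject_id = as.character(subject_id),
                 lead_name = as.character(lead_name),
                 fs = fs,
                 samples = as.numeric(samples),
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> subject %s, lead %s, %.6g Hz, %d samples (%.1f s), %d annotations\n",
              x$record_id, x$subject_id, x$lead_name, x$fs,
              length(x$samples), length(x$samples) / x$fs,
              nrow(x$annotations)))
  if (nrow(x$annotations) > 0) {
    tab <- table(x$annotations$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resample a record to a new rate
#'
#' Band-limited polyphase resampling of the signal (via
#' [signal::resample()] at the reduced rational rate p/q) with annotation
#' indices rescaled by the same ratio and rounded half-to-even. If the
#' rounding ever collapses two annotations onto one sample the later one
#' is nudged forward so strict ordering is preserved.
#'
#' @param rec an [ecg_record()].
#' @param target_hz target sampling rate (> 0).
#' @return a new `ecg_record` at `target_hz`.
#' @export
resample_record <- function(rec, target_hz) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(target_hz) || length(target_hz) != 1L ||
      !is.finite(target_hz) || target_hz <= 0) {
    stop("target_hz must be a single positive number")
  }
  if (isTRUE(all.equal(target_hz, rec$fs))) return(rec)
  pq <- rational_ratio(target_hz, rec$fs)
  y <- resample_pq(rec$samples, pq[["p"]], pq[["q"]])
  n_out <- length(y)
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    idx <- round(ann$sample * pq[["p"]] / pq[["q"]])  # half-to-even
    idx <- pmin(pmax(idx, 0), n_out - 1L)
    if (nrow(ann) > 1) {
      for (i in 2:length(idx)) if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + 1L
    }
    ann$sample <- as.integer(idx)
  }
  ecg_record(record_id = rec$record_id, subject_id = rec$subject_id,
             lead_name = rec$lead_name, fs = target_hz,
             samples = y, annotations = ann)
}

# Rational p/q resampling by windowed-sinc interpolation with a
# linear-phase anti-alias FIR (fir1) when decimating. Unlike a causal
# polyphase pass, the FIR group delay ((2d+1)/2 input samples) is
# compensated so output sample k sits exactly at input time k*q/p --
# annotation indices rescale by the bare ratio.
resample_pq <- function(x, p, q, d = 5) {
  r <- p / q
  n_in <- length(x)
  shift <- 0
  if (r < 1) {
    ntaps <- 2 * d + 1
    b <- signal::fir1(ntaps, r)
    x <- signal::fftfilt(b, c(x, numeric(ntaps + 1)))
    shift <- ntaps / 2
  }
  n_out <- ceiling(n_in * r)
  t <- (seq_len(n_out) - 1) / r + 1 + shift
  idx <- floor(t)
  frac <- t - idx
  xp <- c(numeric(d), x, numeric(d + 2))
  y <- numeric(n_out)
  for (i in (-d):d) {
    u <- frac - i
    w <- ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u)) *
      (0.5 + 0.5 * cos(pi * u / (d + 0.5)))
    y <- y + xp[idx + i + d] * w
  }
  y
}

#' Select records by exclusion list, PVC presence, and count
#'
#' Record-selection policy: drop records whose id is on an exclusion list
#' (e.g. paced-beat records), optionally keep only records containing at
#' least one PVC annotation, and optionally truncate to the first
#' `keep_first` records in ascending record-id order (the convention used
#' when a fixed-size subset of a larger archive is wanted). The result is
#' always a subset of the input and the operation is idempotent.
#'
#' @param records list of [ecg_record()] objects.
#' @param exclude_ids character vector of record ids to drop.
#' @param require_pvc keep only records with >= 1 PVC annotation.
#' @param keep_first optional integer; keep the first k by sorted id.
#' @return list of records, sorted by record id.
#' @export
select_records <- function(records, exclude_ids = character(0),
                           require_pvc = FALSE, keep_first = NULL) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$record_id, character(1))
  records <- records[order(ids)]
  ids <- sort(ids)
  keep <- !(ids %in% as.character(exclude_ids))
  if (require_pvc) {
    has_pvc <- vapply(records, function(r) any(r$annotations$label == "PVC"),
                      logical(1))
    keep <- keep & has_pvc
  }
  records <- records[keep]
  if (!is.null(keep_first)) records <- head(records, keep_first)
  records
}
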