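# Pan-Tompkins QRS detection. The classic integer-coefficient recursive
# filters are specified for a 200 Hz sampling rate, so records at other
# rates are resampled to 200 Hz before detection and detections are
# mapped back to native-rate indices by the exact rational ratio.

PT_FS <- 200
PT_REFRACTORY_S <- 0.200
PT_TWAVE_S <- 0.360
PT_MWI_S <- 0.150

#' Pan-Tompkins preprocessing cascade at 200 Hz
#'
#' Computes the four aligned intermediate sequences of the detector:
#' band-pass (~5-15 Hz; cascaded integer-coefficient recursive low-pass
#' and high-pass filters), five-point derivative, point-wise squaring,
#' and moving-window integration over a 150 ms window. The filters'
#' difference equations are:
#' low-pass  `y[n] = 2 y[n-1] - y[n-2] + x[n] - 2 x[n-6] + x[n-12]` (gain 36),
#' high-pass `y[n] = y[n-1] - x[n]/32 + x[n-16] - x[n-17] + x[n-32]/32`,
#' derivative `y[n] = (2 x[n] + x[n-1] - x[n-3] - 2 x[n-4]) / 8`.
#'
#' @param x voltage samples at 200 Hz.
#' @return list with `filtered`, `derivative`, `squared`, `integrated`
#'   and `delays` (per-stage group delays in samples, so peaks in the
#'   integrated signal can be mapped back to signal-domain indices).
#' @export
pt_preprocess <- function(x) {
  win <- round(PT_MWI_S * PT_FS)
  if (length(x) < max(32, win)) {
    stop("input too short for Pan-Tompkins preprocessing (need >= ",
         max(32, win), " samples at 200 Hz)")
  }
  lp <- iir_filter(b = c(1, rep(0, 5), -2, rep(0, 5), 1),
                   a = c(1, -2, 1), x) / 36
  hp <- iir_filter(b = c(-1 / 32, rep(0, 15), 1, -1, rep(0, 14), 1 / 32),
                   a = c(1, -1), lp)
  der <- iir_filter(b = c(2, 1, 0, -1, -2) / 8, a = 1, hp)
  sq <- der^2
  mwi <- pt_mwi(sq, win)
  list(filtered = hp, derivative = der, squared = sq, integrated = mwi,
       delays = c(lowpass = 5, highpass = 16, derivative = 2,
                  integration = (win - 1) / 2))
}

# Direct-form IIR filter; a[1] assumed 1.
iir_filter <- function(b, a, x) {
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

#' Moving-window integration
#'
#' Causal moving average over the last `win` samples (the final stage of
#' the Pan-Tompkins cascade); a unit impulse yields exactly `win` non-zero
#' output samples.
#'
#' @param x input sequence.
#' @param win window length in samples (default: 150 ms at 200 Hz).
#' @export
pt_mwi <- function(x, win = round(PT_MWI_S * PT_FS)) {
  c <- cumsum(x)
  (c - c(rep(0, win), head(c, -win))) / win
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Adaptive dual-threshold peak picking on the integrated signal with
#' running signal/noise peak estimates, a 200 ms refractory period,
#' T-wave rejection by slope comparison inside a 360 ms window, and
#' search-back at the lower threshold when no peak is found within
#' 1.66 x the recent RR average. Each detection is refined to the local
#' maximum of the raw 200 Hz signal within +/- 40 ms (after compensating
#' the filter group delays) and mapped back to the record's native rate.
#' The two thresholds maintain `threshold_2 = 0.5 * threshold_1`, and the
#' learning phase initializes the signal/noise levels from the running
#' maximum/mean of the first 2 s.
#'
#' @param rec an [ecg_record()] at any sampling rate.
#' @return integer vector of strictly increasing R-peak sample indices
#'   (0-based, native rate).
#' @export
detect_r_peaks <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  native_fs <- rec$fs
  rec200 <- if (isTRUE(all.equal(native_fs, PT_FS))) rec else
    resample_record(rec, PT_FS)
  x <- rec200$samples
  win <- round(PT_MWI_S * PT_FS)
  if (length(x) < max(32, win)) return(integer(0))
  pp <- pt_preprocess(x)
  mwi <- pp$integrated
  delay <- sum(pp$delays)
  n <- length(mwi)
  if (max(mwi) <= 0) return(integer(0))

  # candidate peaks: local maxima of the integrated signal
  up <- c(FALSE, diff(mwi) > 0)
  down <- c(diff(mwi) <= 0, FALSE)
  cand <- which(up & down)
  if (length(cand) == 0) return(integer(0))
  # one QRS produces a broad integration hump with micro-maxima; collapse
  # maxima closer than the refractory period to the largest of each group
  sep <- round(PT_REFRACTORY_S * PT_FS)
  if (length(cand) > 1) {
    keep <- integer(0)
    cur <- cand[1]
    for (i in cand[-1]) {
      if (i - cur <= sep) {
        if (mwi[i] >= mwi[cur]) cur <- i
      } else {
        keep <- c(keep, cur)
        cur <- i
      }
    }
    cand <- c(keep, cur)
  }

  learn <- seq_len(min(2 * PT_FS, n))
  spki <- 0.25 * max(mwi[learn])
  npki <- 0.5 * mean(mwi[learn])
  thr1 <- npki + 0.25 * (spki - npki)
  thr2 <- 0.5 * thr1
  refr <- round(PT_REFRACTORY_S * PT_FS)
  twin <- round(PT_TWAVE_S * PT_FS)
  slope_w <- round(0.075 * PT_FS)

  peak_slope <- function(i) {
    lo <- max(1, i - slope_w)
    max(abs(pp$derivative[lo:i]))
  }

  qrs <- integer(0)
  qrs_slope <- numeric(0)
  rr_recent <- rep(0.8 * PT_FS, 8)  # bootstrap at 75 bpm until RRs exist
  rr_count <- 0
  last_checked <- 0L

  accept <- function(i, searchback = FALSE) {
    if (searchback) spki <<- 0.25 * mwi[i] + 0.75 * spki
    else spki <<- 0.125 * mwi[i] + 0.875 * spki
    if (length(qrs) > 0) {
      rr <- i - qrs[length(qrs)]
      rr_recent <<- c(tail(rr_recent, 7), rr)
      rr_count <<- rr_count + 1
    }
    qrs <<- c(qrs, i)
    qrs_slope <<- c(qrs_slope, peak_slope(i))
    thr1 <<- npki + 0.25 * (spki - npki)
    thr2 <<- 0.5 * thr1
  }
  reject <- function(i) {
    npki <<- 0.125 * mwi[i] + 0.875 * npki
    thr1 <<- npki + 0.25 * (spki - npki)
    thr2 <<- 0.5 * thr1
  }

  for (ci in seq_along(cand)) {
    i <- cand[ci]
    since <- if (length(qrs) > 0) i - qrs[length(qrs)] else Inf
    if (since < refr) { next }
    if (mwi[i] > thr1) {
      # T-wave discrimination: a peak soon after a QRS with less than
      # half its slope is the T wave of that beat, not a new QRS
      if (since < twin && length(qrs) > 0 &&
          peak_slope(i) < 0.5 * qrs_slope[length(qrs_slope)]) {
        reject(i)
      } else {
        accept(i)
      }
    } else {
      reject(i)
      # search-back: no QRS within 1.66 x the recent RR average
      rr_avg <- mean(rr_recent)
      if (length(qrs) > 0 && since > 1.66 * rr_avg) {
        lo <- qrs[length(qrs)] + refr
        back <- cand[cand > lo & cand <= i & cand > last_checked]
        back <- back[mwi[back] > thr2 & mwi[back] <= thr1]
        if (length(back) > 0) {
          accept(back[which.max(mwi[back])], searchback = TRUE)
          last_checked <- i
        }
      }
    }
  }
  if (length(qrs) == 0) return(integer(0))
  qrs <- sort(qrs)

  # map integrated-domain peaks back to the signal domain and refine to
  # the extremum of the raw 200 Hz signal. The search window is
  # asymmetric (-120 ms, +40 ms) around the delay-compensated position:
  # wide ectopic complexes spread their integration energy late, so the
  # R wave sits towards the early edge of the hump.
  ref_back <- round(0.120 * PT_FS)
  ref_fwd <- round(0.040 * PT_FS)
  sig_idx <- vapply(qrs, function(i) {
    c0 <- round(i - delay)
    lo <- max(1, c0 - ref_back); hi <- min(length(x), c0 + ref_fwd)
    if (lo > hi) return(NA_integer_)
    as.integer(lo + which.max(abs(x[lo:hi])) - 1L)
  }, integer(1))
  sig_idx <- sig_idx[!is.na(sig_idx)]
  sig_idx <- sig_idx[!duplicated(sig_idx)]
  sig_idx <- sig_idx[c(TRUE, diff(sig_idx) >= refr)]

  # native-rate 0-based indices via the exact rational ratio
  pq <- rational_ratio(native_fs, PT_FS)
  out <- as.integer(round((sig_idx - 1L) * pq[["p"]] / pq[["q"]]))
  out <- out[out >= 0 & out < length(rec$samples)]
  out[!duplicated(out)]
}

#' Match detections against reference R positions
#'
#' Greedy one-to-one matching within a time tolerance; reports
#' sensitivity (matched references / references) and positive
#' predictivity (matched detections / detections).
#'
#' @param detected,reference 0-based sample indices at `fs`.
#' @param fs sampling rate of the indices (Hz).
#' @param tol_s matching tolerance in seconds.
#' @return list with `sensitivity`, `ppv`, `n_matched`, `n_detected`,
#'   `n_reference`.
#' @export
match_detections <- function(detected, reference, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- logical(length(detected))
  matched <- 0L
  for (r in reference) {
    d <- abs(detected - r)
    d[used] <- Inf
    if (length(d) > 0 && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      matched <- matched + 1L
    }
  }
  list(sensitivity = if (length(reference)) matched / length(reference) else NA_real_,
       ppv = if (length(detected)) matched / length(detected) else NA_real_,
       n_matched = matched, n_detected = length(detected),
       n_reference = length(reference))
}
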