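# Independent oracles used across test files. These deliberately avoid
# the package's own kernels: convolution by quadruple loop, metrics from
# the definitions, filter gain from the difference-equation coefficients.

# Naive direct 2-D convolution (cross-correlation, zero padding).
naive_conv2d <- function(x, w, stride = 1, pad = 0) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; O <- dim(w)[4]
  oH <- (H + 2 * pad - kh) %/% stride + 1
  oW <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  y <- array(0, dim = c(oH, oW, O, N))
  for (n in seq_len(N)) for (o in seq_len(O)) {
    for (a in seq_len(oH)) for (b in seq_len(oW)) {
      h0 <- (a - 1) * stride; w0 <- (b - 1) * stride
      y[a, b, o, n] <- sum(xp[h0 + seq_len(kh), w0 + seq_len(kw), , n] *
                             w[, , , o])
    }
  }
  y
}

# Steady-state amplitude gain of a rational filter at frequency f (Hz),
# computed directly from the difference-equation coefficients.
filter_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  Mod(sum(b * z) / sum(a * za))
}

# Metrics recomputed from first principles for a 2x2 matrix given as
# counts (true NORMAL/PVC x predicted NORMAL/PVC).
oracle_metrics <- function(nn, nv, vn, vv) {
  tp <- vv; fp <- nv; fn <- vn; tn <- nn
  div <- function(p, q) if (q == 0) NA_real_ else p / q
  prec_p <- div(tp, tp + fp); rec_p <- div(tp, tp + fn)
  spec_p <- div(tn, tn + fp)
  prec_n <- div(tn, tn + vn); rec_n <- div(tn, tn + nv)
  spec_n <- div(tp, tp + vn)
  f1 <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision_pvc = prec_p, recall_pvc = rec_p, specificity_pvc = spec_p,
       precision_normal = prec_n, recall_normal = rec_n,
       f1_pvc = f1(prec_p, rec_p), f1_normal = f1(prec_n, rec_n),
       macro_f1 = mean(c(f1(prec_p, rec_p), f1(prec_n, rec_n))),
       balanced_accuracy = (rec_p + spec_p) / 2)
}

# A small labelled beat-image dataset shared by the training and
# experiment tests; built once per test run.
local({
  cache <- new.env(parent = emptyenv())
  small_beat_dataset <<- function(n_subjects = 4, n_beats = 40, seed = 1,
                                  px = 48) {
    key <- paste(n_subjects, n_beats, seed, px, sep = "_")
    if (is.null(cache[[key]])) {
      gen <- generate_dataset(n_subjects = n_subjects, n_beats = n_beats,
                              pvc_fraction = 0.2, noise_sd = 0.02, seed = seed)
      cache[[key]] <- build_beat_dataset(lapply(gen, `[[`, "record"),
                                         render_config(px, px))
    }
    cache[[key]]
  }
})
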