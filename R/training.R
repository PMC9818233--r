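# Imbalance-aware fine-tuning: per-batch class weights, weighted binary
# cross-entropy, weighted random sampling, on-the-fly augmentation, Adam
# with plateau learning-rate decay and early stopping.

#' Training configuration
#'
#' Defaults are the pipeline's tuned protocol: initial learning rate
#' 0.001, batch size 32, Adam, learning rate multiplied by 0.1 after 5
#' successive epochs without validation-loss improvement, training halted
#' after 8 such epochs (or at `max_epochs`), 10% of the training items
#' held out as a random validation split.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param plateau_patience epochs without improvement before decay.
#' @param early_stop_patience epochs without improvement before halting.
#' @param validation_fraction fraction of training items held out.
#' @param improvement_tol minimum decrease counting as an improvement
#'   ("remains the same" is implemented as "no decrease beyond this").
#' @param seed seed for split, sampling, init of batches, augmentation.
#' @param augment logical; apply on-the-fly affine jitter.
#' @param sampler `"weighted"` (inverse class frequency, with
#'   replacement) or `"uniform"`.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         max_epochs = 200, plateau_factor = 0.1,
                         plateau_patience = 5, early_stop_patience = 8,
                         validation_fraction = 0.10, improvement_tol = 1e-6,
                         seed = 1, augment = TRUE,
                         sampler = c("weighted", "uniform")) {
  sampler <- match.arg(sampler)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            plateau_patience >= 1, early_stop_patience >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 improvement_tol = improvement_tol,
                 seed = seed, augment = isTRUE(augment), sampler = sampler),
            class = "train_config")
}

#' Per-class weight coefficients from a training batch
#'
#' The weight of class c is `1 - |X_c| / |X|`: the complement of the
#' class's share of the batch, so the minority class carries the larger
#' weight and equally frequent classes both get 0.5. A class filling the
#' whole batch receives weight 0 (the degenerate limit; the training loop
#' falls back to unweighted loss for such batches).
#'
#' @param batch_labels factor or character labels of the batch.
#' @return named numeric vector of class weights.
#' @export
class_weights <- function(batch_labels) {
  stopifnot(length(batch_labels) > 0)
  lab <- factor(as.character(batch_labels), levels = c("NORMAL", "PVC"))
  n <- length(lab)
  counts <- table(lab)
  w <- 1 - as.numeric(counts) / n
  stats::setNames(w, names(counts))
}

#' Weighted binary cross-entropy loss
#'
#' `l = -(1/n) sum_x eta_{i(x)} [ y ln p + (1 - y) ln(1 - p) ]` with
#' predicted PVC probabilities clamped to `[1e-7, 1 - 1e-7]`. The loss is
#' non-negative and zero exactly at (clamped) perfect prediction; with
#' equal per-class weights 0.5 it is half the unweighted binary
#' cross-entropy.
#'
#' @param y_out predicted PVC probabilities.
#' @param y_true 0/1 labels (1 = PVC) or a factor with levels
#'   NORMAL/PVC.
#' @param eta per-class weights as returned by [class_weights()], or a
#'   numeric vector of per-sample weights.
#' @return scalar loss (batch-mean reduction).
#' @export
weighted_bce <- function(y_out, y_true, eta = c(NORMAL = 0.5, PVC = 0.5)) {
  if (is.factor(y_true) || is.character(y_true)) {
    y_true <- as.integer(as.character(y_true) == "PVC")
  }
  if (length(y_out) != length(y_true)) {
    stop("y_out and y_true must have the same length")
  }
  w <- if (!is.null(names(eta))) {
    unname(eta[ifelse(y_true == 1, "PVC", "NORMAL")])
  } else {
    if (length(eta) == 1) rep(eta, length(y_out)) else eta
  }
  p <- clamp(y_out, 1e-7, 1 - 1e-7)
  -mean(w * (y_true * log(p) + (1 - y_true) * log(1 - p)))
}

#' Weighted random sampler
#'
#' Each item's sampling weight is inversely proportional to its class
#' frequency and draws are with replacement, so the expected per-class
#' frequency of a drawn epoch is 1/2 each, regardless of the dataset
#' imbalance. The sampler owns a private RNG stream: a fixed seed gives
#' an identical draw sequence.
#'
#' @param labels dataset labels (factor or character, NORMAL/PVC).
#' @param seed sampler RNG seed.
#' @return list with `weights` (per item) and `draw(n)` returning `n`
#'   item indices.
#' @export
make_weighted_sampler <- function(labels, seed = 1) {
  lab <- as.character(labels)
  counts <- table(lab)
  for (cls in c("NORMAL", "PVC")) {
    if (!cls %in% names(counts) || counts[[cls]] == 0) {
      stop("cannot balance sampling: class ", cls, " is absent")
    }
  }
  w <- 1 / as.numeric(counts[lab])
  w <- w / sum(w)
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  draw <- function(n) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) {
      set.seed(as.integer(seed), kind = "Mersenne-Twister")
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    idx <- sample.int(length(lab), n, replace = TRUE, prob = w)
    env$state <- get(".Random.seed", envir = globalenv())
    idx
  }
  list(weights = w, draw = draw)
}

#' On-the-fly affine augmentation of a beat image
#'
#' Random small affine jitter: translation up to 5% of width/height,
#' scaling 0.95-1.05, rotation up to 5 degrees, resampled by nearest
#' neighbour with background fill. No horizontal flip is ever applied
#' (time reversal would change beat semantics). Draws come from the
#' caller's RNG stream, so a fixed RNG state reproduces the output; with
#' `enabled = FALSE` the image passes through untouched.
#'
#' @param img `(H, W, 3)` numeric array (any intensity scale).
#' @param max_translate,scale_range,max_rotate_deg jitter bounds.
#' @param enabled apply the jitter at all?
#' @param bg background fill intensity (same scale as `img`).
#' @return augmented image array, same shape and scale.
#' @export
augment_image <- function(img, max_translate = 0.05,
                          scale_range = c(0.95, 1.05),
                          max_rotate_deg = 5, enabled = TRUE, bg = NULL) {
  if (!enabled) return(img)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  tx <- runif(1, -max_translate, max_translate) * W
  ty <- runif(1, -max_translate, max_translate) * H
  sc <- runif(1, scale_range[1], scale_range[2])
  th <- runif(1, -max_rotate_deg, max_rotate_deg) * pi / 180
  if (is.null(bg)) bg <- max(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  # inverse map: output pixel -> source pixel
  out_r <- matrix(rep(seq_len(H), W), nrow = H)
  out_c <- matrix(rep(seq_len(W), each = H), nrow = H)
  yr <- out_r - cy - ty
  xr <- out_c - cx - tx
  src_r <- round(cy + ( cos(th) * yr - sin(th) * xr) / sc)
  src_c <- round(cx + ( sin(th) * yr + cos(th) * xr) / sc)
  ok <- src_r >= 1 & src_r <= H & src_c >= 1 & src_c <= W
  out <- array(bg, dim = d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    o <- matrix(bg, H, W)
    o[ok] <- plane[cbind(src_r[ok], src_c[ok])]
    out[, , ch] <- o
  }
  out
}

#' Epoch at which early stopping halts, given a validation-loss trace
#'
#' Pure helper implementing the stopping rule: training halts at the
#' first epoch ending a run of `patience` successive epochs with no
#' improvement (decrease greater than `tol`) over the best loss so far;
#' if the trace never triggers it, the answer is its length.
#'
#' @param val_losses per-epoch validation losses.
#' @param patience successive non-improving epochs required to halt.
#' @param tol minimum decrease that counts as improvement.
#' @return list with `stop_epoch` and `stop_reason`.
#' @export
early_stop_epoch <- function(val_losses, patience = 8, tol = 1e-6) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - tol) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = e, stop_reason = "early_stop"))
      }
    }
  }
  list(stop_epoch = length(val_losses), stop_reason = "max_epochs")
}

#' Fine-tune a model on a beat dataset
#'
#' Holds out a random `validation_fraction` of the items, then per epoch:
#' draws item indices from the weighted sampler, applies on-the-fly
#' augmentation, and minimizes the weighted binary cross-entropy with
#' Adam. After each epoch the learning rate is multiplied by
#' `plateau_factor` if the validation loss has not improved for
#' `plateau_patience` successive epochs, and training halts after
#' `early_stop_patience` such epochs or at `max_epochs`. The weights with
#' the best validation loss are restored at the end. Subjects named in
#' `eval_subjects` must not appear in the training data (asserted).
#'
#' @param model a `resnet_model` from [build_model()].
#' @param dataset a `beat_dataset`.
#' @param cfg a [train_config()].
#' @param eval_subjects subject ids reserved for evaluation.
#' @param verbose print per-epoch progress lines.
#' @return list with `model` (best weights), `history` (data.frame epoch,
#'   train_loss, val_loss, lr), `stop_epoch`, `stop_reason`.
#' @export
fit <- function(model, dataset, cfg = train_config(),
                eval_subjects = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "resnet_model"), inherits(dataset, "beat_dataset"),
            inherits(cfg, "train_config"))
  overlap <- intersect(unique(dataset$subject_id), eval_subjects)
  if (length(overlap) > 0) {
    stop("training data contain evaluation subjects: ",
         paste(overlap, collapse = ", "))
  }
  n <- length(dataset$images)
  if (n == 0) stop("empty training set")
  with_seed(cfg$seed + 104729, {
    n_val <- max(1L, round(cfg$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
  })
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) stop("no training items left after split")
  tr_labels <- dataset$labels[train_idx]
  sampler <- if (cfg$sampler == "weighted" &&
                 all(c("NORMAL", "PVC") %in% tr_labels)) {
    make_weighted_sampler(tr_labels, seed = cfg$seed + 7)
  } else {
    list(draw = local({
      k <- length(train_idx)
      s <- cfg$seed + 7
      env <- new.env(); env$i <- 0L
      function(nn) {
        env$i <- env$i + 1L
        with_seed(s + env$i, sample.int(k, nn, replace = TRUE))
      }
    }))
  }
  val_x <- stack_images(dataset$images[val_idx])
  val_y <- as.integer(dataset$labels[val_idx] == "PVC")
  adam <- adam_init(model$params)
  lr <- cfg$learning_rate
  best_val <- Inf
  best_params <- model$params
  best_state <- model$bn_state
  wait_plateau <- 0L
  wait_stop <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  stop_reason <- "max_epochs"
  stop_epoch <- cfg$max_epochs
  single_class_warned <- FALSE
  n_batches <- max(1L, ceiling(length(train_idx) / cfg$batch_size))

  for (epoch in seq_len(cfg$max_epochs)) {
    order_local <- sampler$draw(n_batches * cfg$batch_size)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      sel <- order_local[((b - 1) * cfg$batch_size + 1):(b * cfg$batch_size)]
      idx <- train_idx[sel]
      imgs <- dataset$images[idx]
      if (cfg$augment) {
        with_seed(cfg$seed + epoch * 1009 + b, {
          imgs <- lapply(imgs, augment_image)
        })
      }
      x <- stack_images(imgs)
      y <- as.integer(dataset$labels[idx] == "PVC")
      eta <- class_weights(dataset$labels[idx])
      if (any(eta == 0)) {
        if (!single_class_warned) {
          warning("single-class batch encountered; using unweighted loss ",
                  "for such batches")
          single_class_warned <- TRUE
        }
        eta <- c(NORMAL = 1, PVC = 1)
      }
      fw <- resnet_forward(model, x, train = TRUE, keep_cache = TRUE)
      model$bn_state <- fw$bn_state
      p_pvc <- fw$probs[2, ]
      loss <- weighted_bce(p_pvc, y, eta)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             " (lr = ", lr, ")")
      }
      epoch_loss <- epoch_loss + loss
      # d(loss)/d(logits): with the 2-class softmax, the PVC probability
      # is sigmoid(z_PVC - z_N), so the gradient splits antisymmetrically
      w <- unname(eta[ifelse(y == 1, "PVC", "NORMAL")])
      p_cl <- clamp(p_pvc, 1e-7, 1 - 1e-7)
      gz <- w * (p_cl - y) / length(y)
      dlogits <- rbind(-gz, gz)
      grads <- resnet_backward(model, fw$cache, dlogits)
      upd <- adam_step(adam, model$params, grads, lr)
      adam <- upd$state
      model$params <- upd$params
    }
    epoch_loss <- epoch_loss / n_batches
    # Recalibrate batch-norm running statistics before validating: with
    # few batches per epoch the exponential running stats lag behind the
    # fast-moving weights, which would corrupt the validation loss the
    # scheduler and early stopping react to. A short calibration pass
    # (plain averaging of batch statistics over unaugmented training
    # batches) gives unbiased inference-mode statistics.
    model$bn_state <- recalibrate_bn(model, dataset, train_idx,
                                     cfg$batch_size)
    vl <- validation_loss(model, val_x, val_y)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_loss = vl, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      epoch, epoch_loss, vl, lr))
    }
    if (vl < best_val - cfg$improvement_tol) {
      best_val <- vl
      best_params <- model$params
      best_state <- model$bn_state
      wait_plateau <- 0L
      wait_stop <- 0L
    } else {
      wait_plateau <- wait_plateau + 1L
      wait_stop <- wait_stop + 1L
      if (wait_plateau >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        wait_plateau <- 0L
      }
      if (wait_stop >= cfg$early_stop_patience) {
        stop_reason <- "early_stop"
        stop_epoch <- epoch
        break
      }
    }
    stop_epoch <- epoch
  }
  model$params <- best_params
  model$bn_state <- best_state
  list(model = model, history = history,
       stop_epoch = stop_epoch, stop_reason = stop_reason)
}

# Plain-average batch statistics over up to `k` fixed training batches:
# forward pass i contributes with weight 1/i (cumulative mean).
recalibrate_bn <- function(model, dataset, train_idx, batch_size, k = 4) {
  for (nm in names(model$bn_state)) model$bn_state[[nm]] <- 0 * model$bn_state[[nm]]
  len <- length(train_idx)
  n_cal <- min(k, max(1L, len %/% batch_size))
  bs <- min(batch_size, len)
  for (i in seq_len(n_cal)) {
    pos <- ((i - 1) * bs + seq_len(bs) - 1L) %% len + 1L
    x <- stack_images(dataset$images[train_idx[pos]])
    fw <- resnet_forward(model, x, train = TRUE, momentum = 1 / i)
    model$bn_state <- fw$bn_state
  }
  model$bn_state
}

validation_loss <- function(model, val_x, val_y, batch_size = 64) {
  n <- length(val_y)
  losses <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    fw <- resnet_forward(model, val_x[, , , i:j, drop = FALSE], train = FALSE)
    losses <- c(losses,
                weighted_bce(fw$probs[2, ], val_y[i:j], c(NORMAL = 1, PVC = 1)) *
                  (j - i + 1))
    i <- j + 1L
  }
  sum(losses) / n
}

# --- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(state = state, params = params)
}
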