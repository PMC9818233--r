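# Residual-network classifier. The architecture is the 18-layer basic-
# block layout: a 7x7/stride-2 stem convolution with 3x3/stride-2 max
# pooling, four stages of two basic blocks each, global average pooling,
# and a fully connected softmax head. Each basic block computes
# y = relu(F(x) + shortcut(x)) with F two 3x3 convolutions (batch norm
# after each, ReLU between). The shortcut is the identity when input and
# output dimensions agree (adding no parameters); when the dimensions
# change (the first block of stages 2-4, stride 2) it is by default a
# learned 1x1 projection W_s, with a parameter-free strided zero-padding
# variant also available. Channel count doubles exactly where spatial
# size halves.

#' Residual-network architecture specification
#'
#' @param stem_filters filters of the 7x7 stride-2 stem convolution.
#' @param stage_filters filter count per stage; each stage has
#'   `blocks_per_stage` basic blocks, the first block of every stage
#'   after the first downsampling with stride 2.
#' @param blocks_per_stage basic blocks per stage (2 for the 18-layer net).
#' @param num_classes output classes (2: NORMAL vs PVC).
#' @param input_channels image channels (3 for RGB).
#' @param input_size nominal square input size in pixels. The head uses
#'   global average pooling, so the model accepts other sizes too; this
#'   field documents the intended raster size.
#' @param shortcut `"projection"` (default, the learned 1x1 W_s) or
#'   `"zero_pad"` (parameter-free strided identity with zero channel
#'   padding) for dimension-increasing blocks.
#' @return object of class `resnet_spec`.
#' @export
resnet_spec <- function(stem_filters = 64,
                        stage_filters = c(64, 128, 256, 512),
                        blocks_per_stage = 2,
                        num_classes = 2,
                        input_channels = 3,
                        input_size = 224,
                        shortcut = c("projection", "zero_pad")) {
  shortcut <- match.arg(shortcut)
  stopifnot(stem_filters >= 1, length(stage_filters) >= 1,
            blocks_per_stage >= 1, num_classes >= 2)
  structure(list(stem_filters = as.integer(stem_filters),
                 stage_filters = as.integer(stage_filters),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 input_size = as.integer(input_size),
                 shortcut = shortcut),
            class = "resnet_spec")
}

#' @rdname resnet_spec
#' @export
resnet18_spec <- function(num_classes = 2) resnet_spec(num_classes = num_classes)

#' Desk-scale reduced spec for fast end-to-end runs
#' @rdname resnet_spec
#' @export
resnet_tiny_spec <- function(num_classes = 2) {
  resnet_spec(stem_filters = 16, stage_filters = c(16, 32),
              num_classes = num_classes, input_size = 64)
}

.block_names <- function(si, bi) sprintf("s%d.b%d", si, bi)

.init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Build a trainable residual-network model
#'
#' When `pretrained_backbone` is `TRUE`, all layers except the head load
#' backbone weights from `backbone_path` (a checkpoint saved by
#' [save_checkpoint()] whose parameter names match the spec's backbone)
#' and the fully connected head is randomly initialized; otherwise all
#' weights are random (He initialization for convolutions). Two builds
#' with the same seed are identical.
#'
#' @param spec a [resnet_spec()].
#' @param pretrained_backbone load externally supplied backbone weights?
#' @param backbone_path checkpoint file holding the backbone weights.
#' @param seed RNG seed for weight initialization.
#' @return object of class `resnet_model`.
#' @export
build_model <- function(spec, pretrained_backbone = FALSE,
                        backbone_path = NULL, seed = 1) {
  stopifnot(inherits(spec, "resnet_spec"))
  if (pretrained_backbone && is.null(backbone_path)) {
    stop("pretrained backbone weights are not available; supply ",
         "backbone_path or run offline with pretrained_backbone = FALSE")
  }
  model <- with_seed(seed, {
    params <- list()
    state <- list()
    add_bn <- function(name, ch) {
      params[[paste0(name, ".gamma")]] <<- rep(1, ch)
      params[[paste0(name, ".beta")]] <<- rep(0, ch)
      state[[paste0(name, ".mean")]] <<- rep(0, ch)
      state[[paste0(name, ".var")]] <<- rep(1, ch)
    }
    params[["stem.conv"]] <- .init_conv(7, 7, spec$input_channels,
                                        spec$stem_filters)
    add_bn("stem.bn", spec$stem_filters)
    cin <- spec$stem_filters
    for (si in seq_along(spec$stage_filters)) {
      cout <- spec$stage_filters[si]
      for (bi in seq_len(spec$blocks_per_stage)) {
        nm <- .block_names(si, bi)
        stride <- if (si > 1 && bi == 1) 2L else 1L
        bin <- if (bi == 1) cin else cout
        params[[paste0(nm, ".conv1")]] <- .init_conv(3, 3, bin, cout)
        add_bn(paste0(nm, ".bn1"), cout)
        params[[paste0(nm, ".conv2")]] <- .init_conv(3, 3, cout, cout)
        add_bn(paste0(nm, ".bn2"), cout)
        if ((bin != cout || stride != 1) && spec$shortcut == "projection") {
          params[[paste0(nm, ".proj")]] <- .init_conv(1, 1, bin, cout)
          add_bn(paste0(nm, ".projbn"), cout)
        }
      }
      cin <- cout
    }
    params[["fc.W"]] <- matrix(rnorm(cin * spec$num_classes, 0, 0.01),
                               nrow = cin, ncol = spec$num_classes)
    params[["fc.b"]] <- rep(0, spec$num_classes)
    structure(list(spec = spec, params = params, bn_state = state,
                   bn_passthrough = FALSE, seed = seed),
              class = "resnet_model")
  })
  if (pretrained_backbone) {
    ck <- load_checkpoint(backbone_path)
    backbone <- setdiff(names(model$params), c("fc.W", "fc.b"))
    missing <- setdiff(backbone, names(ck$params))
    if (length(missing) > 0) {
      stop("backbone checkpoint lacks parameters: ",
           paste(head(missing, 5), collapse = ", "))
    }
    for (nm in backbone) {
      if (!identical(dim(ck$params[[nm]]), dim(model$params[[nm]])) &&
          length(ck$params[[nm]]) != length(model$params[[nm]])) {
        stop("backbone parameter shape mismatch for ", nm)
      }
      model$params[[nm]] <- ck$params[[nm]]
    }
    for (nm in intersect(names(ck$bn_state), names(model$bn_state))) {
      model$bn_state[[nm]] <- ck$bn_state[[nm]]
    }
  }
  model
}

#' @export
print.resnet_model <- function(x, ...) {
  cat(sprintf("<resnet_model> stem %d, stages (%s) x %d blocks, %d classes, %d parameters\n",
              x$spec$stem_filters,
              paste(x$spec$stage_filters, collapse = ", "),
              x$spec$blocks_per_stage, x$spec$num_classes,
              param_count(x)))
  invisible(x)
}

#' Count learnable parameters
#' @param model a `resnet_model`.
#' @return total number of trainable scalars (running BN stats excluded).
#' @export
param_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- residual block ---------------------------------------------------

.block_spec <- function(spec, si, bi, cin) {
  cout <- spec$stage_filters[si]
  stride <- if (si > 1 && bi == 1) 2L else 1L
  bin <- if (bi == 1) cin else cout
  shortcut <- if (bin == cout && stride == 1L) "identity" else spec$shortcut
  list(name = .block_names(si, bi), cin = bin, cout = cout,
       stride = stride, shortcut = shortcut)
}

# Forward through one basic block. `P` and `S` are the model's flat
# parameter/state lists; returns output, cache and updated state entries.
.block_forward <- function(bs, P, S, x, train, passthrough, momentum = 0.1) {
  nm <- bs$name
  bn <- function(xin, tag) {
    nn_bn_forward(xin,
                  P[[paste0(nm, ".", tag, ".gamma")]],
                  P[[paste0(nm, ".", tag, ".beta")]],
                  S[[paste0(nm, ".", tag, ".mean")]],
                  S[[paste0(nm, ".", tag, ".var")]],
                  train = train, passthrough = passthrough,
                  momentum = momentum)
  }
  c1 <- nn_conv_forward(x, P[[paste0(nm, ".conv1")]], bs$stride, 1L)
  b1 <- bn(c1, "bn1")
  r1 <- nn_relu_forward(b1$y)
  c2 <- nn_conv_forward(r1$y, P[[paste0(nm, ".conv2")]], 1L, 1L)
  b2 <- bn(c2, "bn2")
  if (bs$shortcut == "identity") {
    if (!identical(dim(x), dim(b2$y))) {
      stop("identity shortcut requires equal input/output dimensions; got ",
           paste(dim(x), collapse = "x"), " vs ",
           paste(dim(b2$y), collapse = "x"))
    }
    sc <- x
    sc_cache <- NULL
    bp <- NULL
  } else if (bs$shortcut == "projection") {
    pc <- nn_conv_forward(x, P[[paste0(nm, ".proj")]], bs$stride, 0L)
    bp <- nn_bn_forward(pc,
                        P[[paste0(nm, ".projbn.gamma")]],
                        P[[paste0(nm, ".projbn.beta")]],
                        S[[paste0(nm, ".projbn.mean")]],
                        S[[paste0(nm, ".projbn.var")]],
                        train = train, passthrough = passthrough,
                        momentum = momentum)
    sc <- bp$y
    sc_cache <- pc
  } else {  # zero_pad: strided identity, extra channels zero-filled
    d <- dim(x)
    sub <- x[seq(1, d[1], by = bs$stride), seq(1, d[2], by = bs$stride), , ,
             drop = FALSE]
    ds <- dim(sub)
    sc <- array(0, dim = c(ds[1], ds[2], bs$cout, ds[4]))
    sc[, , seq_len(ds[3]), ] <- sub
    sc_cache <- list(x_dim = d, sub_dim = ds)
    bp <- NULL
  }
  sum_ <- b2$y + sc
  r2 <- nn_relu_forward(sum_)
  new_state <- list()
  for (tag in c("bn1", "bn2")) {
    src <- if (tag == "bn1") b1 else b2
    new_state[[paste0(nm, ".", tag, ".mean")]] <- src$run_mean
    new_state[[paste0(nm, ".", tag, ".var")]] <- src$run_var
  }
  if (!is.null(bp)) {
    new_state[[paste0(nm, ".projbn.mean")]] <- bp$run_mean
    new_state[[paste0(nm, ".projbn.var")]] <- bp$run_var
  }
  list(y = r2$y,
       cache = list(bs = bs, x = x, c1 = c1, b1 = b1$cache, r1 = r1,
                    b2 = b2$cache, bp = if (is.null(bp)) NULL else bp$cache,
                    sc_cache = sc_cache, r2_mask = r2$cache),
       state = new_state)
}

.block_backward <- function(cache, P, dy) {
  bs <- cache$bs
  nm <- bs$name
  grads <- list()
  dsum <- nn_relu_backward(cache$r2_mask, dy)
  # shortcut branch
  if (bs$shortcut == "identity") {
    dx_sc <- dsum
  } else if (bs$shortcut == "projection") {
    gb <- nn_bn_backward(cache$bp, dsum)
    if (!is.null(gb$dgamma)) {
      grads[[paste0(nm, ".projbn.gamma")]] <- gb$dgamma
      grads[[paste0(nm, ".projbn.beta")]] <- gb$dbeta
    }
    gc <- nn_conv_backward(cache$x, P[[paste0(nm, ".proj")]], gb$dx,
                           bs$stride, 0L)
    grads[[paste0(nm, ".proj")]] <- gc$dw
    dx_sc <- gc$dx
  } else {  # zero_pad
    d <- cache$sc_cache$x_dim
    ds <- cache$sc_cache$sub_dim
    dsub <- dsum[, , seq_len(d[3]), , drop = FALSE]
    dx_sc <- array(0, dim = d)
    dx_sc[seq(1, d[1], by = bs$stride), seq(1, d[2], by = bs$stride), , ] <- dsub
  }
  # residual branch
  gb2 <- nn_bn_backward(cache$b2, dsum)
  if (!is.null(gb2$dgamma)) {
    grads[[paste0(nm, ".bn2.gamma")]] <- gb2$dgamma
    grads[[paste0(nm, ".bn2.beta")]] <- gb2$dbeta
  }
  gc2 <- nn_conv_backward(cache$r1$y, P[[paste0(nm, ".conv2")]], gb2$dx, 1L, 1L)
  grads[[paste0(nm, ".conv2")]] <- gc2$dw
  dr1 <- nn_relu_backward(cache$r1$cache, gc2$dx)
  gb1 <- nn_bn_backward(cache$b1, dr1)
  if (!is.null(gb1$dgamma)) {
    grads[[paste0(nm, ".bn1.gamma")]] <- gb1$dgamma
    grads[[paste0(nm, ".bn1.beta")]] <- gb1$dbeta
  }
  gc1 <- nn_conv_backward(cache$x, P[[paste0(nm, ".conv1")]], gb1$dx,
                          bs$stride, 1L)
  grads[[paste0(nm, ".conv1")]] <- gc1$dw
  list(dx = gc1$dx + dx_sc, grads = grads)
}

#' Forward pass of a standalone residual block
#'
#' Computes `relu(F(x) + shortcut(x))` for one basic block, exposed for
#' direct inspection and algebraic checks (with `bn_passthrough = TRUE`
#' the batch-norm layers act as identities, so zero residual weights give
#' exactly `relu(shortcut(x))`).
#'
#' @param block a block object from [residual_block()].
#' @param x input activations `(H, W, C_in, N)`.
#' @return output activations.
#' @export
residual_block_forward <- function(block, x) {
  stopifnot(inherits(block, "residual_block"))
  if (dim(x)[3] != block$bs$cin) {
    stop("input has ", dim(x)[3], " channels, block expects ", block$bs$cin)
  }
  .block_forward(block$bs, block$params, block$state, x,
                 train = FALSE, passthrough = block$bn_passthrough)$y
}

#' Construct a standalone residual basic block
#'
#' @param input_channels,output_channels channel counts.
#' @param stride 1 or 2.
#' @param shortcut `"identity"`, `"projection"` or `"zero_pad"`; identity
#'   requires equal input/output shapes (stride 1, equal channels).
#' @param bn_passthrough treat batch norm as identity (algebraic tests).
#' @param seed weight-initialization seed.
#' @return object of class `residual_block` with `$params` exposed so
#'   tests can set weights explicitly.
#' @export
residual_block <- function(input_channels, output_channels, stride = 1,
                           shortcut = c("identity", "projection", "zero_pad"),
                           bn_passthrough = FALSE, seed = 1) {
  shortcut <- match.arg(shortcut)
  if (shortcut == "identity" &&
      (input_channels != output_channels || stride != 1)) {
    stop("identity shortcut requires equal input/output dimensions ",
         "(equal channels and stride 1); use a projection shortcut")
  }
  bs <- list(name = "blk", cin = as.integer(input_channels),
             cout = as.integer(output_channels),
             stride = as.integer(stride), shortcut = shortcut)
  with_seed(seed, {
    params <- list()
    state <- list()
    params[["blk.conv1"]] <- .init_conv(3, 3, bs$cin, bs$cout)
    params[["blk.bn1.gamma"]] <- rep(1, bs$cout)
    params[["blk.bn1.beta"]] <- rep(0, bs$cout)
    state[["blk.bn1.mean"]] <- rep(0, bs$cout)
    state[["blk.bn1.var"]] <- rep(1, bs$cout)
    params[["blk.conv2"]] <- .init_conv(3, 3, bs$cout, bs$cout)
    params[["blk.bn2.gamma"]] <- rep(1, bs$cout)
    params[["blk.bn2.beta"]] <- rep(0, bs$cout)
    state[["blk.bn2.mean"]] <- rep(0, bs$cout)
    state[["blk.bn2.var"]] <- rep(1, bs$cout)
    if (shortcut == "projection") {
      params[["blk.proj"]] <- .init_conv(1, 1, bs$cin, bs$cout)
      params[["blk.projbn.gamma"]] <- rep(1, bs$cout)
      params[["blk.projbn.beta"]] <- rep(0, bs$cout)
      state[["blk.projbn.mean"]] <- rep(0, bs$cout)
      state[["blk.projbn.var"]] <- rep(1, bs$cout)
    }
    structure(list(bs = bs, params = params, state = state,
                   bn_passthrough = bn_passthrough),
              class = "residual_block")
  })
}

# --- full model forward/backward --------------------------------------

#' Forward pass through the full model
#'
#' @param model a `resnet_model`.
#' @param x input images `(H, W, 3, N)` with intensities in `[0, 1]`.
#' @param train batch-statistics mode (TRUE) or running-statistics mode.
#' @param keep_cache retain the per-layer caches needed for backward.
#' @return list with `probs` (`num_classes x N`, columns sum to 1),
#'   `logits`, `bn_state` (updated running stats), and `cache`.
#' @export
resnet_forward <- function(model, x, train = FALSE, keep_cache = FALSE,
                           momentum = 0.1) {
  spec <- model$spec
  P <- model$params
  S <- model$bn_state
  pt <- model$bn_passthrough
  caches <- list()
  sc <- nn_conv_forward(x, P[["stem.conv"]], 2L, 3L)
  sb <- nn_bn_forward(sc, P[["stem.bn.gamma"]], P[["stem.bn.beta"]],
                      S[["stem.bn.mean"]], S[["stem.bn.var"]],
                      train = train, passthrough = pt, momentum = momentum)
  S[["stem.bn.mean"]] <- sb$run_mean
  S[["stem.bn.var"]] <- sb$run_var
  sr <- nn_relu_forward(sb$y)
  mp <- nn_maxpool_forward(sr$y, 3L, 2L, 1L)
  caches$stem <- list(x = x, sc = sc, sb = sb$cache, sr = sr,
                      mp_idx = mp$idx, mp_in_dim = dim(sr$y))
  h <- mp$y
  cin <- spec$stem_filters
  block_caches <- list()
  for (si in seq_along(spec$stage_filters)) {
    for (bi in seq_len(spec$blocks_per_stage)) {
      bs <- .block_spec(spec, si, bi, cin)
      bf <- .block_forward(bs, P, S, h, train, pt, momentum)
      for (nm in names(bf$state)) S[[nm]] <- bf$state[[nm]]
      block_caches[[bs$name]] <- if (keep_cache) bf$cache else NULL
      h <- bf$y
    }
    cin <- spec$stage_filters[si]
  }
  gp <- nn_gap_forward(h)
  fc <- nn_fc_forward(gp$y, P[["fc.W"]], P[["fc.b"]])
  probs <- nn_softmax(fc$y)
  list(probs = probs, logits = fc$y, bn_state = S,
       cache = if (keep_cache) {
         list(stem = caches$stem, blocks = block_caches,
              gap = gp$cache, fc = fc$cache)
       } else NULL)
}

# Backward from dlogits (K x N) to parameter gradients.
resnet_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  P <- model$params
  grads <- list()
  gfc <- nn_fc_backward(cache$fc, P[["fc.W"]], dlogits)
  grads[["fc.W"]] <- gfc$dW
  grads[["fc.b"]] <- gfc$db
  dh <- nn_gap_backward(cache$gap, gfc$dfeat)
  cin_hist <- c(spec$stem_filters,
                rep(spec$stage_filters, each = spec$blocks_per_stage))
  order_blocks <- rev(names(cache$blocks))
  for (nm in order_blocks) {
    bb <- .block_backward(cache$blocks[[nm]], P, dh)
    for (g in names(bb$grads)) grads[[g]] <- bb$grads[[g]]
    dh <- bb$dx
  }
  st <- cache$stem
  dmp <- nn_maxpool_backward(st$mp_idx, dh, st$mp_in_dim)
  dsr <- nn_relu_backward(st$sr$cache, dmp)
  gsb <- nn_bn_backward(st$sb, dsr)
  if (!is.null(gsb$dgamma)) {
    grads[["stem.bn.gamma"]] <- gsb$dgamma
    grads[["stem.bn.beta"]] <- gsb$dbeta
  }
  gsc <- nn_conv_backward(st$x, P[["stem.conv"]], gsb$dx, 2L, 3L)
  grads[["stem.conv"]] <- gsc$dw
  grads
}

#' Predict class probabilities for a set of beat images
#'
#' @param model a trained `resnet_model`.
#' @param images list of `beat_image` objects (or `(H,W,3)` arrays).
#' @param batch_size forward-pass batch size.
#' @return matrix `N x 2` with columns `NORMAL`, `PVC`.
#' @export
predict_proba <- function(model, images, batch_size = 64) {
  n <- length(images)
  out <- matrix(NA_real_, nrow = n, ncol = 2,
                dimnames = list(NULL, c("NORMAL", "PVC")))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    x <- stack_images(images[i:j])
    fw <- resnet_forward(model, x, train = FALSE)
    out[i:j, ] <- t(fw$probs)
    i <- j + 1L
  }
  out
}

#' Predict hard labels (PVC if its probability >= 0.5)
#' @inheritParams predict_proba
#' @return factor with levels NORMAL, PVC.
#' @export
predict_labels <- function(model, images, batch_size = 64) {
  p <- predict_proba(model, images, batch_size)
  factor(ifelse(p[, "PVC"] >= 0.5, "PVC", "NORMAL"),
         levels = c("NORMAL", "PVC"))
}

# Stack a list of (H,W,3) images (0-255 integer or [0,1] numeric) into a
# float (H,W,3,N) batch scaled to [0,1].
stack_images <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], d[3], length(images)))
  for (k in seq_along(images)) {
    img <- images[[k]]
    v <- as.numeric(img)
    if (max(v) > 1) v <- v / 255
    x[, , , k] <- v
  }
  x
}

#' Save / load a model checkpoint
#'
#' Single-file container recording the architecture spec, all weights,
#' batch-norm running statistics and the initialization seed.
#'
#' @param model a `resnet_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               bn_state = model$bn_state, seed = model$seed,
               format = "pvcnet-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "pvcnet-checkpoint-1")) {
    stop("not a pvcnet checkpoint: ", path)
  }
  ck
}

#' Restore a model from a checkpoint
#' @param path checkpoint file path.
#' @return a `resnet_model`.
#' @export
restore_model <- function(path) {
  ck <- load_checkpoint(path)
  structure(list(spec = ck$spec, params = ck$params, bn_state = ck$bn_state,
                 bn_passthrough = FALSE, seed = ck$seed),
            class = "resnet_model")
}
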