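# Patient-specific experiment harnesses: cross-dataset train/test,
# leave-one-subject-out cross-validation, and the beat-level hold-out
# and stratified k-fold baselines.

#' Cross-dataset experiment (train on one archive, test on another)
#'
#' Fits on the full training dataset (with its internal random 10%
#' validation split) and predicts every test beat. Training and test
#' subjects must be disjoint; overlap is refused with the offending ids.
#'
#' @param train_ds,test_ds `beat_dataset` objects.
#' @param spec a [resnet_spec()].
#' @param cfg a [train_config()].
#' @param verbose print training progress.
#' @return list with `confusion`, `metrics`, `fit` (the training result).
#' @export
run_cross_dataset <- function(train_ds, test_ds, spec = resnet_tiny_spec(),
                              cfg = train_config(), verbose = FALSE) {
  overlap <- intersect(unique(train_ds$subject_id), unique(test_ds$subject_id))
  if (length(overlap) > 0) {
    stop("train and test sets share subjects: ",
         paste(overlap, collapse = ", "))
  }
  model <- build_model(spec, pretrained_backbone = FALSE, seed = cfg$seed)
  ft <- fit(model, train_ds, cfg,
            eval_subjects = unique(test_ds$subject_id), verbose = verbose)
  pred <- predict_labels(ft$model, test_ds$images)
  cm <- confusion(test_ds$labels, pred)
  list(confusion = cm, metrics = metrics(cm), fit = ft)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: that subject's beats form the test set and all
#' other subjects train a fresh model. The aggregate confusion matrix is
#' the element-wise sum of the fold matrices (micro aggregation, so its
#' total equals the dataset size); metrics are computed on the aggregate
#' and also reported per fold.
#'
#' @param dataset a `beat_dataset` with >= 2 subjects.
#' @param spec a [resnet_spec()].
#' @param cfg a [train_config()].
#' @param verbose print fold progress.
#' @return list with `fold_confusions` (named by subject), `confusion`
#'   (aggregate), `metrics`, `fold_metrics` (list of per-fold reports).
#' @export
run_losocv <- function(dataset, spec = resnet_tiny_spec(),
                       cfg = train_config(), verbose = FALSE) {
  subjects <- sort(unique(dataset$subject_id))
  if (length(subjects) < 2) stop("LOSOCV needs at least 2 subjects")
  fold_cms <- list()
  fold_reports <- list()
  for (s in subjects) {
    test_i <- dataset$subject_id == s
    train_ds <- subset_dataset(dataset, !test_i)
    test_ds <- subset_dataset(dataset, test_i)
    if (verbose) message("LOSOCV fold: held-out subject ", s,
                         " (", length(test_ds$images), " beats)")
    model <- build_model(spec, pretrained_backbone = FALSE, seed = cfg$seed)
    ft <- fit(model, train_ds, cfg, eval_subjects = s)
    pred <- predict_labels(ft$model, test_ds$images)
    cm <- confusion(test_ds$labels, pred)
    fold_cms[[s]] <- cm
    fold_reports[[s]] <- tryCatch(metrics(cm), error = function(e) NULL)
  }
  agg <- sum_confusions(fold_cms)
  list(fold_confusions = fold_cms, confusion = agg, metrics = metrics(agg),
       fold_metrics = fold_reports)
}

#' Random beat-level hold-out split
#'
#' @param labels dataset labels (only their length is used).
#' @param test_fraction fraction of beats held out for testing.
#' @param seed split seed (same seed, same split).
#' @return logical vector, TRUE = test beat.
#' @export
make_holdout_split <- function(labels, test_fraction = 0.2, seed = 1) {
  n <- length(labels)
  stopifnot(n >= 2, test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test <- logical(n)
    test[sample.int(n, max(1L, round(test_fraction * n)))] <- TRUE
    test
  })
}

#' Stratified k-fold assignment
#'
#' Items of each class are shuffled and dealt round-robin over the k
#' folds, so within every fold the class counts match the dataset
#' proportions to within one beat and no fold can lose a class entirely
#' (given >= k items of each class).
#'
#' @param labels dataset labels (factor or character).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold assignment in `1..k` per item.
#' @export
make_stratified_folds <- function(labels, k = 10, seed = 1) {
  stopifnot(k >= 2)
  lab <- as.character(labels)
  fold <- integer(length(lab))
  with_seed(seed, {
    for (cls in unique(lab)) {
      idx <- which(lab == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Hold-out evaluation harness
#'
#' @param dataset a `beat_dataset`.
#' @param spec,cfg model and training configuration.
#' @param test_fraction held-out fraction of beats.
#' @return list with `confusion`, `metrics`, `fit`.
#' @export
run_holdout <- function(dataset, spec = resnet_tiny_spec(),
                        cfg = train_config(), test_fraction = 0.2) {
  test <- make_holdout_split(dataset$labels, test_fraction, seed = cfg$seed)
  train_ds <- subset_dataset(dataset, !test)
  test_ds <- subset_dataset(dataset, test)
  model <- build_model(spec, pretrained_backbone = FALSE, seed = cfg$seed)
  ft <- fit(model, train_ds, cfg)
  pred <- predict_labels(ft$model, test_ds$images)
  cm <- confusion(test_ds$labels, pred)
  list(confusion = cm, metrics = metrics(cm), fit = ft)
}

#' Stratified k-fold evaluation harness
#'
#' Beat-level folds preserving class proportions; fold matrices are
#' aggregated by summation and metrics computed on the aggregate.
#'
#' @param dataset a `beat_dataset`.
#' @param spec,cfg model and training configuration.
#' @param k number of folds.
#' @return list with `fold_confusions`, `confusion`, `metrics`.
#' @export
run_stratified_kfold <- function(dataset, spec = resnet_tiny_spec(),
                                 cfg = train_config(), k = 10) {
  fold <- make_stratified_folds(dataset$labels, k, seed = cfg$seed)
  counts <- table(dataset$labels, fold)
  if (any(counts == 0)) stop("a class is absent from a fold; use fewer folds")
  fold_cms <- list()
  for (f in seq_len(k)) {
    train_ds <- subset_dataset(dataset, fold != f)
    test_ds <- subset_dataset(dataset, fold == f)
    model <- build_model(spec, pretrained_backbone = FALSE, seed = cfg$seed)
    ft <- fit(model, train_ds, cfg)
    pred <- predict_labels(ft$model, test_ds$images)
    fold_cms[[f]] <- confusion(test_ds$labels, pred)
  }
  agg <- sum_confusions(fold_cms)
  list(fold_confusions = fold_cms, confusion = agg, metrics = metrics(agg))
}
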