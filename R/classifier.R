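#' Classifier configuration
#'
#' Parameters of the two-step gradient-boosted classification scheme:
#' feature extraction with depth-2 boosted trees under stratified k-fold
#' cross-validation, selection of the top `n_top_features` features by
#' fold-averaged total split gain, then depth-1 boosted classifiers (binary
#' per class pair, or soft-probability multiclass) on the selected features
#' with the same fold scheme.  Boosting rounds and learning rate default to
#' 100 and 0.3; sensitivity/specificity use a 0.5 probability threshold.
#'
#' @param n_folds Number of cross-validation folds (default 4).
#' @param extraction_max_depth Tree depth in the extraction step (default 2).
#' @param final_max_depth Tree depth of the final classifiers (default 1).
#' @param n_top_features Number of features kept (default 30).
#' @param nrounds Boosting rounds (default 100).
#' @param eta Learning rate (default 0.3).
#' @param threshold Probability threshold for sensitivity/specificity.
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `repeatsig_classifier_config`.
#' @export
classifier_config <- function(n_folds = 4L, extraction_max_depth = 2L,
                              final_max_depth = 1L, n_top_features = 30L,
                              nrounds = 100L, eta = 0.3, threshold = 0.5,
                              seed = 1L) {
  stopifnot(n_folds >= 2, extraction_max_depth >= 1, final_max_depth >= 1,
            n_top_features >= 1, nrounds >= 1, eta > 0, threshold > 0,
            threshold < 1)
  structure(list(n_folds = as.integer(n_folds),
                 extraction_max_depth = as.integer(extraction_max_depth),
                 final_max_depth = as.integer(final_max_depth),
                 n_top_features = as.integer(n_top_features),
                 nrounds = as.integer(nrounds), eta = eta,
                 threshold = threshold, seed = as.integer(seed)),
            class = "repeatsig_classifier_config")
}

feature_matrix <- function(x) {
  stopifnot(inherits(x, "repeatsig_matrix") || is.data.frame(x))
  feat <- setdiff(names(x), c("sample_id", "class"))
  m <- as.matrix(as.data.frame(x)[feat])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(x)) rownames(m) <- x[["sample_id"]]
  m
}

matrix_labels <- function(x, labels = NULL) {
  if (!is.null(labels)) return(labels)
  if (!"class" %in% names(x)) stop("no class labels available", call. = FALSE)
  x$class
}

# Stratified fold assignment; every class must have >= n_folds samples.
make_folds <- function(labels, n_folds, seed) {
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("stratification error: class(es) ",
         paste(names(counts)[counts < n_folds], collapse = ", "),
         " have fewer than ", n_folds, " samples", call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

xgb_fit <- function(x, y, max_depth, config, objective, num_class = NULL) {
  params <- list(max_depth = max_depth, eta = config$eta,
                 objective = objective, nthread = 1,
                 seed = config$seed)
  if (!is.null(num_class)) params$num_class <- num_class
  if (objective == "binary:logistic") params$eval_metric <- "logloss"
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = config$nrounds,
                     verbose = 0)
}

#' Rank features by fold-averaged boosted-tree gain
#'
#' First step of the two-step scheme: a depth-`extraction_max_depth`
#' boosted model is trained on each training fold and the total split gain
#' of every feature, averaged over folds, ranks the features (ties by
#' column order).  The top `n_top_features` are marked selected.
#'
#' @param x A `repeatsig_matrix` tibble (features + `class` column) or any
#'   data frame shaped like one.
#' @param labels Optional class labels (defaults to the `class` column).
#' @param config A [classifier_config()].
#' @return A tibble `feature`, `gain`, `rank`, `selected`, ordered by rank.
#' @export
select_features <- function(x, labels = NULL, config = classifier_config()) {
  stopifnot(inherits(config, "repeatsig_classifier_config"))
  labels <- matrix_labels(x, labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  xm <- feature_matrix(x)
  fold <- make_folds(labels, config$n_folds, config$seed)
  multi <- length(classes) > 2
  y <- if (multi) match(labels, classes) - 1L else as.integer(labels == classes[1])

  gain <- matrix(0, nrow = ncol(xm), ncol = config$n_folds,
                 dimnames = list(colnames(xm), NULL))
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    fit <- xgb_fit(xm[tr, , drop = FALSE], y[tr], config$extraction_max_depth,
                   config,
                   objective = if (multi) "multi:softprob" else "binary:logistic",
                   num_class = if (multi) length(classes) else NULL)
    imp <- xgboost::xgb.importance(model = fit)
    if (!is.null(imp) && nrow(imp) > 0) {
      gain[imp$Feature, f] <- imp$Gain
    }
  }
  avg <- rowMeans(gain)
  ord <- order(-avg, seq_along(avg))
  tibble::tibble(feature = colnames(xm)[ord], gain = avg[ord],
                 rank = seq_along(ord),
                 selected = seq_along(ord) <= min(config$n_top_features, length(ord)))
}

#' Train pairwise classifiers for every class pair
#'
#' For each unordered pair of classes the two-step scheme is run on that
#' pair's samples only: feature extraction and top-30 selection, then a
#' depth-1 boosted binary classifier per cross-validation fold on the
#' selected features.  Per fold the held-out samples yield AUC (rank
#' statistic), accuracy, sensitivity and specificity (threshold 0.5, the
#' alphabetically first class of the pair as positive), and ROC points.
#'
#' @inheritParams select_features
#' @return An object of class `repeatsig_pairwise`: list with tibbles
#'   `metrics` (per pair x fold), `features` (selected per pair), `roc`
#'   (validation ROC points), `predictions` (out-of-fold probabilities),
#'   the class levels and the `config`.
#' @export
train_pairwise <- function(x, labels = NULL, config = classifier_config()) {
  labels <- matrix_labels(x, labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) train_one_pair(x, labels, pr, config))
  structure(list(
    metrics = dplyr::bind_rows(lapply(res, `[[`, "metrics")),
    features = dplyr::bind_rows(lapply(res, `[[`, "features")),
    roc = dplyr::bind_rows(lapply(res, `[[`, "roc")),
    predictions = dplyr::bind_rows(lapply(res, `[[`, "predictions")),
    classes = classes, config = config
  ), class = "repeatsig_pairwise")
}

train_one_pair <- function(x, labels, pr, config) {
  keep <- labels %in% pr
  xm <- feature_matrix(x)[keep, , drop = FALSE]
  lab <- labels[keep]
  sel <- select_features(tibble::as_tibble(as.data.frame(xm)),
                         labels = lab, config = config)
  top <- sel$feature[sel$selected]
  xs <- xm[, top, drop = FALSE]
  y <- as.integer(lab == pr[1])  # class_a positive
  fold <- make_folds(lab, config$n_folds, config$seed)

  mets <- vector("list", config$n_folds)
  rocs <- vector("list", config$n_folds)
  preds <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    fit <- xgb_fit(xs[tr, , drop = FALSE], y[tr], config$final_max_depth,
                   config, objective = "binary:logistic")
    p <- stats::predict(fit, xgboost::xgb.DMatrix(xs[!tr, , drop = FALSE]))
    yv <- y[!tr]
    hard <- as.integer(p >= config$threshold)
    mets[[f]] <- tibble::tibble(
      class_a = pr[1], class_b = pr[2], fold = f,
      auc = auc_rank(p, yv),
      accuracy = mean(hard == yv),
      sensitivity = if (any(yv == 1)) mean(hard[yv == 1] == 1) else NA_real_,
      specificity = if (any(yv == 0)) mean(hard[yv == 0] == 0) else NA_real_)
    rocs[[f]] <- dplyr::mutate(roc_points(p, yv),
                               class_a = pr[1], class_b = pr[2], fold = f)
    preds[[f]] <- tibble::tibble(class_a = pr[1], class_b = pr[2], fold = f,
                                 sample_id = rownames(xs)[!tr],
                                 truth = yv, prob = p)
  }
  list(metrics = dplyr::bind_rows(mets),
       features = dplyr::mutate(sel[sel$selected, ], class_a = pr[1], class_b = pr[2]),
       roc = dplyr::bind_rows(rocs),
       predictions = dplyr::bind_rows(preds))
}

# predictions of a multi:softprob booster as a samples x classes matrix
softprob_matrix <- function(p, n_classes) {
  if (is.matrix(p)) p else matrix(p, ncol = n_classes, byrow = TRUE)
}

# AUC as the Mann-Whitney rank statistic (mid-ranks for ties).
auc_rank <- function(score, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(score, truth) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(score[truth == 1] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(score[truth == 0] >= t), numeric(1)))
}

#' Train the soft-probability multiclass classifier
#'
#' Two-step multiclass scheme: depth-2 soft-probability boosted extraction
#' with stratified k-fold cross-validation, top-30 selection by
#' fold-averaged gain, then a depth-1 soft-probability model per fold on
#' the selected features.  Every sample receives an out-of-fold class
#' probability profile (rows sum to 1); the confusion matrix comes from the
#' out-of-fold argmax.
#'
#' @inheritParams select_features
#' @return An object of class `repeatsig_multiclass`: list with
#'   `probabilities` (tibble: `sample_id`, `class`, `fold`, one `p_<class>`
#'   column per class), `fold_accuracy`, `confusion` (matrix), `features`,
#'   `models` (per-fold boosters, used by [score_sample()]), `classes`,
#'   `folds` and the `config`.
#' @export
train_multiclass <- function(x, labels = NULL, config = classifier_config()) {
  labels <- matrix_labels(x, labels)
  classes <- sort(unique(labels))
  if (length(classes) < 3) stop("need at least 3 classes", call. = FALSE)
  xm <- feature_matrix(x)
  sel <- select_features(x, labels = labels, config = config)
  top <- sel$feature[sel$selected]
  xs <- xm[, top, drop = FALSE]
  y <- match(labels, classes) - 1L
  fold <- make_folds(labels, config$n_folds, config$seed)

  prob <- matrix(NA_real_, nrow = nrow(xs), ncol = length(classes),
                 dimnames = list(rownames(xs), classes))
  models <- vector("list", config$n_folds)
  acc <- numeric(config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    fit <- xgb_fit(xs[tr, , drop = FALSE], y[tr], config$final_max_depth,
                   config, objective = "multi:softprob",
                   num_class = length(classes))
    p <- softprob_matrix(
      stats::predict(fit, xgboost::xgb.DMatrix(xs[!tr, , drop = FALSE])),
      length(classes))
    prob[!tr, ] <- p
    acc[f] <- mean(classes[max.col(p)] == labels[!tr])
    models[[f]] <- fit
  }
  pred <- classes[max.col(prob)]
  confusion <- table(truth = factor(labels, classes),
                     predicted = factor(pred, classes))
  probs <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(xs), class = labels, fold = fold),
    tibble::as_tibble(prob, .name_repair = ~ paste0("p_", .x)))
  structure(list(
    probabilities = probs,
    fold_accuracy = tibble::tibble(fold = seq_len(config$n_folds), accuracy = acc),
    confusion = unclass(confusion),
    features = sel,
    models = models,
    classes = classes,
    folds = tibble::tibble(sample_id = rownames(xs), fold = fold),
    config = config
  ), class = "repeatsig_multiclass")
}
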