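# Cross-validated gradient-boosted tree classification of binned uptake.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package randomness never leaks into or
# depends on the session's global RNG position.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Seeded fold assignment, stratified by class when every class has at least
# n_folds members, plain shuffled folds otherwise.
assign_folds <- function(labels, n_folds, seed) {
  n <- length(labels)
  with_seed(seed, {
    counts <- table(labels)
    folds <- integer(n)
    if (all(counts >= n_folds)) {
      for (cl in names(counts)) {
        idx <- sample(which(labels == as.integer(cl)))
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    folds
  })
}

#' Default booster hyperparameters
#'
#' Shallow trees (depth 3), 100 boosting rounds, learning rate 0.3, single
#' thread for bit-reproducibility. Override any element via the `params`
#' argument of [crossval_classify()].
#'
#' @return Named list.
#' @export
default_boost_params <- function() {
  list(max_depth = 3L, nrounds = 100L, eta = 0.3)
}

#' Cross-validated uptake classification
#'
#' Splits the dataset into `n_folds` folds (seeded; stratified by class when
#' every class has at least `n_folds` members), trains a gradient-boosted
#' decision-tree ensemble on the training folds only, and evaluates each
#' held-out fold. The score is the F1 averaged over folds: the two-class
#' positive-class formula `2PR/(P+R)` for binary problems, the macro average
#' over classes otherwise. With the seed fixed the whole report is
#' reproducible.
#'
#' @param features Numeric matrix or data.frame of predictors (rows =
#'   samples), e.g. from [feature_matrix()].
#' @param labels Integer class labels `0 .. n_classes-1`, every class
#'   present at least once.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling folds and booster.
#' @param params Booster hyperparameters overriding
#'   [default_boost_params()].
#' @return Object of class `classification_report`: `n_classes`,
#'   `per_fold_confusions`, `pooled_confusion`, `fold_f1s`, `f1`,
#'   `degenerate_folds` (folds whose training data missed a class),
#'   `fold_assignment`, `seed`.
#' @export
crossval_classify <- function(features, labels, n_folds = 5L, seed = 1L,
                              params = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("features and labels disagree in length",
                                call. = FALSE)
  if (n < n_folds) stop("need at least n_folds samples", call. = FALSE)
  classes <- sort(unique(labels))
  n_classes <- max(labels) + 1L
  if (!all(classes %in% 0:(n_classes - 1L))) {
    stop("labels must be integers 0 .. n_classes-1", call. = FALSE)
  }
  hp <- utils::modifyList(default_boost_params(), params)
  folds <- assign_folds(labels, n_folds, seed)
  confusions <- vector("list", n_folds)
  fold_f1s <- numeric(n_folds)
  degenerate <- integer(0)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    if (length(setdiff(classes, unique(labels[tr]))) > 0L) {
      degenerate <- c(degenerate, f)
    }
    dtrain <- xgboost::xgb.DMatrix(features[tr, , drop = FALSE],
                                   label = labels[tr], nthread = 1L)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softmax", num_class = n_classes,
                    max_depth = hp$max_depth, eta = hp$eta, nthread = 1L,
                    seed = seed),
      data = dtrain, nrounds = hp$nrounds, verbose = 0)
    pred <- predict(booster,
                    xgboost::xgb.DMatrix(features[te, , drop = FALSE],
                                         nthread = 1L))
    cm <- matrix(0L, n_classes, n_classes,
                 dimnames = list(actual = 0:(n_classes - 1L),
                                 predicted = 0:(n_classes - 1L)))
    for (idx in seq_along(pred)) {
      a <- labels[te][idx] + 1L
      p <- as.integer(pred[idx]) + 1L
      cm[a, p] <- cm[a, p] + 1L
    }
    confusions[[f]] <- cm
    fold_f1s[f] <- f1_from_confusion(
      cm, averaging = if (n_classes == 2L) "binary" else "macro")
  }
  pooled <- Reduce(`+`, confusions)
  structure(
    list(n_classes = n_classes, per_fold_confusions = confusions,
         pooled_confusion = pooled, fold_f1s = fold_f1s,
         f1 = mean(fold_f1s), degenerate_folds = degenerate,
         fold_assignment = folds, seed = seed),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %d classes, %d folds, mean F1 = %.4f (per fold: %s)\n",
    x$n_classes, length(x$fold_f1s), x$f1,
    paste(sprintf("%.3f", x$fold_f1s), collapse = ", ")))
  if (length(x$degenerate_folds)) {
    cat("  degenerate folds (class missing from training):",
        paste(x$degenerate_folds, collapse = ", "), "\n")
  }
  cat("  pooled confusion (rows = actual, cols = predicted):\n")
  print(x$pooled_confusion)
  invisible(x)
}
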