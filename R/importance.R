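#' Classifier specification
#'
#' Hyperparameters shared by the macrostate classifiers. The tree-based
#' models split on Gini impurity and report feature importance as the
#' normalized total impurity decrease; the single-hidden-layer neural net
#' uses logistic loss with an L2 weight penalty `a` and is included for the
#' accuracy comparison only (its weights are never used downstream).
#'
#' @param n_trees forest size (default 100).
#' @param max_depth tree depth cap; `NULL` means unlimited.
#' @param mtry features tried per split; `NULL` uses the forest
#'   implementation's default (square root of the feature count). Setting
#'   `mtry` to the full feature count concentrates importance on genuinely
#'   discriminative features in high-signal recovery analyses.
#' @param a L2 regularization strength for the neural net (default 1e-4).
#' @param hidden hidden-layer size for the neural net (default 10).
#' @param folds cross-validation folds (default 12).
#' @param seed integer seed.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(n_trees = 100L, max_depth = NULL, a = 1e-4,
                            hidden = 10L, folds = 12L, seed = 1L,
                            mtry = NULL) {
  if (folds < 2L) stop("folds must be >= 2")
  if (a < 0) stop("a must be >= 0")
  out <- list(n_trees = n_trees, max_depth = max_depth, a = a,
              hidden = hidden, folds = folds, seed = seed, mtry = mtry)
  class(out) <- "classifier_spec"
  out
}

## stratified fold assignment, seeded shuffling; fold ids cycle across
## classes so fold sizes stay balanced overall as well as within class
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  at <- 0L
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- (at + seq_along(idx) - 1L) %% folds + 1L
    at <- at + length(idx)
  }
  fold
}

fit_one <- function(kind, x, y, spec) {
  y <- factor(y)
  switch(kind,
    tree = rpart::rpart(y ~ ., data = data.frame(x, y = y),
                        method = "class",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = 2, xval = 0,
                          maxdepth = if (is.null(spec$max_depth)) 30
                                     else spec$max_depth)),
    forest = do.call(randomForest::randomForest, c(
      list(x = x, y = y, ntree = spec$n_trees),
      if (!is.null(spec$mtry)) list(mtry = spec$mtry),
      if (!is.null(spec$max_depth)) list(maxnodes = 2^spec$max_depth))),
    ann = nnet::nnet(x, nnet::class.ind(y), size = spec$hidden,
                     decay = spec$a, maxit = 200, softmax = TRUE,
                     trace = FALSE, MaxNWts = 1e5),
    stop("unknown model kind"))
}

predict_one <- function(kind, fit, x, levels) {
  p <- switch(kind,
    tree = predict(fit, data.frame(x), type = "class"),
    forest = predict(fit, x),
    ann = factor(levels[max.col(predict(fit, x))], levels = levels))
  as.character(p)
}

#' Train and cross-validate the baseline macrostate classifiers
#'
#' Fits a single-hidden-layer neural network, a decision tree, a random
#' forest, and a stratified-random dummy classifier on labeled feature data,
#' reporting training accuracy and stratified k-fold validation accuracy
#' (accuracy = fraction of frames classified correctly). Deterministic given
#' the spec's seed.
#'
#' @param features a `feature_matrix` or plain numeric matrix.
#' @param labels integer macrostate label per frame (>= 2 classes, each with
#'   at least `folds` samples).
#' @param spec a [classifier_spec()].
#' @param models subset of `c("ann", "tree", "forest", "dummy")`.
#' @return data.frame with `model`, `train_accuracy`, `cv_accuracy`, `cv_sd`.
#' @export
train_baselines <- function(features, labels, spec = classifier_spec(),
                            models = c("ann", "tree", "forest", "dummy")) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(labels)
  if (length(y) != nrow(x)) stop("label count must equal frame count")
  tab <- table(y)
  if (length(tab) < 2L) stop("need at least two classes")
  if (any(tab < spec$folds))
    stop("every class needs at least `folds` samples")
  fold <- stratified_folds(y, spec$folds, spec$seed)
  lv <- levels(factor(y))
  res <- lapply(models, function(kind) {
    set.seed(spec$seed)
    if (kind == "dummy") {
      ## stratified random guessing at the training class frequencies
      train_acc <- mean(sample(y) == y)
      accs <- vapply(seq_len(spec$folds), function(f) {
        yte <- y[fold == f]
        mean(sample(y, length(yte), replace = TRUE) == yte)
      }, numeric(1))
    } else {
      fit <- fit_one(kind, x, y, spec)
      train_acc <- mean(predict_one(kind, fit, x, lv) == as.character(y))
      accs <- vapply(seq_len(spec$folds), function(f) {
        tr <- fold != f
        fit_f <- fit_one(kind, x[tr, , drop = FALSE], y[tr], spec)
        mean(predict_one(kind, fit_f, x[!tr, , drop = FALSE], lv) ==
               as.character(y[!tr]))
      }, numeric(1))
    }
    data.frame(model = kind, train_accuracy = train_acc,
               cv_accuracy = mean(accs), cv_sd = stats::sd(accs))
  })
  do.call(rbind, res)
}

#' One-vs-one random forest with per-state-pair feature importance
#'
#' For every unordered pair of macrostates, one random forest is trained on
#' that pair's frames only. Each forest's Gini importance (total impurity
#' decrease accumulated over all nodes splitting on the feature) is
#' normalized to sum to one, giving the pair's feature-importance vector;
#' the overall importance is the arithmetic mean over all pairs. Prediction
#' is by pairwise voting.
#'
#' @param features a `feature_matrix` or numeric matrix.
#' @param labels integer macrostate label per frame; every class pair needs
#'   at least 2 samples per class.
#' @param spec a [classifier_spec()].
#' @return An object of class `ovo_forest`: list with `forests` (named by
#'   `"s1|s2"`), `importance` (an `importance_table`), `classes`, `spec`.
#' @export
train_ovo <- function(features, labels, spec = classifier_spec()) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  pair_labels <- if (inherits(features, "feature_matrix")) features$pair_labels
                 else paste0("f", seq_len(ncol(x)))
  y <- as.integer(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  pairs <- t(utils::combn(classes, 2L))
  forests <- vector("list", nrow(pairs))
  per_pair <- matrix(0, ncol(x), nrow(pairs))
  set.seed(spec$seed)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    idx <- y %in% c(a, b)
    rf <- do.call(randomForest::randomForest, c(
      list(x = x[idx, , drop = FALSE],
           y = factor(y[idx], levels = c(a, b)), ntree = spec$n_trees),
      if (!is.null(spec$mtry)) list(mtry = spec$mtry),
      if (!is.null(spec$max_depth)) list(maxnodes = 2^spec$max_depth)))
    forests[[r]] <- rf
    imp <- rf$importance[, "MeanDecreaseGini"]
    per_pair[, r] <- if (sum(imp) > 0) imp / sum(imp)
                     else rep(1 / length(imp), length(imp))
  }
  names(forests) <- paste0(pairs[, 1], "|", pairs[, 2])
  tab <- importance_table(per_pair, pairs, pair_labels)
  out <- list(forests = forests, importance = tab, classes = classes,
              spec = spec)
  class(out) <- "ovo_forest"
  out
}

#' Assemble an importance table
#'
#' @param per_pair P x n_pairs matrix of per-state-pair importance vectors,
#'   each column nonnegative and summing to one.
#' @param state_pairs n_pairs x 2 matrix of macrostate indices (s1 < s2).
#' @param feature_labels feature names ("T38-G105" style).
#' @return An object of class `importance_table` with `per_pair`,
#'   `state_pairs`, `overall` (mean over pairs), `feature_labels`.
#' @export
importance_table <- function(per_pair, state_pairs, feature_labels = NULL) {
  per_pair <- as.matrix(per_pair)
  if (any(per_pair < -1e-12)) stop("importance must be nonnegative")
  sums <- colSums(per_pair)
  if (any(abs(sums - 1) > 1e-8)) stop("each per-pair vector must sum to 1")
  if (is.null(feature_labels)) feature_labels <- paste0("f", seq_len(nrow(per_pair)))
  colnames(per_pair) <- paste0(state_pairs[, 1], "|", state_pairs[, 2])
  out <- list(per_pair = per_pair, state_pairs = as.matrix(state_pairs),
              overall = rowMeans(per_pair), feature_labels = feature_labels)
  class(out) <- "importance_table"
  out
}

#' @export
print.importance_table <- function(x, n = 5L, ...) {
  cat("Importance table:", nrow(x$per_pair), "features x",
      ncol(x$per_pair), "state pairs\n")
  cat("top", n, "features by overall importance:\n")
  print(ranked_importance(x, n))
  invisible(x)
}

#' @export
print.ovo_forest <- function(x, ...) {
  cat("One-vs-one random forest:", length(x$forests), "pairwise classifiers,",
      length(x$classes), "macrostates,", x$spec$n_trees, "trees each\n")
  invisible(x)
}

#' Predict macrostates by pairwise voting
#'
#' @param object an `ovo_forest`.
#' @param newdata numeric matrix (or `feature_matrix`) of frames to classify.
#' @param ... unused.
#' @return Integer vector of predicted macrostate labels.
#' @export
predict.ovo_forest <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  votes <- matrix(0, nrow(x), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (r in seq_along(object$forests)) {
    p <- as.character(predict(object$forests[[r]], x))
    for (cl in unique(p)) votes[p == cl, cl] <- votes[p == cl, cl] + 1
  }
  object$classes[max.col(votes, ties.method = "first")]
}

#' Ranked overall-importance report
#'
#' Maps each feature to its residue pair and its top contributing state
#' pairs, sorted by overall importance.
#'
#' @param table an `importance_table`.
#' @param n how many features to report.
#' @param n_ranks how many top state pairs to list per feature.
#' @return data.frame with `feature`, `pair`, `overall`, and
#'   `rank1`..`rankK` columns of the form `"s1-s2: xx%"`.
#' @export
ranked_importance <- function(table, n = 5L, n_ranks = 4L) {
  ord <- order(-table$overall, seq_along(table$overall))
  top <- utils::head(ord, n)
  rows <- lapply(top, function(f) {
    v <- table$per_pair[f, ]
    r <- order(-v)[seq_len(min(n_ranks, length(v)))]
    ranks <- sprintf("S%d-S%d: %.2f%%", table$state_pairs[r, 1],
                     table$state_pairs[r, 2], 100 * v[r])
    out <- data.frame(feature = f, pair = table$feature_labels[f],
                      overall_pct = 100 * table$overall[f])
    for (j in seq_along(ranks)) out[[paste0("rank", j)]] <- ranks[j]
    out
  })
  do.call(rbind, rows)
}

#' Overall importance as the mean over state pairs
#'
#' @param table an `importance_table`.
#' @return Numeric vector over features, summing to one.
#' @export
overall_importance <- function(table) table$overall

#' Features needed to reach a cumulative importance threshold
#'
#' The smallest number of features, taken in descending overall-importance
#' order (ties broken by feature index), whose importance sums to at least
#' `threshold`.
#'
#' @param overall importance vector summing to one (or an
#'   `importance_table`).
#' @param threshold cumulative fraction in (0, 1].
#' @return Integer feature count.
#' @export
cumulative_coverage <- function(overall, threshold = 0.9) {
  if (inherits(overall, "importance_table")) overall <- overall$overall
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  v <- overall[order(-overall, seq_along(overall))]
  which(cumsum(v) >= threshold - 1e-12)[1]
}

#' Write an importance table as TSV
#'
#' Columns: feature index, residue pair, overall importance, one column per
#' state pair.
#'
#' @param table an `importance_table`.
#' @param path output TSV path.
#' @export
write_importance_tsv <- function(table, path) {
  df <- data.frame(feature = seq_along(table$overall),
                   pair = table$feature_labels,
                   overall = table$overall)
  df <- cbind(df, as.data.frame(table$per_pair))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hyperparameter grid scan for the baseline classifiers
#'
#' Utility for accuracy-vs-hyperparameter curves: evaluates
#' [train_baselines()] for one model kind over a grid of one hyperparameter.
#'
#' @param features,labels as in [train_baselines()].
#' @param model one of `"ann"`, `"tree"`, `"forest"`.
#' @param param hyperparameter name in [classifier_spec()].
#' @param values grid of values.
#' @param spec base [classifier_spec()].
#' @return data.frame with the grid value and the accuracy columns.
#' @export
scan_hyperparameters <- function(features, labels, model, param, values,
                                 spec = classifier_spec()) {
  rows <- lapply(values, function(v) {
    s <- spec; s[[param]] <- v
    acc <- train_baselines(features, labels, s, models = model)
    cbind(data.frame(value = v), acc)
  })
  do.call(rbind, rows)
}
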