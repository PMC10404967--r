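# Stratified cross-validation machinery shared by every strategy
# pipeline and by the inner tuning loops.

#' Stratified fold assignment
#'
#' Shuffles indices within each class under the seed and deals them
#' round-robin over the folds, so fold sizes differ by at most one and
#' every class is spread as evenly as possible.
#'
#' @param labels Class labels.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  if (k < 2L) stop("folds must be >= 2")
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 names(counts)[which.min(counts)], min(counts), k))
  fold_id <- integer(length(labels))
  with_seed(seed, {
    pos <- 0L
    for (cl in sample(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  fold_id
}

#' Stratified k-fold cross-validation of an estimator
#'
#' The estimator is a list with elements `fit(X, y)` returning a model
#' and `predict(model, X)` returning labels. Each fold's model sees only
#' its training rows; metrics come from [compute_metrics()] on the held
#' out rows.
#'
#' @param features Feature matrix (n x d).
#' @param labels Class labels.
#' @param estimator `list(fit =, predict =)`.
#' @param folds Number of folds, default 10.
#' @param seed Fold-assignment seed.
#' @param scheme Classes for the metrics (defaults to the observed
#'   labels).
#' @return A `cv_result`: `per_fold` (list of metrics reports),
#'   `aggregate` (mean sensitivity/specificity/accuracy over folds, %),
#'   `fold_assignments`, `predictions` (out-of-fold), `folds`.
#' @export
cross_validate <- function(features, labels, estimator, folds = 10L, seed = 1L,
                           scheme = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (is.null(scheme)) scheme <- sort(unique(labels))
  fold_id <- make_stratified_folds(labels, folds, seed)
  per_fold <- vector("list", folds)
  preds <- character(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- estimator$fit(X[tr, , drop = FALSE], labels[tr])
    p <- estimator$predict(model, X[!tr, , drop = FALSE])
    preds[!tr] <- as.character(p)
    per_fold[[f]] <- compute_metrics(labels[!tr], p, scheme)
  }
  aggregate_cv(per_fold, fold_id, preds)
}

#' @keywords internal
#' @noRd
aggregate_cv <- function(per_fold, fold_id, preds) {
  agg <- c(
    sensitivity = mean(vapply(per_fold, function(m) m$macro["sensitivity"], numeric(1))),
    specificity = mean(vapply(per_fold, function(m) m$macro["specificity"], numeric(1))),
    accuracy = mean(vapply(per_fold, function(m) m$overall_accuracy, numeric(1))))
  structure(list(per_fold = per_fold, aggregate = agg,
                 fold_assignments = fold_id, predictions = preds,
                 folds = length(per_fold)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    x$folds, x$aggregate["accuracy"], x$aggregate["sensitivity"],
    x$aggregate["specificity"]))
  invisible(x)
}

# Plain distance-matrix k-nearest-neighbour vote. Cheaper than a
# KD-tree for the tiny problems inside metaheuristic fitness loops;
# ties break toward the first class level (deterministic).
#' @keywords internal
#' @noRd
knn_vote <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  D <- sq_dist(as.matrix(Xte), as.matrix(Xtr))
  lev <- sort(unique(ytr))
  apply(D, 1, function(dr) {
    nb <- ytr[order(dr)[seq_len(k)]]
    lev[which.max(tabulate(match(nb, lev), length(lev)))]
  })
}

# K-nearest-neighbour CV error of a column subset; the cheap inner
# fitness used by the feature-mask optimizers.
#' @keywords internal
#' @noRd
knn_cv_error <- function(X, y, cols, folds = 3L, k = 5L, seed = 1L,
                         fold_id = NULL) {
  if (length(cols) == 0L) return(1)
  Xs <- X[, cols, drop = FALSE]
  if (is.null(fold_id)) fold_id <- make_stratified_folds(y, folds, seed)
  folds <- max(fold_id)
  errs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    p <- knn_vote(Xs[tr, , drop = FALSE], y[tr], Xs[!tr, , drop = FALSE], k)
    mean(p != y[!tr])
  }, numeric(1))
  mean(errs)
}

# Ridge regression onto one-hot targets with arg-max prediction; the
# deterministic linear head used after autoencoder encoding.
#' @keywords internal
#' @noRd
ridge_head_fit <- function(X, y, lambda = 1e-2) {
  X1 <- cbind(1, as.matrix(X))
  lev <- sort(unique(as.character(y)))
  Tm <- one_hot(as.character(y), lev)
  A <- crossprod(X1) + diag(lambda, ncol(X1))
  B <- solve(A, crossprod(X1, Tm))
  list(B = B, levels = lev)
}

#' @keywords internal
#' @noRd
ridge_head_predict <- function(model, X) {
  S <- cbind(1, as.matrix(X)) %*% model$B
  model$levels[max.col(S, ties.method = "first")]
}
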