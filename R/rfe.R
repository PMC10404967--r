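# Recursive feature elimination ranked by linear-SVM weight magnitude.
# Features are z-scored internally so the ranking is invariant to
# feature scaling; multiclass problems are handled one-vs-rest with the
# squared weights summed over classifiers.

#' SVM-based recursive feature elimination
#'
#' Repeats \{train a linear SVM on the surviving features, score each
#' feature by its squared weight, drop the `eliminate_per_round`
#' lowest-scoring\} until no feature remains. The ranking lists features
#' best-first (last survivor first). Constant features carry no
#' discriminative weight and are eliminated first by convention; ties on
#' the criterion are broken toward the lower column index.
#'
#' @param features Numeric matrix (n x d, d >= 2).
#' @param labels Class labels (>= 2 classes present).
#' @param eliminate_per_round Features removed per round, default 1.
#' @param lambda Regularization passed to [linear_svm()].
#' @return An `rfe_ranking`: `ranked_indices` (permutation of `1:d`,
#'   best first), `elimination_trace` (data frame of feature, round and
#'   criterion at elimination time).
#' @export
svm_rfe <- function(features, labels, eliminate_per_round = 1L, lambda = 0.01) {
  X <- as.matrix(features)
  if (ncol(X) < 2L) stop("need at least 2 features")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("labels must contain at least 2 classes")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  constant <- sdv == 0
  sdv[constant] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  surviving <- seq_len(ncol(X))
  eliminated <- integer(0)
  trace <- list()
  round_i <- 0L
  while (length(surviving) > 0L) {
    round_i <- round_i + 1L
    crit <- numeric(length(surviving))
    is_const <- constant[surviving]
    if (any(!is_const) && length(surviving) > 1L) {
      Xr <- Xs[, surviving, drop = FALSE]
      w2 <- numeric(length(surviving))
      if (length(lev) == 2L) {
        fit <- linear_svm(Xr, labels, lambda = lambda)
        w2 <- fit$w^2
      } else {
        for (cl in lev) {
          fit <- linear_svm(Xr, ifelse(labels == cl, cl, "rest"), lambda = lambda)
          w2 <- w2 + fit$w^2
        }
      }
      crit <- w2
    }
    crit[is_const] <- -Inf
    k <- min(eliminate_per_round, length(surviving))
    # lowest criterion leaves first; ties -> lower index first
    ord <- order(crit, seq_along(crit))
    drop_local <- ord[seq_len(k)]
    dropped <- surviving[drop_local]
    trace[[round_i]] <- data.frame(feature = dropped, round = round_i,
                                   criterion = crit[drop_local])
    # record in elimination order (worst of the round first)
    eliminated <- c(eliminated, dropped)
    surviving <- surviving[-drop_local]
  }
  structure(list(ranked_indices = rev(eliminated),
                 elimination_trace = do.call(rbind, trace)),
            class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf("<rfe_ranking> %d features; top 10: %s\n",
              length(x$ranked_indices),
              paste(utils::head(x$ranked_indices, 10), collapse = ", ")))
  invisible(x)
}
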