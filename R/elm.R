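# Extreme learning machine: a single-hidden-layer feed-forward network
# whose input weights and biases are random and fixed; only the output
# weights are learned, in closed form through the Moore-Penrose
# pseudo-inverse of the hidden-layer output matrix.

#' Train an extreme learning machine
#'
#' Input weights and biases are drawn uniformly from \[-1, 1\] under the
#' given seed; hidden activations are sigmoid; labels are one-hot
#' encoded and the output weights solve `H beta = T` in the
#' least-squares sense via the pseudo-inverse.
#'
#' @param X Feature matrix (n x d, n >= 2).
#' @param labels Class labels.
#' @param L Hidden neuron count, default 30.
#' @param seed RNG seed for the random layer.
#' @return An `elm_model`: `w` (L x d), `b` (length L), `beta`
#'   (L x n_classes), `levels`.
#' @export
elm_train <- function(X, labels, L = 30L, seed = 1L) {
  X <- as.matrix(X)
  if (L < 1L) stop("L must be >= 1")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  with_seed(seed, {
    w <- matrix(stats::runif(L * ncol(X), -1, 1), L, ncol(X))
    b <- stats::runif(L, -1, 1)
    H <- sigmoid(tcrossprod(X, w) + matrix(b, nrow(X), L, byrow = TRUE))
    Tmat <- one_hot(labels, lev)
    beta <- pinv(H) %*% Tmat
    structure(list(w = w, b = b, beta = beta, levels = lev), class = "elm_model")
  })
}

# Regression form: continuous targets, no one-hot encoding. Used by the
# residual-compensation stages of the mode-decomposition pipeline.
#' @keywords internal
#' @noRd
elm_regress <- function(X, Tmat, L = 30L, seed = 1L) {
  X <- as.matrix(X); Tmat <- as.matrix(Tmat)
  with_seed(seed, {
    w <- matrix(stats::runif(L * ncol(X), -1, 1), L, ncol(X))
    b <- stats::runif(L, -1, 1)
    H <- sigmoid(tcrossprod(X, w) + matrix(b, nrow(X), L, byrow = TRUE))
    beta <- pinv(H) %*% Tmat
    structure(list(w = w, b = b, beta = beta, levels = colnames(Tmat)),
              class = "elm_model")
  })
}

#' @keywords internal
#' @noRd
elm_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$w))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 ncol(model$w), ncol(X)))
  H <- sigmoid(tcrossprod(X, model$w) + matrix(model$b, nrow(X), length(model$b),
                                               byrow = TRUE))
  H %*% model$beta
}

#' Predict with an extreme learning machine
#'
#' @param model An `elm_model`.
#' @param X Feature matrix with matching dimension.
#' @param type `"label"` (default) for arg-max labels (ties break toward
#'   the lower class index) or `"score"` for the raw output channels.
#' @return Character labels or the score matrix.
#' @export
elm_predict <- function(model, X, type = c("label", "score")) {
  type <- match.arg(type)
  S <- elm_scores(model, X)
  if (type == "score") return(S)
  model$levels[max.col(S, ties.method = "first")]
}
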