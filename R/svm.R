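# Small in-package SVM cores. No established SVM implementation ships
# with this environment, so two deterministic stand-ins are provided:
# a linear max-margin classifier trained on the squared hinge loss
# (weights used for recursive feature elimination), and a least-squares
# SVM with a Gaussian kernel exposing the usual (c, g) hyperparameters
# for the metaheuristic tuners.

#' Train a linear soft-margin classifier (squared hinge)
#'
#' Minimizes `lambda/2 ||w||^2 + mean(max(0, 1 - y f(x))^2)` with
#' `f(x) = x'w + b` by BFGS with analytic gradients. Deterministic.
#'
#' @param X Numeric feature matrix (n x d).
#' @param y Labels coercible to two classes; internally mapped to -1/+1
#'   in level order.
#' @param lambda L2 regularization strength, default 0.01.
#' @param maxit Optimizer iteration cap.
#' @return A `linear_svm`: `w`, `b`, `levels`.
#' @export
linear_svm <- function(X, y, lambda = 0.01, maxit = 200L) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("linear_svm requires exactly 2 classes")
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  n <- nrow(X); d <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    marg <- 1 - yy * (drop(X %*% w) + b)
    h <- pmax(0, marg)
    0.5 * lambda * sum(w^2) + mean(h^2)
  }
  grad <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    marg <- 1 - yy * (drop(X %*% w) + b)
    h <- pmax(0, marg)
    coefv <- -2 * yy * h / n
    c(lambda * w + drop(crossprod(X, coefv)), sum(coefv))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  structure(list(w = fit$par[seq_len(d)], b = fit$par[d + 1L], levels = lev),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  scores <- drop(as.matrix(newdata) %*% object$w) + object$b
  object$levels[ifelse(scores > 0, 2L, 1L)]
}

#' @keywords internal
#' @noRd
sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
}

#' Train a Gaussian-kernel support vector classifier (least-squares form)
#'
#' One-vs-rest least-squares SVM: per class, solve
#' `(K + I/c) a = y_pm` with `K_ij = exp(-g ||x_i - x_j||^2)` and +-1
#' targets; prediction is the arg-max class score. `c` plays the role of
#' the penalty parameter and `g` the kernel width parameter.
#'
#' @param X Feature matrix (n x d).
#' @param y Class labels.
#' @param c_penalty Penalty parameter c (> 0), default 10.
#' @param g_kernel Kernel parameter g (> 0), default 1 / d.
#' @return An `svc_rbf` model.
#' @export
svc_rbf <- function(X, y, c_penalty = 10, g_kernel = 1 / ncol(X)) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) < 2L) stop("need at least 2 classes")
  K <- exp(-g_kernel * sq_dist(X, X))
  A <- K + diag(1 / c_penalty + 1e-10, nrow(X))
  R <- chol(A)
  alphas <- vapply(lev, function(cl) {
    ypm <- ifelse(as.character(y) == cl, 1, -1)
    backsolve(R, forwardsolve(t(R), ypm))
  }, numeric(nrow(X)))
  structure(list(X = X, alphas = alphas, levels = lev,
                 c_penalty = c_penalty, g_kernel = g_kernel),
            class = "svc_rbf")
}

#' @export
predict.svc_rbf <- function(object, newdata, ...) {
  Kt <- exp(-object$g_kernel * sq_dist(as.matrix(newdata), object$X))
  scores <- Kt %*% object$alphas
  object$levels[max.col(scores, ties.method = "first")]
}
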