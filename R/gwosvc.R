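# Grey-wolf tuning of the Gaussian-kernel support vector classifier's
# penalty (c) and kernel (g) parameters over the usual log grid range
# 10^-3 .. 10^3, with inner cross-validated error as the fitness.

#' Tune a Gaussian-kernel SVC with the grey wolf optimizer
#'
#' Searches `log10(c)` and `log10(g)` in \[-3, 3\]; each wolf's fitness
#' is the stratified inner cross-validation error of an [svc_rbf()]
#' classifier at those parameters. The classifier is refit on all data
#' at the best parameters found.
#'
#' @param X Feature matrix (n x d).
#' @param y Class labels (>= 2 classes).
#' @param wolves Number of wolves, default 10.
#' @param iters Optimizer iterations, default 15.
#' @param folds Inner CV folds, default 3.
#' @param seed Seed (folds and wolves).
#' @return List with `model` (refit `svc_rbf`), `c_penalty`, `g_kernel`,
#'   `cv_error` and the optimizer `result`.
#' @export
gwo_svc_tune <- function(X, y, wolves = 10L, iters = 15L, folds = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  fold_id <- make_stratified_folds(y, folds, seed = split_seed(seed, 11L))
  fitness <- function(theta) {
    cp <- 10^theta[1]; gk <- 10^theta[2]
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      if (length(unique(y[tr])) < 2L) return(1)
      m <- svc_rbf(X[tr, , drop = FALSE], y[tr], c_penalty = cp, g_kernel = gk)
      mean(predict(m, X[te, , drop = FALSE]) != y[te])
    }, numeric(1))
    mean(errs)
  }
  obj <- objective_spec(fitness, dim = 2L, lower = -3, upper = 3)
  res <- gwo(obj, gwo_config(pop_size = wolves, max_iters = iters, seed = seed))
  cp <- 10^res$best_candidate[1]
  gk <- 10^res$best_candidate[2]
  list(model = svc_rbf(X, y, c_penalty = cp, g_kernel = gk),
       c_penalty = cp, g_kernel = gk, cv_error = res$best_fitness,
       result = res)
}
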