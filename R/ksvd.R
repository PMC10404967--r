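# Dictionary learning: orthogonal matching pursuit for the sparse-coding
# step and K-SVD (rank-1 SVD atom updates) for the dictionary step.

#' Orthogonal matching pursuit
#'
#' Greedy sparse coding of each column of `Z` over dictionary `D` with at
#' most `l0` nonzero coefficients per column.
#'
#' @param D Dictionary (d x m), unit-norm columns.
#' @param Z Data matrix (d x n) or vector.
#' @param l0 Sparsity bound (>= 1).
#' @return Coefficient matrix (m x n).
#' @export
omp_code <- function(D, Z, l0) {
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1)
  m <- ncol(D)
  C <- matrix(0, m, ncol(Z))
  l0 <- min(l0, m, nrow(D))
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    resid <- z
    support <- integer(0)
    for (s in seq_len(l0)) {
      corrs <- abs(crossprod(D, resid))
      corrs[support] <- -Inf
      k <- which.max(corrs)
      support <- c(support, k)
      Ds <- D[, support, drop = FALSE]
      coef <- tryCatch(qr.solve(Ds, z), error = function(e) drop(pinv(Ds) %*% z))
      resid <- z - drop(Ds %*% coef)
      if (sqrt(sum(resid^2)) < 1e-12) break
    }
    C[support, j] <- coef
  }
  C
}

#' K-SVD dictionary learning
#'
#' Alternates OMP sparse coding (at most `l0` nonzeros per column) with
#' sequential rank-1 SVD updates of each atom and its active
#' coefficients. Atoms are renormalized to unit norm every sweep; unused
#' atoms are reseeded from the worst-represented data column. The
#' Frobenius objective `||Z - DC||_F^2` is recorded after every
#' iteration and is guaranteed non-increasing: if a fresh OMP coding
#' would increase a column's residual, the previous coding of that
#' column is kept.
#'
#' @param Z Data matrix (d x n), columns are samples.
#' @param n_atoms Number of atoms (<= n).
#' @param l0 Sparsity bound.
#' @param iters Alternation sweeps, default 15.
#' @param seed Seed for the initial atom draw.
#' @return An `ksvd_dict`: `D` (unit-norm columns), `C`, `objective_trace`.
#' @export
ksvd <- function(Z, n_atoms, l0, iters = 15L, seed = 1L) {
  Z <- as.matrix(Z)
  n <- ncol(Z)
  if (n_atoms > n) stop("n_atoms must not exceed the number of samples")
  if (l0 < 1L) stop("l0 must be >= 1")
  with_seed(seed, {
    init_idx <- sample.int(n, n_atoms)
    D <- Z[, init_idx, drop = FALSE]
    nrm <- sqrt(colSums(D^2))
    nrm[nrm == 0] <- 1
    D <- sweep(D, 2, nrm, "/")
    C <- matrix(0, n_atoms, n)
    obj <- function(C_) sum((Z - D %*% C_)^2)
    trace <- numeric(iters)
    prev_obj <- Inf
    for (it in seq_len(iters)) {
      C_new <- omp_code(D, Z, l0)
      # per-column monotonicity safeguard
      old_res <- colSums((Z - D %*% C)^2)
      new_res <- colSums((Z - D %*% C_new)^2)
      worse <- new_res > old_res
      if (it > 1L && any(worse)) C_new[, worse] <- C[, worse]
      C <- C_new
      for (k in seq_len(n_atoms)) {
        using <- which(C[k, ] != 0)
        if (length(using) == 0L) {
          resid_norms <- colSums((Z - D %*% C)^2)
          j <- which.max(resid_norms)
          d_new <- Z[, j]
          if (sum(d_new^2) > 0) D[, k] <- d_new / sqrt(sum(d_new^2))
          next
        }
        Ek <- Z[, using, drop = FALSE] -
          D[, -k, drop = FALSE] %*% C[-k, using, drop = FALSE]
        sv <- svd(Ek, nu = 1, nv = 1)
        D[, k] <- sv$u[, 1]
        C[k, using] <- sv$d[1] * sv$v[, 1]
      }
      trace[it] <- obj(C)
      prev_obj <- trace[it]
    }
    structure(list(D = D, C = C, objective_trace = trace), class = "ksvd_dict")
  })
}

#' Learn a class-tagged sparse-representation dictionary
#'
#' Trains one K-SVD sub-dictionary per class on that class's samples and
#' concatenates them, keeping a class index per atom; the operating
#' per-class atom counts are the usual \{10, 20, 30, 40, 50\}.
#'
#' @param Z Data matrix (d x n).
#' @param labels Length-n class labels for the columns.
#' @param atoms_per_class Atoms per class (default 10); capped at each
#'   class's sample count.
#' @param l0 Sparsity bound, default 5.
#' @param iters K-SVD sweeps per class.
#' @param seed Seed.
#' @return An `src_dictionary`: `D`, `atom_classes`, `classes`, `l0`.
#' @export
src_dictionary <- function(Z, labels, atoms_per_class = 10L, l0 = 5L,
                           iters = 10L, seed = 1L) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  Ds <- list(); tags <- character(0)
  for (cl in classes) {
    Zc <- Z[, labels == cl, drop = FALSE]
    k <- min(atoms_per_class, ncol(Zc))
    if (k < 1L) stop(sprintf("class '%s' has no samples", cl))
    fit <- ksvd(Zc, n_atoms = k, l0 = min(l0, k), iters = iters,
                seed = split_seed(seed, match(cl, classes)))
    Ds[[cl]] <- fit$D
    tags <- c(tags, rep(cl, k))
  }
  structure(list(D = do.call(cbind, Ds), atom_classes = tags,
                 classes = classes, l0 = l0),
            class = "src_dictionary")
}

#' Classify by class-wise sparse-representation residual
#'
#' Solves the ridge-regularized code `a = (D'D + mu I)^{-1} D' z` and
#' assigns the class minimizing the normalized class residual
#' `||z - D a_i||^2 / ||a_i||^2`, where `a_i` keeps only the
#' coefficients of class-i atoms. Classes with an all-zero coefficient
#' block are skipped; if every class is skipped an error is raised.
#'
#' @param dict An `src_dictionary`.
#' @param z Query vector (same dimension as the atoms).
#' @param mu Ridge parameter (> 0), default 1.
#' @return The winning class label.
#' @export
src_classify <- function(dict, z, mu = 1) {
  if (mu <= 0) stop("mu must be > 0")
  D <- dict$D
  a <- drop(solve(crossprod(D) + diag(mu, ncol(D)), crossprod(D, z)))
  best <- NA_character_; best_val <- Inf
  for (cl in dict$classes) {
    sel <- dict$atom_classes == cl
    ai <- a[sel]
    nrm2 <- sum(ai^2)
    if (nrm2 == 0) next
    resid <- sum((z - drop(D[, sel, drop = FALSE] %*% ai))^2) / nrm2
    if (resid < best_val) { best_val <- resid; best <- cl }
  }
  if (is.na(best)) stop("all classes skipped (every class coefficient block is zero)")
  best
}
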