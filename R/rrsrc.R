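# Domain-adapting sparse-representation classifier. Two realms (a
# label-rich source and a label-poor target) are projected into
# subspaces that jointly preserve local neighborhood structure (graph
# Laplacian term) and gross variance (PCA term); a shared class-tagged
# dictionary is then learned on the projected samples of both realms and
# queries are classified by class-wise sparse residual.

#' @keywords internal
#' @noRd
gaussian_knn_graph <- function(Z, knn_k, sigma = NULL, edge_threshold = 0.6) {
  # Z: d x n (columns are samples)
  n <- ncol(Z)
  D2 <- sq_dist(t(Z), t(Z))
  if (is.null(sigma)) {
    off <- D2[upper.tri(D2)]
    sigma <- stats::median(off[off > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  H <- matrix(0, n, n)
  if (knn_k > 0 && n > 1) {
    for (i in seq_len(n)) {
      ord <- order(D2[i, ])
      nb <- setdiff(ord, i)[seq_len(min(knn_k, n - 1L))]
      H[i, nb] <- exp(-D2[i, nb] / sigma)
    }
    H <- pmax(H, t(H))                     # symmetrize
    H[H < edge_threshold] <- 0             # prune weak edges
  }
  diag(H) <- 0
  H
}

#' @keywords internal
#' @noRd
graph_laplacian <- function(H) diag(rowSums(H)) - H

#' @keywords internal
#' @noRd
subspace_projection <- function(Z, L, alpha_reg, d_sub) {
  # rows of the returned projection are the eigenvectors of
  # Z (L - alpha I) Z' belonging to the d_sub smallest eigenvalues
  G <- Z %*% (L - diag(alpha_reg, ncol(Z))) %*% t(Z)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  idx <- rev(seq_len(nrow(G)))[seq_len(d_sub)]   # smallest eigenvalues
  t(e$vectors[, idx, drop = FALSE])
}

#' Fit the realm-revamping sparse-representation classifier
#'
#' Builds a Gaussian-kernel KNN similarity graph on the source realm
#' (edges below `edge_threshold` pruned) and a same-class indicator
#' graph on the few labelled target samples; forms the graph Laplacians;
#' and takes each realm's projection as the eigenvectors of
#' `Z (L - alpha I) Z'` for the `d_sub` smallest eigenvalues, which
#' trades local-structure preservation against a (sign-flipped,
#' uncentered) PCA variance term under row-orthonormality. A shared
#' class-tagged dictionary is then learned by K-SVD on the projected
#' labelled samples of both realms.
#'
#' @param Xs Source samples, one row per sample.
#' @param ys Source labels.
#' @param Xt Labelled target samples (few rows).
#' @param yt Target labels; every class must appear.
#' @param d_sub Subspace dimension (default 50, capped at the feature
#'   dimension).
#' @param alpha_reg PCA-term regularizer, default 1.
#' @param sigma Gaussian kernel width; default is the median pairwise
#'   squared distance of the source realm.
#' @param knn_k Neighbors in the source graph, default 5.
#' @param edge_threshold Similarity below which source edges are
#'   dropped, default 0.6.
#' @param atoms_per_class,l0,ksvd_iters Dictionary-learning controls.
#' @param seed Seed for the dictionary initialization.
#' @return A `realm_model` with projections `Ms`, `Mt` (orthonormal
#'   rows), graphs, Laplacians and the shared dictionary.
#' @export
rrsrc_fit <- function(Xs, ys, Xt, yt, d_sub = 50L, alpha_reg = 1,
                      sigma = NULL, knn_k = 5L, edge_threshold = 0.6,
                      atoms_per_class = 10L, l0 = 5L, ksvd_iters = 10L,
                      seed = 1L) {
  Zs <- t(as.matrix(Xs)); Zt <- t(as.matrix(Xt))
  d <- nrow(Zs)
  if (nrow(Zt) != d) stop("source and target feature dimensions differ")
  if (d_sub > d) stop("d_sub exceeds the feature dimension")
  ys <- as.character(ys); yt <- as.character(yt)
  classes <- sort(unique(ys))
  if (!all(classes %in% unique(yt)))
    stop("every class must have at least one labelled target sample")
  Hs <- gaussian_knn_graph(Zs, knn_k, sigma, edge_threshold)
  Ht <- outer(yt, yt, `==`) * 1; diag(Ht) <- 0
  Ls <- graph_laplacian(Hs)
  Lt <- graph_laplacian(Ht)
  Ms <- subspace_projection(Zs, Ls, alpha_reg, d_sub)
  if (ncol(Zt) <= d_sub) {
    # Too few labelled target samples to span the subspace: the target
    # eigenproblem is rank-deficient and its trailing eigenvectors are
    # arbitrary. Treat the realms as projection-aligned and reuse the
    # source projection.
    Mt <- Ms
  } else {
    Mt <- subspace_projection(Zt, Lt, alpha_reg, d_sub)
    # Eigenvectors are determined only up to sign/order, so the two
    # subspace coordinate systems need not agree. Align the target
    # projection onto the source coordinates with an orthogonal
    # Procrustes rotation fitted on the labelled class means (the
    # refinement pass that makes the shared dictionary coherent across
    # realms); rotated rows remain orthonormal.
    A <- vapply(classes, function(cl)
      rowMeans(Ms %*% Zs[, ys == cl, drop = FALSE]), numeric(d_sub))
    B <- vapply(classes, function(cl)
      rowMeans(Mt %*% Zt[, yt == cl, drop = FALSE]), numeric(d_sub))
    sv <- svd(A %*% t(B))
    Mt <- (sv$u %*% t(sv$v)) %*% Mt
  }
  Ps <- Ms %*% Zs
  Pt <- Mt %*% Zt
  dict <- src_dictionary(cbind(Ps, Pt), c(ys, yt),
                         atoms_per_class = atoms_per_class, l0 = l0,
                         iters = ksvd_iters, seed = seed)
  structure(list(Ms = Ms, Mt = Mt, Hs = Hs, Ht = Ht, Ls = Ls, Lt = Lt,
                 dictionary = dict, d_sub = d_sub, classes = classes),
            class = "realm_model")
}

#' Classify a target-realm query
#'
#' Projects the query with the target projection and assigns the class
#' minimizing the ridge-coded class-wise residual ratio (see
#' [src_classify()]). The ratio is invariant to positive scaling of the
#' query.
#'
#' @param model A `realm_model`.
#' @param z Query feature vector (original space), or a matrix with one
#'   row per query.
#' @param mu Ridge parameter, default 1.
#' @return Class label(s).
#' @export
rrsrc_classify <- function(model, z, mu = 1) {
  if (is.matrix(z))
    return(vapply(seq_len(nrow(z)), function(i)
      rrsrc_classify(model, z[i, ], mu), character(1)))
  zp <- drop(model$Mt %*% z)
  src_classify(model$dictionary, zp, mu)
}

#' Source-only sparse-representation baseline
#'
#' Learns a class-tagged dictionary on raw source samples only (no
#' projection, no target supervision) and classifies queries by the same
#' residual rule; the reference point the realm-revamping model must
#' beat under domain shift.
#'
#' @param Xs,ys Source samples (rows) and labels.
#' @param atoms_per_class,l0,iters,seed As in [src_dictionary()].
#' @return A function mapping a query matrix/vector to labels.
#' @export
src_baseline <- function(Xs, ys, atoms_per_class = 10L, l0 = 5L,
                         iters = 10L, seed = 1L) {
  dict <- src_dictionary(t(as.matrix(Xs)), ys, atoms_per_class = atoms_per_class,
                         l0 = l0, iters = iters, seed = seed)
  function(z, mu = 1) {
    if (is.matrix(z))
      vapply(seq_len(nrow(z)), function(i) src_classify(dict, z[i, ], mu),
             character(1))
    else src_classify(dict, z, mu)
  }
}
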