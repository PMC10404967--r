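# Extreme learning machine, dictionary learning / sparse-representation
# classification, domain adaptation, sparse autoencoder, tuned SVC, and
# the evaluation metrics.

make_blobs <- function(n_per, seed, sep = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

test_that("ELM interpolates exactly when hidden count reaches sample count", {
  set.seed(13)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- sample(c("a", "b", "c"), 40, replace = TRUE)
  m <- elm_train(X, y, L = 40, seed = 2)
  S <- elm_predict(m, X, type = "score")
  expect_lt(mean((S - respsound:::one_hot(y, m$levels))^2), 1e-6)
  expect_equal(elm_predict(m, X), y)
})

test_that("ELM separates well-spaced blobs and is deterministic", {
  tr <- make_blobs(50, 14); te <- make_blobs(30, 15)
  m <- elm_train(tr$X, tr$y, L = 30, seed = 7)
  expect_gte(mean(elm_predict(m, tr$X) == tr$y), 0.99)
  expect_gte(mean(elm_predict(m, te$X) == te$y), 0.95)
  m2 <- elm_train(tr$X, tr$y, L = 30, seed = 7)
  expect_identical(m$beta, m2$beta)
  # scores are linear in beta
  m3 <- m; m3$beta <- 2 * m$beta
  expect_equal(elm_predict(m3, te$X, type = "score"),
               2 * elm_predict(m, te$X, type = "score"))
  expect_error(elm_predict(m, te$X[, 1, drop = FALSE]), "dimension mismatch")
  expect_error(elm_train(tr$X, tr$y, L = 0), "L must be")
})

test_that("ELM training error never worsens as neurons are appended", {
  set.seed(16)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- ifelse(X[, 1] + X[, 2] > 0, "a", "b")
  Tm <- respsound:::one_hot(y, c("a", "b"))
  errs <- vapply(c(5, 10, 20, 40), function(L) {
    # nested weight sets: same seed draws a prefix-stable random layer?
    # draw the largest layer once and truncate for nesting
    full <- respsound:::with_seed(99, list(
      w = matrix(stats::runif(40 * 4, -1, 1), 40, 4),
      b = stats::runif(40, -1, 1)))
    H <- respsound:::sigmoid(tcrossprod(X, full$w[1:L, , drop = FALSE]) +
                               matrix(full$b[1:L], 60, L, byrow = TRUE))
    beta <- respsound:::pinv(H) %*% Tm
    mean((H %*% beta - Tm)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("K-SVD recovers a planted dictionary with a monotone objective", {
  set.seed(17)
  d <- 15; m <- 20; n <- 600
  D0 <- matrix(rnorm(d * m), d, m)
  D0 <- sweep(D0, 2, sqrt(colSums(D0^2)), "/")
  C0 <- matrix(0, m, n)
  for (j in 1:n) C0[sample(m, 3), j] <- rnorm(3)
  fit <- ksvd(D0 %*% C0, n_atoms = m, l0 = 3, iters = 25, seed = 2)
  expect_false(is.unsorted(rev(fit$objective_trace)))
  expect_equal(max(abs(sqrt(colSums(fit$D^2)) - 1)), 0, tolerance = 1e-12)
  recov <- mean(apply(abs(crossprod(fit$D, D0)), 2, max) > 0.95)
  expect_gte(recov, 0.8)
})

test_that("K-SVD limits: square dictionary with full sparsity reconstructs exactly", {
  set.seed(18)
  Z <- matrix(rnorm(5 * 30), 5, 30)
  fit <- ksvd(Z, n_atoms = 5, l0 = 5, iters = 5, seed = 1)
  expect_lt(tail(fit$objective_trace, 1), 1e-12)
  expect_error(ksvd(Z, n_atoms = 31, l0 = 2), "exceed")
  expect_error(ksvd(Z, n_atoms = 5, l0 = 0), "l0")
})

test_that("sparse-representation classifier basics", {
  set.seed(19)
  X <- rbind(matrix(rnorm(30 * 6, 0), 30, 6), matrix(rnorm(30 * 6, 4), 30, 6))
  y <- rep(c("a", "b"), each = 30)
  dict <- src_dictionary(t(X), y, atoms_per_class = 5, l0 = 3, seed = 2)
  expect_equal(length(dict$atom_classes), 10)
  # an atom's pre-image classifies to its own class at small mu
  expect_equal(src_classify(dict, dict$D[, 1], mu = 1e-8), dict$atom_classes[1])
  # ridge shrinks the code toward zero as mu grows
  z <- X[1, ]
  n2 <- function(mu) sum(drop(solve(crossprod(dict$D) + diag(mu, 10),
                                    crossprod(dict$D, z)))^2)
  expect_gt(n2(1e-3), n2(1e3))
  expect_error(src_classify(dict, numeric(6)), "skipped")
  expect_error(src_classify(dict, z, mu = 0), "mu must be")
})

test_that("realm model: orthonormal projections, zero-sum Laplacians, scaling invariance", {
  src <- make_realm_data(30, 21)
  tgt <- make_realm_data(3, 22, rotate = 30, shift = 0.8)
  m <- rrsrc_fit(src$X, src$y, tgt$X, tgt$y, d_sub = 5, atoms_per_class = 8,
                 l0 = 4, seed = 1)
  expect_equal(max(abs(m$Ms %*% t(m$Ms) - diag(5))), 0, tolerance = 1e-8)
  expect_equal(max(abs(m$Mt %*% t(m$Mt) - diag(5))), 0, tolerance = 1e-8)
  expect_equal(max(abs(rowSums(m$Ls))), 0, tolerance = 1e-10)
  expect_equal(max(abs(rowSums(m$Lt))), 0, tolerance = 1e-10)
  q <- make_realm_data(5, 23, rotate = 30, shift = 0.8)$X
  expect_identical(rrsrc_classify(m, q), rrsrc_classify(m, 7.3 * q))
  expect_error(rrsrc_fit(src$X, src$y, tgt$X, tgt$y, d_sub = 99), "exceeds")
  expect_error(rrsrc_fit(src$X, src$y, tgt$X[tgt$y != "a", ],
                         tgt$y[tgt$y != "a"], d_sub = 5), "every class")
})

test_that("with no graph edges the source projection reduces to (uncentered) PCA", {
  set.seed(24)
  Xs <- matrix(rnorm(40 * 8), 40, 8) %*% diag(c(5, 4, 3, 2, rep(0.2, 4)))
  ys <- rep(c("a", "b"), 20)
  tgt <- list(X = Xs[1:10, ], y = ys[1:10])
  m <- rrsrc_fit(Xs, ys, tgt$X, tgt$y, d_sub = 3, knn_k = 0, alpha_reg = 1)
  pca <- svd(t(Xs))$u[, 1:3]
  # subspace angle: projections onto each other's span
  P1 <- t(m$Ms) %*% m$Ms
  P2 <- pca %*% t(pca)
  expect_lt(max(abs(P1 - P2)), 1e-6)
})

test_that("realm revamping beats the source-only baseline under domain shift", {
  src <- make_realm_data(40, 31)
  tgt_l <- make_realm_data(3, 131, rotate = 30, shift = 0.8)
  tgt_te <- make_realm_data(25, 231, rotate = 30, shift = 0.8)
  m <- rrsrc_fit(src$X, src$y, tgt_l$X, tgt_l$y, d_sub = 5, atoms_per_class = 8,
                 l0 = 4, seed = 31)
  acc <- mean(rrsrc_classify(m, tgt_te$X) == tgt_te$y)
  base <- src_baseline(src$X, src$y, atoms_per_class = 8, l0 = 4, seed = 31)
  acc_base <- mean(base(tgt_te$X) == tgt_te$y)
  expect_gt(acc, acc_base)
})

test_that("sparse autoencoder: KL identity, descent, and improvement over init", {
  expect_equal(kl_sparsity(0.05, 0.05), 0)
  expect_gt(kl_sparsity(0.05, 0.3), 0)
  set.seed(25)
  X <- matrix(runif(80 * 12), 80, 12)
  cfg <- sae_config(hidden = 8, epochs = 40, batch = 16, seed = 2)
  m <- sae_train(X, cfg)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[2])       # later < first epoch
  rec_err <- mean((sae_reconstruct(m, X) - X)^2)
  init <- respsound:::sae_init(12, 8, 2)
  rec_err0 <- mean((respsound:::sae_forward(init, X)$out - X)^2)
  expect_lt(rec_err, rec_err0)
  H <- sae_encode(m, X)
  expect_true(all(H > 0 & H < 1))
  expect_error(sae_config(rho = 1.5), "rho")
  expect_error(sae_train(X * 3, cfg), "\\[0, 1\\]")
})

test_that("the sparsity penalty keeps the total objective above the reconstruction term", {
  set.seed(26)
  X <- matrix(runif(40 * 6), 40, 6)
  m <- sae_train(X, sae_config(hidden = 5, epochs = 10, batch = 20, seed = 3))
  rec <- 0.5 * mean(rowSums((sae_reconstruct(m, X) - X)^2))
  expect_gte(tail(m$loss_trace, 1), rec - 1e-12)
})

test_that("grey-wolf tuned SVC solves concentric circles where a linear rule cannot", {
  set.seed(27)
  n <- 100
  r1 <- runif(n, 0, 1); r2 <- runif(n, 2, 3)
  th <- runif(2 * n, 0, 2 * pi)
  X <- cbind(c(r1, r2) * cos(th), c(r1, r2) * sin(th))
  y <- rep(c("in", "out"), each = n)
  tuned <- gwo_svc_tune(X, y, wolves = 6, iters = 8, seed = 4)
  expect_gte(mean(predict(tuned$model, X) == y), 0.95)
  expect_true(tuned$c_penalty >= 1e-3 && tuned$c_penalty <= 1e3)
  expect_true(tuned$g_kernel >= 1e-3 && tuned$g_kernel <= 1e3)
  lin <- linear_svm(X, y)
  expect_lte(mean(predict(lin, X) == y), 0.6)
  tuned2 <- gwo_svc_tune(X, y, wolves = 6, iters = 8, seed = 4)
  expect_identical(c(tuned$c_penalty, tuned$g_kernel),
                   c(tuned2$c_penalty, tuned2$g_kernel))
})

test_that("metrics match hand-computed confusion tables", {
  expect_equal(unname(confusion_metrics(50, 40, 5, 5)),
               c(100 * 50 / 55, 100 * 40 / 45, 90))
  y <- rep(c("normal", "abnormal"), each = 10)
  perfect <- compute_metrics(y, y, c("normal", "abnormal"))
  expect_equal(unname(perfect$macro), c(100, 100, 100))
  expect_equal(perfect$overall_accuracy, 100)
  # all-positive predictor on a balanced binary set
  allpos <- compute_metrics(y, rep("abnormal", 20), c("normal", "abnormal"))
  row <- allpos$per_class[allpos$per_class$class == "abnormal", ]
  expect_equal(row$sensitivity, 100)
  expect_equal(row$specificity, 0)
  expect_equal(row$accuracy, 50)
  expect_equal(allpos$overall_accuracy, 50)
})

test_that("per-class confusion tables always sum to n", {
  set.seed(28)
  classes <- c("a", "b", "c")
  for (i in 1:5) {
    yt <- sample(classes, 40, replace = TRUE)
    yp <- sample(classes, 40, replace = TRUE)
    rep_ <- compute_metrics(yt, yp, classes)
    expect_true(all(rowSums(rep_$per_class[, c("TP", "TN", "FP", "FN")]) == 40))
    expect_equal(rep_$overall_accuracy, 100 * mean(yt == yp))
  }
  expect_error(compute_metrics(character(0), character(0), classes), "empty")
  expect_error(compute_metrics(c("a", "x"), c("a", "a"), classes), "outside")
})
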