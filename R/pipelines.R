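# End-to-end strategy pipelines under stratified cross-validation. Every
# label-dependent stage (scaling statistics, feature selection, mode
# number selection, metaheuristic fitness, classifier training) is fit
# on the training rows of each fold only; per-cycle feature extraction
# is unsupervised and sample-local, so it is computed once and shared
# across folds (and across a run and its label-permuted control) through
# an optional cache environment.

#' Configure a classification strategy pipeline
#'
#' Six strategies are available:
#' * `gssr`: ensemble-EMD + autoregressive features, SVM-based recursive
#'   feature elimination, KNN classifier;
#' * `rrsrc`: the same features, realm split of the training fold,
#'   domain-adapting sparse-representation classifier;
#' * `dmvmd_elm`: min-max normalization, distance-metric VMD mode-number
#'   selection on training cycles, per-mode descriptors, extreme
#'   learning machine with three-stage residual error compensation;
#' * `hho_sfpde`: binary feature-mask search by the nested hawks-over-DE
#'   tuner with inner-CV error fitness, then a KNN classifier;
#' * `dr_gwo_svc`: PCA reduction then a grey-wolf tuned Gaussian SVC;
#' * `dr_goa_sae`: grasshopper feature-mask selection, sparse
#'   autoencoder encoding, ridge linear head.
#'
#' Desk-scale defaults (ensemble size, optimizer budgets, epochs) are
#' deliberately smaller than the published full-data settings so a run
#' completes in minutes; each can be overridden through `opts`.
#'
#' @param strategy One of the six names above.
#' @param scheme A [label_scheme()].
#' @param cv_folds Folds, default 10.
#' @param seed Master seed.
#' @param opts Named list of strategy options overriding the defaults
#'   (see Details in the vignette).
#' @return A `strategy_config`.
#' @export
strategy_config <- function(strategy = c("gssr", "rrsrc", "dmvmd_elm",
                                         "hho_sfpde", "dr_gwo_svc", "dr_goa_sae"),
                            scheme = label_scheme("three_class"),
                            cv_folds = 10L, seed = 1L, opts = list()) {
  strategy <- match.arg(strategy)
  defaults <- list(
    # shared feature extraction (strategies other than dmvmd_elm)
    seemd_q = 3L, seemd_noise = 0.4, max_imfs = 6L, n_modes = 4L,
    mvar_order = 2L,
    # gssr
    rfe_keep = 30L, rfe_per_round = 5L, knn_k = 5L,
    # rrsrc
    d_sub = 20L, alpha_reg = 1, knn_graph_k = 5L, edge_threshold = 0.6,
    atoms_per_class = 10L, l0 = 5L, src_mu = 1, target_per_class = 3L,
    # dmvmd_elm
    dm_metric = "manhattan", dm_threshold = 0.99, dm_kmax = 6L,
    vmd_alpha = 300, vmd_tau = 0.5, vmd_tol = 1e-3, vmd_iters = 120L,
    dm_select_n = 3L, elm_hidden = 30L,
    # hho_sfpde
    hho_hawks = 3L, hho_iters = 2L, de_np = 8L, de_iters = 5L,
    # dr_gwo_svc
    dr_dim = 10L, gwo_wolves = 6L, gwo_iters = 8L,
    # dr_goa_sae
    goa_agents = 10L, goa_iters = 10L, sae_hidden = 24L, sae_epochs = 60L)
  defaults[names(opts)] <- opts
  structure(list(strategy = strategy, scheme = scheme,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 opts = defaults),
            class = "strategy_config")
}

#' @keywords internal
#' @noRd
get_cached <- function(cache, key, compute) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  val <- compute()
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# Common length for a dataset: the minimum cycle length, so truncation
# never pads silence into the features.
#' @keywords internal
#' @noRd
dataset_matrix <- function(dataset) {
  n_min <- min(vapply(dataset, function(cy) length(cy$signal$samples), integer(1)))
  t(vapply(dataset, function(cy) cy$signal$samples[seq_len(n_min)],
           numeric(n_min)))
}

#' @keywords internal
#' @noRd
gssr_feature_matrix <- function(dataset, config, cache = NULL) {
  o <- config$opts
  key <- sprintf("gssr_q%d_m%d_l%d", o$seemd_q, o$n_modes, o$mvar_order)
  get_cached(cache, key, function() {
    rows <- lapply(seq_along(dataset), function(i) {
      cfg <- seemd_config(noise_std_fraction = o$seemd_noise,
                          ensemble_size = o$seemd_q,
                          seed = split_seed(config$seed, 500000L + i),
                          max_imfs = o$max_imfs)
      ensemble_gssr_features(dataset[[i]], cfg, mvar_order = o$mvar_order,
                             n_modes = o$n_modes)
    })
    do.call(rbind, rows)
  })
}

#' @keywords internal
#' @noRd
vmd_feature_matrix <- function(dataset, K, config, cache = NULL) {
  o <- config$opts
  key <- sprintf("vmdfeat_K%d", K)
  get_cached(cache, key, function() {
    cfg <- vmd_config(K = K, alpha = o$vmd_alpha, tau = o$vmd_tau,
                      tol = o$vmd_tol, max_iters = o$vmd_iters)
    rows <- lapply(dataset, function(cy) {
      sig <- normalize_minmax(cy$signal)
      res <- vmd(sig, cfg)
      imf_features(res)
    })
    do.call(rbind, rows)
  })
}

#' @keywords internal
#' @noRd
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

#' @keywords internal
#' @noRd
zscore_apply <- function(sc, X) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Run a strategy pipeline under stratified cross-validation
#'
#' @param dataset List of labelled cycles (e.g. from
#'   [synthesize_dataset()] or [segment_cycles()]); every class needs at
#'   least `cv_folds` members.
#' @param config A [strategy_config()].
#' @param cache Optional environment reusing per-cycle decompositions
#'   across calls (features are label-independent, so a run and its
#'   permuted-label control can share one cache).
#' @param labels Optional label override (e.g. permuted labels for a
#'   null control); defaults to the dataset's own labels.
#' @return A `cv_result` with an added `config` snapshot.
#' @export
run_strategy <- function(dataset, config, cache = NULL, labels = NULL) {
  stopifnot(inherits(config, "strategy_config"))
  if (is.null(labels)) labels <- cycle_labels(dataset)
  labels <- as.character(labels)
  classes <- config$scheme$classes
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop("dataset labels outside the scheme: ", paste(bad, collapse = ", "))
  fold_id <- make_stratified_folds(labels, config$cv_folds,
                                   seed = split_seed(config$seed, 1L))
  fit_fold <- switch(config$strategy,
    gssr = fold_gssr, rrsrc = fold_rrsrc, dmvmd_elm = fold_dmvmd_elm,
    hho_sfpde = fold_hho_sfpde, dr_gwo_svc = fold_dr_gwo_svc,
    dr_goa_sae = fold_dr_goa_sae)
  per_fold <- vector("list", config$cv_folds)
  preds <- character(length(labels))
  for (f in seq_len(config$cv_folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    p <- fit_fold(dataset, labels, tr, te, config, cache, fold = f)
    preds[te] <- p
    per_fold[[f]] <- compute_metrics(labels[te], p, classes)
  }
  out <- aggregate_cv(per_fold, fold_id, preds)
  out$config <- config
  out
}

#' @keywords internal
#' @noRd
fold_gssr <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  X <- gssr_feature_matrix(dataset, config, cache)
  sc <- zscore_fit(X[tr, , drop = FALSE])
  Xtr <- zscore_apply(sc, X[tr, , drop = FALSE])
  Xte <- zscore_apply(sc, X[te, , drop = FALSE])
  rk <- svm_rfe(Xtr, labels[tr], eliminate_per_round = o$rfe_per_round)
  keep <- rk$ranked_indices[seq_len(min(o$rfe_keep, ncol(X)))]
  p <- FNN::knn(Xtr[, keep, drop = FALSE], Xte[, keep, drop = FALSE],
                factor(labels[tr]), k = o$knn_k)
  as.character(p)
}

#' @keywords internal
#' @noRd
fold_rrsrc <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  X <- gssr_feature_matrix(dataset, config, cache)
  sc <- zscore_fit(X[tr, , drop = FALSE])
  Xtr <- zscore_apply(sc, X[tr, , drop = FALSE])
  Xte <- zscore_apply(sc, X[te, , drop = FALSE])
  ytr <- labels[tr]
  # realm split of the training fold: 70% source, a few labelled target
  # cycles per class from the remainder
  src_idx <- integer(0); tgt_idx <- integer(0)
  with_seed(split_seed(config$seed, 9000L + fold), {
    for (cl in unique(ytr)) {
      idx <- sample(which(ytr == cl))
      n_src <- max(1L, floor(0.7 * length(idx)))
      src_idx <- c(src_idx, idx[seq_len(n_src)])
      rest <- idx[-seq_len(n_src)]
      tgt_idx <- c(tgt_idx, rest[seq_len(min(o$target_per_class, length(rest)))])
    }
  })
  model <- rrsrc_fit(Xtr[src_idx, , drop = FALSE], ytr[src_idx],
                     Xtr[tgt_idx, , drop = FALSE], ytr[tgt_idx],
                     d_sub = min(o$d_sub, ncol(X)), alpha_reg = o$alpha_reg,
                     knn_k = o$knn_graph_k, edge_threshold = o$edge_threshold,
                     atoms_per_class = o$atoms_per_class, l0 = o$l0,
                     seed = split_seed(config$seed, 9100L + fold))
  rrsrc_classify(model, Xte, mu = o$src_mu)
}

#' @keywords internal
#' @noRd
fold_dmvmd_elm <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  # mode number selected on a seeded handful of training cycles only
  sel_idx <- with_seed(split_seed(config$seed, 9200L + fold),
                       sample(tr, min(o$dm_select_n, length(tr))))
  vcfg <- vmd_config(K = 2L, alpha = o$vmd_alpha, tau = o$vmd_tau,
                     tol = o$vmd_tol, max_iters = o$vmd_iters)
  Ks <- vapply(sel_idx, function(i) {
    sel <- select_vmd_modes(normalize_minmax(dataset[[i]]$signal),
                            metric = o$dm_metric, threshold = o$dm_threshold,
                            K_max = o$dm_kmax, vmd_cfg = vcfg)
    sel$K_selected
  }, numeric(1))
  K <- as.integer(round(stats::median(Ks)))
  X <- vmd_feature_matrix(dataset, K, config, cache)
  sc <- zscore_fit(X[tr, , drop = FALSE])
  Xtr <- zscore_apply(sc, X[tr, , drop = FALSE])
  Xte <- zscore_apply(sc, X[te, , drop = FALSE])
  lev <- sort(unique(labels[tr]))
  Tm <- one_hot(labels[tr], lev)
  # base learner plus three residual-compensation stages
  base <- elm_train(Xtr, labels[tr], L = o$elm_hidden,
                    seed = split_seed(config$seed, 9300L + fold))
  Str <- elm_scores(base, Xtr)
  Ste <- elm_scores(base, Xte)
  resid <- Tm[, base$levels, drop = FALSE] - Str
  for (stage in 1:3) {
    em <- elm_regress(Xtr, resid, L = o$elm_hidden,
                      seed = split_seed(config$seed, 9300L + 10L * stage + fold))
    Etr <- elm_scores(em, Xtr)
    Str <- Str + Etr
    Ste <- Ste + elm_scores(em, Xte)
    resid <- resid - Etr
  }
  base$levels[max.col(Ste, ties.method = "first")]
}

#' @keywords internal
#' @noRd
fold_hho_sfpde <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  X <- gssr_feature_matrix(dataset, config, cache)
  sc <- zscore_fit(X[tr, , drop = FALSE])
  Xtr <- zscore_apply(sc, X[tr, , drop = FALSE])
  Xte <- zscore_apply(sc, X[te, , drop = FALSE])
  ytr <- labels[tr]
  memo <- new.env(parent = emptyenv())
  inner_folds <- make_stratified_folds(ytr, 3L,
                                       seed = split_seed(config$seed, 9400L + fold))
  fitness <- function(bits) {
    key <- paste(as.integer(bits > 0.5), collapse = "")
    if (!is.null(memo[[key]])) return(memo[[key]])
    cols <- which(bits > 0.5)
    val <- knn_cv_error(Xtr, ytr, cols, k = o$knn_k, fold_id = inner_folds)
    memo[[key]] <- val
    val
  }
  obj <- objective_spec(fitness, dim = ncol(X), lower = -2, upper = 2)
  res <- hho_sfpde(
    obj,
    outer = hho_config(pop_size = o$hho_hawks, max_iters = o$hho_iters,
                       seed = split_seed(config$seed, 9500L + fold)),
    inner = sfpde_config(pop_size = o$de_np, max_iters = o$de_iters,
                         binary = TRUE, stall_patience = Inf))
  cols <- which(res$best_candidate > 0.5)
  if (length(cols) == 0L) cols <- seq_len(ncol(X))
  p <- FNN::knn(Xtr[, cols, drop = FALSE], Xte[, cols, drop = FALSE],
                factor(ytr), k = o$knn_k)
  as.character(p)
}

#' @keywords internal
#' @noRd
fold_dr_gwo_svc <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  X <- gssr_feature_matrix(dataset, config, cache)
  sc <- zscore_fit(X[tr, , drop = FALSE])
  Xtr <- zscore_apply(sc, X[tr, , drop = FALSE])
  Xte <- zscore_apply(sc, X[te, , drop = FALSE])
  # delegated linear reduction fit on the training fold
  pc <- stats::prcomp(Xtr, center = FALSE, rank. = min(o$dr_dim, ncol(X)))
  Ztr <- Xtr %*% pc$rotation
  Zte <- Xte %*% pc$rotation
  tuned <- gwo_svc_tune(Ztr, labels[tr], wolves = o$gwo_wolves,
                        iters = o$gwo_iters, folds = 3L,
                        seed = split_seed(config$seed, 9600L + fold))
  as.character(predict(tuned$model, Zte))
}

#' @keywords internal
#' @noRd
fold_dr_goa_sae <- function(dataset, labels, tr, te, config, cache, fold) {
  o <- config$opts
  X <- gssr_feature_matrix(dataset, config, cache)
  ytr <- labels[tr]
  # [0, 1] scaling from training statistics (autoencoder input range)
  lo <- apply(X[tr, , drop = FALSE], 2, min)
  hi <- apply(X[tr, , drop = FALSE], 2, max)
  hi[hi == lo] <- lo[hi == lo] + 1
  unit <- function(M) pmin(pmax(sweep(sweep(M, 2, lo), 2, hi - lo, "/"), 0), 1)
  Xtr <- unit(X[tr, , drop = FALSE])
  Xte <- unit(X[te, , drop = FALSE])
  fitness <- function(bits) {
    cols <- which(bits > 0.5)
    if (length(cols) == 0L) return(1)
    fid <- make_stratified_folds(ytr, 3L, seed = split_seed(config$seed, 9700L + fold))
    errs <- vapply(1:3, function(f2) {
      trr <- fid != f2
      hd <- ridge_head_fit(Xtr[trr, cols, drop = FALSE], ytr[trr])
      mean(ridge_head_predict(hd, Xtr[!trr, cols, drop = FALSE]) != ytr[!trr])
    }, numeric(1))
    mean(errs)
  }
  obj <- objective_spec(function(x) fitness(binarize(x)), dim = ncol(X),
                        lower = -2, upper = 2)
  res <- goa(obj, goa_config(pop_size = o$goa_agents, max_iters = o$goa_iters,
                             seed = split_seed(config$seed, 9800L + fold)))
  cols <- which(with_seed(split_seed(config$seed, 9850L + fold),
                          binarize(res$best_candidate)) > 0.5)
  if (length(cols) == 0L) cols <- seq_len(ncol(X))
  sae <- sae_train(Xtr[, cols, drop = FALSE],
                   sae_config(hidden = o$sae_hidden, epochs = o$sae_epochs,
                              seed = split_seed(config$seed, 9900L + fold)))
  Htr <- sae_encode(sae, Xtr[, cols, drop = FALSE])
  Hte <- sae_encode(sae, Xte[, cols, drop = FALSE])
  head_model <- ridge_head_fit(cbind(Htr, Xtr[, cols, drop = FALSE]), ytr)
  ridge_head_predict(head_model, cbind(Hte, Xte[, cols, drop = FALSE]))
}
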