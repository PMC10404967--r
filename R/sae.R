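# Sparse autoencoder: one sigmoid hidden layer whose mean activations
# are pulled toward a small sparsity target by a KL-divergence penalty,
# trained by minibatch gradient descent. The output layer uses a ReLU
# activation (inputs are expected in [0, 1]).

#' Kullback-Leibler sparsity divergence
#'
#' `KL(rho || rho_hat) = rho log(rho/rho_hat) +
#' (1 - rho) log((1 - rho)/(1 - rho_hat))`, zero iff `rho_hat == rho`.
#'
#' @param rho Sparsity target in (0, 1).
#' @param rho_hat Mean activation(s) in (0, 1).
#' @return Elementwise KL divergence.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse autoencoder configuration
#'
#' @param hidden Hidden units, default 32.
#' @param rho Sparsity target in (0, 1), default 0.05.
#' @param beta_sp Weight of the KL sparsity penalty, default 0.1.
#' @param eta Learning rate, default 0.04.
#' @param epochs Training epochs, default 200.
#' @param batch Minibatch size, default 64.
#' @param seed Seed for initialization and batch shuffling.
#' @return An `sae_config` list.
#' @export
sae_config <- function(hidden = 32L, rho = 0.05, beta_sp = 0.1, eta = 0.04,
                       epochs = 200L, batch = 64L, seed = 1L) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)")
  structure(list(hidden = as.integer(hidden), rho = rho, beta_sp = beta_sp,
                 eta = eta, epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed)),
            class = "sae_config")
}

#' @keywords internal
#' @noRd
sae_init <- function(d, hidden, seed) {
  with_seed(seed, {
    r1 <- sqrt(6 / (d + hidden))
    list(W1 = matrix(stats::runif(hidden * d, -r1, r1), hidden, d),
         b1 = numeric(hidden),
         W2 = matrix(stats::runif(d * hidden, -r1, r1), d, hidden),
         b2 = rep(0.5, d))   # keep ReLU outputs initially live
  })
}

#' @keywords internal
#' @noRd
sae_forward <- function(par, X) {
  # X: n x d, rows are samples
  A1 <- sigmoid(tcrossprod(X, par$W1) + matrix(par$b1, nrow(X), length(par$b1),
                                               byrow = TRUE))
  pre2 <- tcrossprod(A1, par$W2) + matrix(par$b2, nrow(X), length(par$b2),
                                          byrow = TRUE)
  list(A1 = A1, pre2 = pre2, out = pmax(pre2, 0))
}

#' @keywords internal
#' @noRd
sae_loss <- function(par, X, rho, beta_sp) {
  fw <- sae_forward(par, X)
  rho_hat <- pmin(pmax(colMeans(fw$A1), 1e-8), 1 - 1e-8)
  0.5 * mean(rowSums((fw$out - X)^2)) + beta_sp * sum(kl_sparsity(rho, rho_hat))
}

#' Train a sparse autoencoder
#'
#' Minimizes reconstruction error plus `beta_sp` times the summed KL
#' divergence between the target activation `rho` and each hidden
#' unit's mean activation over the minibatch, by plain minibatch
#' gradient descent. Features must be scaled to \[0, 1\].
#'
#' @param X Feature matrix (n x d) with values in \[0, 1\].
#' @param config An [sae_config()].
#' @return An `sae_model` with the weights, the config and
#'   `loss_trace` (full-data objective per epoch, including epoch 0 =
#'   the untrained network).
#' @export
sae_train <- function(X, config = sae_config()) {
  X <- as.matrix(X)
  if (any(X < 0 | X > 1)) stop("features must be scaled to [0, 1]")
  n <- nrow(X); d <- ncol(X)
  par <- sae_init(d, config$hidden, config$seed)
  trace <- numeric(config$epochs + 1L)
  trace[1] <- sae_loss(par, X, config$rho, config$beta_sp)
  with_seed(split_seed(config$seed, 7L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        m <- nrow(Xb)
        fw <- sae_forward(par, Xb)
        rho_hat <- pmin(pmax(colMeans(fw$A1), 1e-8), 1 - 1e-8)
        # output layer: squared error through the ReLU
        delta2 <- (fw$out - Xb) * (fw$pre2 > 0) / m
        gW2 <- crossprod(delta2, fw$A1)
        gb2 <- colSums(delta2)
        # hidden layer: backprop plus the KL penalty gradient
        kl_grad <- config$beta_sp *
          (-config$rho / rho_hat + (1 - config$rho) / (1 - rho_hat)) / m
        delta1 <- (delta2 %*% par$W2 +
                     matrix(kl_grad, m, config$hidden, byrow = TRUE)) *
          fw$A1 * (1 - fw$A1)
        gW1 <- crossprod(delta1, Xb)
        gb1 <- colSums(delta1)
        par$W1 <- par$W1 - config$eta * gW1
        par$b1 <- par$b1 - config$eta * gb1
        par$W2 <- par$W2 - config$eta * gW2
        par$b2 <- par$b2 - config$eta * gb2
      }
      trace[ep + 1L] <- sae_loss(par, X, config$rho, config$beta_sp)
    }
  })
  structure(c(par, list(config = config, loss_trace = trace)), class = "sae_model")
}

#' Hidden-layer encoding of samples
#' @param model An `sae_model`.
#' @param X Feature matrix in \[0, 1\].
#' @return Matrix of hidden activations (n x hidden), values in (0, 1).
#' @export
sae_encode <- function(model, X) sae_forward(model, as.matrix(X))$A1

#' Reconstruction of samples through the autoencoder
#' @param model An `sae_model`.
#' @param X Feature matrix in \[0, 1\].
#' @return Reconstructed matrix (same shape as `X`).
#' @export
sae_reconstruct <- function(model, X) sae_forward(model, as.matrix(X))$out
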