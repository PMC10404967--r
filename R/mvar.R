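# Multivariate autoregression in the L2 (least-squares) sense. The
# lagged coefficients of channel j in the regression of channel k are
# the Granger-style directed-influence features used downstream.

#' Build the lagged design matrix of a multichannel series
#'
#' For p channels of common length n and order l, the design matrix is
#' the column-block concatenation `C = [Q_1, ..., Q_p]` where row r of
#' block `Q_i` holds `z_i(l + r - 1), ..., z_i(r)` (descending lags), so
#' `C` has shape `(n - l) x (p * l)`.
#'
#' @param channel_signals List (or matrix columns) of p equal-length
#'   numeric channels.
#' @param order Lag order l (`1 <= l < n`).
#' @return Matrix of dimension `(n - l) x (p * l)` with columns named
#'   `ch{i}_lag{j}`.
#' @export
build_design_matrix <- function(channel_signals, order) {
  if (is.matrix(channel_signals))
    channel_signals <- lapply(seq_len(ncol(channel_signals)),
                              function(j) channel_signals[, j])
  lens <- lengths(channel_signals)
  if (length(unique(lens)) != 1L) stop("channels must have equal length")
  n <- lens[1]
  l <- as.integer(order)
  if (l < 1L || l >= n) stop("order must satisfy 1 <= order < channel length")
  p <- length(channel_signals)
  blocks <- lapply(channel_signals, function(z) {
    cols <- lapply(seq_len(l), function(j) z[(l - j + 1L):(n - j)])
    do.call(cbind, cols)
  })
  C <- do.call(cbind, blocks)
  colnames(C) <- unlist(lapply(seq_len(p), function(i)
    sprintf("ch%d_lag%d", i, seq_len(l))))
  C
}

#' Fit a multivariate autoregressive model by least squares
#'
#' Per target channel k the coefficient vector solves the normal
#' equations `X_k = (C'C)^{-1} C' y_k`; when `C'C` is singular (detected
#' by reciprocal condition number below 1e-10) the Moore-Penrose
#' pseudo-inverse branch is used instead. Residual variances come from
#' `y_k - C X_k`.
#'
#' @param channel_signals List of p equal-length numeric channels
#'   (finite values).
#' @param order Lag order l. A warning is issued when `n - l < p * l`
#'   (under-determined fit).
#' @return An `mvar_model`: `order`, `channels`, `coefficients`
#'   (`(p*l) x p` matrix, column k = stacked X_k), `residual_variances`,
#'   `singular` (logical, pseudo-inverse branch taken).
#' @export
fit_mvar <- function(channel_signals, order) {
  if (is.matrix(channel_signals))
    channel_signals <- lapply(seq_len(ncol(channel_signals)),
                              function(j) channel_signals[, j])
  for (z in channel_signals) assert_finite(z, "channel")
  C <- build_design_matrix(channel_signals, order)
  p <- length(channel_signals)
  l <- as.integer(order)
  n <- length(channel_signals[[1]])
  if (n - l < p * l)
    warning("fewer equations than coefficients (n - l < p * l); fit is under-determined")
  CtC <- crossprod(C)
  rc <- tryCatch(1 / kappa(CtC, exact = FALSE), error = function(e) 0)
  singular <- !is.finite(rc) || rc < 1e-10
  solver <- if (singular) {
    Cp <- pinv(C)
    function(y) drop(Cp %*% y)
  } else {
    R <- chol(CtC)
    function(y) drop(backsolve(R, forwardsolve(t(R), crossprod(C, y))))
  }
  coefs <- matrix(0, ncol(C), p)
  resvar <- numeric(p)
  for (k in seq_len(p)) {
    yk <- channel_signals[[k]][(l + 1L):n]
    xk <- solver(yk)
    coefs[, k] <- xk
    resvar[k] <- mean((yk - drop(C %*% xk))^2)
  }
  rownames(coefs) <- colnames(C)
  colnames(coefs) <- sprintf("target%d", seq_len(p))
  structure(list(order = l, channels = p, coefficients = coefs,
                 residual_variances = resvar, singular = singular),
            class = "mvar_model")
}

#' Granger feature vector from a mode set
#'
#' Treats the intrinsic modes of a decomposition as the p channels of a
#' multivariate autoregression, fits the model, and concatenates all
#' coefficient vectors (length `p^2 * l`) followed by the p residual
#' variances. Names follow `mvar_k{target}_p{channel}_lag{lag}`.
#'
#' @param imfset An `imf_set` with at least 2 modes (or a list of
#'   channels / matrix accepted by [fit_mvar()]).
#' @param order Lag order, default 4.
#' @return Named numeric vector of length `p^2 * l + p`.
#' @export
granger_features <- function(imfset, order = 4L) {
  channels <- if (inherits(imfset, "imf_set")) imfset$modes else imfset
  if (is.matrix(channels))
    channels <- lapply(seq_len(ncol(channels)), function(j) channels[, j])
  if (length(channels) < 2L) stop("need at least 2 modes/channels for Granger features")
  model <- fit_mvar(channels, order)
  p <- model$channels
  l <- model$order
  coef_vec <- as.numeric(model$coefficients)
  names(coef_vec) <- unlist(lapply(seq_len(p), function(k)
    unlist(lapply(seq_len(p), function(i)
      sprintf("mvar_k%d_p%d_lag%d", k, i, seq_len(l))))))
  resvar <- model$residual_variances
  names(resvar) <- sprintf("mvar_resvar%d", seq_len(p))
  c(coef_vec, resvar)
}
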