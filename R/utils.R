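# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD; tol relative to the largest
# singular value, as in the usual LAPACK-backed implementations.
#' @keywords internal
#' @noRd
pinv <- function(A, tol = .Machine$double.eps * max(dim(A))) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Counter-based seed splitting: per-item seeds derived from one master
# seed so generation order never matters. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
split_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(counter) * 16807) %% 2147483629L)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Dominant frequency of a real signal by periodogram argmax (Hz).
#' @keywords internal
#' @noRd
dominant_freq <- function(x, sample_rate) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2 + 1L)]
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * sample_rate / n
  freqs[which.max(spec)]
}

#' @keywords internal
#' @noRd
sigmoid <- function(z) 1 / (1 + exp(-z))

# One-hot encoding of a factor-like label vector, columns in level order.
#' @keywords internal
#' @noRd
one_hot <- function(labels, levels) {
  T <- matrix(0, length(labels), length(levels))
  T[cbind(seq_along(labels), match(labels, levels))] <- 1
  colnames(T) <- levels
  T
}
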