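# Per-mode descriptors and the ensemble feature vector combining them
# with the Granger (autoregressive) coefficients.

#' Per-mode descriptor features
#'
#' Six descriptors per mode, concatenated in mode order: energy, sample
#' variance, skewness, excess-free kurtosis (moment ratio m4/m2^2),
#' zero-crossing rate (crossings per sample), and spectral centroid.
#' The centroid is in Hz when `sample_rate` is given, otherwise in
#' cycles/sample.
#'
#' @param imfset An `imf_set`, a `vmd_result`, or a list/matrix of modes.
#' @param sample_rate Sampling rate in Hz for the spectral centroid
#'   (default 1, i.e. normalized frequency).
#' @return Named numeric vector of length `6 * n_modes`.
#' @export
imf_features <- function(imfset, sample_rate = 1) {
  modes <- if (inherits(imfset, "imf_set")) imfset$modes
           else if (inherits(imfset, "vmd_result")) {
             sample_rate <- imfset$sample_rate
             lapply(seq_len(nrow(imfset$modes)), function(k) imfset$modes[k, ])
           }
           else if (is.matrix(imfset)) lapply(seq_len(nrow(imfset)), function(k) imfset[k, ])
           else imfset
  if (length(modes) < 1L) stop("empty mode set")
  out <- unlist(lapply(seq_along(modes), function(j) {
    x <- modes[[j]]
    n <- length(x)
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    skew <- if (m2 > 0) m3 / m2^1.5 else 0
    kurt <- if (m2 > 0) m4 / m2^2 else 0
    zcr <- sum(diff(sign(x - mu)) != 0) / n
    spec <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1L)]^2
    freqs <- (seq_len(n %/% 2 + 1L) - 1L) * sample_rate / n
    centroid <- if (sum(spec) > 0) sum(freqs * spec) / sum(spec) else 0
    v <- c(sum(x^2), stats::var(x), skew, kurt, zcr, centroid)
    names(v) <- sprintf("imf%d_%s", j,
                        c("energy", "variance", "skewness", "kurtosis",
                          "zcr", "centroid"))
    v
  }))
  out
}

#' Ensemble decomposition + autoregression feature vector
#'
#' Decomposes a cycle by paired-noise ensemble EMD, then concatenates the
#' Granger (autoregressive) coefficient features computed with the modes
#' as channels and the per-mode descriptors of the same decomposition.
#' Mode count is fixed to `n_modes` for commensurate vectors across
#' cycles: surplus modes are folded into the residual, missing modes are
#' zero-padded (their feature blocks are zero).
#'
#' @param cycle A labelled cycle, `audio_signal` or numeric vector.
#' @param cfg A [seemd_config()]. Its seed is combined with a hash of
#'   the cycle source so decompositions are reproducible per cycle.
#' @param mvar_order Lag order for the autoregressive block, default 4.
#' @param n_modes Fixed number of modes entering the features, default 5.
#' @param sample_rate Sampling rate for the spectral centroid.
#' @return Named numeric vector of length
#'   `n_modes^2 * mvar_order + n_modes + 6 * n_modes`.
#' @export
ensemble_gssr_features <- function(cycle, cfg = seemd_config(),
                                   mvar_order = 4L, n_modes = 5L,
                                   sample_rate = NULL) {
  sig <- if (inherits(cycle, "labeled_cycle")) cycle$signal else cycle
  if (inherits(sig, "audio_signal")) {
    if (is.null(sample_rate)) sample_rate <- sig$sample_rate
    x <- sig$samples
  } else x <- as.numeric(sig)
  if (is.null(sample_rate)) sample_rate <- 1
  dec <- seemd(x, cfg)
  modes <- pad_modes(dec$modes, n_modes, length(x))
  gr <- granger_features(modes, order = mvar_order)
  mf <- imf_features(modes, sample_rate = sample_rate)
  c(gr, mf)
}

# Fix a decomposition to exactly n_modes channels: truncate (surplus into
# nothing -- features only) or pad with tiny seeded-free jitter-less zero
# modes. Zero channels would make the autoregressive design matrix
# rank-deficient, which the pseudo-inverse branch handles.
#' @keywords internal
#' @noRd
pad_modes <- function(modes, n_modes, n) {
  if (length(modes) >= n_modes) return(modes[seq_len(n_modes)])
  c(modes, replicate(n_modes - length(modes), numeric(n), simplify = FALSE))
}
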