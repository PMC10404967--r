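# Empirical mode decomposition by cubic-spline envelope sifting, and its
# paired-noise ensemble variant. The ensemble adds q pairs of white-noise
# realizations with opposite signs, decomposes all 2q noisy copies, and
# averages matching modes; the pairing cancels the injected noise in the
# mean, which is what suppresses mode aliasing without leaving residual
# noise in the reconstruction.

#' @keywords internal
#' @noRd
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus register a single extremum
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  sc <- s[nz]
  turns <- which(diff(sc) != 0)
  idx <- nz[turns] + 1L
  kind <- sc[turns]                      # +1 then down => maximum
  list(max = idx[kind > 0], min = idx[kind < 0])
}

# Envelope through extrema with mirrored end conditions: the first/last
# extrema are reflected about the signal ends so splines do not diverge.
#' @keywords internal
#' @noRd
spline_envelope <- function(x, idx) {
  n <- length(x)
  xs <- idx
  ys <- x[idx]
  # mirror two extrema beyond each boundary
  left_x <- 2 - rev(xs[seq_len(min(2L, length(xs)))])
  left_y <- rev(ys[seq_len(min(2L, length(ys)))])
  right_x <- 2 * n - rev(rev(xs)[seq_len(min(2L, length(xs)))])
  right_y <- rev(rev(ys)[seq_len(min(2L, length(ys)))])
  xx <- c(left_x, xs, rev(right_x))
  yy <- c(left_y, ys, rev(right_y))
  keep <- !duplicated(xx)
  stats::spline(xx[keep], yy[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard sifting: subtract the mean of the upper and lower cubic
#' spline envelopes until the mode criterion is met, peel the mode off,
#' repeat on the remainder. Modes are ordered highest to lowest
#' characteristic frequency. By construction
#' `rowSums(modes) + residual == signal` to machine precision.
#'
#' @param signal An `audio_signal` or numeric vector.
#' @param max_imfs Maximum number of modes to extract (default 10).
#' @param sift_tol Cauchy-type sifting stop criterion (default 0.2).
#' @param max_sifts Sifting iterations per mode (default 12).
#' @return An `imf_set`: `modes` (list of numeric vectors, possibly
#'   empty), `residual`, `source_length`.
#' @export
emd <- function(signal, max_imfs = 10L, sift_tol = 0.2, max_sifts = 12L) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
  assert_finite(x, "signal")
  if (length(x) < 4L) stop("signal too short for EMD (need length >= 4)")
  n <- length(x)
  modes <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    ext <- local_extrema(res)
    if (length(ext$max) < 2L || length(ext$min) < 2L) break
    h <- res
    for (s in seq_len(max_sifts)) {
      e <- local_extrema(h)
      if (length(e$max) < 2L || length(e$min) < 2L) break
      m <- (spline_envelope(h, e$max) + spline_envelope(h, e$min)) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < sift_tol) break
    }
    modes[[k]] <- h
    res <- res - h
  }
  imf_set(modes, res, n)
}

#' @keywords internal
#' @noRd
imf_set <- function(modes, residual, source_length) {
  structure(list(modes = modes, residual = residual,
                 source_length = source_length),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d modes over %d samples\n",
              length(x$modes), x$source_length))
  invisible(x)
}

#' Reconstruct the signal from a mode set
#' @param imfset An `imf_set`.
#' @return Numeric vector `sum(modes) + residual`.
#' @export
imf_reconstruct <- function(imfset) {
  out <- imfset$residual
  for (m in imfset$modes) out <- out + m
  out
}

#' Configuration for the paired-noise ensemble decomposition
#'
#' @param noise_std_fraction Injected white-noise standard deviation as a
#'   fraction of the signal's standard deviation. Values outside
#'   \[0.02, 0.4\] trigger a warning (the usual operating range); 0.4 is
#'   the published operating point for lung sounds.
#' @param ensemble_size Number of noise pairs q (>= 1).
#' @param seed Integer seed for the noise draws.
#' @param max_imfs Maximum modes per member decomposition.
#' @return A `seemd_config` list.
#' @export
seemd_config <- function(noise_std_fraction = 0.4, ensemble_size = 10L,
                         seed = 1L, max_imfs = 10L) {
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1")
  if (noise_std_fraction < 0.02 || noise_std_fraction > 0.4)
    warning("noise_std_fraction outside the usual [0.02, 0.4] range")
  structure(list(noise_std_fraction = noise_std_fraction,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed), max_imfs = as.integer(max_imfs)),
            class = "seemd_config")
}

#' Paired-noise ensemble empirical mode decomposition
#'
#' For each of q ensemble members, draws white noise N_i with standard
#' deviation `noise_std_fraction * sd(signal)` and decomposes both
#' `signal + N_i` and `signal - N_i` by [emd()]. Mode j of the result is
#' the mean of mode j over all 2q member decompositions; because every
#' noise realization enters with both signs, the injected noise cancels
#' exactly in the mean of the inputs. Members can produce different mode
#' counts; modes are aligned by truncation to the minimum count and the
#' surplus is folded into the residual, so the output still reconstructs
#' the clean signal exactly.
#'
#' @param signal An `audio_signal` or numeric vector (non-constant).
#' @param config A [seemd_config()].
#' @return An `imf_set`.
#' @export
seemd <- function(signal, config = seemd_config()) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
  assert_finite(x, "signal")
  if (stats::sd(x) == 0) stop("SEEMD requires a non-constant signal")
  q <- config$ensemble_size
  sigma <- config$noise_std_fraction * stats::sd(x)
  members <- with_seed(config$seed, {
    out <- vector("list", 2L * q)
    for (i in seq_len(q)) {
      noise <- stats::rnorm(length(x), sd = sigma)
      out[[2L * i - 1L]] <- emd(x + noise, max_imfs = config$max_imfs)
      out[[2L * i]] <- emd(x - noise, max_imfs = config$max_imfs)
    }
    out
  })
  counts <- vapply(members, function(m) length(m$modes), integer(1))
  n_modes <- min(counts)
  modes <- vector("list", n_modes)
  if (n_modes > 0) {
    for (j in seq_len(n_modes)) {
      acc <- numeric(length(x))
      for (m in members) acc <- acc + m$modes[[j]]
      modes[[j]] <- acc / (2 * q)
    }
  }
  recon <- Reduce(`+`, modes, numeric(length(x)))
  imf_set(modes, x - recon, length(x))
}
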