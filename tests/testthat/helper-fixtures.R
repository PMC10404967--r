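# Shared fixtures, built in code. The session cache avoids recomputing
# expensive objects (feature matrices, datasets) across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

make_tone <- function(freqs, fs = 1000, dur = 1, amps = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amps <- rep_len(amps, length(freqs))
  rowSums(vapply(seq_along(freqs),
                 function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                 numeric(length(t))))
}

# well-separated seeded multi-tone signal: components spaced widely
# relative to the VMD filter bandwidth implied by alpha = 300
make_ktone <- function(k, seed, fs = 1000, dur = 1) {
  set.seed(seed)
  bases <- c(40, 150, 280, 410)[seq_len(k)]
  freqs <- bases * stats::runif(k, 0.9, 1.1)
  make_tone(freqs, fs = fs, dur = dur)
}

# three-class Gaussian realm data used by the domain-adaptation tests:
# 2 informative of 10 dimensions; the target realm is a rotated (30
# degrees in the informative plane) and shifted copy
make_realm_data <- function(n_per, seed, rotate = 0, shift = 0) {
  set.seed(seed)
  cents <- rbind(c(3, 0), c(-1.5, 2.6), c(-1.5, -2.6))
  X <- NULL; y <- NULL
  for (k in 1:3) {
    P <- cbind(matrix(stats::rnorm(n_per * 2, 0, 0.6), n_per, 2) +
                 matrix(cents[k, ], n_per, 2, byrow = TRUE),
               matrix(stats::rnorm(n_per * 8, 0, 0.6), n_per, 8))
    X <- rbind(X, P); y <- c(y, rep(letters[k], n_per))
  }
  th <- rotate * pi / 180
  R <- diag(10)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  list(X = X %*% R + shift, y = y)
}

# small synthetic lung-sound dataset for the pipeline unit tests
small_dataset <- function() fixture("small_ds", function()
  synthesize_dataset(synth_config(n_per_class = 12, seed = 3),
                     label_scheme("three_class")))

# fast pipeline options for unit-level smoke tests
fast_opts <- list(seemd_q = 2L, max_imfs = 5L, n_modes = 3L, mvar_order = 2L,
                  rfe_per_round = 10L, rfe_keep = 15L,
                  dm_select_n = 2L, dm_kmax = 4L, vmd_iters = 100L,
                  hho_hawks = 2L, hho_iters = 2L, de_np = 6L, de_iters = 3L,
                  gwo_wolves = 4L, gwo_iters = 4L,
                  goa_agents = 6L, goa_iters = 5L, sae_epochs = 15L,
                  d_sub = 10L, atoms_per_class = 6L)
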