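# Synthetic lung-sound generator. Emulates the three acoustic archetypes
# of cycle-level auscultation data: broadband vesicular noise (normal),
# sustained amplitude-modulated tones (wheeze, 100-1000 Hz) and brief
# exponentially damped transients (crackles). Not a physical model; see
# the methods vignette for what it does and does not emulate.

#' Configuration for the synthetic cycle generator
#'
#' @param n_per_class Cycles per class in a generated dataset.
#' @param duration_s Cycle duration in seconds.
#' @param sample_rate Sampling rate in Hz; must be at least twice the
#'   upper wheeze frequency.
#' @param snr_db Component-to-background power ratio in dB for the
#'   adventitious components (wheeze tone, crackle train).
#' @param wheeze_freq_range Two-element Hz range the wheeze fundamental
#'   is drawn from.
#' @param crackle_rate Expected crackle events per second (Poisson).
#' @param seed Master seed; per-cycle seeds are derived from it by a
#'   counter-based splitting rule so generation order never matters.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = 50, duration_s = 1.0, sample_rate = 4000,
                         snr_db = 10, wheeze_freq_range = c(100, 1000),
                         crackle_rate = 8, seed = 1L) {
  stopifnot(duration_s > 0, n_per_class >= 1, length(wheeze_freq_range) == 2L,
            wheeze_freq_range[1] > 0, wheeze_freq_range[2] > wheeze_freq_range[1])
  if (sample_rate < 2 * wheeze_freq_range[2])
    stop("sample_rate must be at least twice the upper wheeze frequency")
  structure(list(n_per_class = as.integer(n_per_class), duration_s = duration_s,
                 sample_rate = sample_rate, snr_db = snr_db,
                 wheeze_freq_range = wheeze_freq_range,
                 crackle_rate = crackle_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Scale a component so its average power sits snr_db above ref_power.
#' @keywords internal
#' @noRd
scale_to_snr <- function(component, ref_power, snr_db) {
  p <- mean(component^2)
  if (p == 0) return(component)
  component * sqrt(ref_power * 10^(snr_db / 10) / p)
}

#' @keywords internal
#' @noRd
synth_background <- function(n, sample_rate) {
  noise <- stats::rnorm(n)
  x <- fft_bandpass(noise, sample_rate, 100, 1000)
  x / stats::sd(x)
}

#' @keywords internal
#' @noRd
synth_wheeze_component <- function(n, sample_rate, freq_range) {
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- stats::runif(1, freq_range[1], freq_range[2])
  f_am <- stats::runif(1, 1, 4)              # slow breath-borne modulation
  phase <- stats::runif(1, 0, 2 * pi)
  am <- 1 + 0.5 * sin(2 * pi * f_am * t + stats::runif(1, 0, 2 * pi))
  list(x = am * sin(2 * pi * f0 * t + phase), freq = f0)
}

#' @keywords internal
#' @noRd
synth_crackle_component <- function(n, sample_rate, rate_per_s) {
  duration_s <- n / sample_rate
  n_events <- stats::rpois(1, rate_per_s * duration_s)
  x <- numeric(n)
  if (n_events > 0) {
    for (k in seq_len(n_events)) {
      width_s <- stats::runif(1, 0.005, 0.010)       # 5-10 ms transient
      w <- round(width_s * sample_rate)
      i0 <- sample.int(max(1L, n - w), 1)
      tt <- (seq_len(w) - 1) / sample_rate
      fc <- stats::runif(1, 200, 800)
      tau <- width_s / 4                             # ~4 decay constants
      burst <- sin(2 * pi * fc * tt) * exp(-tt / tau)
      idx <- i0:(i0 + w - 1L)
      x[idx] <- x[idx] + burst
    }
  }
  list(x = x, n_events = n_events)
}

#' Synthesize one labelled respiratory cycle
#'
#' Deterministic for a fixed seed. `normal` is band-limited (100-1000 Hz)
#' Gaussian noise; `wheeze` adds an amplitude-modulated sinusoid at a
#' seeded frequency inside `wheeze_freq_range`; `crackle` adds
#' Poisson-placed damped transients (5-10 ms); `both` adds both
#' components. Adventitious components are scaled to `snr_db` above the
#' background power. `abnormal` (two-class scheme) draws one of the three
#' adventitious types at random.
#'
#' @param class_name Class label to synthesize.
#' @param config A [synth_config()].
#' @param seed Integer seed for this cycle.
#' @return A labelled cycle with a `meta` field recording the wheeze
#'   frequency and crackle event count actually generated.
#' @export
synthesize_cycle <- function(class_name, config = synth_config(), seed = config$seed) {
  known <- c("normal", "wheeze", "crackle", "both", "abnormal")
  if (!class_name %in% known)
    stop(sprintf("unknown class name '%s'", class_name))
  with_seed(seed, {
    n <- round(config$duration_s * config$sample_rate)
    physical <- class_name
    if (class_name == "abnormal")
      physical <- sample(c("wheeze", "crackle", "both"), 1)
    bg <- synth_background(n, config$sample_rate)
    p_bg <- mean(bg^2)
    x <- bg
    meta <- list(physical = physical, wheeze_freq = NA_real_, n_crackles = 0L)
    if (physical %in% c("wheeze", "both")) {
      wz <- synth_wheeze_component(n, config$sample_rate, config$wheeze_freq_range)
      x <- x + scale_to_snr(wz$x, p_bg, config$snr_db)
      meta$wheeze_freq <- wz$freq
    }
    if (physical %in% c("crackle", "both")) {
      cr <- synth_crackle_component(n, config$sample_rate, config$crackle_rate)
      if (cr$n_events > 0) x <- x + scale_to_snr(cr$x, p_bg, config$snr_db)
      meta$n_crackles <- cr$n_events
    }
    sig <- audio_signal(x, config$sample_rate,
                        sprintf("synth:%s:seed%d", class_name, seed))
    structure(list(signal = sig, label = class_name, meta = meta),
              class = "labeled_cycle")
  })
}

#' Synthesize a balanced, shuffled labelled dataset
#'
#' Generates `n_per_class` cycles for every class of `scheme` and
#' shuffles them with a seeded permutation. Identical seeds give
#' bit-identical datasets.
#'
#' @param config A [synth_config()].
#' @param scheme A [label_scheme()].
#' @return List of labelled cycles of length
#'   `n_per_class * length(scheme$classes)`.
#' @export
synthesize_dataset <- function(config = synth_config(),
                               scheme = label_scheme("three_class")) {
  stopifnot(inherits(scheme, "label_scheme"))
  cycles <- list()
  counter <- 0L
  for (cls in scheme$classes) {
    for (j in seq_len(config$n_per_class)) {
      counter <- counter + 1L
      cycles[[counter]] <- synthesize_cycle(cls, config,
                                            seed = split_seed(config$seed, counter))
    }
  }
  perm <- with_seed(split_seed(config$seed, 0L), sample.int(length(cycles)))
  cycles[perm]
}

#' Extract labels from a list of labelled cycles
#' @param dataset List of labelled cycles.
#' @return Character vector of labels.
#' @export
cycle_labels <- function(dataset) vapply(dataset, `[[`, character(1), "label")
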