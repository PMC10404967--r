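# Reading cycle-annotated lung-sound recordings and segmenting them into
# labelled respiratory cycles under a chosen class scheme.

#' Label schemes for respiratory-cycle classification
#'
#' Three schemes are supported:
#' * `two_class`: normal vs abnormal (any crackle and/or wheeze);
#' * `three_class`: normal / crackle / wheeze, cycles carrying both
#'   adventitious sounds are excluded;
#' * `four_class`: normal / crackle / wheeze / both.
#'
#' @param name One of `"two_class"`, `"three_class"`, `"four_class"`.
#' @return A `label_scheme` with fields `name` and `classes`.
#' @export
label_scheme <- function(name = c("three_class", "two_class", "four_class")) {
  name <- match.arg(name)
  classes <- switch(name,
    two_class = c("normal", "abnormal"),
    three_class = c("normal", "crackle", "wheeze"),
    four_class = c("normal", "crackle", "wheeze", "both"))
  structure(list(name = name, classes = classes), class = "label_scheme")
}

#' @keywords internal
#' @noRd
cycle_annotation <- function(start_s, end_s, crackle, wheeze) {
  if (!(start_s >= 0 && end_s > start_s))
    stop("annotation must satisfy 0 <= start < end")
  list(start_s = start_s, end_s = end_s,
       crackle = as.logical(crackle), wheeze = as.logical(wheeze))
}

#' Load a recording with its cycle annotation file
#'
#' The annotation dialect is whitespace-delimited text, one row per
#' respiratory cycle: `start_s end_s crackle(0/1) wheeze(0/1)`. Rows with
#' the wrong column count, non-numeric times, flags outside \{0, 1\} or
#' `end <= start` are rejected with the offending row index.
#'
#' @param wav_path Path to a mono WAV recording.
#' @param annotation_path Path to the annotation text file.
#' @return A list with `signal` (an `audio_signal`) and `annotations`
#'   (list of cycle annotations sorted by start time).
#' @export
load_icbhi_recording <- function(wav_path, annotation_path) {
  signal <- read_wav(wav_path)
  if (!file.exists(annotation_path))
    stop(sprintf("annotation file not found: %s", annotation_path))
  lines <- readLines(annotation_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  anns <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(fields) != 4L)
      stop(sprintf("annotation row %d: expected 4 columns, got %d", i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("annotation row %d: non-numeric field", i))
    if (vals[2] <= vals[1])
      stop(sprintf("annotation row %d: end (%g) <= start (%g)", i, vals[2], vals[1]))
    if (!all(vals[3:4] %in% c(0, 1)))
      stop(sprintf("annotation row %d: crackle/wheeze flags must be 0 or 1", i))
    anns[[i]] <- cycle_annotation(vals[1], vals[2], vals[3] == 1, vals[4] == 1)
  }
  ord <- order(vapply(anns, `[[`, numeric(1), "start_s"))
  list(signal = signal, annotations = anns[ord])
}

#' @keywords internal
#' @noRd
map_flags_to_label <- function(crackle, wheeze, scheme) {
  raw <- if (crackle && wheeze) "both"
         else if (crackle) "crackle"
         else if (wheeze) "wheeze"
         else "normal"
  switch(scheme$name,
    four_class = raw,
    two_class = if (raw == "normal") "normal" else "abnormal",
    three_class = if (raw == "both") NA_character_ else raw)
}

#' Segment a recording into labelled respiratory cycles
#'
#' Cuts the half-open interval `[start, end)` of each annotation out of
#' the signal and maps the crackle/wheeze flag pair to a class label
#' under `scheme`. Under `three_class`, cycles flagged with both sounds
#' are excluded.
#'
#' @param signal An `audio_signal`.
#' @param annotations List of cycle annotations (as from
#'   [load_icbhi_recording()]).
#' @param scheme A [label_scheme()].
#' @return List of labelled cycles, each `list(signal =, label =)`.
#' @export
segment_cycles <- function(signal, annotations, scheme = label_scheme("four_class")) {
  stopifnot(inherits(signal, "audio_signal"), inherits(scheme, "label_scheme"))
  dur <- signal_duration(signal)
  out <- list()
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    if (a$end_s > dur + 1e-9)
      stop(sprintf("annotation %d ends at %gs, beyond signal end (%gs)", i, a$end_s, dur))
    label <- map_flags_to_label(a$crackle, a$wheeze, scheme)
    if (is.na(label)) next
    i0 <- floor(a$start_s * signal$sample_rate) + 1L
    i1 <- min(length(signal$samples), ceiling(a$end_s * signal$sample_rate))
    cyc <- audio_signal(signal$samples[i0:i1], signal$sample_rate,
                        sprintf("%s[cycle %d]", signal$source_id, i))
    out[[length(out) + 1L]] <- labeled_cycle(cyc, label, scheme)
  }
  out
}

#' @keywords internal
#' @noRd
labeled_cycle <- function(signal, label, scheme) {
  if (!label %in% scheme$classes)
    stop(sprintf("label '%s' not valid under scheme '%s'", label, scheme$name))
  structure(list(signal = signal, label = label), class = "labeled_cycle")
}

#' Pad or truncate a cycle to a fixed analysis length
#'
#' Feature vectors must be commensurate across cycles, so cycles are
#' zero-padded (at the end) or truncated to `length_s` seconds.
#'
#' @param cycle A labelled cycle or `audio_signal`.
#' @param length_s Target length in seconds (default 2.5).
#' @return Object of the same kind with exactly
#'   `round(length_s * sample_rate)` samples.
#' @export
fix_cycle_length <- function(cycle, length_s = 2.5) {
  sig <- if (inherits(cycle, "labeled_cycle")) cycle$signal else cycle
  n_target <- round(length_s * sig$sample_rate)
  x <- sig$samples
  if (length(x) >= n_target) x <- x[seq_len(n_target)]
  else x <- c(x, numeric(n_target - length(x)))
  sig$samples <- x
  if (inherits(cycle, "labeled_cycle")) { cycle$signal <- sig; cycle } else sig
}
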