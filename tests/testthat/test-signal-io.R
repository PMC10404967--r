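# Reading annotated recordings, segmentation, normalization, WAV I/O.

write_fixture_recording <- function(dir, ann_lines,
                                    dur = 4, fs = 2000) {
  sig <- audio_signal(sin(2 * pi * 220 * seq(0, dur, by = 1 / fs)), fs, "fixture")
  wav <- file.path(dir, "rec.wav")
  ann <- file.path(dir, "rec.txt")
  write_wav(sig, wav)
  writeLines(ann_lines, ann)
  list(wav = wav, ann = ann)
}

test_that("WAV files round-trip through write_wav/read_wav", {
  dir <- withr::local_tempdir()
  x <- sin(2 * pi * 100 * seq(0, 0.5, by = 1 / 4000)) * 0.8
  sig <- audio_signal(x, 4000, "rt")
  p <- write_wav(sig, file.path(dir, "t.wav"))
  back <- read_wav(p)
  expect_equal(back$sample_rate, 4000)
  expect_equal(length(back), length(sig))
  expect_lt(max(abs(back$samples - x)), 1 / 32768)  # 16-bit quantization
  expect_error(read_wav(file.path(dir, "missing.wav")), "not found")
})

test_that("annotation files parse, sort and validate row by row", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_recording(dir, c("1.5 2.4 1 0",
                                       "0.036 0.579 0 0",
                                       "2.5 3.2 0 1",
                                       "0.6 1.4 1 1"))
  rec <- load_icbhi_recording(fx$wav, fx$ann)
  expect_length(rec$annotations, 4)
  starts <- vapply(rec$annotations, `[[`, numeric(1), "start_s")
  expect_identical(starts, sort(starts))
  a1 <- rec$annotations[[1]]
  expect_equal(a1$start_s, 0.036)
  expect_equal(a1$end_s, 0.579)
  expect_false(a1$crackle); expect_false(a1$wheeze)

  bad <- write_fixture_recording(withr::local_tempdir(),
                                 c("0 1 0 0", "2 1.5 0 0"))
  expect_error(load_icbhi_recording(bad$wav, bad$ann), "row 2")
  bad2 <- write_fixture_recording(withr::local_tempdir(), c("0 1 0"))
  expect_error(load_icbhi_recording(bad2$wav, bad2$ann), "4 columns")
  bad3 <- write_fixture_recording(withr::local_tempdir(), c("0 x 0 0"))
  expect_error(load_icbhi_recording(bad3$wav, bad3$ann), "non-numeric")
})

test_that("segment_cycles maps flag pairs per scheme and excludes 'both' in three_class", {
  dir <- withr::local_tempdir()
  # 6-row fixture: 2 normal, 1 crackle, 1 wheeze, 2 both
  fx <- write_fixture_recording(dir, c("0.0 0.5 0 0", "0.5 1.0 1 0",
                                       "1.0 1.5 0 1", "1.5 2.0 1 1",
                                       "2.0 2.5 0 0", "2.5 3.0 1 1"))
  rec <- load_icbhi_recording(fx$wav, fx$ann)
  four <- segment_cycles(rec$signal, rec$annotations, label_scheme("four_class"))
  expect_equal(cycle_labels(four),
               c("normal", "crackle", "wheeze", "both", "normal", "both"))
  two <- segment_cycles(rec$signal, rec$annotations, label_scheme("two_class"))
  expect_equal(cycle_labels(two),
               c("normal", "abnormal", "abnormal", "abnormal", "normal", "abnormal"))
  three <- segment_cycles(rec$signal, rec$annotations, label_scheme("three_class"))
  expect_length(three, 4)   # 6 rows - 2 'both'
  expect_false("both" %in% cycle_labels(three))

  beyond <- list(list(start_s = 3.9, end_s = 99, crackle = FALSE, wheeze = FALSE))
  expect_error(segment_cycles(rec$signal, beyond, label_scheme("four_class")),
               "beyond signal end")
})

test_that("normalize_minmax is an order-preserving affine map onto [0, 1]", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(-1, 0, 3)), c(0, 0.25, 1))
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(50)
    y <- normalize_minmax(x)
    expect_equal(min(y), 0)
    expect_equal(max(y), 1)
    expect_equal(order(x), order(y))
    expect_equal(normalize_minmax(y), y)   # idempotent
  }
  expect_error(normalize_minmax(rep(2, 10)), "constant")
})

test_that("resampling preserves duration and low-frequency content", {
  t <- seq(0, 1 - 1 / 8000, by = 1 / 8000)
  sig <- audio_signal(sin(2 * pi * 50 * t), 8000, "rs")
  down <- resample_signal(sig, 4000)
  expect_equal(down$sample_rate, 4000)
  expect_equal(length(down), 4000)
  expect_equal(respsound:::dominant_freq(down$samples, 4000), 50, tolerance = 1)
})

test_that("fixed-length padding/truncation yields exact sample counts", {
  sig <- audio_signal(rep(1, 1000), 1000, "p")
  expect_length(fix_cycle_length(sig, 2.5)$samples, 2500)
  expect_length(fix_cycle_length(sig, 0.5)$samples, 500)
  expect_equal(fix_cycle_length(sig, 2)$samples[1001:2000], rep(0, 1000))
})
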