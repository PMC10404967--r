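# Variational mode decomposition, similarity indices, mode-number
# selection.

test_that("VMD recovers a single tone's center frequency and reconstructs it", {
  tone <- make_tone(10)
  v <- vmd(tone, vmd_config(K = 1), sample_rate = 1000)
  expect_lt(abs(v$center_freqs - 10), 0.5)
  relerr <- sqrt(sum((colSums(v$modes) - tone)^2) / sum(tone^2))
  expect_lt(relerr, 0.02)
})

test_that("VMD separates two well-spaced tones", {
  two <- make_tone(c(5, 40))
  v <- vmd(two, vmd_config(K = 2), sample_rate = 1000)
  cf <- sort(v$center_freqs)
  expect_lt(abs(cf[1] - 5), 1)
  expect_lt(abs(cf[2] - 40), 1)
})

test_that("VMD degenerate and error paths", {
  v <- vmd(numeric(64), vmd_config(K = 2, max_iters = 10), sample_rate = 64)
  expect_true(all(v$modes == 0))
  # center frequencies stay at their uniform initialization (Hz)
  expect_equal(sort(v$center_freqs), 64 * 0.5 * (1:2 - 0.5) / 2)
  expect_error(vmd(c(1, NaN, 3, 4, 5, 6), vmd_config(K = 1)), "non-finite")
  expect_error(vmd(numeric(3), vmd_config(K = 2)), "too short")
  res <- vmd(rnorm(128), vmd_config(K = 2, max_iters = 2), sample_rate = 128)
  expect_false(res$converged)   # non-convergence reported, not raised
})

test_that("VMD does not invent energy on tonal signals", {
  for (f in list(c(10), c(5, 40), c(20, 80, 160))) {
    x <- make_tone(f)
    v <- vmd(x, vmd_config(K = length(f)), sample_rate = 1000)
    expect_lte(sum(v$modes^2), 1.05 * sum(x^2))
  }
})

test_that("similarity_index matches hand-computed examples", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  for (m in c("euclidean", "manhattan", "chebyshev", "jaccard", "dice"))
    expect_equal(similarity_index(x, x, m), 1)
  expect_equal(similarity_index(c(0, 0), c(1, 1), "chebyshev"), 0)
  expect_equal(similarity_index(x, y, "jaccard"), 6 / 9)
  expect_equal(similarity_index(x, y, "dice"), 2 * 6 / (6 + 9))
  expect_error(similarity_index(1:3, 1:4, "euclidean"), "equal length")
  expect_error(similarity_index(c(-1, 2), c(1, 2), "jaccard"), "non-negative")
  expect_error(similarity_index(c(0, 0), c(0, 0), "dice"), "all-zero")
})

test_that("similarity_index is symmetric, bounded, and 1 only at equality", {
  set.seed(10)
  for (i in 1:20) {
    x <- abs(rnorm(30)); y <- abs(rnorm(30))
    for (m in c("euclidean", "manhattan", "chebyshev", "jaccard", "dice")) {
      s1 <- similarity_index(x, y, m)
      expect_equal(s1, similarity_index(y, x, m))
      expect_gte(s1, 0); expect_lte(s1, 1)
      expect_lt(s1, 1)   # x != y almost surely
    }
  }
})

test_that("mode-number selection stops at the first K crossing the threshold", {
  tone <- make_tone(10)
  s <- select_vmd_modes(tone, metric = "manhattan", threshold = 0.97, K_max = 6,
                        sample_rate = 1000)
  expect_equal(s$K_selected, 2)   # scan starts at K = 2
  expect_true(s$converged)
  expect_true(all(s$similarity_trace >= 0 & s$similarity_trace <= 1))

  three <- make_tone(c(5, 40, 120))
  s3 <- select_vmd_modes(three, metric = "euclidean", threshold = 0.97,
                         K_max = 6, sample_rate = 1000)
  expect_true(s3$K_selected %in% c(3, 4))

  set.seed(3)
  noisy <- rnorm(400)
  sn <- select_vmd_modes(noisy, metric = "manhattan", threshold = 1, K_max = 4,
                         sample_rate = 400)
  expect_false(sn$converged)
  expect_equal(sn$K_selected, 4)
  expect_error(select_vmd_modes(tone, K_max = 1), "K_max")
})

test_that("similarity trace grows with K on average for tone mixtures", {
  rhos <- vapply(1:20, function(s) {
    x <- make_ktone(3, seed = 400 + s)
    sel <- select_vmd_modes(x, metric = "euclidean", threshold = 1, K_max = 5,
                            vmd_cfg = vmd_config(max_iters = 200),
                            sample_rate = 1000)
    suppressWarnings(stats::cor(seq_along(sel$similarity_trace),
                                sel$similarity_trace, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos, na.rm = TRUE), 0)
})
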