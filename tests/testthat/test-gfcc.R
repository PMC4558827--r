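test_that("the Greenwood map hits its range endpoints and round-trips", {
  map <- greenwood_from_range(10, 10000, k = 0.88)
  # closed-form constants to 4 significant figures
  expect_equal(map$A, 83.3333, tolerance = 1e-4)
  expect_equal(map$a, 2.0824, tolerance = 1e-4)
  expect_equal(greenwood_frequency(map, 0), 10, tolerance = 1e-9)
  expect_equal(greenwood_frequency(map, 1), 10000, tolerance = 1e-9)
  expect_equal(greenwood_frequency(map, 0.5), 842.9, tolerance = 1e-3)
  # warp round-trip on a dense grid
  x <- seq(0, 1, length.out = 501)
  expect_equal(greenwood_position(map, greenwood_frequency(map, x)), x,
               tolerance = 1e-9)
  expect_error(greenwood_from_range(-1, 100), "fmin")
  expect_error(greenwood_from_range(10, 5), "fmax")
  expect_error(greenwood_from_range(10, 100, k = 1.5), "k")
})

test_that("the filterbank has equally spaced warped edges and positive rows", {
  map <- greenwood_from_range(8, 2000)
  fb <- build_filterbank(map, 26, 8, 2000, 4000, 2048)
  xe <- greenwood_position(map, fb$edges)
  expect_equal(diff(xe), rep(diff(xe)[1], length(xe) - 1L),
               tolerance = 1e-9)
  expect_equal(fb$edges[1], 8, tolerance = 1e-9)
  expect_equal(fb$edges[length(fb$edges)], 2000, tolerance = 1e-9)
  expect_true(all(rowSums(fb$weights) > 0))
  # unit-peak triangles, increasing centers
  expect_true(all(abs(apply(fb$weights, 1, max) - 1) < 0.2))
  expect_true(all(diff(fb$centers) > 0))
  expect_error(build_filterbank(map, 26, 8, 3000, 4000, 2048), "Nyquist")
})

test_that("cepstra follow the DCT oracle and are gain-invariant without c0", {
  clip <- fixture_soundscape(snr = 5, seed = 2)$clip
  spec <- stft_spectrogram(clip)
  map <- greenwood_from_range(8, 2000)
  fb <- build_filterbank(map, 26, 8, 2000, clip$rate, 1200)
  feats <- gfcc_frames(spec, fb, n_ceps = 12, drop_c0 = TRUE)
  expect_equal(nrow(feats$vectors), nrow(spec$values))
  expect_true(all(is.finite(feats$vectors)))
  # brute-force cosine-sum oracle for the orthonormal DCT-II
  v <- withr::with_seed(8, rnorm(26))
  D <- elewatch:::dct_matrix(26)
  brute <- vapply(0:25, function(k) {
    s <- sum(v * cos(pi * ((0:25) + 0.5) * k / 26)) * sqrt(2 / 26)
    if (k == 0) s / sqrt(2) else s
  }, numeric(1))
  expect_equal(drop(D %*% v), brute, tolerance = 1e-9)
  # doubling the amplitude shifts only c0
  spec2 <- spec
  spec2$values <- spec$values * 2
  feats2 <- gfcc_frames(spec2, fb, n_ceps = 12, drop_c0 = TRUE)
  expect_equal(feats2$vectors, feats$vectors, tolerance = 1e-6)
  with_c0 <- gfcc_frames(spec, fb, n_ceps = 12, drop_c0 = FALSE)
  with_c0_2 <- gfcc_frames(spec2, fb, n_ceps = 12, drop_c0 = FALSE)
  expect_gt(max(abs(with_c0_2$vectors[, 1] - with_c0$vectors[, 1])), 0.1)
  # an all-zero frame yields zero non-DC coefficients
  zspec <- spec
  zspec$values[3, ] <- 0
  zfeats <- gfcc_frames(zspec, fb, n_ceps = 12, drop_c0 = TRUE)
  expect_equal(unname(zfeats$vectors[3, ]), rep(0, 12), tolerance = 1e-9)
  # grid mismatch is rejected
  fb_bad <- build_filterbank(map, 26, 8, 2000, clip$rate, 2048)
  expect_error(gfcc_frames(spec, fb_bad, 12), "grid")
})

test_that("context aggregation computes windowed means and variances", {
  fs <- structure(list(vectors = matrix(c(1, -1), nrow = 8, ncol = 1),
                       times = (0:7) * 0.1, dim = 1L),
                  class = "feature_sequence")
  # alternating +-1, window 4: mean 0, population variance 1
  ctx <- aggregate_context(fs, window = 4, hop = 2)
  expect_equal(ctx$vectors[, 1], rep(0, nrow(ctx$vectors)))
  expect_equal(ctx$vectors[, 2], rep(1, nrow(ctx$vectors)))
  # constant sequence: variance part all zeros, mean part the constant
  fs$vectors <- matrix(3.5, nrow = 8, ncol = 2)
  ctx2 <- aggregate_context(fs, window = 4, hop = 2)
  expect_true(all(ctx2$vectors[, 1:2] == 3.5))
  expect_true(all(ctx2$vectors[, 3:4] == 0))
  # window equal to the frame count: exactly one context vector
  ctx3 <- aggregate_context(fs, window = 8, hop = 4)
  expect_equal(nrow(ctx3$vectors), 1L)
  expect_equal(ctx3$spans[1, ], c(0, 0.7))
  expect_error(aggregate_context(fs, window = 9), "frames")
  expect_error(aggregate_context(fs, window = 1), "window")
  # sd variant takes the square root of the variance part
  fs$vectors <- matrix(c(1, -1), nrow = 8, ncol = 1)
  v <- aggregate_context(fs, 4, 2, stat = "variance")$vectors[, 2]
  s <- aggregate_context(fs, 4, 2, stat = "sd")$vectors[, 2]
  expect_equal(s, sqrt(v))
})
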