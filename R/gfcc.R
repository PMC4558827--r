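# Greenwood-warped filterbank and cepstral features (GFCC).
#
# The Greenwood function f(x) = A * (10^(a*x) - k) maps normalized
# cochlear position x in [0, 1] to frequency. Fitting A and a to a
# species' hearing range yields a frequency warping analogous to the mel
# scale but matched to that species' critical bands.

#' Fit a Greenwood map to a hearing range
#'
#' Solves `A = fmin / (1 - k)` and `a = log10(fmax / A + k)` so that the
#' forward map hits `f(0) = fmin` and `f(1) = fmax` exactly.
#'
#' @param fmin,fmax Hearing-range limits in Hz, `0 < fmin < fmax`.
#' @param k Greenwood integration constant in (0, 1); 0.88 is the
#'   conventional species-independent value.
#' @return A `greenwood_map` with fields `A`, `a`, `k`.
#' @export
greenwood_from_range <- function(fmin, fmax, k = 0.88) {
  check_positive(fmin, "fmin")
  if (!is.numeric(fmax) || fmax <= fmin) {
    stop("'fmax' must exceed 'fmin'", call. = FALSE)
  }
  if (!is.numeric(k) || k <= 0 || k >= 1) {
    stop("'k' must lie in (0, 1)", call. = FALSE)
  }
  A <- fmin / (1 - k)
  a <- log10(fmax / A + k)
  structure(list(A = A, a = a, k = k), class = "greenwood_map")
}

#' Greenwood forward map: cochlear position to frequency
#' @param map A `greenwood_map`.
#' @param x Normalized position(s) in \[0, 1\].
#' @return Frequency in Hz.
#' @export
greenwood_frequency <- function(map, x) map$A * (10^(map$a * x) - map$k)

#' Greenwood inverse map: frequency to cochlear position
#' @param map A `greenwood_map`.
#' @param f Frequency (Hz).
#' @return Normalized position.
#' @export
greenwood_position <- function(map, f) log10(f / map$A + map$k) / map$a

#' Triangular filterbank on the Greenwood-warped axis
#'
#' `n_filters + 2` edge points are placed equally spaced on the warped
#' axis between the positions of `fmin` and `fmax`, mapped back to Hz,
#' and each filter gets a unit-peak triangle over the FFT bin grid
#' between consecutive edges.
#'
#' @param map A `greenwood_map`.
#' @param n_filters Number of filters (>= 2).
#' @param fmin,fmax Band limits (Hz); `fmax` must not exceed Nyquist.
#' @param rate Sampling rate (Hz).
#' @param fft_size FFT length in samples (the STFT frame length).
#' @return A `filterbank`: `centers` (Hz), `edges` (Hz), `weights`
#'   (filters x bins), `freqs` (Hz per bin), `rate`, `fft_size`.
#' @export
build_filterbank <- function(map, n_filters, fmin, fmax, rate, fft_size) {
  stopifnot(inherits(map, "greenwood_map"))
  if (n_filters < 2) stop("'n_filters' must be >= 2", call. = FALSE)
  if (fmax > rate / 2 + 1e-9) {
    stop("'fmax' exceeds the Nyquist frequency", call. = FALSE)
  }
  x_edges <- seq(greenwood_position(map, fmin),
                 greenwood_position(map, fmax),
                 length.out = n_filters + 2L)
  edges <- greenwood_frequency(map, x_edges)
  n_bins <- fft_size %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1) * rate / fft_size
  weights <- matrix(0, nrow = n_filters, ncol = n_bins)
  for (j in seq_len(n_filters)) {
    l <- edges[j]; c0 <- edges[j + 1L]; r <- edges[j + 2L]
    rising <- (freqs - l) / (c0 - l)
    falling <- (r - freqs) / (r - c0)
    weights[j, ] <- pmax(0, pmin(rising, falling))
  }
  structure(list(centers = edges[2:(n_filters + 1L)], edges = edges,
                 weights = weights, freqs = freqs, rate = rate,
                 fft_size = as.integer(fft_size),
                 n_filters = as.integer(n_filters)),
            class = "filterbank")
}

# Orthonormal DCT-II matrix (rows = coefficients, cols = input points).
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  m <- outer(k, k, function(kk, nn) {
    sqrt(2 / n) * cos(pi * (nn + 0.5) * kk / n)
  })
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Greenwood-frequency cepstral coefficients per frame
#'
#' Per spectrogram frame: squared magnitudes -> filterbank energies ->
#' floored log -> orthonormal DCT-II -> first `n_ceps` coefficients
#' (excluding the overall-gain coefficient c0 when `drop_c0`).
#'
#' @param spec A `spectrogram` whose frequency grid matches the
#'   filterbank's FFT layout.
#' @param fb A [build_filterbank()] result.
#' @param n_ceps Number of cepstral coefficients to keep.
#' @param drop_c0 Exclude c0 so features are invariant to overall gain.
#' @return A `feature_sequence`: `vectors` (frames x n_ceps), `times`.
#' @export
gfcc_frames <- function(spec, fb, n_ceps = 12, drop_c0 = TRUE) {
  stopifnot(inherits(spec, "spectrogram"), inherits(fb, "filterbank"))
  if (ncol(spec$values) != length(fb$freqs) ||
      max(abs(spec$freqs - fb$freqs)) > 1e-6) {
    stop("spectrogram frequency grid does not match the filterbank layout",
         call. = FALSE)
  }
  if (n_ceps > fb$n_filters) {
    stop("'n_ceps' must not exceed the number of filters", call. = FALSE)
  }
  energies <- spec$values^2 %*% t(fb$weights)   # frames x filters
  # log floor relative to the loudest frame: silent frames collapse to a
  # constant instead of amplifying their numerical microstructure
  floor_e <- max(max(energies) * 1e-10, .Machine$double.xmin)
  log_e <- log(pmax(energies, floor_e))
  D <- dct_matrix(fb$n_filters)
  keep <- if (drop_c0) seq_len(n_ceps) + 1L else seq_len(n_ceps)
  vectors <- log_e %*% t(D[keep, , drop = FALSE])
  structure(list(vectors = vectors, times = spec$times,
                 dim = as.integer(n_ceps)),
            class = "feature_sequence")
}

#' Aggregate frame features over context windows
#'
#' Slides a window over the frame sequence and concatenates the
#' per-dimension sample mean with a per-dimension spread statistic,
#' yielding one context vector of length `2 * dim` per window. The
#' second-order statistic captures the temporal modulation that
#' distinguishes voiced calls from stationary noise; the default is the
#' population variance; the population standard deviation is available
#' via `stat = "sd"`.
#'
#' @param features A `feature_sequence`.
#' @param window Window length in frames (>= 2).
#' @param hop Window hop in frames.
#' @param stat Spread statistic: `"variance"` (default) or `"sd"`.
#' @return A `context_features` object: `vectors` (windows x 2*dim) and
#'   `spans` (windows x 2 matrix of start/end times).
#' @export
aggregate_context <- function(features, window = 10, hop = 5,
                              stat = c("variance", "sd")) {
  stat <- match.arg(stat)
  stopifnot(inherits(features, "feature_sequence"))
  n <- nrow(features$vectors)
  if (window < 2) stop("'window' must be >= 2", call. = FALSE)
  if (window > n) stop("too few frames for one context window", call. = FALSE)
  starts <- seq(1L, n - window + 1L, by = hop)
  d <- ncol(features$vectors)
  vectors <- matrix(0, nrow = length(starts), ncol = 2L * d)
  spans <- matrix(0, nrow = length(starts), ncol = 2L)
  for (i in seq_along(starts)) {
    idx <- starts[i] + seq_len(window) - 1L
    block <- features$vectors[idx, , drop = FALSE]
    mu <- colMeans(block)
    v <- pmax(0, colMeans(block^2) - mu^2)
    vectors[i, ] <- c(mu, if (stat == "sd") sqrt(v) else v)
    spans[i, ] <- features$times[c(idx[1], idx[window])]
  }
  structure(list(vectors = vectors, spans = spans),
            class = "context_features")
}
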