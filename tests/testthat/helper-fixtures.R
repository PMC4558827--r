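# Shared fixtures, built in code at test time.

# FFT peak frequency (Hz) of a clip, searched below `fmax`.
fft_peak <- function(clip, fmax = Inf) {
  X <- Mod(stats::fft(clip$samples))
  freqs <- (seq_along(X) - 1) * clip$rate / length(X)
  sel <- freqs > 0 & freqs <= min(fmax, clip$rate / 2)
  freqs[sel][which.max(X[sel])]
}

# A small annotated soundscape with one rumble over wind.
fixture_soundscape <- function(snr = 0, seed = 11, duration = 20) {
  sp <- soundscape_spec(
    duration, 4000,
    events = list(list(spec = rumble_spec(duration = 3), onset = 5)),
    noises = list(list(spec = noise_spec("wind", duration, 1), onset = 0)),
    in_band_snr = snr, seed = seed)
  compose_soundscape(sp)
}

# Deterministic context-feature matrices for two linearly separable
# classes centred at +u and -u.
fixture_separable <- function(n = 60, d = 24, gap = 2, seed = 3,
                              noise = 0.02) {
  withr::with_seed(seed, {
    # equal-magnitude direction keeps per-dimension variances equal (so
    # standardization cannot rotate the boundary), and near-point
    # classes make the max-margin direction coincide with the planted
    # normal: in high dimension the margin direction of diffuse clouds
    # legitimately deviates from the class-mean axis
    u <- sample(c(-1, 1), d, replace = TRUE) / sqrt(d)
    pos <- matrix(rnorm(n * d, 0, noise), n, d) +
      matrix(gap / 2 * u, n, d, byrow = TRUE)
    neg <- matrix(rnorm(n * d, 0, noise), n, d) -
      matrix(gap / 2 * u, n, d, byrow = TRUE)
    list(pos = pos, neg = neg, normal = u)
  })
}

# Angle (degrees) between two directions, sign-insensitive.
angle_between <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# Brute-force maximum one-to-one interval matching by enumeration
# (reference oracle for greedy event matching, feasible for <= 5 events).
exhaustive_match_count <- function(detections, truth) {
  n_d <- nrow(detections); n_t <- nrow(truth)
  if (n_d == 0 || n_t == 0) return(0L)
  overlap <- function(i, j) {
    min(detections$end[i], truth$end[j]) -
      max(detections$start[i], truth$start[j]) > 0
  }
  best <- 0L
  # enumerate assignments of detections to truths (or none)
  recurse <- function(i, used, count) {
    if (i > n_d) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used, count)
    for (j in seq_len(n_t)) {
      if (!used[j] && overlap(i, j)) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n_t), 0L)
  best
}

# Tiny rendered scene shared across visual tests.
fixture_scene <- function(n_frames = 6, distance = "near", n_elephants = 1,
                          seed = 5, width = 160, height = 120) {
  render_scene(scene_spec(width = width, height = height,
                          n_frames = n_frames, distance_class = distance,
                          n_elephants = n_elephants, seed = seed))
}

# Mean band-limited energy of a clip-like object (samples + rate).
band_energy_of <- function(clip, band) {
  x <- clip$samples
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * clip$rate / n
  keep <- freqs >= band[1] & freqs <= band[2]
  sum(Mod(X[keep])^2) / n^2
}
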