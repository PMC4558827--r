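test_that("synthetic rumbles place their harmonics where specified", {
  # single 20 Hz partial
  clip <- synth_rumble(rumble_spec(20, 20, 2, n_harmonics = 1), 1000, seed = 3)
  expect_equal(fft_peak(clip, 500), 20, tolerance = 1 / 20)
  # five-harmonic stack: peaks at 20, 40, ..., 100 Hz
  c5 <- synth_rumble(rumble_spec(20, 20, 2, n_harmonics = 5), 1000, seed = 3)
  X <- Mod(stats::fft(c5$samples))
  freqs <- (seq_along(X) - 1) * 1000 / length(X)
  for (h in 1:5) {
    sel <- freqs > 20 * h - 8 & freqs < 20 * h + 8
    expect_equal(freqs[sel][which.max(X[sel])], 20 * h, tolerance = 1 / (20 * h))
  }
  # zero gain produces a silent clip of the requested length
  z <- synth_rumble(rumble_spec(20, 20, 2, amplitude = 0), 1000)
  expect_true(all(z$samples == 0))
  expect_equal(clip_duration(z), 2)
  # harmonics above Nyquist are dropped, not an error
  hi <- synth_rumble(rumble_spec(30, 30, 1, n_harmonics = 50), 200, seed = 1)
  expect_true(all(is.finite(hi$samples)))
})

test_that("rumble spec validation names the offending field", {
  expect_error(rumble_spec(duration = -1), "duration")
  expect_error(rumble_spec(f0_start = 2), "f0")
  expect_error(synth_rumble(rumble_spec(), rate = -10), "rate")
})

test_that("noise generators match their kind and are seed-deterministic", {
  # engine: harmonic stack at engine_f0
  eng <- synth_noise(noise_spec("engine", 10, engine_f0 = 25), 1000, seed = 2)
  X <- Mod(stats::fft(eng$samples))
  freqs <- (seq_along(X) - 1) * 1000 / length(X)
  for (h in 1:2) {
    sel <- freqs > 25 * h - 5 & freqs < 25 * h + 5
    expect_equal(freqs[sel][which.max(X[sel])], 25 * h, tolerance = 0.05)
  }
  # wind is concentrated below the low-pass cutoff
  wind <- synth_noise(noise_spec("wind", 5), 4000, seed = 2)
  lo <- band_energy_of(wind, c(0, 200))
  hi <- band_energy_of(wind, c(500, 2000))
  expect_gt(lo, 10 * hi)
  # zero level is silent; same seed reproduces bit-identical samples
  expect_true(all(synth_noise(noise_spec("wind", 2, level = 0), 1000)$samples == 0))
  a <- synth_noise(noise_spec("rain", 3), 1000, seed = 9)
  b <- synth_noise(noise_spec("rain", 3), 1000, seed = 9)
  expect_identical(a, b)
  expect_error(noise_spec("hail", 2), "wind")
})

test_that("soundscapes mix at the requested in-band SNR with exact annotations", {
  # empty scene
  empty <- compose_soundscape(soundscape_spec(10, 1000, seed = 1))
  expect_true(all(empty$clip$samples == 0))
  expect_equal(nrow(empty$events), 0L)
  # bookkeeping: one rumble at onset 3 s for 2 s
  one <- compose_soundscape(soundscape_spec(
    10, 1000, events = list(list(spec = rumble_spec(duration = 2), onset = 3)),
    seed = 1))
  expect_equal(one$events$start, 3)
  expect_equal(one$events$end, 5)
  expect_equal(one$events$label, "rumble")
  # in-band SNR calibration: measured ratio within +-0.5 dB of -5 dB
  sp <- soundscape_spec(
    20, 4000,
    events = list(list(spec = rumble_spec(duration = 3), onset = 5),
                  list(spec = rumble_spec(15, 18, duration = 2), onset = 12)),
    noises = list(list(spec = noise_spec("wind", 20, 1), onset = 0)),
    in_band_snr = -5, seed = 7)
  mix <- compose_soundscape(sp)
  # re-derive the mixed components: background alone, then rumble = mix - bg
  bg_only <- compose_soundscape(soundscape_spec(
    20, 4000, noises = sp$noises, seed = 7))
  # scale background to the mix normalization via least squares fit on a
  # rumble-free stretch
  idx_free <- 1:(4000 * 4)
  alpha <- sum(mix$clip$samples[idx_free] * bg_only$clip$samples[idx_free]) /
    sum(bg_only$clip$samples[idx_free]^2)
  for (r in seq_len(nrow(mix$events))) {
    iv <- round(mix$events$start[r] * 4000):round(mix$events$end[r] * 4000 - 1)
    rumble_part <- mix$clip$samples[iv] - alpha * bg_only$clip$samples[iv]
    e_r <- band_energy_of(list(samples = rumble_part, rate = 4000), c(5, 150))
    e_b <- band_energy_of(list(samples = alpha * bg_only$clip$samples[iv],
                               rate = 4000), c(5, 150))
    expect_equal(10 * log10(e_r / e_b), -5, tolerance = 0.5 / 5)
  }
  # engine confounds go to the separate annotation list
  eng <- compose_soundscape(soundscape_spec(
    10, 1000,
    noises = list(list(spec = noise_spec("engine", 8), onset = 1)), seed = 2))
  expect_equal(eng$noise_events$label, "engine")
  expect_equal(nrow(eng$events), 0L)
  # events outside the scene are rejected
  expect_error(soundscape_spec(
    5, 1000, events = list(list(spec = rumble_spec(duration = 3), onset = 4))),
    "total_duration")
})

test_that("soundscape generation is bit-identical under a fixed seed and peak-bounded", {
  sp <- soundscape_spec(
    10, 2000,
    events = list(list(spec = rumble_spec(duration = 2), onset = 2)),
    noises = list(list(spec = noise_spec("wind", 10, 0.8), onset = 0),
                  list(spec = noise_spec("rain", 10, 0.4), onset = 0)),
    in_band_snr = 0, seed = 13)
  a <- compose_soundscape(sp)
  b <- compose_soundscape(sp)
  expect_identical(a, b)
  expect_lte(max(abs(a$clip$samples)), 1)
  expect_equal(max(abs(a$clip$samples)), 0.9)
})

test_that("generated rumble intervals carry above-median band energy", {
  for (seed in 1:3) {
    mix <- fixture_soundscape(snr = 0, seed = seed)
    spec <- stft_spectrogram(mix$clip)
    in_band <- spec$freqs >= 5 & spec$freqs <= 150
    frame_e <- rowSums(spec$values[, in_band]^2)
    inside <- spec$times >= mix$events$start[1] &
      spec$times <= mix$events$end[1]
    expect_gt(max(frame_e[inside]), median(frame_e))
  }
})
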