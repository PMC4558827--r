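# Seeded synthetic soundscapes: rumbles, interfering noise, and composed
# annotated mixtures standing in for field recordings.

#' Rumble synthesis parameters
#'
#' Describes one synthetic elephant rumble: a harmonic stack on a linearly
#' interpolated fundamental-frequency contour, shaped by a formant-like
#' spectral envelope and an attack/release amplitude envelope. Elephant
#' rumbles have fundamentals of roughly 10-30 Hz; the constructor accepts
#' 5-40 Hz so detuned confounds can be generated too.
#'
#' @param f0_start,f0_end Fundamental frequency at onset and offset (Hz).
#' @param duration Call duration in seconds.
#' @param n_harmonics Number of harmonics (>= 1); harmonics above Nyquist
#'   are silently dropped at synthesis time.
#' @param envelope_attack,envelope_release Raised-cosine ramp lengths (s).
#' @param formant_centers Centers (Hz) of raised-Gaussian envelope peaks
#'   emulating vocal-tract resonances.
#' @param amplitude Linear peak gain of the synthesized call.
#' @return A `rumble_spec` list.
#' @export
rumble_spec <- function(f0_start = 20, f0_end = 20, duration = 3,
                        n_harmonics = 8, envelope_attack = 0.3,
                        envelope_release = 0.5,
                        formant_centers = c(40, 120), amplitude = 1) {
  check_positive(duration, "duration")
  for (f0 in c(f0_start, f0_end)) {
    if (!is.numeric(f0) || f0 < 5 || f0 > 40) {
      stop("'f0_start'/'f0_end' must lie in [5, 40] Hz", call. = FALSE)
    }
  }
  if (n_harmonics < 1) stop("'n_harmonics' must be >= 1", call. = FALSE)
  if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
  structure(list(f0_start = f0_start, f0_end = f0_end, duration = duration,
                 n_harmonics = as.integer(n_harmonics),
                 envelope_attack = envelope_attack,
                 envelope_release = envelope_release,
                 formant_centers = formant_centers, amplitude = amplitude),
            class = "rumble_spec")
}

#' Draw a random rumble specification
#'
#' Fundamentals are drawn uniformly from 10-30 Hz (the rumble range) and
#' durations uniformly from 1-5 s; the f0 contour drifts by up to 20\%
#' between onset and offset.
#'
#' @param seed Integer seed.
#' @return A `rumble_spec`.
#' @export
random_rumble_spec <- function(seed) {
  with_seed(seed, {
    f0 <- runif(1, 10, 30)
    rumble_spec(f0_start = f0,
                f0_end = f0 * runif(1, 0.8, 1.2),
                duration = runif(1, 1, 5),
                n_harmonics = sample(5:10, 1))
  })
}

#' Noise synthesis parameters
#'
#' @param kind One of `"wind"` (low-passed broadband noise with slow
#'   amplitude modulation), `"rain"` (sparse impulsive broadband bursts) or
#'   `"engine"` (harmonic stack with near-constant fundamental, the main
#'   acoustic confound for rumbles).
#' @param duration Duration in seconds.
#' @param level Linear peak gain.
#' @param engine_f0 Fundamental (Hz) for `kind = "engine"`, in \[15, 60\].
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind, duration, level = 1, engine_f0 = 30) {
  kinds <- c("wind", "rain", "engine")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop(sprintf("'kind' must be one of: %s", paste(kinds, collapse = ", ")),
         call. = FALSE)
  }
  check_positive(duration, "duration")
  if (level < 0) stop("'level' must be >= 0", call. = FALSE)
  if (kind == "engine" && (engine_f0 < 15 || engine_f0 > 60)) {
    stop("'engine_f0' must lie in [15, 60] Hz", call. = FALSE)
  }
  structure(list(kind = kind, duration = duration, level = level,
                 engine_f0 = engine_f0), class = "noise_spec")
}

peak_normalize <- function(x, target) {
  m <- max(abs(x))
  if (m == 0 || target == 0) return(rep(0, length(x)))
  x * (target / m)
}

# Two-peak raised-Gaussian formant-like spectral envelope with a floor so
# harmonics between resonances are attenuated, not removed.
formant_envelope <- function(freq, centers) {
  env <- rep(0.25, length(freq))
  for (c0 in centers) {
    env <- env + exp(-(freq - c0)^2 / (2 * (0.35 * c0)^2))
  }
  env
}

#' Synthesize one rumble
#'
#' @param spec A [rumble_spec()].
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed (controls the small f0 jitter).
#' @return An [audio_clip()] of length `spec$duration`.
#' @export
synth_rumble <- function(spec, rate, seed = 1) {
  stopifnot(inherits(spec, "rumble_spec"))
  check_positive(rate, "rate")
  n <- max(1L, round(spec$duration * rate))
  t <- (seq_len(n) - 1) / rate
  f0 <- seq(spec$f0_start, spec$f0_end, length.out = n)
  # slow multiplicative jitter (~1%) so repeated calls differ per seed
  jitter <- with_seed(seed, {
    knots <- pmax(2L, ceiling(spec$duration * 2))
    approx(seq(0, spec$duration, length.out = knots),
           rnorm(knots, 0, 0.01), xout = t, rule = 2)$y
  })
  f0 <- f0 * (1 + jitter)
  phase <- 2 * pi * cumsum(f0) / rate
  x <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    fh <- h * f0
    if (min(fh) >= rate / 2) next          # above Nyquist: drop
    gain <- (1 / h) * formant_envelope(fh, spec$formant_centers)
    gain[fh >= rate / 2] <- 0
    x <- x + gain * sin(h * phase)
  }
  # attack/release raised-cosine ramps
  atk <- min(n, max(1L, round(spec$envelope_attack * rate)))
  rel <- min(n, max(1L, round(spec$envelope_release * rate)))
  env <- rep(1, n)
  env[seq_len(atk)] <- 0.5 * (1 - cos(pi * seq_len(atk) / atk))
  env[n - rel + seq_len(rel)] <- pmin(
    env[n - rel + seq_len(rel)],
    0.5 * (1 + cos(pi * seq_len(rel) / rel)))
  audio_clip(peak_normalize(x * env, spec$amplitude), rate)
}

#' Synthesize background/confound noise
#'
#' @param spec A [noise_spec()].
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An [audio_clip()].
#' @export
synth_noise <- function(spec, rate, seed = 1) {
  stopifnot(inherits(spec, "noise_spec"))
  check_positive(rate, "rate")
  n <- max(2L, round(spec$duration * rate))
  x <- with_seed(seed, switch(
    spec$kind,
    wind = {
      w <- rnorm(n)
      bf <- signal::butter(4, min(0.99, 150 / (rate / 2)), type = "low")
      w <- as.numeric(signal::filtfilt(bf, w))
      # slow amplitude modulation: gusts on a ~0.7 s grid
      knots <- max(3L, ceiling(spec$duration / 0.7))
      am <- approx(seq(0, spec$duration, length.out = knots),
                   runif(knots, 0.25, 1), xout = (seq_len(n) - 1) / rate,
                   rule = 2)$y
      w * am
    },
    rain = {
      w <- numeric(n)
      n_drop <- rpois(1, 40 * spec$duration)
      if (n_drop > 0) {
        onsets <- sort(sample.int(n, min(n_drop, n)))
        for (o in onsets) {
          len <- sample(4:32, 1)
          idx <- o:min(n, o + len - 1L)
          w[idx] <- w[idx] +
            runif(1, 0.2, 1) * rnorm(length(idx)) *
            exp(-seq_along(idx) / (len / 3))
        }
      }
      w
    },
    engine = {
      t <- (seq_len(n) - 1) / rate
      drift <- approx(seq(0, spec$duration, length.out = max(3L, ceiling(spec$duration / 2))),
                      rnorm(max(3L, ceiling(spec$duration / 2)), 0, 0.004),
                      xout = t, rule = 2)$y
      f0 <- spec$engine_f0 * (1 + drift)
      phase <- 2 * pi * cumsum(f0) / rate
      w <- numeric(n)
      for (h in 1:10) {
        if (h * max(f0) >= rate / 2) break
        w <- w + (1 / h) * sin(h * phase)
      }
      am <- approx(seq(0, spec$duration, length.out = max(3L, ceiling(spec$duration))),
                   runif(max(3L, ceiling(spec$duration)), 0.85, 1),
                   xout = t, rule = 2)$y
      # vehicles approach and recede: raised-cosine fade over ~20% of
      # the event (at least 2 s), instead of physically implausible
      # instantaneous on/off steps
      ramp <- min(n %/% 2L, max(round(0.2 * n), round(2 * rate)))
      env <- rep(1, n)
      env[seq_len(ramp)] <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
      env[n - ramp + seq_len(ramp)] <- pmin(
        env[n - ramp + seq_len(ramp)],
        0.5 * (1 + cos(pi * seq_len(ramp) / ramp)))
      w * am * env
    }))
  audio_clip(peak_normalize(x, spec$level), rate)
}

#' Soundscape composition parameters
#'
#' @param total_duration Scene length in seconds.
#' @param rate Sampling rate (Hz); 4000 Hz suffices for rumble fundamentals
#'   and their low harmonics.
#' @param events List of `list(spec = rumble_spec, onset = seconds)`.
#' @param noises List of `list(spec = noise_spec, onset = seconds)`.
#' @param in_band_snr Target rumble-to-background energy ratio (dB) inside
#'   `snr_band` and the rumble interval; `NA` leaves rumble gains untouched.
#' @param snr_band Frequency band (Hz) over which the ratio is measured.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return A `soundscape_spec` list.
#' @export
soundscape_spec <- function(total_duration, rate = 4000, events = list(),
                            noises = list(), in_band_snr = NA,
                            snr_band = c(5, 150), seed = 1) {
  check_positive(total_duration, "total_duration")
  check_positive(rate, "rate")
  for (ev in events) {
    stopifnot(inherits(ev$spec, "rumble_spec"), is.numeric(ev$onset))
    if (ev$onset < 0 || ev$onset + ev$spec$duration > total_duration) {
      stop("event exceeds total_duration", call. = FALSE)
    }
  }
  for (nz in noises) {
    stopifnot(inherits(nz$spec, "noise_spec"), is.numeric(nz$onset))
    if (nz$onset < 0 || nz$onset + nz$spec$duration > total_duration) {
      stop("noise exceeds total_duration", call. = FALSE)
    }
  }
  structure(list(total_duration = total_duration, rate = rate,
                 events = events, noises = noises, in_band_snr = in_band_snr,
                 snr_band = snr_band, seed = as.integer(seed)),
            class = "soundscape_spec")
}

# Mean energy of a signal restricted to a frequency band, by FFT.
band_energy <- function(x, rate, band) {
  n <- length(x)
  if (n < 2L) return(0)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs >= band[1] & freqs <= band[2]
  sum(Mod(X[keep])^2) / n
}

#' Compose an annotated synthetic soundscape
#'
#' Mixes rumbles and noises additively at their onsets. When
#' `in_band_snr` is set, each rumble is rescaled so that the ratio of its
#' band-limited energy to the background's, inside the rumble interval and
#' `snr_band`, matches the target. The final mix is peak-normalized to 0.9.
#'
#' @param spec A [soundscape_spec()].
#' @return A list with `clip` (an [audio_clip()]), `events` (rumble
#'   annotations) and `noise_events` (engine annotations, kept separate so
#'   evaluation can report confusions; they are never counted as
#'   positives).
#' @export
compose_soundscape <- function(spec) {
  stopifnot(inherits(spec, "soundscape_spec"))
  n <- round(spec$total_duration * spec$rate)
  background <- numeric(n)
  noise_rows <- list()
  for (i in seq_along(spec$noises)) {
    nz <- spec$noises[[i]]
    clip <- synth_noise(nz$spec, spec$rate, derive_seed(spec$seed, 100L + i))
    i0 <- round(nz$onset * spec$rate)
    idx <- seq_along(clip$samples) + i0
    idx_ok <- idx <= n
    background[idx[idx_ok]] <- background[idx[idx_ok]] +
      clip$samples[idx_ok]
    if (nz$spec$kind == "engine") {
      noise_rows[[length(noise_rows) + 1L]] <-
        data.frame(start = nz$onset, end = nz$onset + nz$spec$duration,
                   label = "engine", stringsAsFactors = FALSE)
    }
  }
  mix <- background
  ev_rows <- list()
  for (i in seq_along(spec$events)) {
    ev <- spec$events[[i]]
    clip <- synth_rumble(ev$spec, spec$rate, derive_seed(spec$seed, 200L + i))
    i0 <- round(ev$onset * spec$rate)
    idx <- seq_along(clip$samples) + i0
    idx <- idx[idx <= n]
    r <- clip$samples[seq_along(idx)]
    if (is.finite(spec$in_band_snr)) {
      e_bg <- band_energy(background[idx], spec$rate, spec$snr_band)
      e_r <- band_energy(r, spec$rate, spec$snr_band)
      if (e_bg > 0 && e_r > 0) {
        r <- r * sqrt(10^(spec$in_band_snr / 10) * e_bg / e_r)
      }
    }
    mix[idx] <- mix[idx] + r
    ev_rows[[i]] <- data.frame(start = ev$onset,
                               end = ev$onset + ev$spec$duration,
                               label = "rumble", stringsAsFactors = FALSE)
  }
  mix <- peak_normalize(mix, 0.9)
  list(clip = audio_clip(mix, spec$rate),
       events = if (length(ev_rows)) do.call(rbind, ev_rows) else annotations(),
       noise_events = if (length(noise_rows)) do.call(rbind, noise_rows)
                      else annotations())
}
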