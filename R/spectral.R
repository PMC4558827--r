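# Spectrogram computation and ridge-enhancing noise reduction.

#' Magnitude short-time Fourier spectrogram
#'
#' Frames the clip with a Hann taper and no zero-padding beyond the final
#' full frame. Frame times are frame centers; the frame count is
#' `floor((n_samples - frame_samples) / hop_samples) + 1`.
#'
#' @param clip An [audio_clip()].
#' @param frame_len Frame length in seconds (default 0.3 s).
#' @param hop Hop between frames in seconds (default 0.1 s, i.e. 2/3
#'   overlap).
#' @param window Taper identifier; only `"hann"` is implemented.
#' @return A `spectrogram` object: `values` (frames x bins magnitude
#'   matrix), `times` (s, frame centers), `freqs` (Hz), `frame_len`,
#'   `hop`, `rate`.
#' @export
stft_spectrogram <- function(clip, frame_len = 0.3, hop = 0.1,
                             window = "hann") {
  stopifnot(inherits(clip, "audio_clip"))
  check_positive(frame_len, "frame_len")
  check_positive(hop, "hop")
  if (hop >= frame_len) stop("'hop' must be smaller than 'frame_len'",
                             call. = FALSE)
  if (!identical(window, "hann")) stop("unknown window taper", call. = FALSE)
  nw <- round(frame_len * clip$rate)
  nh <- round(hop * clip$rate)
  ns <- length(clip$samples)
  if (ns < nw) stop("clip shorter than one frame", call. = FALSE)
  n_frames <- (ns - nw) %/% nh + 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))
  frames <- matrix(0, nrow = nw, ncol = n_frames)
  for (i in seq_len(n_frames)) {
    frames[, i] <- clip$samples[(i - 1L) * nh + seq_len(nw)] * taper
  }
  spec <- Mod(mvfft(frames))
  n_bins <- nw %/% 2L + 1L
  structure(list(values = t(spec[seq_len(n_bins), , drop = FALSE]),
                 times = (seq_len(n_frames) - 1) * nh / clip$rate +
                   frame_len / 2,
                 freqs = (seq_len(n_bins) - 1) * clip$rate / nw,
                 frame_len = frame_len, hop = hop, rate = clip$rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d bins, %.3f-%.1f Hz>\n",
              nrow(x$values), ncol(x$values), x$freqs[1],
              x$freqs[length(x$freqs)]))
  invisible(x)
}

#' Spectrogram enhancement parameters
#'
#' @param bg_window_t,bg_window_f Median-background window extent in
#'   seconds and Hz.
#' @param bg_quantile Order statistic used as the local background
#'   estimate (0.5 = running median; lower values track the noise floor
#'   more aggressively).
#' @param beta Soft-mask steepness, per dB.
#' @param tau Local contrast threshold in dB: structure must stand `tau`
#'   dB above its local median background to survive attenuation.
#' @param coherence_t Temporal coherence extent (s): the local contrast
#'   is averaged over this window along time before masking, so ridges
#'   that persist (frequency contours, harmonics) keep their contrast
#'   while short-lived noise speckle is averaged away.
#' @param mask_floor Lower bound of the soft mask (linear). Diffuse
#'   components are attenuated to this gain rather than to zero, which
#'   preserves the background texture that downstream cepstral features
#'   standardize against (0.05 is a 26 dB cut).
#' @param floor_db Dynamic-range floor (dB, relative to the spectrogram
#'   maximum) applied before taking logs.
#' @return An `enhance_params` list.
#' @export
enhance_params <- function(bg_window_t = 1.5, bg_window_f = 20,
                           bg_quantile = 0.5, beta = 2, tau = 3,
                           coherence_t = 0.7, mask_floor = 0.05,
                           floor_db = -80) {
  check_fraction(bg_quantile, "bg_quantile", open = FALSE)
  check_positive(bg_window_t, "bg_window_t")
  check_positive(bg_window_f, "bg_window_f")
  check_positive(beta, "beta")
  check_positive(tau, "tau")
  check_positive(coherence_t, "coherence_t")
  check_fraction(mask_floor, "mask_floor", open = FALSE)
  structure(list(bg_window_t = bg_window_t, bg_window_f = bg_window_f,
                 bg_quantile = bg_quantile, beta = beta, tau = tau,
                 coherence_t = coherence_t, mask_floor = mask_floor,
                 floor_db = floor_db),
            class = "enhance_params")
}

# Centered moving average along rows (time axis) with edge truncation.
running_mean_t <- function(x, win) {
  if (win <= 1L) return(x)
  n <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  half <- win %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
}

odd_window <- function(extent, step, limit) {
  w <- max(1L, round(extent / step))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(min(w, if (limit %% 2L == 0L) limit - 1L else limit))
}

#' Enhance well-localized spectro-temporal ridges
#'
#' Image-processing noise reduction on the spectrogram: the dB image is
#' compared against a local 2-D order-statistic background, and a
#' logistic soft mask keeps components standing more than `tau` dB above
#' background
#' (frequency contours, harmonic ridges) while attenuating diffuse energy
#' (wind, rain). The mask is strictly below 1, so enhancement never adds
#' energy.
#'
#' @param spec A `spectrogram`.
#' @param params An [enhance_params()].
#' @return A `spectrogram` with masked values; shape, times and freqs
#'   unchanged.
#' @export
enhance_spectrogram <- function(spec, params = enhance_params()) {
  stopifnot(inherits(spec, "spectrogram"))
  stopifnot(inherits(params, "enhance_params"))
  v <- spec$values
  df <- spec$freqs[2] - spec$freqs[1]
  wt <- odd_window(params$bg_window_t, spec$hop, nrow(v))
  wf <- odd_window(params$bg_window_f, df, ncol(v))
  if (round(params$bg_window_t / spec$hop) > nrow(v) ||
      round(params$bg_window_f / df) > ncol(v)) {
    stop("background window larger than the spectrogram", call. = FALSE)
  }
  vmax <- max(v)
  if (vmax == 0) return(spec)
  floor_lin <- vmax * 10^(params$floor_db / 20)
  L <- 20 * log10(pmax(v, floor_lin))
  B <- .quantile_filter2(L, wt, wf, params$bg_quantile)
  C <- L - B
  wc <- max(1L, round(params$coherence_t / spec$hop))
  C <- running_mean_t(C, min(wc, nrow(C)))
  M <- params$mask_floor + (1 - params$mask_floor) /
    (1 + exp(-params$beta * (C - params$tau)))
  out <- spec
  out$values <- v * M
  out
}

#' Ridge-to-background energy ratio
#'
#' Diagnostic for enhancement quality: the ratio (dB) of mean spectrogram
#' energy inside an annotated interval to the mean energy outside it,
#' both restricted to a frequency band.
#'
#' @param spec A `spectrogram`.
#' @param annotation A one-row annotation data frame (or list) with
#'   `start` and `end` in seconds.
#' @param band Numeric length-2 frequency band (Hz).
#' @return Ratio in dB.
#' @export
snr_ridge <- function(spec, annotation, band) {
  stopifnot(inherits(spec, "spectrogram"))
  inside_t <- spec$times >= annotation$start[1] &
    spec$times <= annotation$end[1]
  in_band <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(inside_t) || all(inside_t) || !any(in_band)) {
    stop("annotation/band selects an empty inside or outside region",
         call. = FALSE)
  }
  e_in <- mean(spec$values[inside_t, in_band]^2)
  e_out <- mean(spec$values[!inside_t, in_band]^2)
  10 * log10(e_in / e_out)
}

#' Total spectrogram energy
#' @param spec A `spectrogram`.
#' @return Sum of squared magnitudes.
#' @export
spectrogram_energy <- function(spec) sum(spec$values^2)
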