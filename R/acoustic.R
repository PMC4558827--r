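# Rumble detection: front-end configuration, training split, classifier
# training, sliding-window detection and event-level evaluation.

#' Acoustic front-end and detector configuration
#'
#' Collects every tunable of the acoustic pipeline with its default.
#'
#' @param frame_len,hop STFT framing in seconds (300 ms frames, 2/3
#'   overlap).
#' @param enhance Apply spectrogram enhancement before feature
#'   extraction.
#' @param enhance_params An [enhance_params()] list.
#' @param fmin,fmax,k Greenwood hearing-range fit (Hz, Hz,
#'   dimensionless).
#' @param n_filters,n_ceps,drop_c0 Filterbank and cepstrum sizes.
#' @param context_window,context_hop Context aggregation in frames.
#' @param C Soft-margin penalty for training.
#' @param threshold Decision threshold on window scores.
#' @param max_gap Maximum gap (s) bridged when merging positive windows.
#' @param min_duration Minimum event duration (s) kept.
#' @param score_smooth Width (windows) of an optional moving average
#'   applied to the window score sequence before thresholding (1, the
#'   default, disables it).
#' @return An `acoustic_config` list.
#' @export
acoustic_config <- function(frame_len = 0.3, hop = 0.1, enhance = TRUE,
                            enhance_params = elewatch::enhance_params(),
                            fmin = 8, fmax = 2000, k = 0.88,
                            n_filters = 26, n_ceps = 12, drop_c0 = TRUE,
                            context_window = 20, context_hop = 5,
                            C = 1, threshold = 0, max_gap = 0.6,
                            min_duration = 1.2, score_smooth = 1) {
  structure(list(frame_len = frame_len, hop = hop, enhance = enhance,
                 enhance_params = enhance_params, fmin = fmin, fmax = fmax,
                 k = k, n_filters = n_filters, n_ceps = n_ceps,
                 drop_c0 = drop_c0, context_window = context_window,
                 context_hop = context_hop, C = C, threshold = threshold,
                 max_gap = max_gap, min_duration = min_duration,
                 score_smooth = score_smooth),
            class = "acoustic_config")
}

#' Run the acoustic front end on a clip
#'
#' Spectrogram, optional enhancement, GFCC, context aggregation.
#'
#' @param clip An [audio_clip()].
#' @param cfg An [acoustic_config()].
#' @return A `context_features` object, or `NULL` when the clip is too
#'   short for a single context window.
#' @export
extract_context_features <- function(clip, cfg = acoustic_config()) {
  nw <- round(cfg$frame_len * clip$rate)
  if (length(clip$samples) < nw) return(NULL)
  spec <- stft_spectrogram(clip, cfg$frame_len, cfg$hop)
  if (nrow(spec$values) < cfg$context_window) return(NULL)
  if (isTRUE(cfg$enhance)) {
    spec <- enhance_spectrogram(spec, cfg$enhance_params)
  }
  map <- greenwood_from_range(cfg$fmin, min(cfg$fmax, clip$rate / 2), cfg$k)
  fb <- build_filterbank(map, cfg$n_filters, cfg$fmin,
                         min(cfg$fmax, clip$rate / 2), clip$rate, nw)
  feats <- gfcc_frames(spec, fb, cfg$n_ceps, cfg$drop_c0)
  aggregate_context(feats, cfg$context_window, cfg$context_hop)
}

#' Split annotated rumbles into training and test sets
#'
#' Mirrors the protocol of training from a small random fraction of the
#' annotated rumbles plus negative spans drawn from annotation-free
#' regions.
#'
#' @param ann Annotation data frame; rows labelled `"rumble"` are the
#'   positives.
#' @param negatives Number of negative spans to sample (0 to skip).
#' @param frac Fraction of rumbles used for training, in (0, 1); the
#'   training size is `floor(frac * n_rumbles)`.
#' @param seed Integer seed.
#' @param total_duration Recording length (s), required when sampling
#'   negative spans.
#' @param negative_span Length (s) of each negative span.
#' @return A list with `train_pos` and `test_pos` (row indices into
#'   `ann`) and `negatives` (annotation data frame of sampled spans).
#' @export
make_training_split <- function(ann, negatives = 0, frac = 0.1, seed = 1,
                                total_duration = NULL, negative_span = 2) {
  validate_annotations(ann)
  check_fraction(frac, "frac")
  rumble_idx <- which(ann$label == "rumble")
  n_train <- floor(frac * length(rumble_idx))
  if (n_train < 1L) {
    stop("'frac' yields zero training positives", call. = FALSE)
  }
  train_pos <- with_seed(seed, sort(sample(rumble_idx, n_train)))
  neg <- annotations()
  if (negatives > 0) {
    if (is.null(total_duration)) {
      stop("'total_duration' is required to sample negative spans",
           call. = FALSE)
    }
    starts <- with_seed(derive_seed(seed, 1L), {
      out <- numeric(0)
      tries <- 0L
      while (length(out) < negatives && tries < 1000L * negatives) {
        s <- runif(1, 0, total_duration - negative_span)
        clash <- any(pmin(ann$end, s + negative_span) > pmax(ann$start, s))
        if (!clash) out <- c(out, s)
        tries <- tries + 1L
      }
      out
    })
    if (length(starts) < negatives) {
      stop("could not place the requested negative spans", call. = FALSE)
    }
    neg <- annotations(starts, starts + negative_span,
                       rep("negative", length(starts)))
  }
  list(train_pos = train_pos,
       test_pos = setdiff(rumble_idx, train_pos),
       negatives = neg)
}

#' Train the linear rumble classifier
#'
#' Features are standardized by the training mean and standard deviation
#' and a linear soft-margin SVM is fitted with class weights inversely
#' proportional to class size.
#'
#' @param positives,negatives Context-feature matrices (rows = windows)
#'   or `context_features` objects.
#' @param C Soft-margin penalty.
#' @return A `detector_model`: `weights`, `bias`, `feature_means`,
#'   `feature_scales`, `threshold` (0 by default).
#' @export
train_acoustic_model <- function(positives, negatives, C = 1) {
  as_mat <- function(x) if (inherits(x, "context_features")) x$vectors else x
  fit <- fit_linear_classifier(as_mat(positives), as_mat(negatives), C)
  fit$threshold <- 0
  class(fit) <- "detector_model"
  fit
}

# centered moving average over the window-score sequence
smooth_scores <- function(scores, k) {
  if (k <= 1L || length(scores) < 2L) return(scores)
  n <- length(scores)
  cs <- c(0, cumsum(scores))
  half <- k %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Score context windows with a trained model
#' @param model A `detector_model`.
#' @param context A `context_features` object.
#' @return Numeric decision values, one per window.
#' @export
score_windows <- function(model, context) {
  decision_values(model, context$vectors)
}

#' Detect rumble events in a clip
#'
#' Runs the full front end, scores every context window, and merges
#' consecutive positive windows (gaps up to `max_gap` seconds bridged)
#' into events; events shorter than `min_duration` are discarded. Each
#' event's score is the maximum member window score.
#'
#' @param clip An [audio_clip()].
#' @param model A `detector_model`.
#' @param cfg An [acoustic_config()].
#' @return A data frame of detections: `start`, `end`, `score` (empty,
#'   not an error, when the clip is shorter than one context span).
#' @export
detect_events <- function(clip, model, cfg = acoustic_config()) {
  context <- extract_context_features(clip, cfg)
  if (is.null(context)) {
    return(data.frame(start = numeric(), end = numeric(),
                      score = numeric()))
  }
  scores <- smooth_scores(score_windows(model, context),
                          cfg$score_smooth %||% 1L)
  merge_positive_windows(context, scores, model$threshold,
                         cfg$max_gap, cfg$min_duration)
}

# Merge positive windows (score > threshold) into events, bridging gaps
# up to max_gap seconds and discarding events shorter than min_duration.
merge_positive_windows <- function(context, scores, threshold, max_gap,
                                   min_duration) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      score = numeric())
  pos <- which(scores > threshold)
  if (length(pos) == 0L) return(empty)
  spans <- context$spans[pos, , drop = FALSE]
  sc <- scores[pos]
  ord <- order(spans[, 1])
  spans <- spans[ord, , drop = FALSE]
  sc <- sc[ord]
  events <- list()
  cur <- c(spans[1, ], sc[1])
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans[i, 1] - cur[2] <= max_gap) {
      cur[2] <- max(cur[2], spans[i, 2])
      cur[3] <- max(cur[3], sc[i])
    } else {
      events[[length(events) + 1L]] <- cur
      cur <- c(spans[i, ], sc[i])
    }
  }
  events[[length(events) + 1L]] <- cur
  out <- do.call(rbind, events)
  out <- data.frame(start = out[, 1], end = out[, 2], score = out[, 3])
  out[out$end - out$start >= min_duration, , drop = FALSE]
}

#' Evaluate detected events against annotated truth
#'
#' Greedy one-to-one matching in decreasing overlap-duration order; a
#' detection can match a truth interval iff their temporal overlap is
#' strictly positive. The detection rate is the fraction of truth
#' intervals matched; the false-positive rate is the fraction of emitted
#' detections left unmatched.
#'
#' @param detections Data frame with `start`/`end` (e.g. from
#'   [detect_events()]).
#' @param truth Annotation data frame.
#' @return An `eval_report` list: `n_truth`, `n_detections`,
#'   `n_matched`, `detection_rate`, `false_positive_rate`.
#' @export
evaluate_events <- function(detections, truth) {
  n_t <- nrow(truth)
  n_d <- nrow(detections)
  n_matched <- 0L
  if (n_t > 0L && n_d > 0L) {
    ov <- outer(seq_len(n_d), seq_len(n_t), function(i, j) {
      pmin(detections$end[i], truth$end[j]) -
        pmax(detections$start[i], truth$start[j])
    })
    pairs <- which(ov > 0, arr.ind = TRUE)
    match_of_d <- rep(NA_integer_, n_d)   # truth index per detection
    match_of_t <- rep(NA_integer_, n_t)
    if (nrow(pairs) > 0L) {
      pairs <- pairs[order(ov[pairs], decreasing = TRUE), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (is.na(match_of_d[i]) && is.na(match_of_t[j])) {
          match_of_d[i] <- j
          match_of_t[j] <- i
        }
      }
      # repair the greedy matching to maximum cardinality via
      # augmenting paths, so the result equals the exhaustive optimum
      adj <- lapply(seq_len(n_d), function(i) which(ov[i, ] > 0))
      augment <- function(i, seen) {
        for (j in adj[[i]]) {
          if (seen[j]) next
          seen[j] <- TRUE
          if (is.na(match_of_t[j]) ||
                !is.null(res <- augment(match_of_t[j], seen))) {
            match_of_t[j] <<- i
            match_of_d[i] <<- j
            return(TRUE)
          }
        }
        NULL
      }
      for (i in which(is.na(match_of_d))) {
        augment(i, rep(FALSE, n_t))
      }
    }
    n_matched <- sum(!is.na(match_of_d))
  }
  eval_report(n_t, n_d, n_matched)
}

# n_matched counts matched truths; n_matched_det counts matched
# detections (equal under one-to-one interval matching, but decoupled
# for the visual object-frame convention).
eval_report <- function(n_truth, n_detections, n_matched,
                        n_matched_det = n_matched) {
  structure(list(
    n_truth = as.integer(n_truth),
    n_detections = as.integer(n_detections),
    n_matched = as.integer(n_matched),
    n_matched_det = as.integer(n_matched_det),
    detection_rate = if (n_truth == 0) 0 else n_matched / n_truth,
    false_positive_rate = if (n_detections == 0) 0
                          else (n_detections - n_matched_det) / n_detections),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %d/%d truths detected (%.1f%%), FPR %.1f%% of %d detections>\n",
    x$n_matched, x$n_truth, 100 * x$detection_rate,
    100 * x$false_positive_rate, x$n_detections))
  invisible(x)
}

#' Combine per-recording evaluation reports
#'
#' Sums the underlying counts and recomputes the rates, so pooled rates
#' weight every truth interval and every detection equally.
#'
#' @param reports A list of `eval_report` objects.
#' @return A pooled `eval_report`.
#' @export
combine_reports <- function(reports) {
  n_t <- sum(vapply(reports, `[[`, integer(1), "n_truth"))
  n_d <- sum(vapply(reports, `[[`, integer(1), "n_detections"))
  n_m <- sum(vapply(reports, `[[`, integer(1), "n_matched"))
  n_md <- sum(vapply(reports, `[[`, integer(1), "n_matched_det"))
  eval_report(n_t, n_d, n_m, n_md)
}

#' Persist a detector model as JSON
#' @param model A `detector_model` or `color_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$class <- class(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a detector model from JSON
#' @param path Path written by [write_model()].
#' @return The model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  structure(obj, class = cls)
}
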