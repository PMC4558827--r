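# Seeded end-to-end benchmarks: the synthetic study conditions both
# pipelines are evaluated under. The acoustic suite holds 60 soundscapes
# of 30 s (20 with 1-3 rumbles at in-band SNR of -5, 0 or +5 dB over
# wind/rain backgrounds, 20 noise-only, 20 with engine confounds); the
# visual suite holds near- and far-distance 50-frame sequences at
# 320 x 240.

#' Build the soundscape specifications of the acoustic benchmark
#'
#' @param seed Master seed.
#' @param n_rumble,n_noise,n_engine Scene counts per category.
#' @param duration Scene length (s).
#' @param rate Sampling rate (Hz).
#' @return A list of [soundscape_spec()] objects with a `category`
#'   attribute per element.
#' @export
acoustic_benchmark_specs <- function(seed, n_rumble = 20, n_noise = 20,
                                     n_engine = 20, duration = 30,
                                     rate = 4000) {
  specs <- list()
  idx <- 0L
  for (i in seq_len(n_rumble)) {
    idx <- idx + 1L
    s <- derive_seed(seed, idx)
    specs[[idx]] <- with_seed(s, {
      n_r <- sample(1:3, 1)
      slots <- seq(0, duration, length.out = n_r + 1L)
      events <- lapply(seq_len(n_r), function(j) {
        rs <- random_rumble_spec(derive_seed(s, j))
        room <- (slots[j + 1] - slots[j]) - rs$duration - 1
        list(spec = rs, onset = slots[j] + 0.5 + runif(1, 0, max(0, room)))
      })
      noises <- list(list(spec = noise_spec("wind", duration, level = 1),
                          onset = 0))
      if (runif(1) < 0.5) {
        noises <- c(noises, list(list(
          spec = noise_spec("rain", duration, level = 0.5), onset = 0)))
      }
      sp <- soundscape_spec(duration, rate, events = events,
                            noises = noises,
                            in_band_snr = sample(c(-5, 0, 5), 1), seed = s)
      attr(sp, "category") <- "rumble"
      sp
    })
  }
  for (i in seq_len(n_noise)) {
    idx <- idx + 1L
    s <- derive_seed(seed, idx)
    specs[[idx]] <- with_seed(s, {
      noises <- list(list(spec = noise_spec("wind", duration, level = 1),
                          onset = 0))
      if (i %% 2L == 0L) {
        noises <- c(noises, list(list(
          spec = noise_spec("rain", duration, level = 0.6), onset = 0)))
      }
      sp <- soundscape_spec(duration, rate, noises = noises, seed = s)
      attr(sp, "category") <- "noise"
      sp
    })
  }
  for (i in seq_len(n_engine)) {
    idx <- idx + 1L
    s <- derive_seed(seed, idx)
    specs[[idx]] <- with_seed(s, {
      eng_len <- runif(1, 15, duration - 2)
      noises <- list(
        list(spec = noise_spec("wind", duration, level = 0.7), onset = 0),
        list(spec = noise_spec("engine", eng_len, level = 0.8,
                               engine_f0 = runif(1, 15, 60)),
             onset = runif(1, 0, duration - eng_len)))
      sp <- soundscape_spec(duration, rate, noises = noises, seed = s)
      attr(sp, "category") <- "engine"
      sp
    })
  }
  specs
}

window_overlap_frac <- function(spans, start, end) {
  ov <- pmin(spans[, 2], end) - pmax(spans[, 1], start)
  pmax(0, ov) / (spans[, 2] - spans[, 1])
}

# Smallest threshold at which no detection event forms from these window
# scores: raising the threshold only removes supporting windows, so
# event existence is monotone and the critical point is one of the
# observed scores.
critical_event_threshold <- function(scores, spans, cfg) {
  forms_event <- function(thr) {
    pos <- which(scores > thr)
    if (length(pos) == 0L) return(FALSE)
    s <- spans[pos, , drop = FALSE]
    o <- order(s[, 1])
    s <- s[o, , drop = FALSE]
    cur <- s[1, ]
    for (i in seq_len(nrow(s))[-1]) {
      if (s[i, 1] - cur[2] <= cfg$max_gap) {
        cur[2] <- max(cur[2], s[i, 2])
      } else {
        if (cur[2] - cur[1] >= cfg$min_duration) return(TRUE)
        cur <- s[i, ]
      }
    }
    cur[2] - cur[1] >= cfg$min_duration
  }
  cand <- sort(unique(c(0, scores[scores > 0])))
  for (thr in cand) {
    if (!forms_event(thr)) return(thr)
  }
  max(scores)
}

#' Run the seeded acoustic benchmark
#'
#' Composes the benchmark soundscapes, splits the annotated rumbles via
#' [make_training_split()], trains the linear rumble classifier on
#' context windows from the training scenes (negatives drawn from
#' dedicated rumble-free scenes, three per positive), detects events on
#' every held-out scene and pools the per-scene evaluations.
#'
#' @param seed Master seed for scene synthesis and the split.
#' @param enhance Apply spectrogram enhancement in the front end.
#' @param frac Fraction of rumbles assigned to training.
#' @param cfg An [acoustic_config()]; its `enhance` flag is overridden
#'   by `enhance`.
#' @param specs Optional pre-built scene specs (to share scenes between
#'   runs with and without enhancement).
#' @return A list: `report` (pooled `eval_report`), `model`,
#'   `per_scene` reports, `n_test_scenes`.
#' @export
run_acoustic_benchmark <- function(seed, enhance = TRUE, frac = 0.5,
                                   cfg = acoustic_config(C = 0.3),
                                   specs = NULL) {
  cfg$enhance <- enhance
  if (is.null(specs)) specs <- acoustic_benchmark_specs(seed)
  category <- vapply(specs, attr, character(1), "category")
  scenes <- lapply(specs, compose_soundscape)

  # pooled rumble annotations across scenes
  pooled <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    ev <- scenes[[i]]$events
    if (nrow(ev) == 0L) return(NULL)
    cbind(scene = i, ev)
  }))
  split <- make_training_split(pooled[, c("start", "end", "label")],
                               frac = frac, seed = derive_seed(seed, 777L))
  train_scenes <- sort(unique(pooled$scene[split$train_pos]))
  # 30 rumble-free training sequences (15 wind/rain, 15 engine),
  # mirroring the field protocol of training from sequences without
  # rumbles alongside the sampled rumbles
  calib_scenes <- head(which(category == "noise"), 15)
  neg_scenes <- c(calib_scenes, head(which(category == "engine"), 15))
  # every non-training scene is evaluated; scenes holding training
  # rumbles are evaluated on their held-out rumbles only, with
  # detections overlapping a training interval set aside
  test_scenes <- setdiff(seq_along(scenes), neg_scenes)

  feats <- vector("list", length(scenes))
  for (sc in c(train_scenes, neg_scenes)) {
    feats[[sc]] <- extract_context_features(scenes[[sc]]$clip, cfg)
  }
  pos_rows <- list()
  neg_rows <- list()
  for (sc in train_scenes) {
    ctx <- feats[[sc]]
    if (is.null(ctx)) next
    ev <- pooled[intersect(which(pooled$scene == sc), split$train_pos), ]
    for (r in seq_len(nrow(ev))) {
      hit <- window_overlap_frac(ctx$spans, ev$start[r], ev$end[r]) >= 0.5
      if (any(hit)) {
        pos_rows[[length(pos_rows) + 1L]] <-
          ctx$vectors[hit, , drop = FALSE]
      }
    }
    # annotation-free windows of training scenes are in-scene negatives
    all_ev <- pooled[pooled$scene == sc, ]
    clear <- rep(TRUE, nrow(ctx$spans))
    for (r in seq_len(nrow(all_ev))) {
      clear <- clear &
        window_overlap_frac(ctx$spans, all_ev$start[r], all_ev$end[r]) == 0
    }
    if (any(clear)) {
      neg_rows[[length(neg_rows) + 1L]] <- ctx$vectors[clear, , drop = FALSE]
    }
  }
  positives <- do.call(rbind, pos_rows)
  for (sc in neg_scenes) {
    if (!is.null(feats[[sc]])) {
      neg_rows[[length(neg_rows) + 1L]] <- feats[[sc]]$vectors
    }
  }
  negatives <- do.call(rbind, neg_rows)
  model <- train_acoustic_model(positives, negatives, cfg$C)
  # operating point: the smallest decision threshold at which no event
  # forms on the wind/rain training scenes (event existence is monotone
  # in the threshold); the single worst calibration scene is tolerated
  # so one outlier background does not blunt the detector
  crit <- sort(vapply(calib_scenes, function(sc) {
    sc_scores <- smooth_scores(score_windows(model, feats[[sc]]),
                               cfg$score_smooth %||% 1L)
    critical_event_threshold(sc_scores, feats[[sc]]$spans, cfg)
  }, numeric(1)), decreasing = TRUE)
  model$threshold <- max(model$threshold, crit[min(2L, length(crit))]) +
    1e-6

  per_scene <- vector("list", length(test_scenes))
  n_confusions <- 0L
  for (k in seq_along(test_scenes)) {
    sc <- test_scenes[k]
    det <- detect_events(scenes[[sc]]$clip, model, cfg)
    truth <- scenes[[sc]]$events
    train_iv <- pooled[intersect(which(pooled$scene == sc),
                                 split$train_pos), ]
    if (nrow(train_iv) > 0L) {
      # held-out rumbles only; detections on training intervals are
      # neither credited nor penalized
      truth <- scenes[[sc]]$events[
        setdiff(seq_len(nrow(scenes[[sc]]$events)),
                match(train_iv$start, scenes[[sc]]$events$start)), ,
        drop = FALSE]
      if (nrow(det) > 0L) {
        on_train <- vapply(seq_len(nrow(det)), function(i) {
          any(pmin(det$end[i], train_iv$end) >
                pmax(det$start[i], train_iv$start))
        }, logical(1))
        det <- det[!on_train, , drop = FALSE]
      }
    }
    per_scene[[k]] <- evaluate_events(det, truth)
    # engine-overlapping detections are additionally tallied as
    # confusions (they still count as false positives in the report)
    ne <- scenes[[sc]]$noise_events
    if (nrow(det) > 0L && nrow(ne) > 0L) {
      n_confusions <- n_confusions + sum(vapply(seq_len(nrow(det)),
        function(i) any(pmin(det$end[i], ne$end) >
                          pmax(det$start[i], ne$start)), logical(1)))
    }
  }
  list(report = combine_reports(per_scene), model = model,
       per_scene = per_scene, n_test_scenes = length(test_scenes),
       n_engine_confusions = n_confusions)
}

#' Run the acoustic benchmark with and without enhancement
#'
#' Shares one set of scenes and one split between the two front-end
#' variants so their detection and false-positive rates are directly
#' comparable.
#'
#' @param seed Master seed.
#' @param frac Training fraction of rumbles.
#' @param cfg An [acoustic_config()].
#' @return A list with elements `enhanced` and `plain`, each a
#'   [run_acoustic_benchmark()] result.
#' @export
run_acoustic_benchmark_pair <- function(seed, frac = 0.5,
                                        cfg = acoustic_config(C = 0.3)) {
  specs <- acoustic_benchmark_specs(seed)
  list(enhanced = run_acoustic_benchmark(seed, TRUE, frac, cfg, specs),
       plain = run_acoustic_benchmark(seed, FALSE, frac, cfg, specs))
}

#' Run the seeded visual benchmark
#'
#' Trains one skin-color model on pixels sampled from dedicated near
#' training sequences, then detects and evaluates on a near-distance
#' suite and a far-distance suite rendered under the same background
#' statistics.
#'
#' @param seed Master seed.
#' @param n_near,n_far Number of evaluation sequences per suite.
#' @param n_frames Frames per sequence.
#' @param n_train Number of training sequences.
#' @param cfg A [visual_config()] for the near suite. Far sequences are
#'   segmented with finer bandwidths (`hs` and `hr` halved, half the
#'   minimum region size): resolving objects twenty times smaller needs
#'   a finer partition, which in turn over-segments the background.
#' @param progress Print one line per sequence to standard error.
#' @return A list: `near` and `far` (pooled `eval_report`s), `model`.
#' @export
run_visual_benchmark <- function(seed, n_near = 20, n_far = 8,
                                 n_frames = 50, n_train = 3,
                                 cfg = visual_config(),
                                 progress = FALSE) {
  fg <- list(); bg <- list()
  for (i in seq_len(n_train)) {
    sp <- scene_spec(n_frames = 10, distance_class = "near",
                     n_elephants = 2, seed = derive_seed(seed, 9000L + i))
    scene <- render_scene(sp)
    px <- sample_pixels(scene, 3000, seed = derive_seed(seed, 9100L + i))
    fg[[i]] <- px$foreground
    bg[[i]] <- px$background
  }
  model <- train_skin_model(do.call(rbind, fg), do.call(rbind, bg), cfg$C)

  cfg_far <- cfg
  cfg_far$hs <- cfg$hs / 2
  cfg_far$hr <- cfg$hr / 2
  cfg_far$min_region <- max(1, cfg$min_region %/% 2L)
  run_suite <- function(distance, n_seq, offset, suite_cfg) {
    reports <- vector("list", n_seq)
    for (i in seq_len(n_seq)) {
      sp <- scene_spec(n_frames = n_frames, distance_class = distance,
                       n_elephants = 1 + (i %% 2L),
                       seed = derive_seed(seed, offset + i))
      scene <- render_scene(sp)
      tracks <- detect_visual(scene$frames, model, suite_cfg)
      reports[[i]] <- evaluate_visual(tracks, scene$masks, suite_cfg)
      if (progress) {
        message(sprintf("%s %d/%d: DR %.2f FPR %.2f", distance, i, n_seq,
                        reports[[i]]$detection_rate,
                        reports[[i]]$false_positive_rate))
      }
    }
    combine_reports(reports)
  }
  list(near = run_suite("near", n_near, 100L, cfg),
       far = run_suite("far", n_far, 500L, cfg_far),
       model = model)
}
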