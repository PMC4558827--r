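test_that("the training split follows the floor rule deterministically", {
  ann <- annotations(start = (0:632) * 10, end = (0:632) * 10 + 2,
                     label = "rumble")
  split <- make_training_split(ann, frac = 0.10, seed = 4)
  expect_length(split$train_pos, 63L)
  expect_length(split$test_pos, 570L)
  expect_length(intersect(split$train_pos, split$test_pos), 0L)
  # determinism and the floor rule at small n
  small <- annotations((0:3) * 10, (0:3) * 10 + 2, "rumble")
  s1 <- make_training_split(small, frac = 0.5, seed = 7)
  s2 <- make_training_split(small, frac = 0.5, seed = 7)
  expect_identical(s1$train_pos, s2$train_pos)
  expect_length(s1$train_pos, 2L)
  ten <- annotations((0:9) * 10, (0:9) * 10 + 2, "rumble")
  s3 <- make_training_split(ten, frac = 0.10, seed = 7)
  expect_length(s3$train_pos, 1L)
  expect_length(s3$test_pos, 9L)
  expect_error(make_training_split(ten, frac = 0.05, seed = 1), "zero")
})

test_that("negative spans avoid all annotated intervals", {
  ann <- annotations(c(10, 30, 50), c(14, 34, 54), "rumble")
  split <- make_training_split(ann, negatives = 10, frac = 0.5, seed = 2,
                               total_duration = 100, negative_span = 3)
  expect_equal(nrow(split$negatives), 10L)
  for (i in seq_len(10)) {
    s <- split$negatives$start[i]
    expect_false(any(pmin(ann$end, s + 3) > pmax(ann$start, s)))
  }
})

test_that("the linear classifier separates toy classes and recovers planted boundaries", {
  fx <- fixture_separable()
  model <- train_acoustic_model(fx$pos, fx$neg, C = 1)
  scores_pos <- elewatch:::decision_values(model, fx$pos)
  scores_neg <- elewatch:::decision_values(model, fx$neg)
  expect_true(all(scores_pos > 0))
  expect_true(all(scores_neg < 0))
  # two symmetric classes at +-u: boundary normal within 5 degrees of u
  # (weights live in standardized space; map back before comparing)
  w_orig <- model$weights / model$feature_scales
  expect_lt(angle_between(w_orig, fx$normal), 5)
  # duplication leaves the decision function unchanged on separable data
  m2 <- train_acoustic_model(rbind(fx$pos, fx$pos), rbind(fx$neg, fx$neg), 1)
  expect_lt(angle_between(m2$weights / m2$feature_scales,
                          model$weights / model$feature_scales), 1)
  expect_true(all(elewatch:::decision_values(m2, fx$pos) > 0))
  expect_true(all(elewatch:::decision_values(m2, fx$neg) < 0))
  expect_error(train_acoustic_model(fx$pos, fx$neg[0, , drop = FALSE]),
               "non-empty")
})

test_that("zero-variance feature dimensions get unit scale", {
  pos <- cbind(fixture_separable()$pos, 1)
  neg <- cbind(fixture_separable()$neg, 1)
  model <- train_acoustic_model(pos, neg, 1)
  expect_equal(model$feature_scales[[ncol(pos)]], 1)
  expect_true(all(is.finite(model$weights)))
})

test_that("detection merges positive windows into events per the gap and duration rules", {
  fx <- fixture_separable(d = 24)
  model <- train_acoustic_model(fx$pos, fx$neg, 1)
  # a clip too short for one context span yields an empty list
  cfg <- acoustic_config()
  short <- audio_clip(rnorm(2000) / 10, 4000)
  expect_equal(nrow(detect_events(short, model, cfg)), 0L)
  # constructed scores: the merge rule bridges sub-max_gap holes and
  # drops events shorter than min_duration
  spans <- cbind(seq(0, 9.5, by = 0.5), seq(0, 9.5, by = 0.5) + 0.9)
  scores <- rep(-1, nrow(spans))
  scores[7:9] <- 2          # 3.0 .. 4.9 s run
  scores[15] <- 2           # isolated window: 7.0 .. 7.9 s
  ctx <- structure(list(vectors = matrix(0, nrow(spans), 2),
                        spans = spans), class = "context_features")
  ev <- elewatch:::merge_positive_windows(ctx, scores, 0,
                                          max_gap = 0.6, min_duration = 1.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 3.0)
  expect_equal(ev$end, 4.9)
  expect_equal(ev$score, 2)
})

test_that("raising the threshold never increases the number of detections", {
  mix <- fixture_soundscape(snr = 5, seed = 21, duration = 30)
  fx <- fixture_separable(d = 24)
  model <- train_acoustic_model(fx$pos, fx$neg, 1)
  counts <- vapply(c(-2, -1, 0, 1, 2), function(thr) {
    model$threshold <- thr
    nrow(detect_events(mix$clip, model))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("event evaluation matches the exhaustive one-to-one oracle", {
  # perfect detector
  truth <- annotations(c(0, 5), c(1, 6), "rumble")
  det <- data.frame(start = truth$start, end = truth$end, score = 1)
  r <- evaluate_events(det, truth)
  expect_equal(r$detection_rate, 1)
  expect_equal(r$false_positive_rate, 0)
  # "every 40th detection is not an elephant": 39 matched of 40
  truth40 <- annotations((0:38) * 10, (0:38) * 10 + 2, "rumble")
  det40 <- data.frame(start = c((0:38) * 10 + 0.2, 500),
                      end = c((0:38) * 10 + 1.8, 501), score = 1)
  r40 <- evaluate_events(det40, truth40)
  expect_equal(r40$false_positive_rate, 0.025)
  # hand-checked mixed case
  truth2 <- annotations(c(0, 5), c(1, 6), "rumble")
  det2 <- data.frame(start = c(0.5, 2, 5.2), end = c(1.5, 3, 5.8), score = 1)
  r2 <- evaluate_events(det2, truth2)
  expect_equal(r2$detection_rate, 1)
  expect_equal(r2$false_positive_rate, 1 / 3)
  # degenerate inputs follow the zero conventions
  r0 <- evaluate_events(det2[0, ], truth2[0, ])
  expect_equal(r0$detection_rate, 0)
  expect_equal(r0$false_positive_rate, 0)
  # property: greedy equals the exhaustive optimum on random small cases
  withr::with_seed(31, {
    for (case in 1:60) {
      n_t <- sample(0:4, 1)
      n_d <- sample(0:5, 1)
      truth <- if (n_t > 0) {
        s <- sort(runif(n_t, 0, 20))
        annotations(s, s + runif(n_t, 0.5, 3), "rumble")
      } else annotations()
      det <- data.frame(start = runif(n_d, 0, 20),
                        score = rep(1, n_d))
      det$end <- det$start + runif(n_d, 0.5, 3)
      r <- evaluate_events(det, truth)
      expect_equal(r$n_matched, exhaustive_match_count(det, truth))
      expect_lte(r$n_matched, min(nrow(det), nrow(truth)))
    }
  })
})

test_that("pooled reports recompute rates from summed counts", {
  r1 <- elewatch:::eval_report(4, 5, 4)
  r2 <- elewatch:::eval_report(6, 5, 3)
  pooled <- combine_reports(list(r1, r2))
  expect_equal(pooled$n_truth, 10L)
  expect_equal(pooled$detection_rate, 7 / 10)
  expect_equal(pooled$false_positive_rate, 3 / 10)
})

test_that("detector models survive a JSON round trip", {
  fx <- fixture_separable()
  model <- train_acoustic_model(fx$pos, fx$neg, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$weights, unname(model$weights), tolerance = 1e-12)
  expect_equal(elewatch:::decision_values(back, fx$pos),
               elewatch:::decision_values(model, fx$pos), tolerance = 1e-9)
})
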