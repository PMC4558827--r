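test_that("the skin model separates planted color clouds", {
  withr::with_seed(14, {
    fg <- matrix(c(110, 100, 95), 300, 3, byrow = TRUE) +
      matrix(rnorm(900, 0, 6), 300, 3)
    bg <- matrix(c(95, 105, 52), 300, 3, byrow = TRUE) +
      matrix(rnorm(900, 0, 6), 300, 3)
  })
  model <- train_skin_model(fg, bg)
  expect_true(mean(elewatch:::decision_values(
    model, elewatch:::srgb_to_lab(fg)) > 0) == 1)
  expect_true(mean(elewatch:::decision_values(
    model, elewatch:::srgb_to_lab(bg)) > 0) == 0)
  # swapping the class labels negates the decision function
  swapped <- train_skin_model(bg, fg)
  s1 <- elewatch:::decision_values(model, elewatch:::srgb_to_lab(fg))
  s2 <- elewatch:::decision_values(swapped, elewatch:::srgb_to_lab(fg))
  expect_true(all(sign(s1) == -sign(s2)))
  expect_error(train_skin_model(fg[0, ], bg), "non-empty")
})

test_that("a planted separating plane in Lab is recovered within 5 degrees", {
  withr::with_seed(15, {
    base <- matrix(runif(1200, 0.2, 0.8), 400, 3)  # Lab-ish cloud source
    lab <- elewatch:::srgb_to_lab(base * 255)
    normal <- c(1, 2, -1.5)
    normal <- normal / sqrt(sum(normal^2))
    proj <- drop(scale(lab, scale = FALSE) %*% normal)
    keep <- abs(proj) > 2            # margin
    lab <- lab[keep, ]; base <- base[keep, ]; proj <- proj[keep]
  })
  model <- train_skin_model(base[proj > 0, ] * 255, base[proj < 0, ] * 255)
  w_orig <- model$weights / model$feature_scales
  expect_lt(angle_between(w_orig, normal), 5)
})

test_that("mean-shift segmentation produces exact partitions", {
  # uniform image: a single segment
  uni <- array(120L, c(40, 60, 3))
  expect_length(segment_frame(uni), 1L)
  # strong two-mode image: exactly two segments
  hb <- array(0L, c(40, 60, 3))
  hb[, 31:60, ] <- 255L
  segs2 <- segment_frame(hb)
  expect_length(segs2, 2L)
  expect_setequal(vapply(segs2, `[[`, numeric(1), "area"), c(1200, 1200))
  # partition property on textured scenes
  for (seed in c(2, 7)) {
    scene <- fixture_scene(n_frames = 1, seed = seed)
    segs <- segment_frame(scene$frames[[1]])
    all_px <- sort(unlist(lapply(segs, `[[`, "pixels")))
    expect_identical(all_px, seq_len(160L * 120L))
    expect_true(all(vapply(segs, `[[`, numeric(1), "area") >=
                      visual_config()$min_region))
    # bboxes tightly bound their pixel sets
    for (s in segs[1:min(5, length(segs))]) {
      r <- (s$pixels - 1L) %% 120L + 1L
      c0 <- (s$pixels - 1L) %/% 120L + 1L
      expect_equal(unname(s$bbox),
                   c(min(c0), min(r), diff(range(c0)) + 1, diff(range(r)) + 1))
    }
  }
})

test_that("mean-shift iterates converge below tolerance on a smooth image", {
  withr::with_seed(20, {
    img <- array(0, c(30, 30, 3))
    for (ch in 1:3) img[, , ch] <- 100 + 20 * elewatch:::smooth_noise2(30, 30)
  })
  lab <- elewatch:::frame_to_lab(array(as.integer(round(img)), c(30, 30, 3)))
  m1 <- elewatch:::.meanshift_filter(lab, 30, 30, 8, 8, 50, 0.1)
  m2 <- elewatch:::.meanshift_filter(lab, 30, 30, 8, 8, 200, 0.1)
  # quadrupling the iteration cap moves no mode by more than half the
  # grouping distance, and almost all pixels are already fixed
  expect_lt(max(abs(m1[, 3:5] - m2[, 3:5])), 4)
  expect_lt(mean(abs(m1[, 3:5] - m2[, 3:5])), 0.05)
})

test_that("segment scoring averages per-pixel decisions exactly", {
  scene <- fixture_scene(n_frames = 1, seed = 4)
  px <- sample_pixels(fixture_scene(n_frames = 2, seed = 3), 800, seed = 2)
  model <- train_skin_model(px$foreground, px$background)
  segs <- segment_frame(scene$frames[[1]])
  cands <- score_segments(segs, model, scene$frames[[1]])
  expect_true(all(vapply(cands, `[[`, numeric(1), "skin_score") > 0))
  # brute-force per-pixel average oracle
  pxs <- skin_scores(model, scene$frames[[1]])
  seg1 <- segs[[1]]
  brute <- mean(pxs[seg1$pixels])
  rescored <- score_segments(segs[1], model, scene$frames[[1]])
  if (brute > 0) {
    expect_equal(rescored[[1]]$skin_score, brute, tolerance = 1e-6)
  } else {
    expect_length(rescored, 0L)
  }
})

test_that("temporal linking keeps identities and repairs over-segmentation", {
  mk_cand <- function(x, y, w = 10, h = 10, px_offset = 0) {
    list(pixels = seq_len(w * h) + px_offset, area = w * h,
         bbox = c(x = x, y = y, w = w, h = h),
         mean_color = c(50, 0, 0), skin_score = 1)
  }
  dims <- c(120, 160)
  # one static candidate over 6 frames: one track of length 6
  frames <- replicate(6, {
    out <- list(mk_cand(50, 50))
    attr(out, "frame_dim") <- dims
    out
  }, simplify = FALSE)
  tracks <- link_and_merge(frames, dims)
  expect_length(tracks, 1L)
  expect_equal(tracks[[1]]$frames, 1:6)
  # two candidates far apart: two tracks
  frames2 <- replicate(4, {
    out <- list(mk_cand(10, 10), mk_cand(120, 100))
    attr(out, "frame_dim") <- dims
    out
  }, simplify = FALSE)
  expect_length(link_and_merge(frames2, dims), 2L)
  # two half-blobs both overlapping the previous frame's bbox merge into
  # one member set (they also abut, so the in-frame repair unifies them)
  f1 <- list(mk_cand(50, 50, w = 20, h = 20))
  attr(f1, "frame_dim") <- dims
  f2 <- list(mk_cand(50, 50, w = 10, h = 20),
             mk_cand(60, 50, w = 10, h = 20, px_offset = 400))
  attr(f2, "frame_dim") <- dims
  tracks3 <- link_and_merge(list(f1, f2), dims)
  expect_length(tracks3, 1L)
  expect_length(tracks3[[1]]$members, 2L)
  expect_length(tracks3[[1]]$members[[2]], 400L)
})

test_that("refinement drops short and jumpy tracks, monotonically in min_length", {
  dims <- c(240, 320)
  mk_track <- function(frames, xs) {
    list(id = 1L, frames = frames,
         members = lapply(seq_along(frames), function(i) 1:50),
         centroids = cbind(x = xs, y = rep(50, length(frames))),
         bboxes = lapply(xs, function(x) c(x = x, y = 45, w = 10, h = 10)))
  }
  short <- mk_track(1:4, rep(100, 4))
  steady <- mk_track(1:8, 100 + (0:7))
  jumpy <- mk_track(1:8, c(100, 101, 260, 261, 262, 263, 264, 265))
  kept <- refine_tracks(list(short, steady, jumpy), dims)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$frames, 1:8)
  expect_length(refine_tracks(list(), dims), 0L)
  # increasing min_length never increases the number of final tracks
  counts <- vapply(c(2, 5, 9), function(ml) {
    length(refine_tracks(list(short, steady, jumpy), dims,
                         visual_config(min_length = ml)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("visual evaluation counts object-frames and false track-frames", {
  # two objects, three frames; masks are 20 x 20
  mk_mask <- function(obj1, obj2) {
    m <- matrix(0L, 20, 20)
    m[obj1] <- 1L
    m[obj2] <- 2L
    m
  }
  masks <- replicate(3, mk_mask(1:40, 201:240), simplify = FALSE)
  # a track covering object 1 fully in all frames, plus one spurious
  # track-frame off the masks
  good <- list(id = 1L, frames = 1:3, members = list(1:40, 1:40, 1:40),
               centroids = cbind(x = 1:3, y = 1:3),
               bboxes = replicate(3, c(x = 1, y = 1, w = 2, h = 20),
                                  simplify = FALSE))
  bad <- list(id = 2L, frames = 2L, members = list(300:320),
              centroids = cbind(x = 2, y = 2),
              bboxes = list(c(x = 15, y = 1, w = 2, h = 20)))
  r <- evaluate_visual(list(good, bad), masks)
  # 6 object-frames, 3 covered; 4 track-frames, 1 false
  expect_equal(r$n_truth, 6L)
  expect_equal(r$detection_rate, 0.5)
  expect_equal(r$n_detections, 4L)
  expect_equal(r$false_positive_rate, 0.25)
  # degenerate: no tracks
  r0 <- evaluate_visual(list(), masks)
  expect_equal(r0$detection_rate, 0)
  expect_equal(r0$false_positive_rate, 0)
})

test_that("the visual pipeline finds a rendered elephant end to end", {
  # skin model learned from annotated frames of the same footage
  scene <- fixture_scene(n_frames = 6, n_elephants = 1, seed = 31)
  px <- sample_pixels(scene, 2500, seed = 2)
  model <- train_skin_model(px$foreground, px$background)
  tracks <- detect_visual(scene$frames, model)
  r <- evaluate_visual(tracks, scene$masks)
  expect_gte(r$detection_rate, 0.8)
  expect_lte(r$false_positive_rate, 0.2)
})
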