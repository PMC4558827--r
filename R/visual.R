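# Visual elephant detection: linear skin-color model, mean-shift
# over-segmentation, segment scoring, temporal linking/merging, track
# refinement and mask-based evaluation.

#' Visual pipeline configuration
#'
#' @param hs Spatial mean-shift bandwidth (px).
#' @param hr Range (color) bandwidth in CIELAB units.
#' @param min_region Minimum segment area (px); smaller regions merge
#'   into their most similar neighbor.
#' @param max_iter,tol Mean-shift iteration cap and convergence
#'   tolerance (joint-domain shift magnitude).
#' @param min_bbox_iou Minimum bounding-box IoU for track association.
#' @param max_centroid_dist_frac Centroid-distance fallback for
#'   association, as a fraction of the frame diagonal.
#' @param max_frame_gap Maximum frame gap a track survives.
#' @param min_length Minimum track length (frames) kept by refinement.
#' @param max_step_frac Maximum per-frame centroid step kept by
#'   refinement, as a fraction of the frame diagonal.
#' @param cover_thresh Fraction of an object's visible mask a track must
#'   cover to count as a detection.
#' @param fp_thresh A track-frame is false when less than this fraction
#'   of its pixels lies on any mask.
#' @param C Soft-margin penalty for skin-model training.
#' @return A `visual_config` list.
#' @export
visual_config <- function(hs = 8, hr = 8, min_region = 20, max_iter = 50,
                          tol = 0.1, min_bbox_iou = 0.2,
                          max_centroid_dist_frac = 0.1, max_frame_gap = 2,
                          min_length = 5, max_step_frac = 0.05,
                          cover_thresh = 0.5, fp_thresh = 0.1, C = 1) {
  structure(list(hs = hs, hr = hr, min_region = min_region,
                 max_iter = max_iter, tol = tol,
                 min_bbox_iou = min_bbox_iou,
                 max_centroid_dist_frac = max_centroid_dist_frac,
                 max_frame_gap = max_frame_gap, min_length = min_length,
                 max_step_frac = max_step_frac,
                 cover_thresh = cover_thresh, fp_thresh = fp_thresh,
                 C = C),
            class = "visual_config")
}

# 8-bit sRGB (n x 3, 0-255) to CIELAB (D65).
srgb_to_lab <- function(rgb255) {
  if (is.null(dim(rgb255))) rgb255 <- matrix(rgb255, ncol = 3)
  grDevices::convertColor(rgb255 / 255, from = "sRGB", to = "Lab")
}

frame_to_lab <- function(frame) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  srgb_to_lab(cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
                    as.vector(frame[, , 3])))
}

#' Train the linear skin-color model
#'
#' Colors are converted to CIELAB (D65), standardized, and separated by
#' a linear soft-margin SVM; decision values above zero mean skin.
#'
#' @param fg,bg Matrices of sRGB colors (rows, 0-255) for elephant skin
#'   and background.
#' @param C Soft-margin penalty.
#' @return A `color_model` with `weights`, `bias`, `feature_means`,
#'   `feature_scales`, `space`.
#' @export
train_skin_model <- function(fg, bg, C = 1) {
  fit <- fit_linear_classifier(srgb_to_lab(fg), srgb_to_lab(bg), C)
  fit$space <- "Lab"
  class(fit) <- "color_model"
  fit
}

#' Per-pixel skin decision values
#' @param model A `color_model`.
#' @param frame An 8-bit sRGB frame array (h x w x 3).
#' @return Numeric vector of decision values in pixel (column-major)
#'   order.
#' @export
skin_scores <- function(model, frame) {
  decision_values(model, frame_to_lab(frame))
}

#' Mean-shift over-segmentation of a frame
#'
#' Mean-shift filtering in the joint spatial-range domain (flat kernel,
#' CIELAB range) followed by grouping of converged modes into connected
#' regions; regions below `min_region` pixels are merged into their most
#' similar neighbor. The result is a partition: every pixel belongs to
#' exactly one segment.
#'
#' @param frame An 8-bit sRGB frame array (h x w x 3).
#' @param cfg A [visual_config()].
#' @return A list of segments, each with `pixels` (linear indices),
#'   `area`, `bbox` (`x`, `y`, `w`, `h`), `mean_color` (CIELAB), and the
#'   frame dimensions in attribute `"frame_dim"`.
#' @export
segment_frame <- function(frame, cfg = visual_config()) {
  check_positive(cfg$hs, "hs"); check_positive(cfg$hr, "hr")
  h <- dim(frame)[1]; w <- dim(frame)[2]
  lab <- frame_to_lab(frame)
  modes <- .meanshift_filter(lab, h, w, cfg$hs, cfg$hr, cfg$max_iter,
                             cfg$tol)
  labels <- .group_modes(modes, h, w, cfg$hr / 2)
  labels <- .merge_small_regions_cpp(labels, modes[, 3:5, drop = FALSE],
                                     cfg$min_region)
  build_segments(labels, lab, h, w)
}

build_segments <- function(labels, lab, h, w) {
  px_by_id <- split(seq_len(h * w), as.vector(labels))
  segs <- lapply(px_by_id, function(px) {
    r <- (px - 1L) %% h + 1L
    c0 <- (px - 1L) %/% h + 1L
    list(pixels = px, area = length(px),
         bbox = c(x = min(c0), y = min(r),
                  w = max(c0) - min(c0) + 1L, h = max(r) - min(r) + 1L),
         mean_color = colMeans(lab[px, , drop = FALSE]))
  })
  names(segs) <- NULL
  attr(segs, "frame_dim") <- c(h, w)
  segs
}

#' Score segments with the skin model and keep candidates
#'
#' Each segment's `skin_score` is the mean per-pixel decision value over
#' the segment; segments with positive score are candidate detections.
#'
#' @param segments Output of [segment_frame()].
#' @param model A `color_model`.
#' @param frame The frame the segments partition.
#' @return The candidate segments (positive `skin_score`), with the
#'   frame dimensions in attribute `"frame_dim"`.
#' @export
score_segments <- function(segments, model, frame) {
  px_scores <- skin_scores(model, frame)
  out <- list()
  for (s in segments) {
    s$skin_score <- mean(px_scores[s$pixels])
    if (s$skin_score > 0) out[[length(out) + 1L]] <- s
  }
  attr(out, "frame_dim") <- attr(segments, "frame_dim")
  out
}

bbox_iou <- function(a, b) {
  ix <- max(0, min(a["x"] + a["w"], b["x"] + b["w"]) - max(a["x"], b["x"]))
  iy <- max(0, min(a["y"] + a["h"], b["y"] + b["h"]) - max(a["y"], b["y"]))
  inter <- ix * iy
  un <- a["w"] * a["h"] + b["w"] * b["h"] - inter
  unname(inter / un)
}

union_bbox <- function(boxes) {
  x0 <- min(vapply(boxes, function(b) b["x"], numeric(1)))
  y0 <- min(vapply(boxes, function(b) b["y"], numeric(1)))
  x1 <- max(vapply(boxes, function(b) b["x"] + b["w"], numeric(1)))
  y1 <- max(vapply(boxes, function(b) b["y"] + b["h"], numeric(1)))
  c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

centroid_of <- function(pixels, h) {
  r <- (pixels - 1L) %% h + 1L
  c0 <- (pixels - 1L) %/% h + 1L
  c(x = mean(c0), y = mean(r))
}

# Merge spatially abutting candidates of one frame into single
# candidate detections: over-segmentation splits one animal into many
# touching skin segments, which are one detection for tracking purposes.
merge_adjacent_candidates <- function(cands) {
  n <- length(cands)
  if (n <= 1L) return(cands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # 3 px growth bridges thin occluders that slice one animal into
  # disconnected skin stripes
  grown <- lapply(cands, function(s) {
    b <- s$bbox
    c(x = b[["x"]] - 3, y = b[["y"]] - 3, w = b[["w"]] + 6, h = b[["h"]] + 6)
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bbox_iou(grown[[i]], grown[[j]]) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    members <- cands[roots == r]
    px <- sort(unique(unlist(lapply(members, `[[`, "pixels"))))
    areas <- vapply(members, `[[`, numeric(1), "area")
    list(pixels = px, area = length(px),
         bbox = union_bbox(lapply(members, `[[`, "bbox")),
         mean_color = colSums(t(vapply(members, `[[`, numeric(3),
                                       "mean_color")) * areas) / sum(areas),
         skin_score = sum(vapply(members, `[[`, numeric(1),
                                 "skin_score") * areas) / sum(areas))
  })
  attr(out, "frame_dim") <- attr(cands, "frame_dim")
  out
}

#' Link candidate segments over time and merge over-segmented parts
#'
#' Spatially abutting candidates within a frame are first merged into
#' single candidate detections (over-segmentation repair). Tracking then
#' associates candidates greedily frame-to-frame by highest bounding-box
#' IoU, with a centroid-distance fallback. Several candidates in the
#' same frame may still associate to one track: they become joint
#' members of that frame. Unassociated candidates open new tracks;
#' tracks survive gaps up to `max_frame_gap` frames.
#'
#' @param candidates_by_frame List (one element per frame, in order) of
#'   candidate segment lists from [score_segments()].
#' @param frame_dim `c(height, width)` of the frames.
#' @param cfg A [visual_config()].
#' @return A list of tracks, each with `id`, `frames`, `members` (list
#'   of per-frame pixel index vectors), `centroids` (matrix), `bboxes`.
#' @export
link_and_merge <- function(candidates_by_frame, frame_dim,
                           cfg = visual_config()) {
  h <- frame_dim[1]; w <- frame_dim[2]
  diag_len <- sqrt(h^2 + w^2)
  max_dist <- cfg$max_centroid_dist_frac * diag_len
  tracks <- list()
  active <- integer(0)
  next_id <- 1L
  for (f in seq_along(candidates_by_frame)) {
    cands <- merge_adjacent_candidates(candidates_by_frame[[f]])
    # drop expired tracks
    if (length(active)) {
      last <- vapply(tracks[active], function(t) max(t$frames), numeric(1))
      active <- active[f - last <= cfg$max_frame_gap + 1L]
    }
    assigned <- rep(NA_integer_, length(cands))
    if (length(active) && length(cands)) {
      for (ci in seq_along(cands)) {
        cb <- cands[[ci]]$bbox
        cc <- centroid_of(cands[[ci]]$pixels, h)
        best <- NA_integer_; best_iou <- cfg$min_bbox_iou
        for (ti in active) {
          iou <- bbox_iou(cb, tracks[[ti]]$last_bbox)
          if (iou >= best_iou) { best <- ti; best_iou <- iou }
        }
        if (is.na(best)) {
          best_d <- max_dist
          for (ti in active) {
            d <- sqrt(sum((cc - tracks[[ti]]$last_centroid)^2))
            if (d <= best_d) { best <- ti; best_d <- d }
          }
        }
        assigned[ci] <- best
      }
    }
    # merge all candidates assigned to the same track into one member set
    for (ti in unique(assigned[!is.na(assigned)])) {
      ci <- which(!is.na(assigned) & assigned == ti)
      px <- sort(unique(unlist(lapply(cands[ci], `[[`, "pixels"))))
      bb <- union_bbox(lapply(cands[ci], `[[`, "bbox"))
      tr <- tracks[[ti]]
      tr$frames <- c(tr$frames, f)
      tr$members[[length(tr$members) + 1L]] <- px
      tr$centroids <- rbind(tr$centroids, centroid_of(px, h))
      tr$bboxes[[length(tr$bboxes) + 1L]] <- bb
      tr$last_bbox <- bb
      tr$last_centroid <- centroid_of(px, h)
      tracks[[ti]] <- tr
    }
    for (ci in which(is.na(assigned))) {
      px <- cands[[ci]]$pixels
      cc <- centroid_of(px, h)
      tracks[[next_id]] <- list(id = next_id, frames = f,
                                members = list(px),
                                centroids = matrix(cc, nrow = 1,
                                                   dimnames = list(NULL, c("x", "y"))),
                                bboxes = list(cands[[ci]]$bbox),
                                last_bbox = cands[[ci]]$bbox,
                                last_centroid = cc)
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }
  lapply(tracks, function(t) {
    t$last_bbox <- NULL; t$last_centroid <- NULL
    t$displacement <- if (nrow(t$centroids) > 1)
      sqrt(sum((t$centroids[nrow(t$centroids), ] - t$centroids[1, ])^2))
    else 0
    t
  })
}

#' Refine tracks into final detections
#'
#' Keeps tracks that persist at least `min_length` frames and stay at a
#' similar location throughout: consecutive member bounding boxes may
#' not be separated by a gap larger than `max_step_frac` of the frame
#' diagonal. Segments trackable consistently at a similar location are
#' likely elephants, while tracks that vanish quickly or move abruptly
#' are likely false detections. (The box-gap criterion, rather than a
#' centroid step, keeps a track alive when over-segmented parts of a
#' group merge and split between frames, which moves the joint centroid
#' without any real displacement.)
#'
#' @param tracks Output of [link_and_merge()].
#' @param frame_dim `c(height, width)`.
#' @param cfg A [visual_config()].
#' @return The retained tracks.
#' @export
refine_tracks <- function(tracks, frame_dim, cfg = visual_config()) {
  diag_len <- sqrt(sum(frame_dim^2))
  max_step <- cfg$max_step_frac * diag_len
  keep <- vapply(tracks, function(t) {
    if (length(t$frames) < cfg$min_length) return(FALSE)
    if (length(t$bboxes) > 1) {
      for (i in seq_len(length(t$bboxes) - 1L)) {
        a <- t$bboxes[[i]]; b <- t$bboxes[[i + 1L]]
        gx <- max(0, max(a[["x"]], b[["x"]]) -
                    min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]))
        gy <- max(0, max(a[["y"]], b[["y"]]) -
                    min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]))
        gap <- sqrt(gx^2 + gy^2) / max(1, t$frames[i + 1L] - t$frames[i])
        if (gap > max_step) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  tracks[keep]
}

#' Evaluate tracks against ground-truth masks
#'
#' Object-frame convention: an (object, frame) pair counts as detected
#' when some single track's member pixels cover at least `cover_thresh`
#' of the object's visible mask in that frame. A track-frame is false
#' when less than `fp_thresh` of its member pixels lie on any object
#' mask. The detection rate is detected object-frames over all
#' object-frames; the false-positive rate is false track-frames over
#' all track-frames.
#'
#' @param tracks Final tracks from [refine_tracks()].
#' @param masks List of integer mask matrices (0 = background).
#' @param cfg A [visual_config()].
#' @return An `eval_report`.
#' @export
evaluate_visual <- function(tracks, masks, cfg = visual_config()) {
  n_obj_frames <- 0L
  n_detected <- 0L
  for (f in seq_along(masks)) {
    mask <- masks[[f]]
    for (obj in setdiff(unique(as.vector(mask)), 0L)) {
      obj_px <- which(as.vector(mask) == obj)
      n_obj_frames <- n_obj_frames + 1L
      covered <- FALSE
      for (t in tracks) {
        fi <- match(f, t$frames)
        if (is.na(fi)) next
        cover <- length(intersect(t$members[[fi]], obj_px)) /
          length(obj_px)
        if (cover >= cfg$cover_thresh) { covered <- TRUE; break }
      }
      if (covered) n_detected <- n_detected + 1L
    }
  }
  n_track_frames <- 0L
  n_false <- 0L
  for (t in tracks) {
    for (fi in seq_along(t$frames)) {
      f <- t$frames[fi]
      if (f > length(masks)) next
      n_track_frames <- n_track_frames + 1L
      on_mask <- mean(as.vector(masks[[f]])[t$members[[fi]]] > 0L)
      if (on_mask < cfg$fp_thresh) n_false <- n_false + 1L
    }
  }
  eval_report(n_obj_frames, n_track_frames, n_detected,
              n_matched_det = n_track_frames - n_false)
}

#' Detect elephants in a frame sequence
#'
#' Convenience wrapper: segment each frame, score segments with the
#' skin model, link candidates over time and refine the tracks.
#'
#' @param frames List of 8-bit sRGB frame arrays.
#' @param model A `color_model`.
#' @param cfg A [visual_config()].
#' @return A list of final tracks.
#' @export
detect_visual <- function(frames, model, cfg = visual_config()) {
  cands <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    frame <- frames[[f]]
    h <- dim(frame)[1]; w <- dim(frame)[2]
    lab <- frame_to_lab(frame)          # converted once per frame
    modes <- .meanshift_filter(lab, h, w, cfg$hs, cfg$hr, cfg$max_iter,
                               cfg$tol)
    labels <- .group_modes(modes, h, w, cfg$hr / 2)
    labels <- .merge_small_regions_cpp(labels, modes[, 3:5, drop = FALSE],
                                       cfg$min_region)
    segs <- build_segments(labels, lab, h, w)
    px_scores <- decision_values(model, lab)
    keep <- list()
    for (s in segs) {
      s$skin_score <- mean(px_scores[s$pixels])
      if (s$skin_score > 0) keep[[length(keep) + 1L]] <- s
    }
    attr(keep, "frame_dim") <- c(h, w)
    cands[[f]] <- keep
  }
  dims <- dim(frames[[1]])[1:2]
  tracks <- link_and_merge(cands, dims, cfg)
  refine_tracks(tracks, dims, cfg)
}
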