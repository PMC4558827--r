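# Seeded synthetic wildlife scenes: gray-brown elephant blobs over
# green/brown textured backgrounds with vegetation occlusion, shadow
# patches, camera jitter, illumination drift and slow motion, plus
# per-pixel visibility masks.

#' Scene rendering parameters
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames.
#' @param fps Frame rate (1/s).
#' @param distance_class `"near"` (blob areas 5-25\% of the frame,
#'   emulating elephants up to ~50 m) or `"far"` (0.1-1\%, beyond 50 m).
#' @param n_elephants Number of elephant blobs.
#' @param occlusion_fraction Fraction of each blob hidden behind
#'   vegetation strips, in \[0, 1).
#' @param illumination_drift Maximum per-frame relative change of the
#'   global gain.
#' @param camera_jitter Maximum per-frame global shift (px).
#' @param haze Aerial-perspective strength in \[0, 1): the rendered
#'   frame is mixed toward a light haze tone by this fraction,
#'   compressing color contrast the way distance does. `NULL` (the
#'   default) resolves to 0 for near scenes and 0.2 for far scenes.
#' @param seed Integer seed; fixed seed implies byte-identical frames
#'   and masks.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 320, height = 240, n_frames = 10, fps = 10,
                       distance_class = c("near", "far"), n_elephants = 1,
                       occlusion_fraction = 0.2, illumination_drift = 0.02,
                       camera_jitter = 1, haze = NULL, seed = 1) {
  distance_class <- match.arg(distance_class)
  if (is.null(haze)) haze <- if (distance_class == "far") 0.2 else 0
  check_fraction(haze, "haze", open = FALSE)
  check_positive(width, "width"); check_positive(height, "height")
  check_positive(n_frames, "n_frames"); check_positive(fps, "fps")
  if (n_elephants < 0) stop("'n_elephants' must be >= 0", call. = FALSE)
  if (occlusion_fraction < 0 || occlusion_fraction >= 1) {
    stop("'occlusion_fraction' must lie in [0, 1)", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), fps = fps,
                 distance_class = distance_class,
                 n_elephants = as.integer(n_elephants),
                 occlusion_fraction = occlusion_fraction,
                 illumination_drift = illumination_drift,
                 camera_jitter = camera_jitter, haze = haze,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Smooth 2-D value noise: coarse Gaussian knot grid, bilinearly upsampled.
smooth_noise2 <- function(height, width, knots_x = 9, knots_y = 7, sd = 1) {
  g <- matrix(rnorm(knots_y * knots_x, 0, sd), knots_y, knots_x)
  xi <- seq(1, knots_x, length.out = width)
  yi <- seq(1, knots_y, length.out = height)
  x0 <- pmin(floor(xi), knots_x - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), knots_y - 1L); fy <- yi - y0
  a <- g[y0, x0] * outer(1 - fy, 1 - fx) + g[y0 + 1, x0] * outer(fy, 1 - fx) +
    g[y0, x0 + 1] * outer(1 - fy, fx) + g[y0 + 1, x0 + 1] * outer(fy, fx)
  a
}

# Irregular superellipse blob mask centred at (cx, cy): radius modulated
# by a low-order Fourier series in polar angle. Returns a logical matrix.
blob_mask <- function(height, width, cx, cy, rx, ry, shape) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  dx <- (xs - cx) / rx
  dy <- (ys - cy) / ry
  theta <- atan2(dy, dx)
  mod <- rep(1, length(theta))
  for (k in seq_along(shape$amp)) {
    mod <- mod + shape$amp[k] * cos((k + 1) * theta + shape$phase[k])
  }
  r <- (abs(dx)^shape$p + abs(dy)^shape$p)^(1 / shape$p)
  matrix(r <= mod, height, width)
}

target_area_range <- function(distance_class) {
  if (distance_class == "near") c(0.05, 0.25) else c(0.001, 0.01)
}

#' Render a synthetic annotated scene
#'
#' Frames are 8-bit sRGB arrays (height x width x 3, values 0-255);
#' masks are integer matrices with object ids 1..n_elephants for visible
#' elephant pixels and 0 for background. Vegetation occluders cover
#' `occlusion_fraction` of each blob, and only unoccluded pixels are
#' recorded in the mask. Backgrounds contain smooth green/brown shading,
#' fine texture, and dark shadow patches whose colors deliberately
#' approach the elephant skin distribution.
#'
#' @param spec A [scene_spec()].
#' @return A list with `frames` (list of arrays), `masks` (list of
#'   integer matrices), `timestamps`, and `blob_area_frac` (per-elephant
#'   unoccluded area fraction of the first frame).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # --- static scene content -------------------------------------------
    # green-brown ground: brightness varies through a luminance field
    # shared by all channels (hue is preserved in dark and bright
    # regions, as for real vegetation), plus small hue fields; the blue
    # channel stays at least 30 units below the elephant mean
    # (110, 100, 95) so unshadowed background never wanders into the
    # skin distribution
    base <- c(95, 105, 52)
    lum <- pmax(0.5, 1 + 0.22 * smooth_noise2(h, w))
    hue <- list(8 * smooth_noise2(h, w), 8 * smooth_noise2(h, w),
                5 * smooth_noise2(h, w))
    bg <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      bg[, , ch] <- (base[ch] + hue[[ch]]) * lum +
        rnorm(h * w, 0, if (ch == 3) 4 else 6)
    }
    bg[, , 3] <- pmin(bg[, , 3], 65)
    # shadow patches: darkened, desaturated ellipses that drift toward
    # the elephant gray-brown tone
    n_shadow <- rpois(1, 3)
    shadow <- matrix(1, h, w)
    if (n_shadow > 0) {
      for (s in seq_len(n_shadow)) {
        m <- blob_mask(h, w, runif(1, 1, w), runif(1, 1, h),
                       runif(1, 8, 30), runif(1, 6, 20),
                       list(amp = runif(2, 0, 0.2),
                            phase = runif(2, 0, 2 * pi), p = 2))
        shadow[m] <- pmin(shadow[m], runif(1, 0.45, 0.6))
      }
    }
    # shade darkens multiplicatively (hue preserved) with a mild pull
    # toward gray; the darkest, most desaturated corners of the shadow
    # distribution still brush the elephant skin tones
    gray <- (bg[, , 1] + bg[, , 2] + bg[, , 3]) / 3
    in_shadow <- shadow < 1
    for (ch in 1:3) {
      plane <- bg[, , ch]
      plane[in_shadow] <- shadow[in_shadow] *
        (0.8 * plane[in_shadow] + 0.2 * gray[in_shadow])
      bg[, , ch] <- plane
    }

    # --- elephants -------------------------------------------------------
    area_rng <- target_area_range(spec$distance_class)
    blobs <- list()
    if (spec$n_elephants > 0) {
      for (e in seq_len(spec$n_elephants)) {
        target <- runif(1, area_rng[1] + 0.2 * diff(area_rng),
                        area_rng[2] - 0.2 * diff(area_rng))
        aspect <- runif(1, 0.7, 1.4)
        shape <- list(amp = runif(3, 0, 0.12),
                      phase = runif(3, 0, 2 * pi),
                      p = runif(1, 2, 3))
        r0 <- sqrt(target * h * w / (pi * aspect))
        rx <- r0 * aspect; ry <- r0
        cx <- runif(1, rx + 2, w - rx - 2)
        cy <- runif(1, ry + 2, h - ry - 2)
        # one correction pass so the realized pixel count hits the target
        m <- blob_mask(h, w, cx, cy, rx, ry, shape)
        adj <- sqrt(target * h * w / max(1, sum(m)))
        rx <- rx * adj; ry <- ry * adj
        if (2 * rx > w - 4 || 2 * ry > h - 4) {
          stop("blob cannot fit the frame at the requested area",
               call. = FALSE)
        }
        cx <- min(max(cx, rx + 2), w - rx - 2)
        cy <- min(max(cy, ry + 2), h - ry - 2)
        color <- c(110, 100, 95) + runif(3, -15, 15)
        blobs[[e]] <- list(cx = cx, cy = cy, rx = rx, ry = ry,
                           shape = shape, color = color,
                           step_sd = if (spec$distance_class == "near")
                             1.2 else 0.4)
      }
    }

    # occluder strips: periodic vertical bands in blob-local coordinates
    # covering `occlusion_fraction` of the blob's columns (period 10 px)
    occ_period <- 10L
    occ_cols <- round(occ_period * spec$occlusion_fraction)
    veg_color <- c(60, 95, 45)

    # --- per-frame random walks -----------------------------------------
    nf <- spec$n_frames
    gain <- numeric(nf); gain[1] <- 1
    if (nf > 1) {
      for (f in 2:nf) {
        gain[f] <- min(1.2, max(0.8, gain[f - 1] +
          runif(1, -spec$illumination_drift, spec$illumination_drift)))
      }
    }
    jx <- cumsum(c(0, round(runif(max(0, nf - 1), -spec$camera_jitter,
                                  spec$camera_jitter))))
    jy <- cumsum(c(0, round(runif(max(0, nf - 1), -spec$camera_jitter,
                                  spec$camera_jitter))))
    steps <- lapply(blobs, function(b) {
      cbind(cumsum(c(0, rnorm(max(0, nf - 1), 0, b$step_sd))),
            cumsum(c(0, rnorm(max(0, nf - 1), 0, b$step_sd))))
    })
    # per-blob static texture in image coordinates
    textures <- lapply(blobs, function(b) matrix(rnorm(h * w, 0, 10), h, w))

    frames <- vector("list", nf)
    masks <- vector("list", nf)
    blob_area_frac <- numeric(length(blobs))
    for (f in seq_len(nf)) {
      img <- bg
      # camera jitter: shift the background by whole pixels with clamping
      if (jx[f] != 0 || jy[f] != 0) {
        sx <- pmin(pmax(seq_len(w) + jx[f], 1), w)
        sy <- pmin(pmax(seq_len(h) + jy[f], 1), h)
        img <- img[sy, sx, , drop = FALSE]
      }
      mask <- matrix(0L, h, w)
      for (e in seq_along(blobs)) {
        b <- blobs[[e]]
        cx <- min(max(b$cx + steps[[e]][f, 1] - jx[f], 2), w - 1)
        cy <- min(max(b$cy + steps[[e]][f, 2] - jy[f], 2), h - 1)
        m <- blob_mask(h, w, cx, cy, b$rx, b$ry, b$shape)
        if (f == 1) blob_area_frac[e] <- sum(m) / (h * w)
        idx <- which(m)
        if (length(idx) == 0) next
        tex <- textures[[e]]
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[idx] <- b$color[ch] + tex[idx]
          img[, , ch] <- plane
        }
        # vegetation strips occlude a fixed fraction of blob columns,
        # anchored to the blob so the visible fraction stays stable
        cols <- ((col(m) - round(cx)) %% occ_period) < occ_cols
        occluded <- m & cols
        visible <- m & !cols
        if (any(occluded)) {
          oidx <- which(occluded)
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[oidx] <- veg_color[ch] + tex[oidx]
            img[, , ch] <- plane
          }
        }
        mask[m] <- 0L              # later blobs occlude earlier ones
        mask[visible] <- as.integer(e)
      }
      img <- img * gain[f]
      if (spec$haze > 0) {
        # aerial perspective: distant scenes lose contrast toward a
        # light haze tone
        haze_tone <- c(150, 150, 140)
        for (ch in 1:3) {
          img[, , ch] <- (1 - spec$haze) * img[, , ch] +
            spec$haze * haze_tone[ch]
        }
      }
      frames[[f]] <- array(as.integer(pmin(255, pmax(0, round(img)))),
                           c(h, w, 3))
      masks[[f]] <- mask
    }
    list(frames = frames, masks = masks,
         timestamps = (seq_len(nf) - 1) / spec$fps,
         blob_area_frac = blob_area_frac)
  })
}

#' Sample labeled pixel colors from a rendered scene
#'
#' Uniform without-replacement samples of visible-elephant and
#' background pixel colors, pooled over all frames.
#'
#' @param scene A [render_scene()] result (fields `frames`, `masks`).
#' @param n_per_class Number of pixels per class.
#' @param seed Integer seed.
#' @return A list with `foreground` and `background`, each an
#'   `n_per_class` x 3 matrix of sRGB values (0-255).
#' @export
sample_pixels <- function(scene, n_per_class, seed = 1) {
  nf <- length(scene$frames)
  fg_pool <- list(); bg_pool <- list()
  for (f in seq_len(nf)) {
    mask <- scene$masks[[f]]
    img <- scene$frames[[f]]
    npx <- length(mask)
    cols <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                  as.vector(img[, , 3]))
    fg_pool[[f]] <- cols[as.vector(mask) > 0L, , drop = FALSE]
    bg_pool[[f]] <- cols[as.vector(mask) == 0L, , drop = FALSE]
  }
  fg <- do.call(rbind, fg_pool)
  bg <- do.call(rbind, bg_pool)
  if (nrow(fg) == 0L || nrow(bg) == 0L) {
    stop("both pixel classes must be present in the sequence",
         call. = FALSE)
  }
  with_seed(seed, {
    list(foreground = fg[sample(nrow(fg), min(n_per_class, nrow(fg))), ,
                         drop = FALSE],
         background = bg[sample(nrow(bg), min(n_per_class, nrow(bg))), ,
                         drop = FALSE])
  })
}

#' Write a rendered scene as numbered PNG files
#'
#' Frames go to `frame_%06d.png` (sRGB) and masks to `mask_%06d.png`
#' (single-channel, object id as pixel value), plus a JSON manifest
#' echoing the spec.
#'
#' @param scene A [render_scene()] result.
#' @param spec The [scene_spec()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(scene$frames)) {
    png::writePNG(scene$frames[[f]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", f)))
    png::writePNG(scene$masks[[f]] / 255,
                  file.path(dir, sprintf("mask_%06d.png", f)))
  }
  jsonlite::write_json(c(unclass(spec), list(n_written = length(scene$frames))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#' @param dir Directory containing `frame_*.png` and `mask_*.png`.
#' @return A list with `frames` and `masks`.
#' @export
read_scene <- function(dir) {
  ff <- sort(list.files(dir, "^frame_\\d+\\.png$", full.names = TRUE))
  mf <- sort(list.files(dir, "^mask_\\d+\\.png$", full.names = TRUE))
  frames <- lapply(ff, function(p) {
    a <- png::readPNG(p)
    array(as.integer(round(a * 255)), dim(a))
  })
  masks <- lapply(mf, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  list(frames = frames, masks = masks)
}
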