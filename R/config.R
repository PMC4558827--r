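# Run configuration: one nested list of every tunable, read from YAML,
# validated against the defaults, echoed beside outputs.

#' Default run configuration
#'
#' Nested named list grouping every tunable by namespace: `audio`
#' (synthesis), `enhance`, `gfcc`, `detect`, `scene`, `visual`, plus the
#' master `seed`.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    audio = list(rate = 4000, snr_band = c(5, 150), total_duration = 30,
                 in_band_snr = 0),
    enhance = list(frame_len = 0.3, hop = 0.1, bg_window_t = 1.5,
                   bg_window_f = 20, bg_quantile = 0.5, beta = 2, tau = 3,
                   coherence_t = 0.7,
                   mask_floor = 0.05, floor_db = -80),
    gfcc = list(fmin = 8, fmax = 2000, k = 0.88, n_filters = 26,
                n_ceps = 12, drop_c0 = TRUE, context_window = 20,
                context_hop = 5),
    detect = list(C = 1, threshold = 0, max_gap = 0.6, min_duration = 1.2,
                  score_smooth = 1, enhance = TRUE),
    scene = list(width = 320, height = 240, n_frames = 10, fps = 10,
                 distance_class = "near", n_elephants = 1,
                 occlusion_fraction = 0.2, illumination_drift = 0.02,
                 camera_jitter = 1),
    visual = list(hs = 8, hr = 8, min_region = 20, max_iter = 50,
                  tol = 0.1, min_bbox_iou = 0.2,
                  max_centroid_dist_frac = 0.1, max_frame_gap = 2,
                  min_length = 5, max_step_frac = 0.05,
                  cover_thresh = 0.5, fp_thresh = 0.1, C = 1)),
    class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Values in the file override the defaults; unknown keys are rejected.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  out <- merge_config(unclass(cfg), user)
  structure(out, class = "run_config")
}

#' Write a configuration echo beside an output
#' @param cfg A `run_config`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build an [acoustic_config()] from a run configuration
#' @param cfg A `run_config`.
#' @return An `acoustic_config`.
#' @export
as_acoustic_config <- function(cfg) {
  acoustic_config(
    frame_len = cfg$enhance$frame_len, hop = cfg$enhance$hop,
    enhance = cfg$detect$enhance,
    enhance_params = enhance_params(cfg$enhance$bg_window_t,
                                    cfg$enhance$bg_window_f,
                                    cfg$enhance$bg_quantile,
                                    cfg$enhance$beta, cfg$enhance$tau,
                                    cfg$enhance$coherence_t,
                                    cfg$enhance$mask_floor,
                                    cfg$enhance$floor_db),
    fmin = cfg$gfcc$fmin, fmax = cfg$gfcc$fmax, k = cfg$gfcc$k,
    n_filters = cfg$gfcc$n_filters, n_ceps = cfg$gfcc$n_ceps,
    drop_c0 = cfg$gfcc$drop_c0,
    context_window = cfg$gfcc$context_window,
    context_hop = cfg$gfcc$context_hop,
    C = cfg$detect$C, threshold = cfg$detect$threshold,
    max_gap = cfg$detect$max_gap, min_duration = cfg$detect$min_duration,
    score_smooth = cfg$detect$score_smooth)
}

#' Build a [visual_config()] from a run configuration
#' @param cfg A `run_config`.
#' @return A `visual_config`.
#' @export
as_visual_config <- function(cfg) {
  do.call(visual_config, cfg$visual)
}
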