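#' Event annotations
#'
#' Interval annotations are plain data frames with columns `start`, `end`
#' (seconds from recording start) and `label` (call-type string), the
#' in-memory form of a label-track file.
#'
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @param label Character vector of call-type labels (recycled).
#' @return A data frame with columns `start`, `end`, `label`.
#' @export
annotations <- function(start = numeric(), end = numeric(),
                        label = character()) {
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have equal length", call. = FALSE)
  }
  label <- rep_len(as.character(label), length(start))
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    label = label, stringsAsFactors = FALSE)
  validate_annotations(out)
  out
}

validate_annotations <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end", "label") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0)) stop("annotation 'start' must be >= 0", call. = FALSE)
  if (any(x$end <= x$start)) {
    stop("annotation 'end' must exceed 'start'", call. = FALSE)
  }
  if (any(!nzchar(x$label))) {
    stop("annotation 'label' must be non-empty", call. = FALSE)
  }
  invisible(x)
}

#' Read a tab-separated label track
#'
#' Parses the Audacity label-track dialect: one row per event,
#' `start<TAB>end<TAB>label`, times in seconds.
#'
#' @param path Path to a label-track file.
#' @return An annotation data frame (see [annotations()]).
#' @export
read_label_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(annotations())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) {
      stop(sprintf("label track %s line %d: expected start<TAB>end<TAB>label",
                   path, i), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(p[1]))
    end <- suppressWarnings(as.numeric(p[2]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("label track %s line %d: non-numeric start or end",
                   path, i), call. = FALSE)
    }
    if (end <= start) {
      stop(sprintf("label track %s line %d: end (%.3f) <= start (%.3f)",
                   path, i, end, start), call. = FALSE)
    }
    out[[i]] <- data.frame(start = start, end = end,
                           label = paste(p[-(1:2)], collapse = "\t"),
                           stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  validate_annotations(ann)
  ann
}

#' Write annotations as a tab-separated label track
#'
#' Times are serialized with three decimal places (millisecond precision).
#'
#' @param events An annotation data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(events, path) {
  validate_annotations(events)
  rows <- sprintf("%.3f\t%.3f\t%s", events$start, events$end, events$label)
  extra <- setdiff(names(events), c("start", "end", "label"))
  if ("score" %in% extra) {
    rows <- sprintf("%s\t%.6f", rows, events$score)
  }
  writeLines(rows, path)
  invisible(path)
}
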