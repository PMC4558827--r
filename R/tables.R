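# Annotation bookkeeping: the published call-type tally and summaries of
# annotation tables.

#' Published tally of annotated elephant vocalizations
#'
#' The per-session, per-call-type counts of the annotated field
#' recordings from Bela Bela (2011) and Addo Elephant National Park
#' (2011 and 2012). These counts are the reference input for annotation
#' summaries and the training-split arithmetic.
#'
#' @return A data frame with columns `call_type`, `session`, `n`.
#' @export
elephant_call_counts <- function() {
  types <- c("rumble", "bark", "noisy roar", "tonal roar", "mixed roar",
             "trumpet", "snort", "grunt", "unknown")
  counts <- rbind(
    `Bela Bela 2011` = c(633, 1, 18, 0, 0, 15, 3, 0, 11),
    `Addo 2011`      = c(925, 15, 41, 34, 56, 166, 103, 8, 22),
    `Addo 2012`      = c(529, 1, 19, 23, 20, 137, 87, 7, 6))
  data.frame(
    call_type = rep(types, times = nrow(counts)),
    session = rep(rownames(counts), each = length(types)),
    n = as.vector(t(counts)),
    stringsAsFactors = FALSE)
}

#' Summarize an annotation table by session and call type
#'
#' @param table A data frame with columns `session` and `label` (one row
#'   per annotated call), or a count table with columns `session`,
#'   `call_type`, `n` (e.g. [elephant_call_counts()]).
#' @param call_type Optional filter: keep only these call types.
#' @return A `call_type_summary`: `counts` (session x call-type matrix),
#'   `session_totals`, `grand_total`.
#' @export
summarize_annotations <- function(table, call_type = NULL) {
  if (all(c("session", "call_type", "n") %in% names(table))) {
    df <- table
  } else if (all(c("session", "label") %in% names(table))) {
    if (nrow(table) == 0L) {
      df <- data.frame(session = character(), call_type = character(),
                       n = integer())
    } else {
      df <- as.data.frame(stats::aggregate(
        list(n = rep(1L, nrow(table))),
        by = list(session = table$session, call_type = table$label),
        FUN = sum))
    }
  } else {
    stop("expected columns session+label or session+call_type+n",
         call. = FALSE)
  }
  if (!is.null(call_type)) df <- df[df$call_type %in% call_type, ,
                                    drop = FALSE]
  if (nrow(df) == 0L) {
    counts <- matrix(0L, 0, 0)
  } else {
    counts <- stats::xtabs(n ~ session + call_type, data = df)
  }
  structure(list(counts = counts,
                 session_totals = if (length(counts)) rowSums(counts)
                                  else integer(0),
                 grand_total = sum(counts)),
            class = "call_type_summary")
}

#' @export
print.call_type_summary <- function(x, ...) {
  cat("Calls per session and call type:\n")
  print(x$counts)
  cat("\nSession totals:\n")
  print(x$session_totals)
  cat(sprintf("\nGrand total: %d\n", x$grand_total))
  invisible(x)
}

#' Expand a count table into one annotation row per call
#'
#' Builds a synthetic annotation table holding one interval per counted
#' call (placeholder times, 2 s calls on a 10 s grid), so that count
#' arithmetic such as training splits can be exercised directly on the
#' published tally.
#'
#' @param counts A count table as from [elephant_call_counts()].
#' @param session Optional session filter.
#' @return A data frame with columns `session`, `start`, `end`, `label`.
#' @export
expand_call_counts <- function(counts, session = NULL) {
  if (!is.null(session)) counts <- counts[counts$session %in% session, ,
                                          drop = FALSE]
  n <- rep(seq_len(nrow(counts)), counts$n)
  starts <- (seq_along(n) - 1) * 10
  data.frame(session = counts$session[n], start = starts,
             end = starts + 2, label = counts$call_type[n],
             stringsAsFactors = FALSE)
}
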