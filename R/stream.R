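# Event streams: time-ordered logs of action fluxes.

#' Build an event stream
#'
#' An action flux is one directed, time-stamped social action from a source
#' agent to a target agent. An event stream is a sequence of fluxes sorted
#' by time (ties keep input order).
#'
#' @param time numeric vector of finite, non-negative times (arbitrary
#'   units, 0-based; no calendar semantics).
#' @param source,target character vectors of agent ids; `source != target`
#'   row-wise.
#' @param action character vector of social action labels (never the null
#'   action: absence of events encodes doing nothing).
#' @param duration optional numeric vector of non-negative durations.
#' @return A data.frame of class `event_stream` with columns `time`,
#'   `source`, `target`, `action` (and `duration` when supplied), sorted
#'   stably by time.
#' @examples
#' event_stream(1:4, c("A", "B", "A", "B"), c("B", "A", "B", "A"), "X")
#' @export
event_stream <- function(time = numeric(), source = character(),
                         target = character(), action = character(),
                         duration = NULL) {
  df <- data.frame(time = as.numeric(time), source = as.character(source),
                   target = as.character(target), action = as.character(action),
                   stringsAsFactors = FALSE)
  if (!is.null(duration)) df$duration <- as.numeric(duration)
  validate_event_stream(df)
}

#' Validate and canonicalize an event-stream data.frame
#'
#' @param df data.frame with at least columns `time`, `source`, `target`,
#'   `action`.
#' @return The validated `event_stream` (rows stably sorted by time).
#' @export
validate_event_stream <- function(df) {
  required <- c("time", "source", "target", "action")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("event stream is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df)) {
    if (anyNA(df$time) || any(!is.finite(df$time))) stop("event times must be finite")
    if (any(df$time < 0)) stop("event times must be non-negative")
    if (any(df$source == df$target)) stop("source and target agents must differ")
    if (any(is_null_action(df$action))) {
      stop("the null action never appears in event logs")
    }
    if (anyNA(df$source) || anyNA(df$target) || anyNA(df$action) ||
        any(!nzchar(df$source)) || any(!nzchar(df$target)) || any(!nzchar(df$action))) {
      stop("agent ids and action labels must be non-missing, non-empty strings")
    }
    df <- df[order(df$time, method = "radix"), , drop = FALSE]  # stable for ties
  }
  rownames(df) <- NULL
  class(df) <- unique(c("event_stream", class(df)))
  df
}

#' Agents appearing in a stream
#'
#' @param stream an [event_stream()].
#' @return Sorted character vector of distinct agent ids.
#' @export
stream_agents <- function(stream) {
  sort(unique(c(stream$source, stream$target)))
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream: %d events, %d agents>\n",
              nrow(x), length(stream_agents(x))))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more events\n", nrow(x) - 10L))
  invisible(x)
}

# subset rows, keeping the class
.stream_rows <- function(stream, idx) {
  out <- stream[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("event_stream", class(out)))
  out
}

#' Split a population stream into per-dyad streams
#'
#' @param stream an [event_stream()] over any number of agents.
#' @return Named list of `event_stream`s, one per unordered agent pair with
#'   at least one event; names are `"a|b"` with the pair sorted.
#' @export
split_dyads <- function(stream) {
  if (!nrow(stream)) return(structure(list(), names = character()))
  lo <- pmin(stream$source, stream$target)
  hi <- pmax(stream$source, stream$target)
  key <- paste(lo, hi, sep = "|")
  lapply(split(seq_len(nrow(stream)), key), function(i) .stream_rows(stream, i))
}
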