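# Event-log readers/writers and flat-file configuration.
#
# CSV dialect: comma-separated, header "time,source,target,action[,duration]",
# UTF-8, "." decimal. JSONL: one record object per line, same keys. Times
# are 0-based reals in arbitrary units; no calendar parsing. The null
# action never appears in logs (absence of events encodes doing nothing).

.log_columns <- c("time", "source", "target", "action")

#' Read an event log
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#' @return An [event_stream()], sorted by time (stable for ties).
#' @export
read_event_log <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("event log not found: %s", path))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    missing <- setdiff(.log_columns, names(df))
    if (length(missing)) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing, collapse = ", ")))
    }
    tm <- suppressWarnings(as.numeric(df$time))
    bad <- which(is.na(tm) & !is.na(df$time))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric time on line %d ('%s')",
                   path, bad[1L] + 1L, df$time[bad[1L]]))  # +1 for the header
    }
    df$time <- tm
    if (!is.null(df$duration)) df$duration <- as.numeric(df$duration)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop(sprintf("%s: invalid JSON on line %d: %s",
                                     path, i, conditionMessage(e)))
                      })
      missing <- setdiff(.log_columns, names(rec))
      if (length(missing)) {
        stop(sprintf("%s: line %d missing field(s): %s", path, i,
                     paste(missing, collapse = ", ")))
      }
      if (!is.numeric(rec$time)) {
        stop(sprintf("%s: non-numeric time on line %d", path, i))
      }
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    df <- if (length(recs)) do.call(rbind, recs) else {
      data.frame(time = numeric(), source = character(), target = character(),
                 action = character(), stringsAsFactors = FALSE)
    }
  }
  validate_event_stream(df)
}

#' Write an event log
#'
#' Output is bit-stable for a fixed stream: rows sorted by time, fixed
#' column order, and `%.17g` float formatting (lossless round trip).
#'
#' @param stream an [event_stream()].
#' @param path destination file path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(stream, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  stream <- validate_event_stream(as.data.frame(stream))
  cols <- c(.log_columns, if ("duration" %in% names(stream)) "duration")
  num <- function(x) sprintf("%.17g", x)
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (format == "csv") {
      writeLines(paste(cols, collapse = ","), con, useBytes = TRUE)
      if (nrow(stream)) {
        fields <- lapply(cols, function(cl) {
          if (is.numeric(stream[[cl]])) num(stream[[cl]]) else stream[[cl]]
        })
        writeLines(do.call(paste, c(fields, sep = ",")), con, useBytes = TRUE)
      }
    } else {
      if (nrow(stream)) {
        # numerics via %.17g: jsonlite may shorten doubles, which breaks
        # the lossless round-trip contract
        esc <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
        lines <- vapply(seq_len(nrow(stream)), function(i) {
          parts <- vapply(cols, function(cl) {
            v <- stream[[cl]][i]
            sprintf("\"%s\":%s", cl, if (is.numeric(v)) num(v) else esc(v))
          }, character(1))
          paste0("{", paste(parts, collapse = ","), "}")
        }, character(1))
        writeLines(lines, con, useBytes = TRUE)
      }
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("failed writing event log to %s: %s", path,
                 conditionMessage(e)))
  })
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (comments start with `#`). Keys mirror
#' the [classifier_config()] and [generator_spec()] field names; unknown
#' keys are errors so typos fail fast.
#'
#' @param path file path.
#' @return Named list of parsed values (numerics where possible; the
#'   `actions` / `agents` / `dyad` keys split on commas).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  known <- c(
    "alternation_tolerance", "alpha", "n_permutations", "min_fluxes",
    "balance_tolerance", "seed",
    "category", "actions", "actor", "agents", "n_rounds", "inter_event_gap",
    "noise_drop", "noise_swap", "noise_extra"
  )
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("config line is not 'key = value': '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% known) {
      stop(sprintf("unknown config key: '%s'", key))
    }
    if (key %in% c("actions", "agents")) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else {
      numval <- suppressWarnings(as.numeric(val))
      if (!is.na(numval)) val <- numval
    }
    out[[key]] <- val
  }
  out
}

#' Build a classifier configuration from parsed config values
#'
#' @param values named list as returned by [read_config()]; non-classifier
#'   keys are ignored.
#' @return A [classifier_config()].
#' @export
config_from_values <- function(values) {
  keys <- intersect(names(values),
                    names(formals(classifier_config)))
  do.call(classifier_config, values[keys])
}

#' Write a unit partition as two-column CSV
#'
#' @param partition a [detect_social_units()] result.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- as.data.frame(partition)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interaction graph as edge-list CSV
#'
#' @param graph an [build_interaction_graph()] result.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
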