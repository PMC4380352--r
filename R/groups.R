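# Social-unit detection from interaction weights.
#
# Agents may belong to larger social units that interact as single
# higher-level agents. Pairwise analysis alone misses these effects (an
# attack answered by a fellow group member looks unilateral twice), so the
# interaction graph is thresholded to isolate units and the stream is
# re-expressed between unit-level agents before classification.

#' Build the weighted interaction graph of a population stream
#'
#' One node per agent, one edge per unordered pair with at least one event;
#' the edge weight is the pair's event count, plus a total duration when
#' events carry one.
#'
#' @param stream an [event_stream()] over any number of agents.
#' @return An object of class `interaction_graph`: list with `nodes`
#'   (character) and `edges` (data.frame `agent_a`, `agent_b`, `weight`
#'   and optionally `duration`, with `agent_a < agent_b`).
#' @export
build_interaction_graph <- function(stream) {
  stream <- validate_event_stream(as.data.frame(stream))
  nodes <- stream_agents(stream)
  if (!nrow(stream)) {
    edges <- data.frame(agent_a = character(), agent_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, edges = edges),
                     class = "interaction_graph"))
  }
  lo <- pmin(stream$source, stream$target)
  hi <- pmax(stream$source, stream$target)
  key <- paste(lo, hi, sep = "\r")
  idx <- split(seq_len(nrow(stream)), key)
  pairs <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  edges <- data.frame(agent_a = pairs[, 1L], agent_b = pairs[, 2L],
                      weight = vapply(idx, length, numeric(1)),
                      stringsAsFactors = FALSE)
  if ("duration" %in% names(stream)) {
    edges$duration <- vapply(idx, function(i) sum(stream$duration[i]), numeric(1))
  }
  edges <- edges[order(edges$agent_a, edges$agent_b, method = "radix"), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph: %d agents, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print.data.frame(utils::head(x$edges, 10L))
  invisible(x)
}

#' Detect social units by thresholding the interaction graph
#'
#' Units are the connected components of the subgraph keeping edges whose
#' weight is at least `weight_threshold`; agents left isolated become
#' singleton units. Raising the threshold can only split units, never
#' merge them.
#'
#' @param graph an [build_interaction_graph()] result.
#' @param weight_threshold non-negative minimum edge weight.
#' @param weight_by `"count"` (default) or `"duration"`: which edge weight
#'   to threshold (duration requires events with a duration field).
#' @return An object of class `unit_partition`: named character vector
#'   mapping each agent id to a unit id (`U1`, `U2`, ... numbered by the
#'   sorted first member of each unit).
#' @export
detect_social_units <- function(graph, weight_threshold,
                                weight_by = c("count", "duration")) {
  stopifnot(inherits(graph, "interaction_graph"),
            is.numeric(weight_threshold), length(weight_threshold) == 1L,
            weight_threshold >= 0)
  weight_by <- match.arg(weight_by)
  w <- if (weight_by == "count") graph$edges$weight else {
    if (is.null(graph$edges$duration)) {
      stop("graph has no duration weights; build it from a stream with durations")
    }
    graph$edges$duration
  }
  keep <- graph$edges[w >= weight_threshold, c("agent_a", "agent_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)$membership
  # deterministic unit ids: number components by their sorted first member
  agents <- sort(names(comp))
  first_member <- vapply(split(agents, comp[agents]), min, character(1))
  relabel <- rank(first_member)  # component id -> unit index
  units <- paste0("U", relabel[as.character(comp[agents])])
  structure(stats::setNames(units, agents), class = "unit_partition")
}

#' @export
print.unit_partition <- function(x, ...) {
  cat(sprintf("<unit_partition: %d agents in %d unit(s)>\n",
              length(x), length(unique(unclass(x)))))
  print(unclass(x))
  invisible(x)
}

#' @export
as.data.frame.unit_partition <- function(x, ...) {
  data.frame(agent = names(x), unit = as.character(unclass(x)),
             stringsAsFactors = FALSE)
}

#' Number of units along a threshold sweep
#'
#' The threshold separating within-unit from between-unit interaction
#' intensity is data-set specific; this helper reports the unit count at
#' each candidate threshold so a plateau can be picked by inspection.
#'
#' @param graph an [build_interaction_graph()] result.
#' @param thresholds numeric vector of thresholds; defaults to the sorted
#'   distinct edge weights (plus 0).
#' @param weight_by passed to [detect_social_units()].
#' @return data.frame with columns `threshold` and `n_units`.
#' @export
unit_count_sweep <- function(graph, thresholds = NULL,
                             weight_by = c("count", "duration")) {
  weight_by <- match.arg(weight_by)
  if (is.null(thresholds)) {
    w <- if (weight_by == "count") graph$edges$weight else graph$edges$duration
    thresholds <- sort(unique(c(0, w)))
  }
  n_units <- vapply(thresholds, function(th) {
    length(unique(unclass(detect_social_units(graph, th, weight_by))))
  }, numeric(1))
  data.frame(threshold = thresholds, n_units = n_units)
}

#' Re-express a stream between unit-level agents
#'
#' Each inter-unit event (time, a in G1, b in G2, action) becomes
#' (time, G1, G2, action). Intra-unit events are dropped by default (the
#' model applies separately to pairs within a unit and to pairs of units);
#' keep them to analyze within-unit dyads at the unit scale.
#'
#' @param stream an [event_stream()].
#' @param partition a [detect_social_units()] result (or named vector
#'   agent -> unit) covering every agent in the stream.
#' @param drop_intra drop events whose endpoints share a unit (default
#'   `TRUE`).
#' @return An [event_stream()] whose agents are unit ids; event order and
#'   times are preserved.
#' @export
aggregate_stream <- function(stream, partition, drop_intra = TRUE) {
  stream <- validate_event_stream(as.data.frame(stream))
  part <- stats::setNames(as.character(unclass(partition)), names(partition))
  missing <- setdiff(stream_agents(stream), names(part))
  if (length(missing)) {
    stop(sprintf("agent(s) not mapped by the partition: %s",
                 paste(missing, collapse = ", ")))
  }
  if (!nrow(stream)) return(stream)
  su <- part[stream$source]
  tu <- part[stream$target]
  intra <- su == tu
  out <- stream
  out$source <- unname(su)
  out$target <- unname(tu)
  if (drop_intra) {
    out <- out[!intra, , drop = FALSE]
  } else if (any(intra)) {
    # within-unit events cannot become self-edges; keep the original agents
    out$source[intra] <- stream$source[intra]
    out$target[intra] <- stream$target[intra]
  }
  rownames(out) <- NULL
  class(out) <- unique(c("event_stream", class(out)))
  out
}
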