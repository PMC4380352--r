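# Category detection in per-dyad event streams.
#
# Each category leaves a characteristic flux pattern: EM is an alternated
# exchange of one action in both directions; MP two separate alternated
# exchanges of two actions covering both orderings; AR one alternated
# exchange of two different actions with fixed roles; CS bilateral but
# non-alternated flux of one action; UNILATERAL one-directional flux; NULL
# no flux at all. Patterns overlap (an MP dyad also shows bilateral flux of
# each action), so candidates are tested in a fixed precedence and events
# are attributed greedily: NULL, EM, MP, AR, CS, UNILATERAL.

#' Classifier configuration
#'
#' @param alternation_tolerance tolerance theta in \[0, 1\]: a sequence
#'   counts as alternated only if its [alternation_score()] is at least
#'   `1 - theta`. 0 demands strict alternation; the default 0.2 forgives
#'   occasional double turns.
#' @param alpha significance level in (0, 1) for the permutation test of
#'   alternation.
#' @param n_permutations Monte-Carlo sample size for [alternation_pvalue()].
#' @param min_fluxes minimum number of events before a sequence can be
#'   called alternated (EM/MP/AR); shorter exchanges fall through to CS or
#'   UNILATERAL with `low_evidence = TRUE`.
#' @param balance_tolerance allowed imbalance between the two directions of
#'   an alternated exchange: `|m - n|` may not exceed
#'   `max(1, ceiling(balance_tolerance * L))`.
#' @param seed integer seed making Monte-Carlo p-values reproducible.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(alternation_tolerance = 0.2, alpha = 0.05,
                              n_permutations = 2000L, min_fluxes = 4L,
                              balance_tolerance = 0.2, seed = 1L) {
  stopifnot(
    is.numeric(alternation_tolerance), length(alternation_tolerance) == 1L,
    alternation_tolerance >= 0, alternation_tolerance <= 1,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(n_permutations), length(n_permutations) == 1L, n_permutations >= 1,
    is.numeric(min_fluxes), length(min_fluxes) == 1L, min_fluxes >= 1,
    is.numeric(balance_tolerance), length(balance_tolerance) == 1L,
    balance_tolerance >= 0,
    is.numeric(seed), length(seed) == 1L, !is.na(seed)
  )
  structure(
    list(alternation_tolerance = alternation_tolerance, alpha = alpha,
         n_permutations = as.integer(n_permutations),
         min_fluxes = as.integer(min_fluxes),
         balance_tolerance = balance_tolerance, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

# conjunction defining "alternated" for a direction-labeled sequence;
# p-value is only computed once the cheap conditions hold
.alternation_test <- function(labels, config) {
  L <- length(labels)
  counts <- table(labels)
  m <- if (length(counts) >= 1L) as.integer(counts[1L]) else 0L
  n <- L - m
  res <- list(L = L, m = m, n = n, score = NA_real_, p = NA_real_, pass = FALSE)
  if (L < 2L) return(res)
  res$score <- alternation_score(labels)
  if (L < config$min_fluxes) return(res)
  if (length(counts) < 2L) return(res)
  if (abs(m - n) > max(1, ceiling(config$balance_tolerance * L))) return(res)
  if (res$score < 1 - config$alternation_tolerance - 1e-12) return(res)
  res$p <- as.numeric(alternation_pvalue(labels, config$n_permutations))
  res$pass <- res$p <= config$alpha
  res
}

.detection <- function(instance, events, m, n, score, p, low_evidence = FALSE,
                       window = c(NA_real_, NA_real_)) {
  structure(
    list(instance = instance, events = events, n_events = length(events),
         m = m, n = n, score = score, p_value = p,
         low_evidence = low_evidence,
         window_start = window[1L], window_end = window[2L]),
    class = "detection"
  )
}

#' @export
format.detection <- function(x, ...) {
  extra <- character()
  if (!is.na(x$score)) extra <- c(extra, sprintf("score=%.3f", x$score))
  if (!is.na(x$p_value)) extra <- c(extra, sprintf("p=%.4g", x$p_value))
  if (isTRUE(x$low_evidence)) extra <- c(extra, "low evidence")
  sprintf("%s [m=%d, n=%d%s]", format(x$instance), x$m, x$n,
          if (length(extra)) paste0(", ", paste(extra, collapse = ", ")) else "")
}

#' @export
print.detection <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Classify one dyad's event stream into category detections
#'
#' Bins the stream's events by (direction, action) and tests candidate
#' patterns in the fixed precedence NULL, EM, MP, AR, CS, UNILATERAL. A
#' candidate claims its bins only when they are still unattributed, so each
#' event supports exactly one detection and every event is attributed.
#' "Alternated" means: at least `min_fluxes` events, balanced directions,
#' [alternation_score()] `>= 1 - alternation_tolerance`, and permutation
#' p-value `<= alpha`. Within a precedence level, candidates with smaller
#' p-values fire first.
#'
#' @param stream an [event_stream()] whose events all belong to one
#'   unordered agent pair.
#' @param config a [classifier_config()].
#' @param agents optional character vector of the two agent ids (needed to
#'   name agents when the stream is empty).
#' @param window internal: time interval recorded on the detections.
#' @return An object of class `dyad_classification`: list with elements
#'   `agents`, `n_events`, `detections` (list of `detection`), `config`.
#' @examples
#' s <- event_stream(1:8, rep(c("A", "B"), 4), rep(c("B", "A"), 4), "X")
#' classify_dyad(s)  # EM(X)
#' @export
classify_dyad <- function(stream, config = classifier_config(), agents = NULL,
                          window = c(NA_real_, NA_real_)) {
  stream <- validate_event_stream(as.data.frame(stream))
  stream <- .bundle_simultaneous(stream)
  seen <- stream_agents(stream)
  if (length(seen) > 2L) {
    stop(sprintf("dyad stream contains %d agents; split it with split_dyads() first",
                 length(seen)))
  }
  if (is.null(agents)) {
    agents <- if (length(seen) == 2L) seen else c(seen, c("A", "B"))[1:2]
  }
  agents <- sort(as.character(agents))
  if (length(agents) != 2L || anyDuplicated(agents)) {
    stop("`agents` must name two distinct agents")
  }
  if (!all(seen %in% agents)) stop("stream agents do not match `agents`")
  A <- agents[1L]; B <- agents[2L]
  if (nrow(stream) == 0L) {
    det <- .detection(category_instance("NULL", agents = agents),
                      integer(), 0L, 0L, NA_real_, NA_real_, window = window)
    return(.classification(agents, stream, list(det), config))
  }

  bin_key <- paste(stream$source, stream$action, sep = "\r")
  bins <- split(seq_len(nrow(stream)), bin_key)
  acts_A <- sort(unique(stream$action[stream$source == A]))
  acts_B <- sort(unique(stream$action[stream$source == B]))
  kA <- function(s) paste(A, s, sep = "\r")
  kB <- function(s) paste(B, s, sep = "\r")

  # ---- candidate construction (deterministic order) ----
  cands <- list()
  add <- function(level, keys, instance, seqs) {
    cands[[length(cands) + 1L]] <<- list(level = level, keys = keys,
                                         instance = instance, seqs = seqs)
  }
  both <- intersect(acts_A, acts_B)
  for (s in both) {
    add("EM", c(kA(s), kB(s)), category_instance("EM", s, agents = agents),
        list(sort(c(bins[[kA(s)]], bins[[kB(s)]]))))
  }
  if (length(both) || (length(acts_A) && length(acts_B))) {
    pool <- sort(union(acts_A, acts_B))
    if (length(pool) >= 2L) {
      prs <- utils::combn(pool, 2L, simplify = FALSE)
      for (p in prs) {
        s <- p[1L]; t <- p[2L]
        keys <- c(kA(s), kB(t), kA(t), kB(s))
        if (all(keys %in% names(bins))) {
          add("MP", keys, category_instance("MP", c(s, t), agents = agents),
              list(sort(c(bins[[kA(s)]], bins[[kB(t)]])),
                   sort(c(bins[[kA(t)]], bins[[kB(s)]]))))
        }
      }
    }
    for (s in acts_A) {
      for (t in acts_B) {
        if (s == t) next
        add("AR", c(kA(s), kB(t)),
            category_instance("AR", c(s, t), agents = agents),
            list(sort(c(bins[[kA(s)]], bins[[kB(t)]]))))
      }
    }
  }
  for (s in both) {
    add("CS", c(kA(s), kB(s)), category_instance("CS", s, agents = agents),
        list(sort(c(bins[[kA(s)]], bins[[kB(s)]]))))
  }
  for (key in sort(names(bins))) {
    src <- sub("\r.*$", "", key)
    s <- sub("^.*\r", "", key)
    add("UNILATERAL", key,
        category_instance("UNILATERAL", s, actor = src, agents = agents),
        list(bins[[key]]))
  }

  # ---- pattern tests (seeded, deterministic candidate order) ----
  cands <- .with_seed(config$seed, {
    lapply(cands, function(cd) {
      if (cd$level %in% c("EM", "MP", "AR")) {
        tests <- lapply(cd$seqs, function(idx) {
          .alternation_test(stream$source[idx], config)
        })
        cd$pass <- all(vapply(tests, `[[`, logical(1), "pass"))
        cd$p <- max(vapply(tests, `[[`, numeric(1), "p"))
        cd$score <- min(vapply(tests, `[[`, numeric(1), "score"))
      } else {
        cd$pass <- TRUE
        cd$p <- NA_real_
        idx <- cd$seqs[[1L]]
        cd$score <- if (length(idx) >= 2L) {
          alternation_score(stream$source[idx])
        } else NA_real_
      }
      cd$events <- sort(unique(unlist(cd$seqs)))
      cd
    })
  })

  # ---- greedy attribution in precedence order ----
  used <- character()
  detections <- list()
  for (level in c("EM", "MP", "AR", "CS", "UNILATERAL")) {
    lv <- Filter(function(cd) cd$level == level && isTRUE(cd$pass), cands)
    if (!length(lv)) next
    ord <- order(vapply(lv, function(cd) ifelse(is.na(cd$p), 1, cd$p), numeric(1)),
                 -vapply(lv, function(cd) length(cd$events), numeric(1)),
                 vapply(lv, function(cd) .instance_key(cd$instance), character(1)))
    for (cd in lv[ord]) {
      if (any(cd$keys %in% used)) next
      idx <- cd$events
      m <- sum(stream$source[idx] == A)
      n <- length(idx) - m
      detections[[length(detections) + 1L]] <-
        .detection(cd$instance, idx, m, n, cd$score, cd$p,
                   low_evidence = level %in% c("CS", "UNILATERAL") &&
                     length(idx) < config$min_fluxes,
                   window = window)
      used <- c(used, cd$keys)
    }
  }
  .classification(agents, stream, detections, config)
}

# simultaneous same-direction events at one timestamp act as one compound
# flux: collapse them into a single bundle-action event; opposite-direction
# ties keep stable input order
.bundle_simultaneous <- function(stream) {
  if (!nrow(stream)) return(stream)
  key <- paste(stream$time, stream$source, sep = "\r")
  if (!anyDuplicated(key)) return(stream)
  groups <- split(seq_len(nrow(stream)), match(key, unique(key)))
  rows <- lapply(groups, function(i) {
    r <- stream[i[1L], , drop = FALSE]
    if (length(i) > 1L) {
      r$action <- make_bundle(stream$action[i])
      if ("duration" %in% names(stream)) r$duration <- sum(stream$duration[i])
    }
    r
  })
  validate_event_stream(do.call(rbind, rows))
}

.classification <- function(agents, stream, detections, config) {
  structure(
    list(agents = agents, n_events = nrow(stream), detections = detections,
         stream = stream, config = config),
    class = "dyad_classification"
  )
}

#' @export
print.dyad_classification <- function(x, ...) {
  cat(sprintf("<dyad_classification: %s -- %s, %d events, %d detection(s)>\n",
              x$agents[1L], x$agents[2L], x$n_events, length(x$detections)))
  for (d in x$detections) cat("  ", format(d), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dyad_classification <- function(object, ...) {
  as.data.frame(object)
}

#' @export
as.data.frame.dyad_classification <- function(x, ...) {
  if (!length(x$detections)) {
    return(data.frame(dyad = character(), category = character(),
                      actions = character(), actor = character(),
                      m = integer(), n = integer(), score = numeric(),
                      p_value = numeric(), n_events = integer(),
                      low_evidence = logical(), window_start = numeric(),
                      window_end = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(x$detections, function(d) {
    data.frame(
      dyad = paste(x$agents, collapse = "|"),
      category = d$instance$category,
      actions = paste(d$instance$actions, collapse = ";"),
      actor = d$instance$actor,
      m = d$m, n = d$n, score = d$score, p_value = d$p_value,
      n_events = d$n_events, low_evidence = d$low_evidence,
      window_start = d$window_start, window_end = d$window_end,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Categories detected in a classification
#'
#' @param x a `dyad_classification`.
#' @return Character vector of canonical instance keys
#'   (`"category|actions|actor"`), sorted.
#' @export
detected_keys <- function(x) {
  sort(vapply(x$detections, function(d) .instance_key(d$instance), character(1)))
}

#' Classify every dyad of a population stream
#'
#' @param stream an [event_stream()] over any number of agents.
#' @param config a [classifier_config()].
#' @return Named list of [classify_dyad()] results, one per dyad.
#' @export
classify_dyads <- function(stream, config = classifier_config()) {
  lapply(split_dyads(stream), classify_dyad, config = config)
}

#' Classify a dyad stream over sliding time windows
#'
#' Relationships can change over time; windowed analysis classifies each
#' half-open window \[t, t + window_length) independently, with windows
#' anchored at the stream's first event time and advanced by `step`.
#'
#' @param stream an [event_stream()] for one dyad.
#' @param window_length positive window span (time units of the stream).
#' @param step positive advance between window starts; at most
#'   `window_length` (equal for non-overlapping tiling).
#' @param config a [classifier_config()].
#' @param agents optional pair of agent ids (used when the stream is empty).
#' @return An object of class `window_classification`: list of entries with
#'   `start`, `end` and `classification`, ordered by window start.
#' @export
classify_windows <- function(stream, window_length, step = window_length,
                             config = classifier_config(), agents = NULL) {
  stopifnot(window_length > 0, step > 0, step <= window_length)
  stream <- validate_event_stream(as.data.frame(stream))
  if (nrow(stream) == 0L) {
    res <- classify_dyad(stream, config, agents = agents,
                         window = c(0, window_length))
    out <- list(list(start = 0, end = window_length, classification = res))
    return(structure(out, class = "window_classification"))
  }
  t0 <- stream$time[1L]
  tmax <- stream$time[nrow(stream)]
  starts <- seq(t0, tmax, by = step)
  out <- lapply(starts, function(st) {
    en <- st + window_length
    idx <- which(stream$time >= st & stream$time < en)
    res <- classify_dyad(.stream_rows(stream, idx), config, agents = agents,
                         window = c(st, en))
    list(start = st, end = en, classification = res)
  })
  structure(out, class = "window_classification")
}

#' @export
print.window_classification <- function(x, ...) {
  cat(sprintf("<window_classification: %d window(s)>\n", length(x)))
  for (w in x) {
    cats <- vapply(w$classification$detections, function(d) format(d$instance),
                   character(1))
    cat(sprintf("  [%g, %g): %s\n", w$start, w$end,
                paste(cats, collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.window_classification <- function(x, ...) {
  do.call(rbind, lapply(x, function(w) as.data.frame(w$classification)))
}

#' Detection records for serialization
#'
#' Flattens classifications into the JSON record schema
#' `{dyad, category, actions, actor, m, n, score, p_value, n_events,
#' low_evidence, window_start, window_end}`.
#'
#' @param x a `dyad_classification`, `window_classification`, or list of
#'   either.
#' @return A list of named lists, one per detection.
#' @export
detection_records <- function(x) {
  if (inherits(x, "dyad_classification")) x <- list(x)
  if (inherits(x, "window_classification")) {
    x <- lapply(unclass(x), `[[`, "classification")
  }
  recs <- list()
  for (cl in x) {
    if (inherits(cl, "window_classification")) {
      recs <- c(recs, detection_records(cl))
      next
    }
    for (d in cl$detections) {
      recs[[length(recs) + 1L]] <- list(
        dyad = cl$agents,
        category = d$instance$category,
        actions = as.list(d$instance$actions),
        actor = if (is.na(d$instance$actor)) NULL else d$instance$actor,
        m = d$m, n = d$n,
        score = if (is.na(d$score)) NULL else d$score,
        p_value = if (is.na(d$p_value)) NULL else d$p_value,
        n_events = d$n_events,
        low_evidence = d$low_evidence,
        window_start = if (is.na(d$window_start)) NULL else d$window_start,
        window_end = if (is.na(d$window_end)) NULL else d$window_end
      )
    }
  }
  recs
}
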