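# Seeded synthetic event-stream generation.
#
# The generator realizes the canonical flux pattern of each category so
# classification can be validated by round trip: EM is a strict alternation
# of one action in both directions; MP interleaves (in blocks) two strict
# alternations covering both orderings of its action pair; AR is a strict
# alternation of two actions with fixed roles; CS draws unbalanced counts
# in both directions and shuffles them until the order is clearly not
# alternated; UNILATERAL is one-directional; NULL is an empty stream.
# Optional noise (drop, swap-adjacent, insert) emulates flexible turn
# taking, occasional cheating and inexact record keeping.

#' Specify a synthetic dyad stream
#'
#' @param category one of [category_labels()].
#' @param actions action label(s) for the instance: one for EM/CS/
#'   UNILATERAL, two for MP/AR (for AR: first done by `agents[1]`, second
#'   by `agents[2]`), none for NULL.
#' @param actor for UNILATERAL: the acting agent (default the first).
#' @param agents the two agent ids (default `c("A", "B")`).
#' @param n_rounds number of exchange rounds: per-direction event count for
#'   EM/AR/UNILATERAL (and the larger CS direction), rounds per ordering
#'   for MP. At least 2 for CS (unequal counts need two candidates).
#' @param inter_event_gap mean time between consecutive events (arbitrary
#'   units); event k is placed at `k * gap` plus jitter smaller than half
#'   the gap, so the intended order survives.
#' @param noise_drop,noise_swap,noise_extra per-event probabilities of
#'   dropping an event, swapping it with its successor, and inserting a
#'   spurious random event. Applied in that fixed order.
#' @param seed integer seed; identical specs and seeds yield identical
#'   streams.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(category, actions = character(), actor = NULL,
                           agents = c("A", "B"), n_rounds = 10L,
                           inter_event_gap = 1, noise_drop = 0,
                           noise_swap = 0, noise_extra = 0, seed = 1L) {
  agents <- as.character(agents)
  if (length(agents) != 2L || agents[1L] == agents[2L]) {
    stop("`agents` must be two distinct ids")
  }
  category <- .check_category(category)
  if (category == "UNILATERAL" && is.null(actor)) actor <- agents[1L]
  instance <- category_instance(category, actions, actor = actor, agents = agents)
  stopifnot(n_rounds >= 1, inter_event_gap > 0,
            noise_drop >= 0, noise_drop <= 1,
            noise_swap >= 0, noise_swap <= 1,
            noise_extra >= 0, noise_extra <= 1)
  if (category == "CS" && n_rounds < 2L) {
    stop("CS needs n_rounds >= 2: unequal direction counts are impossible otherwise")
  }
  structure(
    list(instance = instance, agents = agents, n_rounds = as.integer(n_rounds),
         inter_event_gap = inter_event_gap, noise_drop = noise_drop,
         noise_swap = noise_swap, noise_extra = noise_extra,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec: %s, %d rounds, noise (%g, %g, %g), seed %d>\n",
              format(x$instance), x$n_rounds, x$noise_drop, x$noise_swap,
              x$noise_extra, x$seed))
  invisible(x)
}

# sequence of (source, action) pairs realizing the noise-free pattern;
# called inside a seeded RNG context
.pattern_events <- function(spec) {
  A <- spec$agents[1L]; B <- spec$agents[2L]
  inst <- spec$instance
  R <- spec$n_rounds
  switch(inst$category,
    "NULL" = data.frame(source = character(), action = character(),
                        stringsAsFactors = FALSE),
    EM = data.frame(source = rep(c(A, B), R),
                    action = inst$actions, stringsAsFactors = FALSE),
    AR = data.frame(source = rep(c(A, B), R),
                    action = rep(inst$actions, R), stringsAsFactors = FALSE),
    MP = {
      s <- inst$actions[1L]; t <- inst$actions[2L]
      # two strict alternations, interleaved in blocks of two rounds: the
      # first ordering (A starts with s, B answers with t) and the second
      # (B starts with s, A answers with t). Blocks keep each single-action
      # direction sequence clumped (A,A,B,B,...), so a true MP stream never
      # masquerades as EM of s or of t.
      o1 <- data.frame(source = c(A, B), action = c(s, t),
                       stringsAsFactors = FALSE)
      o2 <- data.frame(source = c(B, A), action = c(s, t),
                       stringsAsFactors = FALSE)
      blocks <- list()
      r1 <- r2 <- 0L
      while (r1 < R || r2 < R) {
        take1 <- min(2L, R - r1)
        if (take1 > 0L) {
          blocks <- c(blocks, rep(list(o1), take1)); r1 <- r1 + take1
        }
        take2 <- min(2L, R - r2)
        if (take2 > 0L) {
          blocks <- c(blocks, rep(list(o2), take2)); r2 <- r2 + take2
        }
      }
      do.call(rbind, blocks)
    },
    CS = {
      m <- R
      # unbalanced reply count, at least 1 off, up to ~a third of m
      d <- sample(seq_len(max(1L, as.integer(round(m / 3)))), 1L)
      n <- if (stats::runif(1) < 0.5) max(1L, m - d) else m + d
      if (n == m) n <- m + d
      src <- c(rep(A, m), rep(B, n))
      # shuffle until clearly non-alternated (the EM/CS boundary is the
      # alternation criterion, so fixtures must not look alternated)
      thr <- 1 - 0.2  # default alternation tolerance
      for (i in seq_len(1000L)) {
        src <- sample(src)
        if (alternation_score(src) < thr) break
      }
      if (alternation_score(src) >= thr) src <- sort(src)  # deterministic fallback
      data.frame(source = src, action = inst$actions, stringsAsFactors = FALSE)
    },
    UNILATERAL = data.frame(source = rep(inst$actor, R),
                            action = inst$actions, stringsAsFactors = FALSE)
  )
}

# deterministic arithmetic timestamps plus jitter below half the gap
.timestamps <- function(n, gap) {
  if (n == 0L) return(numeric())
  seq_len(n) * gap + stats::runif(n, -gap / 4, gap / 4)
}

.apply_noise <- function(df, spec) {
  n <- nrow(df)
  if (n == 0L) return(df)
  other <- function(src) ifelse(src == spec$agents[1L], spec$agents[2L],
                                spec$agents[1L])
  # 1. drop
  if (spec$noise_drop > 0) {
    keep <- stats::runif(n) >= spec$noise_drop
    df <- df[keep, , drop = FALSE]
  }
  # 2. swap-adjacent: event contents trade places, time slots stay put
  n <- nrow(df)
  if (spec$noise_swap > 0 && n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (stats::runif(1) < spec$noise_swap) {
        df[c(i, i + 1L), c("source", "target", "action")] <-
          df[c(i + 1L, i), c("source", "target", "action")]
      }
    }
  }
  # 3. insert spurious events
  if (spec$noise_extra > 0 && n > 0L) {
    ins <- which(stats::runif(n) < spec$noise_extra)
    if (length(ins)) {
      acts <- unique(df$action)
      extra <- data.frame(
        time = df$time[ins] + spec$inter_event_gap / 3,
        source = sample(spec$agents, length(ins), replace = TRUE),
        action = sample(acts, length(ins), replace = TRUE),
        stringsAsFactors = FALSE
      )
      extra$target <- other(extra$source)
      df <- rbind(df, extra[, names(df)])
    }
  }
  df
}

#' Generate a synthetic dyad stream
#'
#' Noise-free output realizes the spec's category pattern exactly (see
#' [generator_spec()]); noise operators are then applied independently per
#' event in the fixed order drop, swap-adjacent, insert. Fully reproducible
#' from the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return An [event_stream()].
#' @examples
#' generate_dyad(generator_spec("EM", "X", n_rounds = 5))
#' @export
generate_dyad <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .with_seed(spec$seed, {
    ev <- .pattern_events(spec)
    other <- ifelse(ev$source == spec$agents[1L], spec$agents[2L],
                    spec$agents[1L])
    df <- data.frame(time = .timestamps(nrow(ev), spec$inter_event_gap),
                     source = ev$source, target = other, action = ev$action,
                     stringsAsFactors = FALSE)
    df <- .apply_noise(df, spec)
    validate_event_stream(df)
  })
}

#' Merge several component streams into one composite relationship
#'
#' Composite relationships realize several categories at once (friends may
#' share freely, direct a task, split costs and trade, all in one
#' relationship). Component streams are merged on a common clock either
#' interleaved (a seeded random shuffle preserving each component's
#' internal order) or as sequential blocks; per-component event counts are
#' preserved.
#'
#' @param specs list of [generator_spec()]s, all on the same agent pair.
#' @param interleave merge by random interleaving (default) or concatenate
#'   sequentially.
#' @param seed integer seed for the interleaving and re-timing.
#' @return An [event_stream()].
#' @export
generate_composite <- function(specs, interleave = TRUE, seed = 1L) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "generator_spec")))
  pairs <- vapply(specs, function(s) paste(sort(s$agents), collapse = "|"),
                  character(1))
  if (length(unique(pairs)) != 1L) {
    stop("all component specs must involve the same dyad")
  }
  streams <- lapply(specs, generate_dyad)
  if (length(streams) == 1L) return(streams[[1L]])
  gap <- min(vapply(specs, `[[`, numeric(1), "inter_event_gap"))
  sizes <- vapply(streams, nrow, integer(1))
  .with_seed(seed, {
    if (interleave) {
      lane <- sample(rep(seq_along(streams), sizes))
      total <- sum(sizes)
      times <- .timestamps(total, gap)
      rows <- vector("list", total)
      taken <- integer(length(streams))
      for (k in seq_len(total)) {
        l <- lane[k]
        taken[l] <- taken[l] + 1L
        r <- streams[[l]][taken[l], , drop = FALSE]
        r$time <- times[k]
        rows[[k]] <- r
      }
      validate_event_stream(do.call(rbind, rows))
    } else {
      offset <- 0
      shifted <- lapply(streams, function(s) {
        if (nrow(s)) {
          s$time <- s$time - min(s$time) + offset
          offset <<- max(s$time) + gap
        }
        s
      })
      validate_event_stream(do.call(rbind, shifted))
    }
  })
}

#' Specify a synthetic population with social units
#'
#' @param unit_sizes integer vector: number of member agents per unit.
#'   Units are named `G1`, `G2`, ...; members `G1_1`, `G1_2`, ...
#' @param assignments list of dyad assignments; each element is a list with
#'   `dyad` (two agent or unit ids), `category`, and optionally `actions`,
#'   `actor`, `n_rounds`, plus any other [generator_spec()] field. A dyad
#'   of unit ids is realized at the unit level by randomly chosen members.
#' @param inter_event_gap,seed shared generator settings.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(unit_sizes, assignments = list(),
                            inter_event_gap = 1, seed = 1L) {
  stopifnot(length(unit_sizes) >= 1L, all(unit_sizes >= 1))
  units <- paste0("G", seq_along(unit_sizes))
  members <- lapply(seq_along(unit_sizes), function(i) {
    paste0(units[i], "_", seq_len(unit_sizes[i]))
  })
  names(members) <- units
  known <- c(units, unlist(members))
  for (a in assignments) {
    if (is.null(a$dyad) || length(a$dyad) != 2L || !all(a$dyad %in% known)) {
      stop("each assignment needs `dyad`: two known agent or unit ids")
    }
    if (is.null(a$category)) stop("each assignment needs `category`")
  }
  structure(
    list(units = units, members = members, assignments = assignments,
         inter_event_gap = inter_event_gap, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Generate a population stream with unit-level relationships
#'
#' Intra-unit (or member-member) assignments are generated directly between
#' the named agents. Unit-level assignments are generated between the unit
#' ids and then realized by substituting, per event, a randomly chosen
#' member of the acting unit and of the receiving unit. Streams are offset
#' so dyads do not collide on identical timestamps; fully reproducible from
#' the seed.
#'
#' @param pop a [population_spec()].
#' @return An [event_stream()] over member agents, with attribute
#'   `partition` (named vector agent -> unit covering every member).
#' @export
generate_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  partition <- stats::setNames(
    rep(pop$units, vapply(pop$members, length, integer(1))),
    unlist(pop$members)
  )
  streams <- .with_seed(pop$seed, {
    lapply(seq_along(pop$assignments), function(i) {
      a <- pop$assignments[[i]]
      spec_args <- a[setdiff(names(a), c("dyad", "category"))]
      spec_args$category <- a$category
      spec_args$agents <- a$dyad
      if (is.null(spec_args$inter_event_gap)) {
        spec_args$inter_event_gap <- pop$inter_event_gap
      }
      if (is.null(spec_args$seed)) spec_args$seed <- pop$seed + i
      s <- generate_dyad(do.call(generator_spec, spec_args))
      # unit-level dyads: realized by randomly chosen members per event
      for (side in c("source", "target")) {
        is_unit <- s[[side]] %in% pop$units
        if (any(is_unit)) {
          mem <- pop$members[s[[side]][is_unit]]
          s[[side]][is_unit] <- vapply(mem, function(ms) {
            if (length(ms) == 1L) ms else sample(ms, 1L)
          }, character(1))
        }
      }
      # deterministic per-dyad offset so timestamps never tie across dyads
      s$time <- s$time + (i - 1L) * pop$inter_event_gap / (length(pop$assignments) + 1L)
      s
    })
  })
  out <- if (length(streams)) {
    validate_event_stream(do.call(rbind, streams))
  } else {
    event_stream()
  }
  attr(out, "partition") <- partition
  out
}
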