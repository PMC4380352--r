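# Structural decomposition of a relationship into category instances.

#' Create a category instance
#'
#' One detected or assigned occurrence of a category: the category label
#' plus the action(s) it involves and, where roles matter, who does what.
#'
#' @param category one of [category_labels()].
#' @param actions the action(s) involved: one action for EM, CS and
#'   UNILATERAL; an unordered pair for MP; an ordered pair (action by the
#'   first agent, action by the second) for AR; none for NULL.
#' @param actor for UNILATERAL only: which agent acts (by convention `"A"`
#'   and `"B"` for the structural model; classifier detections substitute
#'   real agent ids).
#' @param agents optional character vector of length 2 naming the dyad's
#'   agents in (A, B) order; defaults to `c("A", "B")`.
#' @return An object of class `category_instance`.
#' @examples
#' category_instance("EM", "X")
#' category_instance("AR", c("X", "Y"))      # A does X, B does Y
#' category_instance("UNILATERAL", "X", actor = "A")
#' @export
category_instance <- function(category, actions = character(), actor = NULL,
                              agents = c("A", "B")) {
  category <- .check_category(category)
  actions <- as.character(actions)
  arity <- switch(category, "NULL" = 0L, MP = 2L, AR = 2L, 1L)
  if (length(actions) != arity) {
    stop(sprintf("category %s takes %d action(s), got %d",
                 category, arity, length(actions)))
  }
  if (length(actions)) {
    .check_actions(actions)  # also rejects duplicates, so AR/MP actions differ
  }
  if (category == "MP") actions <- sort(actions)  # unordered pair
  if (category == "UNILATERAL") {
    if (is.null(actor) || !actor %in% agents) {
      stop("UNILATERAL needs `actor`, one of the two agents")
    }
  } else if (!is.null(actor)) {
    stop("`actor` is only meaningful for UNILATERAL")
  }
  structure(
    list(category = category, actions = actions,
         actor = if (is.null(actor)) NA_character_ else actor,
         agents = as.character(agents)),
    class = "category_instance"
  )
}

#' @export
format.category_instance <- function(x, ...) {
  switch(x$category,
    "NULL" = "NULL",
    EM = sprintf("EM(%s)", x$actions),
    CS = sprintf("CS(%s)", x$actions),
    MP = sprintf("MP{%s, %s}", x$actions[1L], x$actions[2L]),
    AR = sprintf("AR(%s by %s, %s by %s)",
                 x$actions[1L], x$agents[1L], x$actions[2L], x$agents[2L]),
    UNILATERAL = sprintf("UNILATERAL(%s by %s)", x$actions, x$actor)
  )
}

#' @export
print.category_instance <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# canonical key used to compare instance sets in tests and detections
.instance_key <- function(x) {
  paste(x$category, paste(x$actions, collapse = ","),
        if (x$category == "UNILATERAL") x$actor else "", sep = "|")
}

#' Decompose a relationship into category instances
#'
#' Every composite relationship can be read as a combination of the six
#' categories: each of its elementary interactions is covered by exactly
#' one instance. Rules, applied to the set of interactions:
#' * `(s, s)` is an EM instance for s;
#' * the pair `(s, t)` and `(t, s)` (both present, s != t non-null) is one
#'   MP instance for \{s, t\};
#' * `(s, t)` alone (s != t non-null) is an AR instance (A does s, B does t);
#' * the pair `(s, null)` and `(null, s)` (both present) is one CS instance
#'   for s;
#' * `(s, null)` or `(null, s)` alone is a UNILATERAL instance of s by the
#'   acting agent;
#' * the empty (null) relationship is the single NULL instance.
#'
#' @param rel a [relationship()].
#' @param agents optional agent names carried into the instances.
#' @return A list of [category_instance()] objects.
#' @examples
#' decompose_relationship(relationship(rbind(c("X", "X"), c("Y", "Y"))))
#' @export
decompose_relationship <- function(rel, agents = c("A", "B")) {
  if (!inherits(rel, "relationship")) rel <- relationship(rel)
  nul <- null_action()
  n <- nrow(rel)
  if (n == 0L) {
    return(list(category_instance("NULL", agents = agents)))
  }
  a <- rel[, 1L]; b <- rel[, 2L]
  if (any(is_null_action(a) & is_null_action(b))) {
    stop("malformed relationship: contains the null interaction")
  }
  key <- .ei_key(rel)
  out <- list()
  used <- rep(FALSE, n)
  # EM: identical non-null actions
  em <- which(a == b)
  for (i in em) {
    out[[length(out) + 1L]] <- category_instance("EM", a[i], agents = agents)
    used[i] <- TRUE
  }
  # bilateral different non-null actions: MP when the swapped pair is there
  bil <- which(!used & !is_null_action(a) & !is_null_action(b))
  for (i in bil) {
    if (used[i]) next
    j <- match(paste(b[i], a[i], sep = "\r"), key)
    if (!is.na(j) && !used[j]) {
      out[[length(out) + 1L]] <- category_instance("MP", c(a[i], b[i]),
                                                   agents = agents)
      used[c(i, j)] <- TRUE
    }
  }
  # remaining bilateral: AR (first agent does a, second does b)
  for (i in bil) {
    if (used[i]) next
    out[[length(out) + 1L]] <- category_instance("AR", c(a[i], b[i]),
                                                 agents = agents)
    used[i] <- TRUE
  }
  # one-sided: CS when both directions of s are present, else UNILATERAL
  uni <- which(!used)
  for (i in uni) {
    if (used[i]) next
    s <- if (is_null_action(b[i])) a[i] else b[i]
    j <- match(paste(b[i], a[i], sep = "\r"), key)
    if (!is.na(j) && !used[j]) {
      out[[length(out) + 1L]] <- category_instance("CS", s, agents = agents)
      used[c(i, j)] <- TRUE
    } else {
      actor <- if (is_null_action(b[i])) agents[1L] else agents[2L]
      out[[length(out) + 1L]] <- category_instance("UNILATERAL", s,
                                                   actor = actor,
                                                   agents = agents)
      used[i] <- TRUE
    }
  }
  out
}

#' Reconstruct the interactions covered by a set of category instances
#'
#' Inverse of [decompose_relationship()]: expands each instance back into
#' the elementary interactions it stands for, so conservation can be
#' checked (the multiset of reconstructed interactions equals the input
#' relationship).
#'
#' @param instances list of [category_instance()] objects.
#' @return A [relationship()].
#' @export
recompose_instances <- function(instances) {
  nul <- null_action()
  rows <- lapply(instances, function(x) {
    switch(x$category,
      "NULL" = NULL,
      EM = rbind(c(x$actions, x$actions)),
      MP = rbind(c(x$actions[1L], x$actions[2L]),
                 c(x$actions[2L], x$actions[1L])),
      AR = rbind(c(x$actions[1L], x$actions[2L])),
      CS = rbind(c(x$actions, nul), c(nul, x$actions)),
      UNILATERAL = if (identical(x$actor, x$agents[1L])) {
        rbind(c(x$actions, nul))
      } else {
        rbind(c(nul, x$actions))
      }
    )
  })
  relationship(do.call(rbind, c(rows, list(.ei_matrix(character(), character())))))
}
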