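# Elementary interactions and the relationship space.
#
# An elementary interaction is the ordered pair (what A does to B, what B
# does to A), each entry a social action or the null action. A relationship
# is a set of non-null elementary interactions realized by one dyad; the
# empty set is the null relationship. Interactions are stored as rows of a
# two-column character matrix (a_to_b, b_to_a), sorted for a canonical form.

.ei_matrix <- function(a_to_b, b_to_a) {
  m <- cbind(a_to_b = as.character(a_to_b), b_to_a = as.character(b_to_a))
  rownames(m) <- NULL
  m
}

.ei_is_null <- function(m) {
  is_null_action(m[, 1L]) & is_null_action(m[, 2L])
}

.ei_key <- function(m) paste(m[, 1L], m[, 2L], sep = "\r")

#' Enumerate the elementary interactions generated by a set of actions
#'
#' Each of the two agents of a dyad independently picks one of the N social
#' actions or the null action, giving the full cross product of per-agent
#' choices: (N+1)^2 elementary interactions, exactly one of which is the
#' null interaction (both agents doing nothing). With two actions this
#' yields the classical nine interactions; with three, sixteen.
#'
#' @param actions character vector of distinct social action labels.
#' @return A two-column character matrix with columns `a_to_b` and
#'   `b_to_a`, one row per elementary interaction.
#' @examples
#' nrow(enumerate_elementary_interactions(c("X", "Y")))       # 9
#' nrow(enumerate_elementary_interactions(c("X", "Y", "Z")))  # 16
#' @export
enumerate_elementary_interactions <- function(actions) {
  actions <- if (length(actions)) .check_actions(actions) else character()
  choices <- c(actions, null_action())
  grid <- expand.grid(b_to_a = choices, a_to_b = choices,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  .ei_matrix(grid$a_to_b, grid$b_to_a)
}

#' Construct a relationship from elementary interactions
#'
#' A relationship is a set of non-null elementary interactions; the empty
#' set denotes the null relationship (which stands for the lone null
#' interaction, since doing nothing cannot coexist with doing something).
#'
#' @param interactions a two-column matrix (or coercible data.frame / list
#'   of length-2 vectors) of (a_to_b, b_to_a) action labels; may have zero
#'   rows.
#' @return An object of class `relationship`: a canonical (row-sorted,
#'   deduplicated) two-column character matrix.
#' @examples
#' relationship(rbind(c("X", "X"), c("Y", "Y")))
#' relationship(NULL)   # the null relationship
#' @export
relationship <- function(interactions = NULL) {
  if (is.null(interactions) || (is.matrix(interactions) && nrow(interactions) == 0L)) {
    return(new_relationship(.ei_matrix(character(), character())))
  }
  if (is.data.frame(interactions)) interactions <- as.matrix(interactions)
  if (is.list(interactions)) interactions <- do.call(rbind, interactions)
  if (is.character(interactions) && is.null(dim(interactions))) {
    interactions <- matrix(interactions, ncol = 2L, byrow = TRUE)
  }
  if (!is.matrix(interactions) || ncol(interactions) != 2L) {
    stop("`interactions` must be pairs (a_to_b, b_to_a) of action labels")
  }
  m <- .ei_matrix(interactions[, 1L], interactions[, 2L])
  if (any(.ei_is_null(m))) {
    if (nrow(m) > 1L) {
      stop("the null interaction cannot coexist with any other elementary interaction")
    }
    m <- m[0L, , drop = FALSE]  # {null interaction} is identified with the null relationship
  }
  m <- m[!duplicated(.ei_key(m)), , drop = FALSE]
  m <- m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
  new_relationship(m)
}

# internal constructor, no validation (hot path of enumerate_relationships)
new_relationship <- function(m) {
  structure(m, class = c("relationship", class(m)))
}

#' @export
print.relationship <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.relationship <- function(x, null_symbol = null_action(), ...) {
  if (nrow(x) == 0L) {
    return("<relationship: NULL>")
  }
  lab <- function(a) ifelse(is_null_action(a), null_symbol, a)
  pairs <- sprintf("[%s, %s]", lab(x[, 1L]), lab(x[, 2L]))
  sprintf("<relationship: {%s}>", paste(pairs, collapse = ", "))
}

#' Is a relationship simple?
#'
#' Simple relationships consist of a single elementary-interaction type;
#' the null relationship is neither simple nor composite.
#'
#' @param rel a [relationship()].
#' @return Logical scalar.
#' @export
is_simple <- function(rel) {
  stopifnot(inherits(rel, "relationship"))
  nrow(rel) == 1L
}

#' Count the relationships generated by N social actions
#'
#' All subsets of the (N+1)^2 - 1 non-null elementary interactions, with
#' the empty subset identified with the null relationship: 2^((N+1)^2 - 1)
#' relationships. For two actions this is 2^8 = 256 (the naive 2^9 = 512
#' subsets collapse once the null interaction, which cannot coexist with
#' any other, is accounted for).
#'
#' @param actions character vector of distinct action labels, or a single
#'   non-negative integer N.
#' @return Number of relationships (double; exact for N <= 5).
#' @examples
#' count_relationships(c("X", "Y"))  # 256
#' count_relationships(1)            # 8
#' count_relationships(0)            # 1, the null relationship alone
#' @export
count_relationships <- function(actions) {
  n <- .n_actions(actions)
  2^((n + 1)^2 - 1)
}

.n_actions <- function(actions) {
  if (is.numeric(actions) && length(actions) == 1L) {
    n <- actions
    if (is.na(n) || n < 0 || n != trunc(n)) stop("N must be a non-negative integer")
    return(as.integer(n))
  }
  length(.check_actions(actions))
}

.default_actions <- function(n) {
  if (n == 0L) character() else paste0("S", seq_len(n))
}

#' Enumerate the full relationship space
#'
#' Yields every subset of the non-null elementary interactions exactly once
#' (the empty subset, i.e. the null relationship, first). The number of
#' non-null interactions, (N+1)^2 - 1, must not exceed `cap` so that the
#' 2^((N+1)^2-1) subsets stay enumerable in memory.
#'
#' @param actions character vector of distinct action labels (or integer N,
#'   in which case labels S1..SN are used).
#' @param cap maximum number of non-null elementary interactions (default
#'   24, i.e. at most 2^24 relationships).
#' @return A list of [relationship()] objects of length
#'   `count_relationships(actions)`.
#' @examples
#' length(enumerate_relationships(c("X", "Y")))  # 256
#' @export
enumerate_relationships <- function(actions, cap = 24L) {
  if (is.numeric(actions) && length(actions) == 1L) {
    actions <- .default_actions(.n_actions(actions))
  }
  ei <- enumerate_elementary_interactions(actions)
  ei <- ei[!.ei_is_null(ei), , drop = FALSE]
  k <- nrow(ei)
  if (k > cap) {
    stop(sprintf(
      "enumeration of 2^%d relationships exceeds the cap of %d non-null interactions (2^%d subsets); raise `cap` to force",
      k, cap, cap))
  }
  if (k == 0L) return(list(new_relationship(ei)))
  # canonical row order so every subset comes out sorted without re-sorting
  ei <- ei[order(ei[, 1L], ei[, 2L], method = "radix"), , drop = FALSE]
  lapply(0:(2^k - 1), function(mask) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))))
    new_relationship(ei[sel, , drop = FALSE])
  })
}

#' The six category labels
#'
#' @return Character vector of the six relationship categories, in test
#'   precedence order: `EM`, `NULL`, `MP`, `AR`, `CS`, `UNILATERAL`
#'   (the last also known as "asocial" in its exploitative special case).
#' @export
category_labels <- function() {
  c("EM", "NULL", "MP", "AR", "CS", "UNILATERAL")
}

.check_category <- function(category) {
  match.arg(category, category_labels())
}

#' Representative relationship forms of a category
#'
#' Every category is defined by a representative relationship up to the
#' (arbitrary) notation chosen for the actions; this returns all
#' notation-equivalent canonical forms over a given action set. Counts:
#' EM has N forms (one per action), NULL one, MP choose(N,2), AR N(N-1),
#' CS N, UNILATERAL 2N.
#'
#' @param category one of [category_labels()].
#' @param actions character vector of distinct action labels (or integer
#'   N). MP and AR need at least two actions, the other non-NULL
#'   categories at least one.
#' @return A list of [relationship()] objects.
#' @examples
#' length(representative_forms("AR", c("X", "Y", "Z")))  # 6
#' length(representative_forms("MP", c("X", "Y", "Z")))  # 3
#' @export
representative_forms <- function(category, actions) {
  category <- .check_category(category)
  if (is.numeric(actions) && length(actions) == 1L) {
    actions <- .default_actions(.n_actions(actions))
  }
  actions <- if (length(actions)) .check_actions(actions) else character()
  actions <- sort(actions)
  n <- length(actions)
  min_n <- switch(category, MP = 2L, AR = 2L, "NULL" = 0L, 1L)
  if (n < min_n) {
    stop(sprintf("category %s needs at least %d action(s), got %d",
                 category, min_n, n))
  }
  nul <- null_action()
  forms <- switch(category,
    EM = lapply(actions, function(s) rbind(c(s, s))),
    "NULL" = list(NULL),
    MP = {
      pairs <- utils::combn(actions, 2L, simplify = FALSE)
      lapply(pairs, function(p) rbind(c(p[1L], p[2L]), c(p[2L], p[1L])))
    },
    AR = {
      grid <- expand.grid(s = actions, t = actions, stringsAsFactors = FALSE)
      grid <- grid[grid$s != grid$t, ]
      mapply(function(s, t) rbind(c(s, t)), grid$s, grid$t, SIMPLIFY = FALSE)
    },
    CS = lapply(actions, function(s) rbind(c(s, nul), c(nul, s))),
    UNILATERAL = c(
      lapply(actions, function(s) rbind(c(s, nul))),
      lapply(actions, function(s) rbind(c(nul, s)))
    )
  )
  unname(lapply(forms, relationship))
}
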