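# Social actions and bundles.
#
# An action is represented by its canonical label. A bundle of atomic
# actions is itself a first-class action whose label is deterministically
# derived from the sorted atom labels, so two bundles are equal iff their
# atom sets are equal. The null action (doing nothing) is a reserved
# symbol that is never a social action.

#' The null action
#'
#' The distinguished "do nothing" symbol. It is not a social action: it can
#' appear inside an elementary interaction but never in an event log, where
#' absence of events encodes it.
#'
#' @return A length-one character string (the empty-set symbol).
#' @export
null_action <- function() "\u2205"

#' Test for the null action
#'
#' @param x character vector of action labels.
#' @return Logical vector, `TRUE` where the label is the null action.
#' @export
is_null_action <- function(x) {
  x == null_action()
}

.bundle_sep <- "+"

#' Bundle atomic actions into a compound social action
#'
#' Several atomic actions performed together form a bundle, which is itself
#' a social action distinct from each of its atoms. The bundle label is
#' derived from the sorted atom labels, so bundling is idempotent and
#' insensitive to the order of the atoms.
#'
#' @param atoms character vector (treated as a set) of atomic action labels.
#' @return A single character label: the atom itself for a singleton set,
#'   otherwise the sorted atoms joined by `"+"`.
#' @examples
#' make_bundle(c("S1", "S2"))        # "S1+S2"
#' make_bundle(c("S2", "S1"))        # identical
#' make_bundle("S1")                 # a singleton bundle is the action
#' @export
make_bundle <- function(atoms) {
  atoms <- unique(as.character(atoms))
  if (length(atoms) == 0L || any(is.na(atoms)) || any(!nzchar(atoms))) {
    stop("`atoms` must be a non-empty set of non-empty action labels")
  }
  if (any(is_null_action(atoms))) {
    stop("the null action cannot be part of a bundle")
  }
  # atoms may themselves be bundles; flatten so the canonical form is unique
  atoms <- unique(unlist(strsplit(atoms, .bundle_sep, fixed = TRUE)))
  paste(sort(atoms), collapse = .bundle_sep)
}

#' Atoms of a social action
#'
#' @param action a single action label (possibly a bundle).
#' @return Character vector of the atomic labels making up the action.
#' @export
action_atoms <- function(action) {
  stopifnot(length(action) == 1L, !is.na(action))
  if (is_null_action(action)) {
    stop("the null action has no atoms")
  }
  sort(unique(strsplit(action, .bundle_sep, fixed = TRUE)[[1L]]))
}

# validate a set of (non-null) social action labels; returns them unchanged
.check_actions <- function(actions) {
  actions <- as.character(actions)
  if (anyNA(actions) || any(!nzchar(actions))) {
    stop("action labels must be non-missing, non-empty strings")
  }
  if (any(is_null_action(actions))) {
    stop("the null action is not a social action")
  }
  if (anyDuplicated(actions)) {
    stop("action ids must be distinct")
  }
  actions
}
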