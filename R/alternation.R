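# Alternation statistic and its permutation null.
#
# Alternation is the discriminator between the reciprocating categories
# (EM, MP, AR) and non-alternated bilateral flux (CS): in an alternated
# exchange each flux of one type is followed by a flux of the paired type.

#' Alternation score of a two-valued sequence
#'
#' The fraction of adjacent pairs whose labels differ: 1 for strict
#' alternation, 0 when the sequence never switches.
#'
#' @param seq vector of labels (any atomic type); at least two elements.
#' @return A real in \[0, 1\].
#' @examples
#' alternation_score(c("a", "b", "a", "b"))       # 1
#' alternation_score(rep(c("a", "b"), each = 3))  # 0.2
#' @export
alternation_score <- function(seq) {
  L <- length(seq)
  if (L < 2L) stop("insufficient data: alternation needs at least 2 events")
  mean(seq[-1L] != seq[-L])
}

#' Permutation p-value for the alternation score
#'
#' One-sided p-value of the observed alternation score under the null of
#' random ordering: all arrangements of the sequence preserving the count
#' of each label are equally likely. When the number of distinct
#' arrangements `choose(L, m)` is at most `exact_limit`, the null is
#' enumerated exactly; otherwise a seeded Monte-Carlo sample of
#' `n_permutations` shuffles is used with the add-one estimator
#' `(1 + #\{score_perm >= score_obs\}) / (n_permutations + 1)`, so p > 0.
#'
#' @param seq vector with exactly two distinct labels (a single label gives
#'   the degenerate null: p = 1 with attribute `degenerate = TRUE`).
#' @param n_permutations Monte-Carlo sample size (default 2000).
#' @param seed optional integer seed for the Monte-Carlo branch; the
#'   caller's RNG state is left untouched.
#' @param exact_limit largest number of distinct arrangements enumerated
#'   exactly (default 10000).
#' @return p-value in (0, 1], with attributes `method` ("exact",
#'   "monte-carlo" or "degenerate") and `degenerate` (logical).
#' @examples
#' alternation_pvalue(c("a", "b", "a", "b"))  # exact: 2/6
#' @export
alternation_pvalue <- function(seq, n_permutations = 2000L, seed = NULL,
                               exact_limit = 10000L) {
  L <- length(seq)
  if (L < 2L) stop("insufficient data: alternation needs at least 2 events")
  labs <- unique(seq)
  if (length(labs) > 2L) stop("alternation is defined for two-valued sequences")
  if (length(labs) == 1L) {
    return(structure(1, method = "degenerate", degenerate = TRUE))
  }
  v <- seq == labs[1L]
  m <- sum(v)
  obs <- alternation_score(v)
  eps <- 1e-12
  if (choose(L, m) <= exact_limit) {
    # exact enumeration: place the m positions of the first label
    pos <- utils::combn(L, m)
    null_scores <- apply(pos, 2L, function(idx) {
      w <- rep(FALSE, L)
      w[idx] <- TRUE
      sum(w[-1L] != w[-L])
    }) / (L - 1)
    p <- mean(null_scores >= obs - eps)
    return(structure(p, method = "exact", degenerate = FALSE))
  }
  null_scores <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      w <- sample(v)
      sum(w[-1L] != w[-L])
    }, numeric(1))
  }) / (L - 1)
  p <- (1 + sum(null_scores >= obs - eps)) / (n_permutations + 1)
  structure(p, method = "monte-carlo", degenerate = FALSE)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards; NULL seed uses the current state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
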