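# Shared fixtures and independent oracles.

# build a dyad stream from parallel source/action vectors; targets are the
# other agent, times equally spaced from 1
manual_stream <- function(source, action, agents = c("A", "B"),
                          time = seq_along(source)) {
  target <- ifelse(source == agents[1L], agents[2L], agents[1L])
  event_stream(time, source, target, action)
}

# closed-form null distribution of the number of adjacent unequal pairs
# (runs - 1) in a random arrangement of m ones and n zeros; independent of
# the package's enumeration / Monte-Carlo code path
runs_switch_null <- function(m, n) {
  tot <- choose(m + n, m)
  ks <- 1:(m + n - 1)
  pr <- vapply(ks, function(kk) {
    r <- kk + 1L
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(m - 1, k - 1) * choose(n - 1, k - 1) / tot
    } else {
      k <- (r - 1) / 2
      (choose(m - 1, k - 1) * choose(n - 1, k) +
         choose(m - 1, k) * choose(n - 1, k - 1)) / tot
    }
  }, numeric(1))
  data.frame(k = ks, prob = pr)
}

# exact one-sided p-value for an observed switch count, from the oracle
runs_pvalue <- function(k_obs, m, n) {
  d <- runs_switch_null(m, n)
  sum(d$prob[d$k >= k_obs])
}

# canonical instance keys of a classification, e.g. "EM|X|"
inst_keys <- function(cl) detected_keys(cl)

# the six canonical generator arguments, one per category
category_grid <- function() {
  list(
    EM = list(category = "EM", actions = "X"),
    "NULL" = list(category = "NULL", actions = character()),
    MP = list(category = "MP", actions = c("X", "Y")),
    AR = list(category = "AR", actions = c("X", "Y")),
    CS = list(category = "CS", actions = "X"),
    UNILATERAL = list(category = "UNILATERAL", actions = "X")
  )
}

# expected canonical key prefix for each generated category
expected_key <- function(args, agents = c("A", "B")) {
  switch(args$category,
    EM = sprintf("EM|%s|", args$actions),
    "NULL" = "NULL||",
    MP = sprintf("MP|%s|", paste(sort(args$actions), collapse = ",")),
    AR = sprintf("AR|%s|", paste(args$actions, collapse = ",")),
    CS = sprintf("CS|%s|", args$actions),
    UNILATERAL = sprintf("UNILATERAL|%s|%s", args$actions, agents[1L])
  )
}
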