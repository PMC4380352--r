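# Formal model: actions, interactions, relationship space, decomposition.

test_that("bundles are canonical, order-insensitive and distinct from atoms", {
  expect_identical(make_bundle(c("S1", "S2")), "S1+S2")
  expect_identical(make_bundle(c("S2", "S1")), make_bundle(c("S1", "S2")))
  expect_identical(make_bundle("S1"), "S1")
  expect_identical(make_bundle(c("S1", "S1")), "S1")
  # a bundle is itself bundleable and flattens to the same canonical form
  expect_identical(make_bundle(c(make_bundle(c("S1", "S2")), "S3")),
                   make_bundle(c("S3", "S2", "S1")))
  expect_false(make_bundle(c("S1", "S2")) %in% c("S1", "S2"))
  expect_setequal(action_atoms("S1+S2"), c("S1", "S2"))
  expect_error(make_bundle(character()), "non-empty")
  expect_error(make_bundle(null_action()), "null action")
})

test_that("elementary interactions are the full (N+1)^2 cross product", {
  for (n in 0:5) {
    actions <- if (n) paste0("S", 1:n) else character()
    ei <- enumerate_elementary_interactions(actions)
    # brute-force oracle: nested loops over per-agent choices
    choices <- c(actions, null_action())
    oracle <- character()
    for (a in choices) for (b in choices) {
      oracle <- c(oracle, paste(a, b, sep = "::"))
    }
    got <- paste(ei[, "a_to_b"], ei[, "b_to_a"], sep = "::")
    expect_setequal(got, oracle)
    expect_identical(nrow(ei), (n + 1L) * (n + 1L))
    expect_identical(sum(is_null_action(ei[, 1L]) & is_null_action(ei[, 2L])), 1L)
  }
  expect_error(enumerate_elementary_interactions(c("X", "X")), "distinct")
})

test_that("relationship counting matches enumeration and identifies the null", {
  expect_identical(count_relationships(c("X", "Y")), 256)
  expect_identical(count_relationships(1), 8)
  expect_identical(count_relationships(0), 1)
  for (n in 0:3) {
    expect_identical(length(enumerate_relationships(n)), as.integer(count_relationships(n)))
  }
  rels <- enumerate_relationships(c("X", "Y"))
  sizes <- vapply(rels, nrow, integer(1))
  expect_identical(sizes[1L], 0L)              # null relationship first
  expect_identical(sum(sizes <= 1L), 9L)       # 8 simple + the null
  expect_identical(max(sizes), 8L)             # largest composite
  keys <- vapply(rels, function(r) paste(r, collapse = "|"), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # the singleton {null interaction} is the null relationship
  nul <- null_action()
  expect_identical(nrow(relationship(rbind(c(nul, nul)))), 0L)
  expect_error(relationship(rbind(c("X", "X"), c(nul, nul))), "cannot coexist")
  expect_error(enumerate_relationships(4, cap = 20), "cap")
})

test_that("representative form counts follow the category formulas", {
  for (n in 2:4) {
    actions <- paste0("S", 1:n)
    counts <- vapply(category_labels(), function(cl) {
      length(representative_forms(cl, actions))
    }, integer(1))
    expect_identical(
      unname(counts),
      as.integer(c(n, 1L, choose(n, 2L), n * (n - 1L), n, 2L * n))
    )
  }
  # N = 2 -> 3 increments: AR +4, MP +2, EM/CS +1, UNILATERAL +2
  inc <- function(cl) {
    length(representative_forms(cl, 3)) - length(representative_forms(cl, 2))
  }
  expect_identical(inc("AR"), 4L)
  expect_identical(inc("MP"), 2L)
  expect_identical(inc("EM"), 1L)
  expect_identical(inc("CS"), 1L)
  expect_identical(inc("UNILATERAL"), 2L)
  # EM forms at N=2 are the two same-action interactions
  em <- representative_forms("EM", c("X", "Y"))
  expect_setequal(vapply(em, function(r) paste(r, collapse = ","), character(1)),
                  c("X,X", "Y,Y"))
  expect_error(representative_forms("MP", "X"), "at least 2")
  expect_error(representative_forms("EM", character()), "at least 1")
  expect_length(representative_forms("NULL", 0), 1L)
})

test_that("category forms cover every elementary interaction", {
  for (n in 2:4) {
    actions <- paste0("S", 1:n)
    ei <- enumerate_elementary_interactions(actions)
    all_keys <- paste(ei[, 1L], ei[, 2L], sep = "::")
    component_counts <- integer()
    covered <- character()
    for (cl in category_labels()) {
      forms <- representative_forms(cl, actions)
      keys <- unlist(lapply(forms, function(r) {
        if (nrow(r) == 0L) {
          paste(null_action(), null_action(), sep = "::")  # NULL stands for the null interaction
        } else {
          paste(r[, 1L], r[, 2L], sep = "::")
        }
      }))
      # within one category no interaction appears in two forms
      expect_false(anyDuplicated(keys) > 0, label = sprintf("%s N=%d", cl, n))
      component_counts[cl] <- length(keys)
      covered <- union(covered, keys)
    }
    # joint coverage of the full (N+1)^2 set
    expect_setequal(covered, all_keys)
    # component count formula N + 1 + 2C(N,2) + N(N-1) + 2N + 2N
    expect_identical(sum(component_counts),
                     as.integer(n + 1 + 2 * choose(n, 2) + n * (n - 1) + 4 * n))
    # MP/AR share the different-action interactions; CS/UNILATERAL the
    # one-null ones; the four flux-characteristics classes are disjoint
    chr <- list(
      identical = all_keys[ei[, 1L] == ei[, 2L] & !is_null_action(ei[, 1L])],
      null = paste(null_action(), null_action(), sep = "::"),
      different = all_keys[ei[, 1L] != ei[, 2L] &
                             !is_null_action(ei[, 1L]) & !is_null_action(ei[, 2L])],
      one_null = all_keys[xor(is_null_action(ei[, 1L]), is_null_action(ei[, 2L]))]
    )
    expect_identical(sum(lengths(chr)), (n + 1L) * (n + 1L))
  }
})

test_that("worked composite relationships decompose to the printed categories", {
  nul <- null_action()
  keyset <- function(rel) {
    sort(vapply(decompose_relationship(rel), relflux:::.instance_key, character(1)))
  }
  expect_identical(keyset(relationship(rbind(c("X", "X"), c("Y", "Y")))),
                   c("EM|X|", "EM|Y|"))
  expect_identical(keyset(relationship(rbind(c("X", "X"), c("Y", nul), c(nul, "Y")))),
                   c("CS|Y|", "EM|X|"))
  expect_identical(keyset(relationship(rbind(c("X", "X"), c("X", "Y"), c("Y", "X")))),
                   c("EM|X|", "MP|X,Y|"))
  gold <- relationship(rbind(c("S1", nul), c(nul, "S1"), c("S2", "S3"),
                             c("S4", "S4"), c("S5", "S6"), c("S6", "S5")))
  expect_identical(keyset(gold),
                   c("AR|S2,S3|", "CS|S1|", "EM|S4|", "MP|S5,S6|"))
  expect_identical(keyset(relationship(NULL)), "NULL||")
})

test_that("decomposition is total and conservative on the full N=2 space", {
  rels <- enumerate_relationships(c("X", "Y"))
  for (rel in rels) {
    inst <- decompose_relationship(rel)
    expect_gt(length(inst), 0L)
    back <- recompose_instances(inst)
    expect_identical(unclass(back)[, , drop = FALSE], unclass(rel)[, , drop = FALSE])
    # every interaction covered exactly once: sizes add up
    sizes <- vapply(inst, function(x) {
      switch(x$category, "NULL" = 0L, MP = 2L, CS = 2L, 1L)
    }, integer(1))
    expect_identical(sum(sizes), nrow(rel))
  }
})

test_that("decomposition is invariant under relabeling and flips under agent swap", {
  set.seed(11)
  actions <- c("X", "Y", "Z")
  ei <- enumerate_elementary_interactions(actions)
  ei <- ei[!(is_null_action(ei[, 1L]) & is_null_action(ei[, 2L])), ]
  for (rep in 1:25) {
    rel <- relationship(ei[sample(nrow(ei), sample(0:6, 1)), , drop = FALSE])
    inst <- decompose_relationship(rel)
    cats <- sort(vapply(inst, `[[`, character(1), "category"))
    # relabel actions by a random permutation
    perm <- setNames(sample(actions), actions)
    perm[null_action()] <- null_action()
    rel2 <- relationship(cbind(perm[rel[, 1L]], perm[rel[, 2L]]))
    inst2 <- decompose_relationship(rel2)
    expect_identical(sort(vapply(inst2, `[[`, character(1), "category")), cats)
    # swap agents: (a_to_b, b_to_a) -> (b_to_a, a_to_b)
    rel3 <- relationship(unclass(rel)[, c(2L, 1L), drop = FALSE])
    inst3 <- decompose_relationship(rel3)
    expect_identical(sort(vapply(inst3, `[[`, character(1), "category")), cats)
    sym <- function(x) sort(vapply(x, relflux:::.instance_key, character(1)))
    flip <- function(x) {
      if (x$category == "AR") {
        category_instance("AR", rev(x$actions), agents = x$agents)
      } else if (x$category == "UNILATERAL") {
        category_instance("UNILATERAL", x$actions,
                          actor = setdiff(x$agents, x$actor), agents = x$agents)
      } else x
    }
    expect_identical(sym(inst3), sym(lapply(inst, flip)))
  }
})
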