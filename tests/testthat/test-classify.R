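# Category detection in dyad streams.

cfg <- classifier_config()

test_that("the six canonical flux patterns are detected", {
  # EM: alternated same-action flux in both directions
  em <- manual_stream(rep(c("A", "B"), 5), "X")
  expect_identical(inst_keys(classify_dyad(em, cfg)), "EM|X|")
  # NULL: no fluxes
  expect_identical(inst_keys(classify_dyad(event_stream(), cfg)), "NULL||")
  # MP: two separate alternations covering both orderings (blocked so the
  # per-action direction sequences do not alternate)
  src <- c(rep(c("A", "B"), 4), rep(c("B", "A"), 4), rep(c("A", "B"), 4), rep(c("B", "A"), 4))
  act <- c(rep(c("X", "Y"), 4), rep(c("X", "Y"), 4), rep(c("X", "Y"), 4), rep(c("X", "Y"), 4))
  mp <- manual_stream(src, act)
  expect_identical(inst_keys(classify_dyad(mp, cfg)), "MP|X,Y|")
  # AR: one alternation of two different actions, fixed roles
  ar <- manual_stream(rep(c("A", "B"), 5), rep(c("X", "Y"), 5))
  expect_identical(inst_keys(classify_dyad(ar, cfg)), "AR|X,Y|")
  # CS: bilateral but not alternated (7 vs 3, clumped order)
  cs <- manual_stream(c("A", "A", "A", "B", "A", "A", "B", "B", "A", "A"), "X")
  expect_identical(inst_keys(classify_dyad(cs, cfg)), "CS|X|")
  # UNILATERAL: one direction only
  uni <- manual_stream(rep("A", 6), "X")
  expect_identical(inst_keys(classify_dyad(uni, cfg)), "UNILATERAL|X|A")
})

test_that("MP prevails over CS and AR on MP streams", {
  st <- generate_dyad(generator_spec("MP", c("X", "Y"), n_rounds = 8, seed = 3))
  keys <- inst_keys(classify_dyad(st, cfg))
  expect_identical(keys, "MP|X,Y|")
  expect_false(any(grepl("^CS", keys)))
})

test_that("alternation is required: shuffled EM-like flux falls to CS", {
  set.seed(4)
  src <- sample(c(rep("A", 7), rep("B", 3)))
  # re-shuffle until clearly non-alternating (score below threshold)
  while (alternation_score(src) >= 0.8) src <- sample(src)
  st <- manual_stream(src, "X")
  expect_identical(inst_keys(classify_dyad(st, cfg)), "CS|X|")
})

test_that("short exchanges fall through with a low-evidence flag", {
  st <- manual_stream(c("A", "B"), "X")
  cl <- classify_dyad(st, cfg)
  expect_identical(inst_keys(cl), "CS|X|")
  expect_true(cl$detections[[1L]]$low_evidence)
  uni <- classify_dyad(manual_stream(c("A", "A"), "X"), cfg)
  expect_true(uni$detections[[1L]]$low_evidence)
})

test_that("streams with more than two agents are rejected", {
  st <- event_stream(1:2, c("A", "B"), c("B", "C"), "X")
  expect_error(classify_dyad(st, cfg), "agents")
})

test_that("every event is attributed to exactly one detection", {
  set.seed(9)
  for (rep in 1:20) {
    n_comp <- sample(1:3, 1)
    acts <- sample(paste0("S", 1:6))
    specs <- list()
    used <- 0
    for (i in seq_len(n_comp)) {
      cat_i <- sample(c("EM", "MP", "AR", "CS", "UNILATERAL"), 1)
      need <- if (cat_i %in% c("MP", "AR")) 2L else 1L
      specs[[i]] <- generator_spec(cat_i, acts[(used + 1):(used + need)],
                                   n_rounds = sample(4:8, 1),
                                   seed = rep * 10 + i)
      used <- used + need
    }
    st <- generate_composite(specs, seed = rep)
    cl <- classify_dyad(st, cfg)
    expect_identical(sum(vapply(cl$detections, `[[`, integer(1), "n_events")),
                     nrow(st))
    expect_identical(sort(unlist(lapply(cl$detections, `[[`, "events"))),
                     seq_len(nrow(st)))
  }
})

test_that("detections are invariant under action relabeling and agent swap", {
  st <- generate_composite(list(
    generator_spec("EM", "X", n_rounds = 6, seed = 1),
    generator_spec("AR", c("Y", "Z"), n_rounds = 6, seed = 2)
  ), seed = 3)
  base <- classify_dyad(st, cfg)
  base_cats <- sort(vapply(base$detections, function(d) d$instance$category,
                           character(1)))
  # permute action labels
  perm <- c(X = "Z", Y = "X", Z = "Y")
  st2 <- st
  st2$action <- unname(perm[st2$action])
  cl2 <- classify_dyad(st2, cfg)
  expect_identical(sort(vapply(cl2$detections, function(d) d$instance$category,
                               character(1))), base_cats)
  mapped <- sort(vapply(base$detections, function(d) {
    paste(d$instance$category, paste(sort(unname(perm[d$instance$actions])),
                                     collapse = ","))
  }, character(1)))
  got <- sort(vapply(cl2$detections, function(d) {
    paste(d$instance$category, paste(sort(d$instance$actions), collapse = ","))
  }, character(1)))
  expect_identical(got, mapped)
  # swap the two agents: categories persist, AR roles flip
  st3 <- st
  st3$source <- chartr("AB", "BA", st$source)
  st3$target <- chartr("AB", "BA", st$target)
  cl3 <- classify_dyad(st3, cfg)
  expect_identical(sort(vapply(cl3$detections, function(d) d$instance$category,
                               character(1))), base_cats)
  ar_base <- Filter(function(d) d$instance$category == "AR", base$detections)[[1L]]
  ar_sw <- Filter(function(d) d$instance$category == "AR", cl3$detections)[[1L]]
  expect_identical(ar_sw$instance$actions, rev(ar_base$instance$actions))
})

test_that("simultaneous same-direction events are bundled into one flux", {
  # at t=1 agent A performs S1 and S2 together; at t=2 B does the same
  st <- event_stream(c(1, 1, 2, 2), c("A", "A", "B", "B"),
                     c("B", "B", "A", "A"), c("S1", "S2", "S1", "S2"))
  cl <- classify_dyad(st, cfg)
  expect_identical(cl$n_events, 2L)
  acts <- unlist(lapply(cl$detections, function(d) d$instance$actions))
  expect_identical(unique(acts), make_bundle(c("S1", "S2")))
})

test_that("windowed classification tracks relationship change over time", {
  # EM(X) on times 0..9, unilateral A->Y on times 10..19
  em <- manual_stream(rep(c("A", "B"), 5), "X", time = 0:9)
  uni <- manual_stream(rep("A", 10), "Y", time = 10:19)
  st <- validate_event_stream(rbind(em, uni))
  wins <- classify_windows(st, window_length = 10, step = 10, config = cfg)
  expect_length(wins, 2L)
  expect_identical(inst_keys(wins[[1L]]$classification), "EM|X|")
  expect_identical(inst_keys(wins[[2L]]$classification), "UNILATERAL|Y|A")
  # tiling: consecutive half-open windows, ordered by start
  starts <- vapply(wins, `[[`, numeric(1), "start")
  ends <- vapply(wins, `[[`, numeric(1), "end")
  expect_identical(starts[-1L], ends[-length(ends)])
  # stationary EM stream: every window with enough events is EM
  em_long <- manual_stream(rep(c("A", "B"), 20), "X", time = 0:39)
  wins2 <- classify_windows(em_long, window_length = 10, step = 10, config = cfg)
  for (w in wins2) {
    expect_identical(inst_keys(w$classification), "EM|X|")
  }
  # empty stream: one NULL-classified window anchored at 0
  wins3 <- classify_windows(event_stream(), 5, config = cfg)
  expect_length(wins3, 1L)
  expect_identical(wins3[[1L]]$start, 0)
  expect_identical(inst_keys(wins3[[1L]]$classification), "NULL||")
})
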