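test_that("chance-other keeps the person's turns and fills other slots from donors", {
  x <- toy_corpus()
  ch <- make_chance_other(x, "p1", seed = 5)
  real <- x$dialogues[[1]]
  expect_length(ch$turns, length(real$turns))
  own <- which(vapply(real$turns, function(t) t$speaker == "p1", logical(1)))
  for (i in own) {
    expect_identical(ch$turns[[i]]$text, real$turns[[i]]$text)
    expect_identical(ch$turns[[i]]$speaker, "p1")
  }
  donors_text <- unlist(lapply(x$dialogues[[2]]$turns, function(t) t$text))
  for (i in setdiff(seq_along(real$turns), own)) {
    expect_true(ch$turns[[i]]$text %in% donors_text)
  }
  plan <- attr(ch, "plan")
  expect_identical(nrow(plan), length(real$turns) - length(own))
  expect_true(all(plan$source_dialogue == "d2"))
})

test_that("chance-other is deterministic in the seed and needs a donor pool", {
  x <- toy_corpus()
  a <- make_chance_other(x, "p2", seed = 99)
  b <- make_chance_other(x, "p2", seed = 99)
  expect_true(corpus_equal_public(corpus(list(a)), corpus(list(b))))
  solo <- corpus(list(x$dialogues[[1]]))
  expect_error(make_chance_other(solo, "p1", seed = 1), "at least 2 dialogues")
  expect_error(make_chance_other(x, "nobody", seed = 1), "not found")
})

test_that("donor slots are drawn uniformly from the donor pool", {
  # 2-turn target dialogue (1 other slot) against a 8-turn donor dialogue
  d1 <- dialogue("t", list(turn("a", "mine"), turn("b", "theirs")))
  d2 <- dialogue("u", lapply(1:8, function(i) turn("u1", paste("donor", i))))
  x <- corpus(list(d1, d2))
  picks <- vapply(1:4000, function(s) {
    make_chance_other(x, "a", seed = s)$turns[[2]]$text
  }, character(1))
  tab <- table(picks)
  expect_identical(length(tab), 8L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("chance-self pairings are derangements, uniform for n = 3", {
  d <- dialogue("s", lapply(1:6, function(i) {
    turn(if (i %% 2 == 1) "A" else "B", paste("text", i))
  }))
  # n = 3 own turns for A: only two derangements (231, 312), both seen,
  # never the identity on any element
  seen <- character(0)
  for (s in 1:60) {
    plan <- make_chance_self(d, "A", seed = s)
    expect_false(any(plan$source_position == plan$position))
    expect_setequal(plan$source_position, 1:3)
    seen <- c(seen, paste(plan$source_position, collapse = ""))
  }
  expect_setequal(unique(seen), c("231", "312"))
  # n = 2: the unique swap
  d2 <- dialogue("s2", list(turn("A", "a1"), turn("B", "b1"),
                            turn("A", "a2"), turn("B", "b2"), turn("A", "a3")))
  plan2 <- make_chance_self(d2, "B", seed = 1)
  expect_identical(plan2$source_position, c(2L, 1L))
  # determinism
  expect_identical(make_chance_self(d, "A", seed = 7),
                   make_chance_self(d, "A", seed = 7))
})

test_that("a person with fewer than two turns is skipped with a warning", {
  d <- dialogue("one", list(turn("A", "only"), turn("B", "x"), turn("B", "y")))
  expect_warning(plan <- make_chance_self(d, "A", seed = 1), "fewer than 2")
  expect_null(plan)
})

test_that("chance record builders preserve each person's own turn multiset", {
  x <- toy_corpus()
  rec <- chance_other_records(x, seed = 3)
  expect_true(all(rec$relation == "other"))
  expect_true(all(rec$condition == "chance_other"))
  # every target turn is one of the person's real turns
  real_rec <- corpus_similarities(x)
  for (p in c("p1", "p2", "q1", "q2")) {
    expect_setequal(unique(rec$target_index[rec$person == p]),
                    unique(real_rec$target_index[real_rec$person == p]))
  }
  recs <- chance_self_records(x, seed = 3)
  expect_true(all(recs$relation == "self"))
  # with k = 2 own turns, only distance 1 for the later turn is populated
  p1 <- recs[recs$person == "p1", ]
  expect_identical(sum(!is.na(p1$lexical)), 1L)
})

test_that("chance-self distance-d contexts follow the deranged own stream", {
  d <- dialogue("cs", lapply(1:8, function(i) {
    turn(if (i %% 2 == 1) "A" else "B", paste("w", i))
  }))
  x <- corpus(list(d, dialogue("dummy", list(turn("z", "pad"), turn("z2", "pad2")))))
  rec <- chance_self_records(x, seed = 21)
  a <- rec[rec$person == "A" & !is.na(rec$context_index), ]
  own <- c(0L, 2L, 4L, 6L)
  plan <- make_chance_self(d, "A", seed = turnsim:::derive_seed(21, 1001))
  for (r in seq_len(nrow(a))) {
    i <- match(a$target_index[r], own)
    expect_identical(a$context_index[r],
                     own[plan$source_position[i - a$distance[r]]])
  }
})
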