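test_that("lexical similarity matches hand-counted word-pair matching", {
  # min-count matching with Dice normalisation: 2*1 / (3+2)
  expect_equal(lexical_similarity(turn("A", "a b b"), turn("B", "b c")), 0.4)
  # verbatim repeat scores exactly 1
  t <- turn("A", "it does very handy")
  expect_identical(lexical_similarity(t, t), 1)
  # no shared words scores exactly 0
  expect_identical(
    lexical_similarity(turn("B", "yeah really"),
                       turn("A", "I feel very sorry for the person talking to her")),
    0)
  expect_identical(
    lexical_similarity(turn("Y", "mm"),
                       turn("A", "ed oh god she's still talking isn't she laura never gets off the phone")),
    0)
  # case-insensitive through the norm
  expect_identical(lexical_similarity(turn("A", "Laura's AMAZING"),
                                      turn("B", "laura's amazing")), 1)
  # both turns empty of words: missing, not 0
  expect_true(is.na(lexical_similarity(turn("A", ""), turn("B", ""))))
  expect_identical(lexical_similarity(turn("A", ""), turn("B", "hi")), 0)
})

test_that("syntactic similarity hits the 0/1 boundary conditions", {
  fa <- list(parse_tree("(S (NP (PRP it)) (VP (VBZ does)))"))
  ta <- turn("A", "it does", forest = fa)
  expect_identical(syntactic_similarity(ta, ta), 1)
  # disjoint category alphabets share nothing
  tb <- turn("B", "x", forest = list(parse_tree("(Q (R (W x)))")))
  expect_identical(syntactic_similarity(ta, tb), 0)
  # empty forest yields missing, not 0
  expect_true(is.na(syntactic_similarity(ta, turn("B", "words no trees"))))
})

test_that("a single shared NP subtree scores what the brute-force oracle says", {
  fa <- list(parse_tree("(S (NP (DT the) (NN dog)) (VP (VBD sat)))"))
  fb <- list(parse_tree("(FRAG (NP (DT a) (NN cat)))"))
  # shared keys: (NP DT NN), DT, NN -> overlap 3; totals 6 and 4
  expect_equal(syntactic_similarity(turn("A", "the dog sat", forest = fa),
                                    turn("B", "a cat", forest = fb)),
               oracle_syntactic_similarity(fa, fb))
  expect_equal(oracle_syntactic_similarity(fa, fb), 2 * 3 / (6 + 4))
})

test_that("syntactic similarity agrees with the exhaustive oracle on random pairs", {
  set.seed(101)
  for (i in 1:100) {
    fa <- random_forest(); fb <- random_forest()
    ta <- turn("A", "x", forest = fa); tb <- turn("B", "y", forest = fb)
    expect_equal(syntactic_similarity(ta, tb),
                 oracle_syntactic_similarity(fa, fb))
    expect_equal(syntactic_similarity(ta, tb, include_preterminals = FALSE),
                 oracle_syntactic_similarity(fa, fb, include_preterminals = FALSE))
  }
})

test_that("both measures are symmetric and bounded on random inputs", {
  set.seed(202)
  words <- c("a", "b", "c", "d", "e")
  for (i in 1:40) {
    ta <- turn("A", paste(sample(words, sample(1:6, 1), replace = TRUE), collapse = " "),
               forest = random_forest())
    tb <- turn("B", paste(sample(words, sample(1:6, 1), replace = TRUE), collapse = " "),
               forest = random_forest())
    l1 <- lexical_similarity(ta, tb); l2 <- lexical_similarity(tb, ta)
    s1 <- syntactic_similarity(ta, tb); s2 <- syntactic_similarity(tb, ta)
    expect_equal(l1, l2)
    expect_equal(s1, s2)
    expect_true(l1 >= 0 && l1 <= 1)
    expect_true(s1 >= 0 && s1 <= 1)
  }
})

test_that("adding a shared structure to both turns never lowers similarity", {
  set.seed(303)
  extra <- parse_tree("(UH yeah)")  # one non-terminal, one shared key
  for (i in 1:25) {
    fa <- random_forest(); fb <- random_forest()
    ta <- turn("A", "x", forest = fa); tb <- turn("B", "y", forest = fb)
    before <- syntactic_similarity(ta, tb)
    ta2 <- turn("A", "x yeah", forest = c(fa, list(extra)))
    tb2 <- turn("B", "y yeah", forest = c(fb, list(extra)))
    expect_gte(syntactic_similarity(ta2, tb2), before)
  }
})

test_that("similarity is exactly 1 iff the bags coincide, 0 iff disjoint", {
  set.seed(404)
  for (i in 1:25) {
    fa <- random_forest(); fb <- random_forest()
    ta <- turn("A", "x", forest = fa); tb <- turn("B", "y", forest = fb)
    s <- syntactic_similarity(ta, tb)
    ba <- enumerate_subtrees(fa); bb <- enumerate_subtrees(fb)
    same_bags <- isTRUE(all.equal(ba$counts[sort(names(ba$counts))],
                                  bb$counts[sort(names(bb$counts))]))
    disjoint <- length(intersect(names(ba$counts), names(bb$counts))) == 0L
    expect_identical(s == 1, same_bags)
    expect_identical(s == 0, disjoint)
  }
})
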