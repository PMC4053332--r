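#' Worked-example dialogue fixtures
#'
#' `fixture_table2()` returns the ten-turn two-party conversation excerpt
#' (DCPSE conversation DI-B33-1) used as the package's worked example, with
#' speakers A and B alternating. `fixture_table2_chance()` returns the
#' corresponding randomised Chance-Other sequence: A's turns in place, B's
#' slots replaced by turns from five other conversations (speakers V, W,
#' X, Y, Z).
#'
#' The attached parse forests are *synthetic toy parses* written for this
#' package so that the syntactic path can be exercised on the fixture;
#' they are not the source corpus annotations. Lexical values computed on
#' these turns depend only on the transcribed words.
#'
#' @return a dialogue object.
#' @export
fixture_table2 <- function() {
  tt <- function(speaker, text, trees = character(0)) {
    turn(speaker, text, forest = lapply(trees, parse_tree))
  }
  dialogue("DI-B33-1", list(
    tt("A", "ed oh god she's still talking isn't she laura never gets off the phone",
       "(S (NP (NNP laura)) (VP (ADVP (RB never)) (VBZ gets) (PP (IN off) (NP (DT the) (NN phone)))))"),
    tt("B", "she doesn't Laura's amazing once on the phone really I've never heard",
       c("(S (NP (PRP she)) (VP (VBZ doesn't)))",
         "(S (NP (NNP Laura's)) (ADJP (JJ amazing)))",
         "(VP (ADVP (RB never)) (VBN heard))")),
    tt("A", "you know I had three people try to ring me and constantly engaged here apparently three people",
       c("(S (NP (PRP you)) (VP (VBP know)))",
         "(S (NP (PRP I)) (VP (VBD had) (NP (CD three) (NNS people))))")),
    tt("B", "really Laura's amazing when she gets on that phone she just does not get off",
       c("(S (NP (NNP Laura's)) (ADJP (JJ amazing)))",
         "(S (NP (PRP she)) (VP (VBZ gets) (PP (IN on) (NP (DT that) (NN phone)))))")),
    tt("A", "I know",
       "(S (NP (PRP I)) (VP (VBP know)))"),
    tt("B", "I've never heard anybody spend so much time on the phone and such useless drivel most of the time",
       "(S (NP (PRP I've)) (VP (ADVP (RB never)) (VBN heard) (NP (NN anybody))))"),
    tt("A", "I feel very sorry for the person talking to her",
       "(S (NP (PRP I)) (VP (VBP feel) (ADJP (RB very) (JJ sorry)) (PP (IN for) (NP (DT the) (NN person)))))"),
    tt("B", "yeah really",
       "(S (INTJ (UH yeah)) (ADVP (RB really)))"),
    tt("A", "it looks a good vehicle yeah",
       "(S (NP (PRP it)) (VP (VBZ looks) (NP (DT a) (JJ good) (NN vehicle))))"),
    tt("B", "it does very handy",
       "(S (NP (PRP it)) (VP (VBZ does) (ADVP (RB very) (JJ handy))))")))
}

#' @rdname fixture_table2
#' @export
fixture_table2_chance <- function() {
  real <- fixture_table2()
  tt <- function(speaker, text, trees = character(0)) {
    turn(speaker, text, forest = lapply(trees, parse_tree))
  }
  repl <- list(
    tt("V", "no but at home what do they speak",
       "(S (NP (PRP they)) (VP (VBP speak)))"),
    tt("W", "did they look at Forster's work as a whole",
       "(SQ (VBD did) (NP (PRP they)) (VP (VB look) (PP (IN at) (NP (NNP Forster's) (NN work)))))"),
    tt("X", "oh yeah I've got a big bag of uh recyclable sort of some time",
       "(S (INTJ (UH oh)) (NP (PRP I've)) (VP (VBN got) (NP (DT a) (JJ big) (NN bag))))"),
    tt("Y", "mm",
       "(INTJ (UH mm))"),
    tt("Z", "oh we must try it it was so good grilled",
       "(S (NP (PRP we)) (VP (MD must) (VP (VB try) (NP (PRP it)))))"))
  turns <- real$turns
  bslots <- seq(2, 10, by = 2)
  for (j in seq_along(bslots)) turns[[bslots[j]]] <- repl[[j]]
  dialogue("DI-B33-1-chance-other", turns)
}
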