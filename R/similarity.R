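#' Turn-pair similarity measures
#'
#' Two statistics quantify repetition between a pair of turns, each Dice
#' normalised to lie in `[0, 1]`: 0 for no match, 1 for a verbatim repeat.
#'
#' *Lexical similarity* counts matching word pairs: with word multisets
#' `A`, `B` over lowercase comparison forms, the number of matches is
#' `m = sum_w min(A(w), B(w))` (a maximal one-to-one matching between token
#' occurrences), normalised by the total number of words in the two turns
#' combined: `2 m / (|A| + |B|)`.
#'
#' *Syntactic similarity* counts complete subtrees shared between the two
#' turns' parse forests. Every non-terminal node roots one complete
#' subtree; subtrees are compared over category labels only (lexical
#' leaves dropped, see [enumerate_subtrees()]), so word repetition is not
#' double-counted inside the syntactic measure. With subtree multisets
#' `A`, `B`: `2 sum_k min(A(k), B(k)) / (A.total + B.total)`.
#'
#' @param a,b turn objects (see [turn()]).
#' @param include_preterminals count preterminal (part-of-speech) nodes as
#'   structures; default `TRUE`.
#' @return a single numeric in `[0, 1]`, or `NA` when undefined: lexical
#'   similarity is `NA` when both turns are empty of words; syntactic
#'   similarity is `NA` when either turn has an empty parse forest (absence
#'   of annotation is not absence of structure).
#' @examples
#' a <- turn("A", "yeah really")
#' b <- turn("B", "I feel very sorry for the person talking to her")
#' lexical_similarity(a, b)   # 0
#' lexical_similarity(a, a)   # 1
#' @export
lexical_similarity <- function(a, b) {
  na <- length(a$norms); nb <- length(b$norms)
  if (na + nb == 0L) return(NA_real_)
  m <- multiset_overlap(a$norms, b$norms)
  2 * m / (na + nb)
}

#' @rdname lexical_similarity
#' @export
syntactic_similarity <- function(a, b, include_preterminals = TRUE) {
  if (length(a$forest) == 0L || length(b$forest) == 0L) return(NA_real_)
  ba <- enumerate_subtrees(a$forest, include_preterminals)
  bb <- enumerate_subtrees(b$forest, include_preterminals)
  if (ba$total + bb$total == 0L) return(NA_real_)
  s <- bag_overlap(ba$counts, bb$counts)
  2 * s / (ba$total + bb$total)
}

# size of the multiset intersection of two character vectors
multiset_overlap <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0L)
  tx <- table(x); ty <- table(y)
  shared <- intersect(names(tx), names(ty))
  if (length(shared) == 0L) return(0L)
  sum(pmin(as.integer(tx[shared]), as.integer(ty[shared])))
}

# size of the intersection of two named count vectors
bag_overlap <- function(cx, cy) {
  shared <- intersect(names(cx), names(cy))
  if (length(shared) == 0L) return(0L)
  sum(pmin(cx[shared], cy[shared]))
}

# precomputed per-turn similarity profile, cached by the windowing code
turn_profile <- function(t, include_preterminals = TRUE) {
  wt <- if (length(t$norms)) table(t$norms) else NULL
  bag <- if (length(t$forest)) enumerate_subtrees(t$forest, include_preterminals) else NULL
  list(ntok = length(t$norms), wtab = wt, bag = bag)
}

profile_lexical <- function(pa, pb) {
  if (pa$ntok + pb$ntok == 0L) return(NA_real_)
  if (is.null(pa$wtab) || is.null(pb$wtab)) return(0)
  shared <- intersect(names(pa$wtab), names(pb$wtab))
  m <- if (length(shared)) sum(pmin(as.integer(pa$wtab[shared]),
                                    as.integer(pb$wtab[shared]))) else 0L
  2 * m / (pa$ntok + pb$ntok)
}

profile_syntactic <- function(pa, pb) {
  if (is.null(pa$bag) || is.null(pb$bag)) return(NA_real_)
  if (pa$bag$total + pb$bag$total == 0L) return(NA_real_)
  2 * bag_overlap(pa$bag$counts, pb$bag$counts) / (pa$bag$total + pb$bag$total)
}
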