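# Independent brute-force subtree machinery used as the oracle against
# enumerate_subtrees()/syntactic_similarity(). Deliberately written with a
# different algorithm: iterative stack traversal and its own serializer.

# serialize the category structure of the subtree rooted at `node`
oracle_serialize <- function(node) {
  if (!is.null(node$word)) return(NULL)            # lexical leaf: no subtree
  kids <- Filter(function(ch) is.null(ch$word), node$children)
  if (length(kids) == 0L) return(node$label)       # preterminal
  inner <- vapply(kids, oracle_serialize, character(1))
  sprintf("<%s|%s>", node$label, paste(inner, collapse = ","))
}

# every complete subtree of a forest, one string per non-leaf node,
# collected with an explicit stack
oracle_subtrees <- function(forest, include_preterminals = TRUE) {
  out <- character(0)
  stack <- forest
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!is.null(node$word)) next
    pre <- all(vapply(node$children, function(ch) !is.null(ch$word), logical(1)))
    if (include_preterminals || !pre) {
      out <- c(out, oracle_serialize(node))
    }
    for (ch in node$children) stack[[length(stack) + 1L]] <- ch
  }
  out
}

# multiset intersection size by explicit pairing-off
oracle_overlap <- function(xs, ys) {
  n <- 0L
  for (x in xs) {
    hit <- which(ys == x)
    if (length(hit) > 0L) {
      ys <- ys[-hit[1]]
      n <- n + 1L
    }
  }
  n
}

oracle_syntactic_similarity <- function(fa, fb, include_preterminals = TRUE) {
  sa <- oracle_subtrees(fa, include_preterminals)
  sb <- oracle_subtrees(fb, include_preterminals)
  if (length(fa) == 0L || length(fb) == 0L) return(NA_real_)
  2 * oracle_overlap(sa, sb) / (length(sa) + length(sb))
}

# random labelled tree with at most `max_nodes` non-leaf nodes
random_tree <- function(max_nodes = 12L,
                        cats = c("S", "NP", "VP", "PP", "X", "Y"),
                        words = letters[1:8]) {
  budget <- sample.int(max_nodes, 1L)
  grow <- function(depth) {
    budget <<- budget - 1L
    if (budget <= 0L || depth > 4L || stats::runif(1) < 0.35) {
      # preterminal over one word
      return(tree_node(sample(cats, 1L), list(tree_leaf(sample(words, 1L)))))
    }
    nk <- sample(1:3, 1L)
    kids <- vector("list", nk)
    for (i in seq_len(nk)) kids[[i]] <- grow(depth + 1L)
    tree_node(sample(cats, 1L), kids)
  }
  grow(1L)
}

random_forest <- function(max_trees = 2L, ...) {
  lapply(seq_len(sample.int(max_trees, 1L)), function(i) random_tree(...))
}

# tiny deterministic two-dialogue corpus for reader/randomization tests
toy_corpus <- function() {
  d1 <- dialogue("d1", list(
    turn("p1", "the cat sat", forest = list(parse_tree("(S (NP (DT the) (NN cat)) (VP (VBD sat)))"))),
    turn("p2", "a dog ran", forest = list(parse_tree("(S (NP (DT a) (NN dog)) (VP (VBD ran)))"))),
    turn("p1", "the dog sat"),
    turn("p2", "so it goes")))
  d2 <- dialogue("d2", list(
    turn("q1", "where is it", forest = list(parse_tree("(SQ (WRB where) (VBZ is) (NP (PRP it)))"))),
    turn("q2", "it is here"),
    turn("q1", "no idea"),
    turn("q2", "fine then")))
  corpus(list(d1, d2))
}

corpus_equal_public <- function(a, b) turnsim:::corpus_equal(a, b)
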