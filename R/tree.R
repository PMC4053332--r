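#' Parse trees in Penn-style bracketed notation
#'
#' A parse tree is represented as a nested list. Non-terminal nodes are
#' `list(label = <category>, children = <list of nodes>)`; leaves are
#' `list(word = <token>)`. Trees are constructed with [parse_tree()] and
#' serialised back with [deparse_tree()].
#'
#' @param text a single character string holding one bracketed tree, e.g.
#'   `"(S (NP (PRP it)) (VP (VBZ does)))"`.
#' @param where optional character used to locate parse errors in messages
#'   (e.g. `"file.txt:12"`).
#' @return `parse_tree()` returns a tree node (class `"turnsim_tree"`).
#' @examples
#' tr <- parse_tree("(S (NP (PRP it)) (VP (VBZ does)))")
#' deparse_tree(tr)
#' @export
parse_tree <- function(text, where = NULL) {
  toks <- tokenize_sexpr(text)
  if (length(toks) == 0L) {
    stop(tree_err("empty tree string", where))
  }
  st <- parse_node(toks, 1L, where)
  if (st$pos <= length(toks)) {
    stop(tree_err(sprintf("trailing content after tree: '%s'", toks[st$pos]), where))
  }
  st$node
}

tree_err <- function(msg, where) {
  if (is.null(where)) paste0("malformed bracketed tree: ", msg)
  else paste0("malformed bracketed tree at ", where, ": ", msg)
}

# split a bracketed expression into "(", ")" and atom tokens
tokenize_sexpr <- function(text) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", text))
  toks <- strsplit(trimws(spaced), "[ \t\r\n]+")[[1]]
  toks[nzchar(toks)]
}

parse_node <- function(toks, pos, where) {
  if (pos > length(toks)) stop(tree_err("unexpected end of input", where))
  tk <- toks[pos]
  if (tk == ")") stop(tree_err("unexpected ')'", where))
  if (tk != "(") {
    # bare atom: a lexical leaf
    return(list(node = tree_leaf(tk), pos = pos + 1L))
  }
  pos <- pos + 1L
  if (pos > length(toks) || toks[pos] %in% c("(", ")")) {
    stop(tree_err("expected a category label after '('", where))
  }
  label <- toks[pos]
  pos <- pos + 1L
  children <- list()
  repeat {
    if (pos > length(toks)) stop(tree_err("missing ')'", where))
    if (toks[pos] == ")") {
      pos <- pos + 1L
      break
    }
    st <- parse_node(toks, pos, where)
    children[[length(children) + 1L]] <- st$node
    pos <- st$pos
  }
  if (length(children) == 0L) {
    stop(tree_err(sprintf("non-terminal '%s' has no children", label), where))
  }
  list(node = tree_node(label, children), pos = pos)
}

#' @rdname parse_tree
#' @param label category label of a non-terminal node.
#' @param children list of child nodes.
#' @export
tree_node <- function(label, children) {
  structure(list(label = label, children = children), class = "turnsim_tree")
}

#' @rdname parse_tree
#' @param word a token string for a lexical leaf.
#' @export
tree_leaf <- function(word) {
  structure(list(word = word), class = "turnsim_tree")
}

#' @rdname parse_tree
#' @param tree a tree node.
#' @export
is_leaf <- function(tree) !is.null(tree$word)

#' @rdname parse_tree
#' @export
deparse_tree <- function(tree) {
  if (is_leaf(tree)) return(tree$word)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, deparse_tree, character(1)), collapse = " "),
         ")")
}

#' @rdname parse_tree
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$word)
  unlist(lapply(tree$children, tree_leaves))
}

#' Count non-leaf nodes of a tree
#'
#' Every non-terminal node (preterminals included) counts as one.
#'
#' @param tree a tree node.
#' @return integer count.
#' @export
count_nonterminals <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + sum(vapply(tree$children, count_nonterminals, integer(1)))
}

#' Enumerate complete subtrees of a parse forest
#'
#' Every non-terminal node roots exactly one complete subtree: the node
#' together with all its descendants. Subtrees are reduced to canonical keys
#' over category labels only -- lexical leaves are dropped, and a preterminal
#' (a node dominating only words) is represented by its bare category label.
#' Two subtrees share a key iff they are identical as ordered labelled trees
#' over categories.
#'
#' @param forest a list of parse trees (possibly empty).
#' @param include_preterminals should preterminal nodes themselves contribute
#'   entries to the bag? They remain visible inside their ancestors' keys
#'   either way. Default `TRUE`.
#' @return a list with `counts` (named integer vector: key -> occurrences)
#'   and `total` (number of subtree occurrences counted).
#' @examples
#' b <- enumerate_subtrees(list(parse_tree("(S (NP (PRP it)) (VP (VBZ does)))")))
#' b$total  # 5: S, NP, VP, PRP, VBZ
#' @export
enumerate_subtrees <- function(forest, include_preterminals = TRUE) {
  keys <- character(0)
  for (tree in forest) {
    keys <- c(keys, collect_subtree_keys(tree, include_preterminals))
  }
  if (length(keys) == 0L) {
    return(list(counts = integer(0), total = 0L))
  }
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  list(counts = counts, total = length(keys))
}

is_preterminal <- function(tree) {
  !is_leaf(tree) && all(vapply(tree$children, is_leaf, logical(1)))
}

# canonical key of the complete subtree rooted at `tree`
subtree_key <- function(tree) {
  if (is_preterminal(tree)) return(tree$label)
  parts <- character(0)
  for (ch in tree$children) {
    if (is_leaf(ch)) next  # stray lexical leaf under a phrasal node
    parts <- c(parts, subtree_key(ch))
  }
  paste0("(", tree$label, " ", paste(parts, collapse = " "), ")")
}

collect_subtree_keys <- function(tree, include_preterminals) {
  if (is_leaf(tree)) return(character(0))
  own <- if (include_preterminals || !is_preterminal(tree)) subtree_key(tree) else character(0)
  c(own, unlist(lapply(tree$children, collect_subtree_keys, include_preterminals)))
}
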