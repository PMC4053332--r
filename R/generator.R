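#' Probabilistic grammar for the dialogue simulator
#'
#' A PCFG is a list of phrasal productions (`lhs`, ordered `rhs`
#' categories, base probability) plus a lexicon mapping each preterminal
#' category to words with base probabilities. Probabilities must normalise
#' per left-hand side.
#'
#' @param productions list of `list(lhs=, rhs=, prob=)` entries.
#' @param lexicon named list: preterminal -> `list(words=, probs=)`.
#' @param start start symbol (default `"S"`).
#' @return an object of class `"turnsim_grammar"`.
#' @export
grammar <- function(productions, lexicon, start = "S") {
  lhs <- vapply(productions, function(r) r$lhs, character(1))
  for (s in unique(lhs)) {
    p <- vapply(productions[lhs == s], function(r) r$prob, numeric(1))
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
      stop("production probabilities for '", s, "' do not normalise")
    }
  }
  for (s in names(lexicon)) {
    lx <- lexicon[[s]]
    if (length(lx$words) != length(lx$probs) || any(lx$probs <= 0) ||
        abs(sum(lx$probs) - 1) > 1e-8) {
      stop("lexicon probabilities for '", s, "' do not normalise")
    }
  }
  phrasal <- unique(lhs)
  if (length(intersect(phrasal, names(lexicon)))) {
    stop("categories cannot be both phrasal and preterminal: ",
         paste(intersect(phrasal, names(lexicon)), collapse = ", "))
  }
  g <- structure(list(productions = productions, lexicon = lexicon,
                      start = start), class = "turnsim_grammar")
  g$min_depth <- grammar_min_depth(g)
  g
}

# per-category minimum derivation depth, used to cap recursion
grammar_min_depth <- function(g) {
  cats <- unique(c(vapply(g$productions, function(r) r$lhs, character(1)),
                   names(g$lexicon)))
  depth <- stats::setNames(rep(Inf, length(cats)), cats)
  depth[names(g$lexicon)] <- 1
  repeat {
    changed <- FALSE
    for (r in g$productions) {
      cand <- 1 + max(depth[r$rhs])
      if (is.finite(cand) && cand < depth[r$lhs]) {
        depth[r$lhs] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (any(!is.finite(depth))) {
    stop("grammar has non-terminating categories: ",
         paste(names(depth)[!is.finite(depth)], collapse = ", "))
  }
  depth
}

#' Default simulator grammar
#'
#' A small English-like PCFG: 8 phrasal categories, 17 phrasal
#' productions, 9 preterminal categories and a 60-word vocabulary --
#' large enough that chance similarity sits well below 1, small enough
#' for desk-scale simulation.
#'
#' @return a `turnsim_grammar` object.
#' @export
default_grammar <- function() {
  P <- function(lhs, rhs, prob) list(lhs = lhs, rhs = rhs, prob = prob)
  productions <- list(
    P("S", c("NP", "VP"), 0.55),
    P("S", c("UH", "S"), 0.10),
    P("S", "VP", 0.15),
    P("S", "UH", 0.20),
    P("NP", c("DT", "NN"), 0.45),
    P("NP", "PRP", 0.30),
    P("NP", c("DT", "JJ", "NN"), 0.15),
    P("NP", c("NP", "PP"), 0.10),
    P("VP", c("VB", "NP"), 0.35),
    P("VP", "VB", 0.20),
    P("VP", c("VB", "PP"), 0.15),
    P("VP", c("VB", "ADJP"), 0.10),
    P("VP", c("MD", "VP"), 0.08),
    P("VP", c("VB", "NP", "PP"), 0.12),
    P("PP", c("IN", "NP"), 1.00),
    P("ADJP", "JJ", 0.70),
    P("ADJP", c("RB", "JJ"), 0.30))
  unif <- function(words) list(words = words, probs = rep(1 / length(words), length(words)))
  lexicon <- list(
    DT = unif(c("the", "a", "that")),
    NN = unif(c("phone", "time", "person", "vehicle", "bag", "home", "work",
                "thing", "day", "house", "car", "dog", "tea")),
    VB = unif(c("talk", "look", "know", "feel", "get", "try", "ring",
                "speak", "go", "want", "like", "see")),
    JJ = unif(c("good", "handy", "amazing", "sorry", "big", "useless",
                "nice", "busy")),
    PRP = unif(c("i", "you", "she", "he", "it", "they")),
    IN = unif(c("in", "on", "at", "with", "for", "to")),
    RB = unif(c("very", "really", "quite", "so")),
    MD = unif(c("can", "will", "must")),
    UH = unif(c("yeah", "oh", "mm", "well", "right")))
  grammar(productions, lexicon, start = "S")
}

#' Configuration for the dialogue simulator
#'
#' @param grammar a `turnsim_grammar` (default [default_grammar()]).
#' @param lambda_syn syntactic cross-speaker priming strength in (-1, 1):
#'   each production's log-probability is shifted by `lambda_syn` times the
#'   partner-recency weight of that production before renormalisation.
#'   0 gives the exact null (turns i.i.d. from the base grammar); positive
#'   values induce convergence, negative values divergence.
#' @param lambda_lex lexical cross-speaker priming strength in (-1, 1),
#'   acting analogously on word choice at each preterminal.
#' @param tau decay constant in turns (> 0): a production or word used in
#'   the partner's turn `d` turns back contributes with weight
#'   `exp(-d / tau)` per occurrence, over the partner's last 5 turns.
#' @param n_dialogues number of two-party dialogues.
#' @param turns_per_dialogue turns per dialogue (>= 12 so that every
#'   window position is populated for late turns).
#' @param mean_turn_sentences mean sentences per turn (>= 1; sentence
#'   count is `1 + Poisson(mean_turn_sentences - 1)`).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param max_depth derivation depth at which recursion is forced down the
#'   shallowest production.
#' @return a list of class `"turnsim_genconfig"`.
#' @export
generator_config <- function(grammar = default_grammar(),
                             lambda_syn = 0, lambda_lex = 0, tau = 2,
                             n_dialogues = 20L, turns_per_dialogue = 30L,
                             mean_turn_sentences = 1.5, seed = 1L,
                             max_depth = 10L) {
  stopifnot(inherits(grammar, "turnsim_grammar"),
            lambda_syn > -1, lambda_syn < 1,
            lambda_lex > -1, lambda_lex < 1,
            tau > 0, n_dialogues >= 1, turns_per_dialogue >= 12,
            mean_turn_sentences >= 1)
  structure(list(grammar = grammar, lambda_syn = lambda_syn,
                 lambda_lex = lambda_lex, tau = tau,
                 n_dialogues = as.integer(n_dialogues),
                 turns_per_dialogue = as.integer(turns_per_dialogue),
                 mean_turn_sentences = mean_turn_sentences,
                 seed = as.integer(seed), max_depth = as.integer(max_depth)),
            class = "turnsim_genconfig")
}

#' Generate a synthetic parsed dialogue corpus
#'
#' Two speakers alternate turns. Each sentence is sampled top-down from
#' the PCFG; at every choice point the log-probability of each candidate
#' production (or word) is shifted by `lambda_syn` (resp. `lambda_lex`)
#' times its recency-weighted count in the partner's last five turns,
#' weights `exp(-d / tau)` per occurrence at partner-distance `d`, and the
#' distribution is renormalised. With both lambdas 0 the shift vanishes
#' and turns are i.i.d. from the base grammar. Parse trees are recorded as
#' each turn's forest. Fully deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return a corpus object with label `"real"`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "turnsim_genconfig"))
  with_seed(config$seed, {
    dialogues <- vector("list", config$n_dialogues)
    for (di in seq_len(config$n_dialogues)) {
      dialogues[[di]] <- generate_dialogue(config, sprintf("syn%03d", di))
    }
    corpus(dialogues, label = "real")
  })
}

generate_dialogue <- function(config, id) {
  g <- config$grammar
  speakers <- paste0(id, c("_a", "_b"))
  turns <- vector("list", config$turns_per_dialogue)
  # per-turn usage histories for the priming state
  rule_hist <- vector("list", config$turns_per_dialogue)
  word_hist <- vector("list", config$turns_per_dialogue)
  spk_seq <- rep(speakers, length.out = config$turns_per_dialogue)

  for (i in seq_len(config$turns_per_dialogue)) {
    me <- spk_seq[i]
    partner_turns <- rev(which(spk_seq[seq_len(i - 1L)] != me))
    partner_turns <- partner_turns[seq_len(min(5L, length(partner_turns)))]
    w <- exp(-seq_along(partner_turns) / config$tau)
    state <- list(rules = weighted_counts(rule_hist[partner_turns], w),
                  words = weighted_counts(word_hist[partner_turns], w))

    n_sent <- 1L + stats::rpois(1L, config$mean_turn_sentences - 1)
    forest <- vector("list", n_sent)
    rc <- character(0); wc <- character(0)
    for (s in seq_len(n_sent)) {
      sent <- sample_sentence(g, config, state)
      forest[[s]] <- sent$tree
      rc <- c(rc, sent$rules)
      wc <- c(wc, sent$words)
    }
    text <- paste(unlist(lapply(forest, tree_leaves)), collapse = " ")
    turns[[i]] <- turn(me, text, forest = forest)
    rule_hist[[i]] <- rc
    word_hist[[i]] <- wc
  }
  dialogue(id, turns)
}

# recency-weighted occurrence counts over a list of per-turn usage vectors
weighted_counts <- function(hists, w) {
  out <- numeric(0)
  for (j in seq_along(hists)) {
    if (length(hists[[j]]) == 0L) next
    tb <- table(hists[[j]])
    add <- as.numeric(tb) * w[j]
    nm <- names(tb)
    hit <- nm %in% names(out)
    out[nm[hit]] <- out[nm[hit]] + add[hit]
    out <- c(out, stats::setNames(add[!hit], nm[!hit]))
  }
  out
}

sample_sentence <- function(g, config, state) {
  rules_used <- character(0)
  words_used <- character(0)
  lhs_all <- vapply(g$productions, function(r) r$lhs, character(1))

  expand <- function(sym, depth) {
    if (sym %in% names(g$lexicon)) {
      lx <- g$lexicon[[sym]]
      lp <- log(lx$probs)
      if (config$lambda_lex != 0) {
        hit <- lx$words %in% names(state$words)
        lp[hit] <- lp[hit] + config$lambda_lex * state$words[lx$words[hit]]
      }
      pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
      wd <- lx$words[sample.int(length(lx$words), 1L, prob = pr)]
      words_used <<- c(words_used, wd)
      return(tree_node(sym, list(tree_leaf(wd))))
    }
    idx <- which(lhs_all == sym)
    if (depth >= config$max_depth) {
      # force termination down the shallowest derivation
      md <- vapply(idx, function(k) max(g$min_depth[g$productions[[k]]$rhs]),
                   numeric(1))
      idx <- idx[md == min(md)]
    }
    lp <- log(vapply(idx, function(k) g$productions[[k]]$prob, numeric(1)))
    ids <- vapply(idx, function(k) rule_id(g$productions[[k]]), character(1))
    if (config$lambda_syn != 0) {
      hit <- ids %in% names(state$rules)
      lp[hit] <- lp[hit] + config$lambda_syn * state$rules[ids[hit]]
    }
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    pick <- sample.int(length(idx), 1L, prob = pr)
    rules_used <<- c(rules_used, ids[pick])
    r <- g$productions[[idx[pick]]]
    tree_node(sym, lapply(r$rhs, expand, depth = depth + 1L))
  }

  tree <- expand(g$start, 1L)
  list(tree = tree, rules = rules_used, words = words_used)
}

rule_id <- function(r) paste(r$lhs, "->", paste(r$rhs, collapse = " "))
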