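#' Seeded evaluation preserving the caller's RNG state
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic substream seeds below 2^31, derived from a master seed
derive_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  ((s * 48271 + as.double(i) * 69621 + 1) %% m) + 1
}

#' Build a Chance-Other counterpart dialogue
#'
#' Keeps one person's real turns in their original order and positions and
#' replaces every other-speaker turn slot with a turn drawn uniformly at
#' random (with replacement) from the turns of the *other* dialogues in the
#' corpus. Replacement turns keep their original text, parse forest and
#' speaker label. Deterministic given `(corpus, person, seed)`.
#'
#' @param x a corpus with at least two dialogues.
#' @param person the person whose real turns are preserved.
#' @param seed integer seed.
#' @return a dialogue object; the randomization plan (source dialogue id
#'   and turn index for each replaced slot) is attached as attribute
#'   `"plan"`.
#' @export
make_chance_other <- function(x, person, seed) {
  stopifnot(inherits(x, "turnsim_corpus"))
  if (length(x$dialogues) < 2L) {
    stop("chance-other requires at least 2 dialogues (no 'rest of the corpus')")
  }
  has_p <- vapply(x$dialogues, function(d) person %in% d$persons, logical(1))
  if (!any(has_p)) stop("person not found in corpus: ", person)
  dlg <- x$dialogues[[which(has_p)[1]]]

  donors <- list()
  for (d in x$dialogues) {
    if (d$id == dlg$id) next
    for (t in d$turns) {
      donors[[length(donors) + 1L]] <- list(dialogue_id = d$id, turn = t)
    }
  }
  if (length(donors) == 0L) stop("donor pool is empty")

  slots <- which(vapply(dlg$turns, function(t) t$speaker != person, logical(1)))
  picks <- with_seed(seed, sample.int(length(donors), length(slots), replace = TRUE))

  new_turns <- dlg$turns
  plan <- data.frame(slot_index = slots - 1L,
                     source_dialogue = character(length(slots)),
                     source_index = integer(length(slots)),
                     stringsAsFactors = FALSE)
  for (j in seq_along(slots)) {
    donor <- donors[[picks[j]]]
    dt <- donor$turn
    if (identical(dt$speaker, person)) dt$speaker <- paste0(donor$dialogue_id, ":", dt$speaker)
    new_turns[[slots[j]]] <- dt
    plan$source_dialogue[j] <- donor$dialogue_id
    plan$source_index[j] <- donor$turn$index
  }
  out <- dialogue(paste0(dlg$id, "#chance_other#", person), new_turns)
  attr(out, "plan") <- plan
  out
}

#' Build a Chance-Self pairing
#'
#' Pairs each of one person's real turns, in sequence, with a random
#' re-ordering of those same turns under the constraint that no turn is
#' matched with itself (a derangement, sampled uniformly by seeded
#' rejection). Deterministic given `(dialogue, person, seed)`.
#'
#' @param dlg a dialogue object.
#' @param person a speaker with at least two turns in `dlg`.
#' @param seed integer seed.
#' @return a data.frame with one row per own turn: `position` (1-based rank
#'   in the person's own-turn sequence), `target_index` (dialogue turn
#'   index, 0-based), `source_position` and `source_index` identifying the
#'   deranged partner turn. Returns `NULL` with a warning when the person
#'   has fewer than two turns (no derangement exists).
#' @export
make_chance_self <- function(dlg, person, seed) {
  stopifnot(inherits(dlg, "turnsim_dialogue"))
  own <- which(vapply(dlg$turns, function(t) t$speaker == person, logical(1)))
  k <- length(own)
  if (k < 2L) {
    warning("person '", person, "' has fewer than 2 turns; chance-self skipped")
    return(NULL)
  }
  sigma <- with_seed(seed, sample_derangement(k))
  data.frame(position = seq_len(k),
             target_index = own - 1L,
             source_position = sigma,
             source_index = own[sigma] - 1L,
             stringsAsFactors = FALSE)
}

# uniform derangement by rejection sampling (uses the current RNG stream)
sample_derangement <- function(k) {
  stopifnot(k >= 2L)
  repeat {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
}

#' Chance-condition similarity records for a whole corpus
#'
#' `chance_other_records()` builds, for every person in every dialogue, a
#' Chance-Other counterpart dialogue (see [make_chance_other()]) and
#' computes that person's other-similarity window over it.
#' `chance_self_records()` computes, for every person, self-similarity
#' records in which the context stream at distance `d` is the deranged
#' re-ordering of the person's own prior turns (see [make_chance_self()]).
#' Per-person substream seeds are derived deterministically from `seed`.
#'
#' @param x a corpus object.
#' @param seed integer master seed.
#' @param reps number of chance realizations per person; records from all
#'   realizations are returned (rep id in column `rep`) and average out
#'   Monte-Carlo noise when aggregated.
#' @param max_distance window depth.
#' @param include_preterminals passed to [syntactic_similarity()].
#' @return a record data.frame as in [window_similarities()], with
#'   `condition` `"chance_other"` / `"chance_self"` and an extra `rep`
#'   column.
#' @export
chance_other_records <- function(x, seed, reps = 1L, max_distance = 5L,
                                 include_preterminals = TRUE) {
  stopifnot(inherits(x, "turnsim_corpus"))
  out <- list()
  pi <- 0L
  for (d in x$dialogues) {
    for (p in d$persons) {
      pi <- pi + 1L
      for (r in seq_len(reps)) {
        ch <- make_chance_other(x, p, derive_seed(seed, pi * 1000L + r))
        rec <- window_similarities(ch, max_distance = max_distance,
                                   include_preterminals = include_preterminals,
                                   persons = p, condition = "chance_other")
        rec <- rec[rec$relation == "other", , drop = FALSE]
        rec$dialogue_id <- d$id
        rec$rep <- r
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  do.call(rbind, out)
}

#' @rdname chance_other_records
#' @export
chance_self_records <- function(x, seed, reps = 1L, max_distance = 5L,
                                include_preterminals = TRUE) {
  stopifnot(inherits(x, "turnsim_corpus"))
  out <- list()
  pi <- 0L
  for (d in x$dialogues) {
    for (p in d$persons) {
      pi <- pi + 1L
      own <- which(vapply(d$turns, function(t) t$speaker == p, logical(1)))
      k <- length(own)
      if (k < 2L) next
      prof <- lapply(d$turns[own], turn_profile,
                     include_preterminals = include_preterminals)
      for (r in seq_len(reps)) {
        plan <- make_chance_self(d, p, derive_seed(seed, pi * 1000L + r))
        md <- as.integer(max_distance)
        n <- k * md
        target_index <- integer(n); distance <- integer(n)
        context_index <- rep(NA_integer_, n)
        lex <- rep(NA_real_, n); syn <- rep(NA_real_, n)
        z <- 0L
        for (i in seq_len(k)) {
          for (dd in seq_len(md)) {
            z <- z + 1L
            target_index[z] <- own[i] - 1L
            distance[z] <- dd
            if (i - dd >= 1L) {
              sp <- plan$source_position[i - dd]
              context_index[z] <- own[sp] - 1L
              lex[z] <- profile_lexical(prof[[i]], prof[[sp]])
              syn[z] <- profile_syntactic(prof[[i]], prof[[sp]])
            }
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          dialogue_id = d$id, person = p, target_index = target_index,
          relation = "self", distance = distance, condition = "chance_self",
          context_index = context_index, lexical = lex, syntactic = syn,
          rep = r, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
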