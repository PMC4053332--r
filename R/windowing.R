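#' Moving-window similarity records for a dialogue
#'
#' For every turn a person produces, computes lexical and syntactic
#' similarity against each of the `max_distance` most recent preceding
#' turns by their interlocutors (*other*-similarity) and by themselves
#' (*self*-similarity) -- with the default of 5 this is the ten-turn moving
#' window passed over the whole conversation. Distance is counted within
#' the partner (resp. own) turn stream: other-distance `d` pairs the target
#' with the `d`-th most recent prior turn by any other speaker, pooling all
#' interlocutors into one stream in multi-party dialogues. Setting
#' `distance_mode = "offset"` instead counts raw turn offsets `1..max_distance`
#' and classifies each offset's turn as self or other.
#'
#' Targets near the start of the conversation that lack a context turn at
#' some distance yield records with missing (`NA`) scores, so every turn
#' contributes exactly `2 * max_distance` records.
#'
#' @param dlg a dialogue object.
#' @param max_distance window depth per relation (default 5).
#' @param include_preterminals passed to [syntactic_similarity()].
#' @param persons restrict target turns to these speakers (default: all).
#' @param condition condition label stamped on the records
#'   (`"real"`, `"chance_other"` or `"chance_self"`).
#' @param distance_mode `"stream"` (default) or `"offset"`, see above.
#' @return a data.frame with one row per record: `dialogue_id`, `person`,
#'   `target_index`, `relation`, `distance`, `condition`, `context_index`,
#'   `lexical`, `syntactic`. Missing scores are `NA`.
#' @export
window_similarities <- function(dlg, max_distance = 5L,
                                include_preterminals = TRUE,
                                persons = NULL,
                                condition = "real",
                                distance_mode = c("stream", "offset")) {
  stopifnot(inherits(dlg, "turnsim_dialogue"))
  distance_mode <- match.arg(distance_mode)
  n <- length(dlg$turns)
  speakers <- vapply(dlg$turns, function(t) t$speaker, character(1))
  targets <- seq_len(n)
  if (!is.null(persons)) targets <- targets[speakers %in% persons]

  md <- as.integer(max_distance)
  rows_per_target <- 2L * md
  total <- length(targets) * rows_per_target
  person <- character(total); target_index <- integer(total)
  relation <- character(total); distance <- integer(total)
  context_index <- rep(NA_integer_, total)
  lex <- rep(NA_real_, total); syn <- rep(NA_real_, total)

  # cache per-turn word tables and subtree bags: each turn enters many pairs
  profiles <- lapply(dlg$turns, turn_profile,
                     include_preterminals = include_preterminals)

  k <- 0L
  for (i in targets) {
    p <- speakers[i]
    prior <- seq_len(i - 1L)
    if (distance_mode == "stream") {
      other_stream <- rev(prior[speakers[prior] != p])
      self_stream <- rev(prior[speakers[prior] == p])
      ctx_for <- function(rel, d) {
        s <- if (rel == "other") other_stream else self_stream
        if (d <= length(s)) s[d] else NA_integer_
      }
      for (rel in c("other", "self")) {
        for (d in seq_len(md)) {
          k <- k + 1L
          person[k] <- p; target_index[k] <- i - 1L
          relation[k] <- rel; distance[k] <- d
          j <- ctx_for(rel, d)
          if (!is.na(j)) {
            context_index[k] <- j - 1L
            lex[k] <- profile_lexical(profiles[[i]], profiles[[j]])
            syn[k] <- profile_syntactic(profiles[[i]], profiles[[j]])
          }
        }
      }
    } else {
      # raw-offset alternative: turn i - d, classified by its speaker
      for (rel in c("other", "self")) {
        for (d in seq_len(md)) {
          k <- k + 1L
          person[k] <- p; target_index[k] <- i - 1L
          relation[k] <- rel; distance[k] <- d
          j <- i - d
          if (j >= 1L) {
            is_self <- speakers[j] == p
            if ((rel == "self") == is_self) {
              context_index[k] <- j - 1L
              lex[k] <- profile_lexical(profiles[[i]], profiles[[j]])
              syn[k] <- profile_syntactic(profiles[[i]], profiles[[j]])
            }
          }
        }
      }
    }
  }

  data.frame(dialogue_id = rep(dlg$id, total),
             person = person,
             target_index = target_index,
             relation = relation,
             distance = distance,
             condition = rep(condition, total),
             context_index = context_index,
             lexical = lex,
             syntactic = syn,
             stringsAsFactors = FALSE)
}

#' Window similarities over a whole corpus
#'
#' @param x a corpus object.
#' @inheritParams window_similarities
#' @return row-bound records of [window_similarities()] over all dialogues.
#' @export
corpus_similarities <- function(x, max_distance = 5L,
                                include_preterminals = TRUE,
                                condition = x$label) {
  stopifnot(inherits(x, "turnsim_corpus"))
  recs <- lapply(x$dialogues, window_similarities,
                 max_distance = max_distance,
                 include_preterminals = include_preterminals,
                 condition = condition)
  do.call(rbind, recs)
}

#' Write similarity records to CSV
#'
#' One row per record; missing scores are written as empty fields.
#'
#' @param records a record data.frame from [window_similarities()].
#' @param path output file.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(NULL)
}
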