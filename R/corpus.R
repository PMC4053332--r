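#' Dialogue corpus containers
#'
#' A `Corpus` is a list of dialogues; a `Dialogue` is an ordered list of
#' speaker turns; a `Turn` carries the speaker, the raw text, its tokens
#' (surface and lowercase comparison forms) and a parse forest of zero or
#' more bracketed constituency trees. Turn indices are 0-based internally;
#' distances reported to the user follow the -1..-5 convention.
#'
#' @param speaker person identifier.
#' @param text raw transcription of the turn.
#' @param forest list of parse trees (see [parse_tree()]); may be empty for
#'   unparsed turns.
#' @param index 0-based position in the dialogue (assigned by [dialogue()]
#'   when `NA`).
#' @param policy tokenization policy, see [tokenization_policy()].
#' @return `turn()` returns an object of class `"turnsim_turn"`.
#' @export
turn <- function(speaker, text, forest = list(), index = NA_integer_,
                 policy = tokenization_policy()) {
  toks <- tokenize(text, policy)
  structure(list(speaker = as.character(speaker),
                 index = as.integer(index),
                 text = text,
                 tokens = toks$surface,
                 norms = toks$norm,
                 forest = forest),
            class = "turnsim_turn")
}

#' @rdname turn
#' @param id dialogue identifier.
#' @param turns list of turns in order.
#' @return `dialogue()` returns an object of class `"turnsim_dialogue"`.
#' @export
dialogue <- function(id, turns) {
  turns <- lapply(seq_along(turns), function(i) {
    t <- turns[[i]]
    t$index <- i - 1L
    t
  })
  persons <- unique(vapply(turns, function(t) t$speaker, character(1)))
  structure(list(id = as.character(id), turns = turns, persons = persons),
            class = "turnsim_dialogue")
}

#' @rdname turn
#' @param dialogues list of dialogues.
#' @param label corpus label, e.g. `"real"`, `"chance_other"`, `"chance_self"`.
#' @return `corpus()` returns an object of class `"turnsim_corpus"`.
#' @export
corpus <- function(dialogues, label = "real") {
  ids <- vapply(dialogues, function(d) d$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dialogue ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(dialogues = dialogues, label = label),
            class = "turnsim_corpus")
}

#' @export
#' @method print turnsim_corpus
print.turnsim_corpus <- function(x, ...) {
  nturns <- sum(vapply(x$dialogues, function(d) length(d$turns), integer(1)))
  npers <- length(unique(unlist(lapply(x$dialogues, function(d) d$persons))))
  cat(sprintf("<turnsim corpus '%s': %d dialogue(s), %d turns, %d persons>\n",
              x$label, length(x$dialogues), nturns, npers))
  invisible(x)
}

#' @export
#' @method print turnsim_dialogue
print.turnsim_dialogue <- function(x, ...) {
  cat(sprintf("<dialogue '%s': %d turns, speakers %s>\n",
              x$id, length(x$turns), paste(x$persons, collapse = ", ")))
  invisible(x)
}

#' Read a corpus of parsed dialogues
#'
#' Reads the package's plain-text dialogue format. In `bracketed` format a
#' file holds one or more dialogues, each introduced by a `#DIALOGUE <id>`
#' line; every turn is a `#TURN <speaker>` line, followed by the raw turn
#' text on one line, then zero or more lines each carrying one Penn-style
#' bracketed parse tree; a blank line ends the turn. In `plain` format turns
#' are `speaker<TAB>text` lines grouped under `#DIALOGUE` headers (no
#' trees). `path` may be a single file or a directory of such files.
#'
#' @param path file or directory to read.
#' @param format `"bracketed"` (default) or `"plain"`.
#' @param label corpus label to attach.
#' @param policy tokenization policy.
#' @return a corpus object.
#' @seealso [write_corpus()] for the inverse; reading is lossless with
#'   respect to writing.
#' @export
read_corpus <- function(path, format = c("bracketed", "plain"),
                        label = "real", policy = tokenization_policy()) {
  format <- match.arg(format)
  files <- if (dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else if (file.exists(path)) {
    path
  } else {
    stop("no such file or directory: ", path)
  }
  dialogues <- list()
  for (f in files) {
    dialogues <- c(dialogues, read_dialogue_file(f, format, policy))
  }
  corpus(dialogues, label = label)
}

read_dialogue_file <- function(file, format, policy) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  dialogues <- list()
  cur_id <- NULL
  cur_turns <- list()
  # turn under construction (bracketed format)
  cur_speaker <- NULL
  cur_text <- NULL
  cur_trees <- list()

  flush_turn <- function() {
    if (is.null(cur_speaker)) return()
    cur_turns[[length(cur_turns) + 1L]] <<-
      turn(cur_speaker, if (is.null(cur_text)) "" else cur_text,
           forest = cur_trees, policy = policy)
    cur_speaker <<- NULL; cur_text <<- NULL; cur_trees <<- list()
  }
  flush_dialogue <- function() {
    flush_turn()
    if (is.null(cur_id)) return()
    dialogues[[length(dialogues) + 1L]] <<- dialogue(cur_id, cur_turns)
    cur_id <<- NULL; cur_turns <<- list()
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    loc <- paste0(file, ":", i)
    if (grepl("^#DIALOGUE\\b", ln)) {
      flush_dialogue()
      cur_id <- trimws(sub("^#DIALOGUE", "", ln))
      if (!nzchar(cur_id)) stop("missing dialogue id at ", loc)
      next
    }
    if (is.null(cur_id)) {
      if (!nzchar(trimws(ln))) next
      stop("content before #DIALOGUE header at ", loc)
    }
    if (format == "plain") {
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("expected 'speaker<TAB>text' at ", loc)
      cur_turns[[length(cur_turns) + 1L]] <-
        turn(parts[1], paste(parts[-1], collapse = "\t"), policy = policy)
      next
    }
    if (grepl("^#TURN\\b", ln)) {
      flush_turn()
      cur_speaker <- trimws(sub("^#TURN", "", ln))
      if (!nzchar(cur_speaker)) stop("missing speaker at ", loc)
      next
    }
    if (!nzchar(trimws(ln))) {
      flush_turn()
      next
    }
    if (is.null(cur_speaker)) stop("turn text before #TURN header at ", loc)
    if (is.null(cur_text)) {
      cur_text <- ln
    } else {
      cur_trees[[length(cur_trees) + 1L]] <- parse_tree(ln, where = loc)
    }
  }
  flush_dialogue()
  dialogues
}

#' Write a corpus of parsed dialogues
#'
#' Serialises a corpus to the bracketed dialogue format read by
#' [read_corpus()]. Output bytes are deterministic for a fixed corpus.
#'
#' @param x a corpus object.
#' @param path output file.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "turnsim_corpus"))
  out <- character(0)
  for (d in x$dialogues) {
    out <- c(out, paste("#DIALOGUE", d$id))
    for (t in d$turns) {
      out <- c(out, paste("#TURN", t$speaker), t$text)
      for (tr in t$forest) out <- c(out, deparse_tree(tr))
      out <- c(out, "")
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(NULL)
}

# structural equality over the fields that define a corpus
corpus_equal <- function(a, b) {
  strip <- function(x) {
    x$dialogues <- lapply(x$dialogues, function(d) {
      d$turns <- lapply(d$turns, function(t) {
        t$forest <- lapply(t$forest, deparse_tree)
        t
      })
      d
    })
    x
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = FALSE))
}
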