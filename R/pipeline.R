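#' Pipeline configuration
#'
#' Exactly one of `input` (a corpus file or directory in the format of
#' [read_corpus()]) or `generator` (a [generator_config()]) must be given.
#'
#' @param input path to a corpus file or directory, or `NULL`.
#' @param generator a generator config, or `NULL`.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param reps chance realizations per person.
#' @param max_distance window depth (default 5, i.e. the ten-turn window).
#' @param include_preterminals count POS nodes as structures.
#' @param tokenization tokenization policy for `input` corpora.
#' @param output_dir directory for artifacts (created if needed).
#' @return a list of class `"turnsim_pipeconfig"`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL, seed = 1L,
                            reps = 1L, max_distance = 5L,
                            include_preterminals = TRUE,
                            tokenization = tokenization_policy(),
                            output_dir = tempfile("turnsim_run_")) {
  if (is.null(input) == is.null(generator)) {
    stop("specify exactly one of 'input' or 'generator'")
  }
  structure(list(input = input, generator = generator,
                 seed = as.integer(seed), reps = as.integer(reps),
                 max_distance = as.integer(max_distance),
                 include_preterminals = include_preterminals,
                 tokenization = tokenization, output_dir = output_dir),
            class = "turnsim_pipeconfig")
}

#' Run the full divergence analysis
#'
#' Ingests or generates a corpus, computes the real moving-window
#' similarity records, builds Chance-Other and Chance-Self counterparts,
#' aggregates per-person cells, fits the other- and self-similarity mixed
#' models and writes all artifacts to the output directory:
#' `records_real.csv`, `records_chance_other.csv`,
#' `records_chance_self.csv`, `person_cells.csv`, `model_other.json`,
#' `model_self.json`, `emmeans_other.csv`, `emmeans_self.csv` and
#' `run_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the corpus, record tables, person cells
#'   and both `divergence_fit` objects (`fit_other`, `fit_self`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "turnsim_pipeconfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("turnsim run, seed %d", config$seed)
  say("R %s, turnsim %s", as.character(getRversion()),
      as.character(utils::packageVersion("turnsim")))

  x <- if (!is.null(config$input)) {
    read_corpus(config$input, policy = config$tokenization)
  } else {
    gc2 <- config$generator
    gc2$seed <- as.integer(derive_seed(config$seed, 1L))
    generate_corpus(gc2)
  }
  say("corpus: %d dialogues, %d turns", length(x$dialogues),
      sum(vapply(x$dialogues, function(d) length(d$turns), integer(1))))

  real <- corpus_similarities(x, max_distance = config$max_distance,
                              include_preterminals = config$include_preterminals,
                              condition = "real")
  real$rep <- 1L
  ch_other <- chance_other_records(x, seed = derive_seed(config$seed, 2L),
                                   reps = config$reps,
                                   max_distance = config$max_distance,
                                   include_preterminals = config$include_preterminals)
  ch_self <- chance_self_records(x, seed = derive_seed(config$seed, 3L),
                                 reps = config$reps,
                                 max_distance = config$max_distance,
                                 include_preterminals = config$include_preterminals)
  write_records(real, file.path(config$output_dir, "records_real.csv"))
  write_records(ch_other, file.path(config$output_dir, "records_chance_other.csv"))
  write_records(ch_self, file.path(config$output_dir, "records_chance_self.csv"))

  cells <- aggregate_by_person(rbind(real, ch_other, ch_self))
  utils::write.csv(cells, file.path(config$output_dir, "person_cells.csv"),
                   row.names = FALSE, na = "")

  fits <- list()
  for (rel in c("other", "self")) {
    fit <- fit_divergence(cells, relation = rel)
    say("%s model: %d cells, %d persons, %d dropped%s", rel, fit$n_cells,
        fit$n_persons, fit$n_dropped,
        if (fit$singular) " (singular random-effect fit)" else "")
    write_model_json(fit, file.path(config$output_dir,
                                    sprintf("model_%s.json", rel)))
    utils::write.csv(fit$emmeans,
                     file.path(config$output_dir, sprintf("emmeans_%s.csv", rel)),
                     row.names = FALSE)
    fits[[rel]] <- fit
  }
  writeLines(log, file.path(config$output_dir, "run_log.txt"))
  invisible(list(corpus = x, records_real = real,
                 records_chance_other = ch_other,
                 records_chance_self = ch_self,
                 cells = cells,
                 fit_other = fits$other, fit_self = fits$self))
}

#' One seeded simulate-and-test experiment
#'
#' Convenience wrapper used for calibration and parameter-recovery
#' studies: generates a corpus under the given priming strengths, computes
#' real and chance records for one relation, aggregates and fits the
#' divergence model. Cheaper than [run_pipeline()] because it fits only
#' the requested relation and writes nothing.
#'
#' @param seed integer seed.
#' @param relation `"other"` or `"self"`.
#' @param lambda_syn,lambda_lex,tau,n_dialogues,turns_per_dialogue passed
#'   to [generator_config()].
#' @param reps chance realizations per person.
#' @param contrasts passed to [fit_divergence()]; set `FALSE` to skip the
#'   marginal-means machinery when only omnibus tests are needed.
#' @param ... further arguments to [generator_config()].
#' @return the `divergence_fit` for the requested relation; the aggregated
#'   cells are attached as attribute `"cells"`.
#' @export
divergence_experiment <- function(seed, relation = c("other", "self"),
                                  lambda_syn = 0, lambda_lex = 0, tau = 2,
                                  n_dialogues = 20L, turns_per_dialogue = 30L,
                                  reps = 2L, contrasts = TRUE, ...) {
  relation <- match.arg(relation)
  cfg <- generator_config(lambda_syn = lambda_syn, lambda_lex = lambda_lex,
                          tau = tau, n_dialogues = n_dialogues,
                          turns_per_dialogue = turns_per_dialogue,
                          seed = as.integer(derive_seed(seed, 1L)), ...)
  x <- generate_corpus(cfg)
  real <- corpus_similarities(x, condition = "real")
  real <- real[real$relation == relation, , drop = FALSE]
  real$rep <- 1L
  ch <- if (relation == "other") {
    chance_other_records(x, seed = derive_seed(seed, 2L), reps = reps)
  } else {
    chance_self_records(x, seed = derive_seed(seed, 3L), reps = reps)
  }
  cells <- aggregate_by_person(rbind(real, ch))
  fit <- fit_divergence(cells, relation = relation, contrasts = contrasts)
  attr(fit, "cells") <- cells
  fit
}
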