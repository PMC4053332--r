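#' Aggregate similarity records into per-person cell means
#'
#' Averages the non-missing lexical and syntactic similarities into one
#' cell per person x relation x condition x distance, the unit of analysis
#' for the mixed model. Chance conditions are collapsed onto a two-level
#' `condition` factor (`"real"` vs `"chance"`); the relation column keeps
#' self and other apart.
#'
#' @param records a record data.frame (rows from [window_similarities()],
#'   [chance_other_records()] and/or [chance_self_records()], possibly
#'   row-bound).
#' @return a data.frame of person cells: `person`, `relation`, `condition`,
#'   `distance`, `mean_syntactic`, `mean_lexical`, `n_pairs` (count of
#'   records with a non-missing syntactic score). Cells present in the
#'   design but with no non-missing records carry `NA` means and
#'   `n_pairs = 0`.
#' @export
aggregate_by_person <- function(records) {
  stopifnot(all(c("person", "relation", "distance", "condition",
                  "lexical", "syntactic") %in% names(records)))
  cond2 <- ifelse(records$condition == "real", "real", "chance")
  key <- interaction(records$person, records$relation, cond2,
                     records$distance, drop = TRUE, sep = "\r")
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    person = vapply(parts, `[`, character(1), 1L),
    relation = vapply(parts, `[`, character(1), 2L),
    condition = vapply(parts, `[`, character(1), 3L),
    distance = as.integer(vapply(parts, `[`, character(1), 4L)),
    mean_syntactic = agg(records$syntactic, mean_or_na),
    mean_lexical = agg(records$lexical, mean_or_na),
    n_pairs = as.integer(agg(!is.na(records$syntactic), sum)),
    stringsAsFactors = FALSE)
  out <- out[order(out$person, out$relation, out$condition, out$distance), ]
  rownames(out) <- NULL
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Sequentially rejective Bonferroni adjustment with monotonicity
#' enforcement, delegated to [stats::p.adjust()] after validating the
#' input. Output order matches input order.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Test real-vs-chance similarity with a linear mixed model
#'
#' Fits the divergence test for one relation (similarity to others or to
#' self): per-person mean syntactic similarity is modelled with
#' Conversation condition (real vs chance) and Distance (1-5 turns back,
#' a 5-level factor) as repeated fixed factors, mean lexical similarity as
#' a covariate (all interactions included), and a person random intercept:
#'
#' `mean_syntactic ~ condition * distance * mean_lexical + (1 | person)`
#'
#' Fixed effects are tested with Type III F-tests (Satterthwaite
#' denominator degrees of freedom). Estimated marginal means per
#' condition x distance are computed at the covariate mean, and the
#' real - chance contrast at each distance is tested with Holm-adjusted
#' p-values. The criterion level is 0.05 throughout. Cells with missing
#' means are dropped listwise (the count is recorded in the result).
#'
#' @param cells person-cell data.frame from [aggregate_by_person()].
#' @param relation `"other"` or `"self"`: which similarity stream to test.
#' @param alpha criterion level for the significance flags (default 0.05).
#' @param contrasts compute estimated marginal means and per-distance
#'   contrasts (default `TRUE`); turn off to fit many models quickly when
#'   only the omnibus F-tests are needed.
#' @return an object of class `"divergence_fit"`: a list with elements
#'   `relation`, `model` (the underlying `lmerModLmerTest` fit), `anova`
#'   (Type III fixed-effect F table), `fixed_effects` (tidy data.frame of
#'   term, F, df, p), `covariate_slope`, `emmeans` (condition x distance
#'   estimated marginal means), `contrasts` (per-distance real - chance
#'   differences with raw and Holm-adjusted p), `n_dropped` and `singular`.
#' @seealso [print.divergence_fit()], [summary.divergence_fit()],
#'   [plot.divergence_fit()]
#' @export
fit_divergence <- function(cells, relation = c("other", "self"), alpha = 0.05,
                           contrasts = TRUE) {
  relation <- match.arg(relation)
  d <- cells[cells$relation == relation, , drop = FALSE]
  if (nrow(d) == 0L) stop("no cells for relation '", relation, "'")
  complete <- !is.na(d$mean_syntactic) & !is.na(d$mean_lexical)
  n_dropped <- sum(!complete)
  d <- d[complete, , drop = FALSE]
  if (length(unique(d$person)) < 2L) {
    stop("need cells from at least 2 persons to fit the mixed model")
  }
  if (length(unique(d$condition)) < 2L) {
    stop("need both real and chance cells to fit the divergence model")
  }
  d$condition <- factor(d$condition, levels = c("chance", "real"))
  d$distance <- factor(d$distance)

  fit <- lmerTest::lmer(
    mean_syntactic ~ condition * distance * mean_lexical + (1 | person),
    data = d,
    contrasts = list(condition = "contr.sum", distance = "contr.sum"),
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)

  an <- stats::anova(fit, type = 3)
  fixed_effects <- data.frame(
    term = rownames(an),
    F = an[["F value"]],
    df1 = an[["NumDF"]],
    df2 = an[["DenDF"]],
    p = an[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  rownames(fixed_effects) <- NULL

  # unstandardized lexical-similarity slope (at the factor means under
  # sum-to-zero coding)
  covariate_slope <- unname(lme4::fixef(fit)["mean_lexical"])

  emm_df <- NULL
  contrast_tab <- NULL
  if (isTRUE(contrasts)) {
    # emmeans notes that condition is involved in interactions; the
    # per-distance contrasts below are exactly the focused comparisons wanted
    emm <- suppressMessages(emmeans::emmeans(fit, ~ condition | distance,
                                             lmer.df = "satterthwaite"))
    emm_df <- as.data.frame(emm)

    ctr <- suppressMessages(emmeans::contrast(emm, method = "revpairwise",
                                              by = "distance", adjust = "none"))
    ctr_df <- as.data.frame(ctr)
    contrast_tab <- data.frame(
      distance = as.integer(as.character(ctr_df$distance)),
      estimate = ctr_df$estimate,   # real - chance
      SE = ctr_df$SE,
      df = ctr_df$df,
      p_raw = ctr_df$p.value,
      stringsAsFactors = FALSE)
    # contrasts can be untestable (NA p) on degenerate cells; adjust the rest
    ok <- !is.na(contrast_tab$p_raw)
    contrast_tab$p_holm <- NA_real_
    contrast_tab$p_holm[ok] <- holm_adjust(contrast_tab$p_raw[ok])
    contrast_tab$significant <- !is.na(contrast_tab$p_holm) &
      contrast_tab$p_holm < alpha
  }

  structure(list(relation = relation,
                 model = fit,
                 anova = an,
                 fixed_effects = fixed_effects,
                 covariate_slope = covariate_slope,
                 emmeans = emm_df,
                 contrasts = contrast_tab,
                 n_cells = nrow(d),
                 n_persons = length(unique(d$person)),
                 n_dropped = n_dropped,
                 singular = singular,
                 alpha = alpha),
            class = "divergence_fit")
}

#' @export
#' @method print divergence_fit
print.divergence_fit <- function(x, ...) {
  cat(sprintf("Divergence test (%s-similarity): %d cells, %d persons",
              x$relation, x$n_cells, x$n_persons))
  if (x$n_dropped > 0) cat(sprintf(" (%d incomplete cells dropped)", x$n_dropped))
  cat("\n")
  if (x$singular) cat("note: random-effect fit is singular\n")
  cond <- x$fixed_effects[x$fixed_effects$term == "condition", ]
  cat(sprintf("Condition (real vs chance): F(%g, %.1f) = %.3f, p = %.4g\n",
              cond$df1, cond$df2, cond$F, cond$p))
  cat(sprintf("Lexical-similarity slope: %+.3f\n", x$covariate_slope))
  if (!is.null(x$contrasts)) {
    d1 <- x$contrasts[x$contrasts$distance == 1L, ]
    cat(sprintf("Real - chance at distance 1: %+.4f (Holm p = %.4g)\n",
                d1$estimate, d1$p_holm))
  }
  invisible(x)
}

#' @export
#' @method summary divergence_fit
summary.divergence_fit <- function(object, ...) {
  cat(sprintf("Linear mixed model of %s-similarity, per-person cell means\n",
              object$relation))
  cat("Fixed effects (Type III, Satterthwaite df):\n")
  fe <- object$fixed_effects
  fe$F <- round(fe$F, 3); fe$df2 <- round(fe$df2, 1)
  fe$p <- signif(fe$p, 4)
  print(fe, row.names = FALSE)
  cat(sprintf("\nLexical-similarity covariate slope: %+.4f\n",
              object$covariate_slope))
  cat("\nReal - chance contrasts by distance (Holm-adjusted):\n")
  ct <- object$contrasts
  ct$estimate <- round(ct$estimate, 4); ct$SE <- round(ct$SE, 4)
  ct$df <- round(ct$df, 1)
  ct$p_raw <- signif(ct$p_raw, 4); ct$p_holm <- signif(ct$p_holm, 4)
  print(ct, row.names = FALSE)
  invisible(object)
}

#' @export
#' @method coef divergence_fit
coef.divergence_fit <- function(object, ...) {
  lme4::fixef(object$model)
}

#' @export
#' @method residuals divergence_fit
residuals.divergence_fit <- function(object, ...) {
  stats::residuals(object$model, ...)
}

#' Plot estimated marginal means by condition and distance
#'
#' Draws the model-adjusted mean syntactic similarity per distance, one
#' line per condition, with 95 percent confidence bars.
#'
#' @param x a `divergence_fit` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.divergence_fit <- function(x, ...) {
  em <- x$emmeans
  dist <- sort(unique(as.integer(as.character(em$distance))))
  conds <- levels(em$condition)
  m <- sapply(conds, function(cc) {
    em$emmean[em$condition == cc][order(as.integer(as.character(em$distance[em$condition == cc])))]
  })
  graphics::matplot(dist, m, type = "b", pch = c(1, 16), lty = c(2, 1),
                    col = c("grey40", "black"),
                    xlab = "Distance (turns back)",
                    ylab = "Estimated marginal mean syntactic similarity",
                    main = sprintf("%s-similarity: real vs chance", x$relation),
                    ...)
  for (cc in seq_along(conds)) {
    sub <- em[em$condition == conds[cc], ]
    o <- order(as.integer(as.character(sub$distance)))
    graphics::arrows(dist, sub$lower.CL[o], dist, sub$upper.CL[o],
                     angle = 90, code = 3, length = 0.03,
                     col = c("grey40", "black")[cc])
  }
  graphics::legend("topright", legend = conds, pch = c(1, 16), lty = c(2, 1),
                   col = c("grey40", "black"), bty = "n")
  invisible(x)
}

#' Export a model result as JSON
#'
#' @param x a `divergence_fit` object.
#' @param path output file.
#' @export
write_model_json <- function(x, path) {
  out <- list(relation = x$relation,
              fixed_effects = x$fixed_effects,
              covariate_slope = x$covariate_slope,
              emmeans = x$emmeans,
              contrasts = x$contrasts,
              n_cells = x$n_cells,
              n_persons = x$n_persons,
              n_dropped = x$n_dropped,
              singular = x$singular)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
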