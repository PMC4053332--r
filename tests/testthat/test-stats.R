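make_cells <- function(n_person = 6, relation = "other", noise = 0.02,
                       cond_shift = 0, seed = 1) {
  # balanced person x condition x distance grid with a person intercept
  set.seed(seed)
  grid <- expand.grid(person = paste0("p", seq_len(n_person)),
                      relation = relation,
                      condition = c("chance", "real"),
                      distance = 1:5,
                      stringsAsFactors = FALSE)
  pint <- stats::setNames(stats::rnorm(n_person, 0, 0.03), unique(grid$person))
  grid$mean_lexical <- stats::runif(nrow(grid), 0.02, 0.2)
  grid$mean_syntactic <- 0.2 + pint[grid$person] +
    0.5 * grid$mean_lexical +
    ifelse(grid$condition == "real", cond_shift, 0) +
    stats::rnorm(nrow(grid), 0, noise)
  grid$n_pairs <- 10L
  grid
}

test_that("Holm adjustment reproduces the hand-computed step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4))
  expect_equal(holm_adjust(rep(0.3, 5)), rep(1, 5))  # capped at 1
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(0.5, NA)), "\\[0, 1\\]")
  # order invariance and monotonicity
  set.seed(5)
  p <- stats::runif(12)
  o <- sample.int(12)
  expect_equal(holm_adjust(p)[o], holm_adjust(p[o]))
  expect_true(all(diff(sort(holm_adjust(p))) >= -1e-12))
  expect_true(all(holm_adjust(p) >= p))
})

test_that("per-person aggregation averages non-missing records per cell", {
  one <- data.frame(person = "p1", relation = "other", distance = 1L,
                    condition = "real", lexical = 0.25, syntactic = 0.5)
  cell <- aggregate_by_person(one)
  expect_identical(nrow(cell), 1L)
  expect_identical(cell$mean_syntactic, 0.5)
  expect_identical(cell$n_pairs, 1L)

  # all-missing cells survive with n_pairs 0 and NA means
  rec <- rbind(one,
               data.frame(person = "p1", relation = "other", distance = 5L,
                          condition = "real", lexical = NA_real_,
                          syntactic = NA_real_))
  cells <- aggregate_by_person(rec)
  d5 <- cells[cells$distance == 5L, ]
  expect_identical(d5$n_pairs, 0L)
  expect_true(is.na(d5$mean_syntactic))

  # chance_* labels collapse onto the two-level condition factor
  rec2 <- data.frame(person = "p1", relation = "other", distance = 1L,
                     condition = c("chance_other", "chance_other"),
                     lexical = c(0.1, 0.3), syntactic = c(0.2, 0.4))
  c2 <- aggregate_by_person(rec2)
  expect_identical(c2$condition, "chance")
  expect_equal(c2$mean_syntactic, 0.3)
})

test_that("worked-example aggregation equals the arithmetic mean of the records", {
  rec <- window_similarities(fixture_table2())
  cells <- aggregate_by_person(rec)
  b1 <- cells[cells$person == "B" & cells$relation == "other" &
                cells$distance == 1L, ]
  raw <- rec$lexical[rec$person == "B" & rec$relation == "other" &
                       rec$distance == 1L]
  expect_equal(b1$mean_lexical, mean(raw, na.rm = TRUE))
  expect_identical(b1$n_pairs, 5L)
})

test_that("identical condition values give a zero real-chance difference", {
  cells <- make_cells(n_person = 6, cond_shift = 0, noise = 0.02, seed = 3)
  # force the two conditions identical cell-by-cell
  ch <- cells[cells$condition == "chance", ]
  re <- ch; re$condition <- "real"
  fit <- fit_divergence(rbind(ch, re), relation = "other")
  expect_true(all(abs(fit$contrasts$estimate) < 1e-8))
  em <- fit$emmeans
  for (d in 1:5) {
    vals <- em$emmean[em$distance == d]
    expect_equal(vals[1], vals[2])
  }
})

test_that("the divergence fit reports effects, slope and adjusted contrasts", {
  cells <- make_cells(n_person = 8, cond_shift = -0.05, seed = 11)
  fit <- fit_divergence(cells, relation = "other")
  expect_s3_class(fit, "divergence_fit")
  expect_true(all(is.finite(fit$emmeans$emmean)))
  expect_true(all(fit$contrasts$p_holm >= fit$contrasts$p_raw - 1e-12))
  expect_identical(nrow(fit$contrasts), 5L)
  # built-in shift is recovered with the right sign
  expect_lt(mean(fit$contrasts$estimate), 0)
  cond_p <- fit$fixed_effects$p[fit$fixed_effects$term == "condition"]
  expect_lt(cond_p, 0.05)
  # covariate slope close to the generating 0.5
  expect_gt(fit$covariate_slope, 0.2)
  # methods run
  expect_output(print(fit), "Condition")
  expect_output(summary(fit), "contrasts")
  expect_length(coef(fit), 20L)
  expect_identical(length(residuals(fit)), fit$n_cells)
})

test_that("incomplete cells are dropped listwise and reported", {
  cells <- make_cells(n_person = 5, seed = 21)
  cells$mean_syntactic[c(3, 17)] <- NA
  fit <- fit_divergence(cells, relation = "other")
  expect_identical(fit$n_dropped, 2L)
  expect_identical(fit$n_cells, nrow(cells) - 2L)
})

test_that("degenerate inputs are refused with clear errors", {
  cells <- make_cells(n_person = 4, seed = 31)
  expect_error(fit_divergence(cells[cells$person == "p1", ], "other"),
               "at least 2 persons")
  expect_error(fit_divergence(cells[cells$condition == "real", ], "other"),
               "both real and chance")
  expect_error(fit_divergence(cells, relation = "self"), "no cells")
})

test_that("condition p-values are roughly uniform under label permutation", {
  # within-person real/chance label flips on small null corpora; permutation
  # p-values are pooled over independent corpora, since a single dataset
  # conditions its whole permutation distribution
  pvals <- unlist(lapply(1:10, function(k) {
    fit0 <- divergence_experiment(seed = 2600 + k, relation = "other",
                                  n_dialogues = 6L, turns_per_dialogue = 15L,
                                  reps = 1L)
    cells <- attr(fit0, "cells")
    set.seed(900 + k)
    replicate(20, {
      perm <- cells
      for (p in unique(perm$person)) {
        if (stats::runif(1) < 0.5) {
          sel <- perm$person == p
          perm$condition[sel] <- ifelse(perm$condition[sel] == "real",
                                        "chance", "real")
        }
      }
      f <- fit_divergence(perm, relation = "other", contrasts = FALSE)
      f$fixed_effects$p[f$fixed_effects$term == "condition"]
    })
  }))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(mean(pvals < 0.05), 0.15)
})
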