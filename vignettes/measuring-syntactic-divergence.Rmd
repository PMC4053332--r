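---
title: "Measuring lexical and syntactic divergence in dialogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lexical and syntactic divergence in dialogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnsim)
```

## The question

Do people reuse each other's syntactic constructions in ordinary
conversation more than chance would predict — as automatic structural
priming accounts expect — or less? `turnsim` implements the measurement
pipeline needed to ask that question of any corpus of parsed dialogue
transcripts, and a dialogue simulator that lets the whole pipeline be
validated end to end, with known ground truth, before it is pointed at
real data.

## Similarity between turns

The unit of comparison is the speaker turn. Two statistics quantify the
repetition between a pair of turns, both Dice-normalised so that 0 means
no match and 1 a verbatim repeat.

**Lexical similarity.** Let $A$ and $B$ be the multisets of words in the
two turns (lowercased comparison forms). With
$m = \sum_w \min(A(w), B(w))$ matching word pairs — a maximal one-to-one
matching between token occurrences —

$$\mathrm{lex}(a,b) = \frac{2m}{|A| + |B|}.$$

The `min`-of-counts matching (rather than a cross product) is what keeps
the statistic inside $[0,1]$; the factor 2 is the unique normalisation
"for the total number of words in the two turns combined" under which a
verbatim repeat scores exactly 1.

**Syntactic similarity.** Every non-terminal node of a constituency
parse roots exactly one *complete subtree* (the node with all its
descendants). `enumerate_subtrees()` reduces each subtree to a canonical
key over category labels only: lexical leaves are dropped and a
preterminal (part-of-speech node) is represented by its bare label. Two
turns' parse forests then yield two multisets of keys, intersected and
normalised exactly as above. Dropping the words from the keys is
deliberate: lexical repetition is measured separately, and the analysis
covaries it out, so it must not be double-counted inside the syntactic
measure. Preterminals count as structures by default
(`include_preterminals = TRUE`); they are non-terminals in both
hand-annotated and CCG-style parses, but the switch is exposed because
the choice shifts the absolute similarity level.

Tokenization is whitespace splitting with lowercase comparison forms,
pure-punctuation tokens removed, and clitic contractions kept attached
(`"she's"` is one token). Transcription conventions differ enough across
corpora that no single policy can be canonical; this one reproduces
every zero-valued lexical cell of the worked example exactly
(`fixture_table2()`), while the non-zero published example values are
sensitive to the (unpublished) original tokenizer and are therefore
treated as indicative rather than as targets.

Degenerate inputs: a turn with no parsed sentences contributes a
*missing* syntactic score, not 0 — absence of annotation is not absence
of structure. Lexical similarity is missing only when both turns carry
no words at all.

## The moving window

For each turn a person produces, `window_similarities()` pairs it with
the 1st–5th most recent prior turns by their interlocutors
(other-similarity) and by themselves (self-similarity): a ten-turn
moving window. Distance is counted within the partner (or own) turn
stream, so in a strictly alternating two-party dialogue other-distance
$d$ is raw offset $2d-1$ and self-distance $d$ is offset $2d$; in
multi-party dialogues all interlocutors pool into a single "other"
stream, since the question is person-versus-interlocutors rather than
pairwise. Turns near the start of a conversation that lack a context
turn at some distance produce records with missing values, so the
design stays balanced: every turn yields exactly ten records. A
raw-offset alternative (`distance_mode = "offset"`) is provided because
published descriptions of window distance are ambiguous between the two
readings; the stream reading is the default because it is the one under
which an alternating dialogue populates all five context columns with
consecutive partner turns.

## Chance baselines

Observed similarity is meaningless without an estimate of how much
repetition arises by chance from people speaking the same language
about the same kinds of things. Two randomised counterpart conversations
provide it:

* **Chance Other** (`make_chance_other()`): a person's real turns stay
  in sequence and position; every other-speaker slot is filled by a turn
  drawn uniformly at random from the *other* dialogues of the corpus.
  Sampling is with replacement — no exhaustion constraint is imposed —
  and the donor pool excludes the whole target dialogue, not just the
  target person.
* **Chance Self** (`make_chance_self()`): the person's own turns are
  paired with a uniform random re-ordering of those same turns under the
  constraint that no turn is matched with itself — a derangement,
  sampled by seeded rejection (uniform over derangements by
  construction). The constraint bars same-position self-matches only; a
  turn can still meet its own content at a non-zero distance, as in any
  randomisation of this kind. Persons with fewer than two turns are
  skipped with a warning, since no derangement exists.

Both schemes preserve each person's own turns exactly, so speaker and
language are counterbalanced across the real and chance conditions, and
whatever difference remains is attributable to the interaction itself.
All randomisation is seeded; the per-slot source mapping is attached to
the chance dialogue for audit. The `reps` argument averages several
chance realisations per person, which reduces Monte-Carlo noise in the
chance cell means at small corpus sizes.

## The statistical model

`aggregate_by_person()` averages records into one cell per person ×
relation × condition × distance. `fit_divergence()` then models the
per-person mean syntactic similarity for one relation:

```
mean_syntactic ~ condition * distance * mean_lexical + (1 | person)
```

with condition (real vs chance) and distance (a 5-level categorical
factor, since per-level contrasts are the quantity of interest) as
repeated fixed factors, mean lexical similarity as a covariate to
separate the lexical-boost pathway from genuinely structural repetition,
and a person random intercept giving a compound-symmetry covariance over
the repeated cells. Modelling cell means rather than record-level data
matches the design in which each person contributes one observation per
cell; no crossed record-level random effects are attempted.

Choices that the design left open, fixed here: F-tests are Type III with
Satterthwaite denominator degrees of freedom (Kenward–Roger would add a
heavier dependency for no change at these cell counts); the covariate
slope is reported unstandardised; factors are sum-coded so that the
slope is evaluated at the factor means; cells with missing means are
dropped listwise with the count reported in the fit object. Marginal
means per condition × distance are computed at the covariate mean, and
the real − chance contrast at each distance is tested with Holm's
step-down adjustment (`holm_adjust()`, delegating to
`stats::p.adjust`) at a criterion level of 0.05. A singular
random-effect fit is flagged on the object and printed, never silently
replaced by a simpler model.

## The dialogue simulator

`generate_corpus()` emulates the hypothesised priming mechanism
directly, so that the pipeline can be validated by parameter recovery.
Two speakers alternate; each turn contains $1 + \mathrm{Poisson}(\mu-1)$
sentences sampled top-down from a small PCFG (8 phrasal categories, 17
productions, 9 preterminals, 60 words — `default_grammar()`). At every
choice point the log-probability of each candidate production is shifted
by $\lambda_{\mathrm{syn}} \cdot w$, where $w$ is the recency-weighted
count of that production in the partner's last five turns with weights
$e^{-d/\tau}$ at partner-distance $d$, and the distribution is
renormalised; word choices are shifted analogously by
$\lambda_{\mathrm{lex}}$. The additive log-space shift keeps every
distribution proper for any $\lambda \in (-1, 1)$ and makes the null
exact: at $\lambda = 0$ turns are i.i.d. from the base grammar, so real
and chance similarity coincide by construction. Positive $\lambda$
produces convergence, negative $\lambda$ divergence, and small $\tau$
concentrates the effect at distance 1.

Default study conditions: 20 dialogues of 30 turns, $\mu = 1.5$
sentences per turn, $\tau = 2$, two chance realisations per person in
`divergence_experiment()`. Twenty dialogues give 40 simulated persons,
enough for the mixed model's asymptotics to behave; 30 turns give each
person roughly 13 fully populated windows, which pilot simulation during
design showed is the scale at which a $|\lambda_{\mathrm{syn}}| = 0.8$
regime is recovered reliably in both directions while a null corpus
stays at the nominal false-positive rate. A maximum derivation depth of
10 forces recursion down the shallowest production, bounding sentence
length without re-weighting the bulk of the distribution.

What the simulator deliberately does *not* reproduce: discourse
structure (questions licensing answers, corrections, elaborations),
topic drift, disfluencies, overlapping speech, and the long-tailed turn
length and vocabulary distributions of real conversation. Passing the
recovery suite therefore shows that the pipeline detects the priming
mechanism when it is present and stays quiet when it is absent — it does
not show that real conversation contains (or lacks) that mechanism.

## Worked example

The ten-turn fixture and its randomised counterpart reproduce the
structure of the published example conversation; the attached parse
forests are toy parses written for this package (the source corpus
annotation is licensed and not redistributable), so only the lexical
zero cells are exact reference points:

```{r example}
rec <- window_similarities(fixture_table2())
subset(rec, target_index == 7 & relation == "other",
       select = c(distance, context_index, lexical, syntactic))
```

The `yeah really` turn shares no words with any of the four preceding
partner turns: all populated lexical cells are exactly 0, while its toy
parses still share structure with them.

## Numerical and degenerate-input notes

* Similarity denominators of zero yield missing values, never `NaN`.
* Derangement sampling is rejection-based; the acceptance rate is
  $\approx 1/e$, so it terminates quickly for any $n \ge 2$.
* `make_chance_other()` refuses a single-dialogue corpus (there is no
  "rest of the corpus" to sample from).
* Random seeds: every randomised operation takes an explicit seed, and
  corpus-level drivers derive per-person substream seeds from the master
  seed, so results are reproducible and independent of call order.
  All derived seeds stay below $2^{31}$.
* Distance-1 contrasts are read from the Holm-adjusted table; with five
  distances the adjustment at most quintuples the raw p-value.

## Known limitations

* The tokenizer is intentionally simple; corpora with heavy punctuation,
  markup or disfluency coding should be normalised before ingestion.
* Syntactic similarity compares parses as given: two corpora parsed with
  different grammars or formalisms are not comparable on absolute level
  (the chance baseline, built from the same corpus, absorbs this for
  within-corpus comparisons).
* The mixed model assumes cell means are approximately normal;
  similarity means over very few pairs (short dialogues) are coarse,
  and such cells carry the same weight as well-estimated ones.
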