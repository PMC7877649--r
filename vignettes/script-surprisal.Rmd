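---
title: "Estimating event predictability from script knowledge corpora"
author: "scriptsurp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating event predictability from script knowledge corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scriptsurp)
```

## The problem

Predictability effects in language — faster reading, phonetic reduction,
omission of predictable material — are usually quantified with n-gram
language models over *words*, i.e. through local linguistic context. But
many utterances are predictable from the *situation* alone: a passenger
entering a taxi is likely to name a destination before saying a single
word. `scriptsurp` operationalizes this extralinguistic predictability
through **script knowledge**: stereotyped knowledge of the typical
events, order and participants of everyday activities (cooking pasta,
riding a train). The package turns crowd-sourced **event-sequence
descriptions** (ESDs) — one contributor's ordered list of short textual
descriptions of a scenario's events — into:

1. canonical **event labels** (main verb + post-verbal noun, e.g.
   `pour pasta`),
2. a **bigram event language model** giving transition probabilities
   $p(e_j \mid e_i)$ between events,
3. **event surprisal** $-\log_2 p(e_j \mid e_i)$ in bits,
4. maximum-likelihood **event chains** and 2 × 2
   (Predictability × Sententiality) **stimulus specifications** for
   acceptability experiments, and
5. a **cumulative link mixed model** (CLMM) analysis of the resulting
   7-point Likert ratings, with likelihood-ratio backward selection.

A synthetic-data layer generates ESD corpora from a known probabilistic
script graph and rating tables from a known ordinal mixed model, so
every stage can be validated against ground truth.

## Event labels

Raw descriptions of one and the same event differ in lexical choice,
syntax and explicitness ("Pour eggs into the pan", "Put contents of
bowl in pan", "Pour them into a pan", "Pour in pan"). If each variant
kept its own label, the probability mass of the event would be split
among them. Labeling therefore proceeds in three steps:

- **Parsing.** Parsing is a *provider contract* — any function
  returning tokens, POS tags, a head-verb index and an object index can
  stand behind `parse_description()`. The bundled `fallback_parse()` is
  a deterministic rule-based parser tuned to the genre (short verb-first
  imperatives, frequent object ellipsis): the first verb-list token (or
  a plausible sentence-initial verb) is the head; the first noun or
  pronoun after it, skipping determiners/adjectives/adverbs, is the
  object; a preposition encountered first signals ellipsis. Statistical
  parsers mislabel exactly these structures unless retrained, so a
  deterministic fallback keeps the pipeline testable offline; plug in a
  trained provider for production corpora.
- **Normalization.** A machine-readable `normalization_lexicon()`
  replaces interactive curation: pronoun resolution, default objects for
  elided arguments, synonym pooling (*pan*/*skillet*), and whole-label
  event mapping, applied in that order. All maps must be fixed points,
  which makes normalization **idempotent** — a property test in the
  suite.
- **Screening.** `label_corpus()` emits a `uniqueness_report`: merge
  candidates (same verb with nouns within edit distance 2, or vice
  versa), unresolved placeholders, and the action/participant
  inventories. Curation thus becomes versioned data plus a report,
  rather than an undocumented manual pass.

Lemmatization is dictionary-plus-rules (irregular list, plural and
inflection stripping), lowercase throughout — deterministic and
locale-independent, which matters for reproducible tests. The
`PLACEHOLDER` sentinel marks unresolved objects; the language-model
module refuses sequences containing it, so unresolved items must be
fixed or explicitly excluded.

## The event language model

`fit_ngram()` wraps every label sequence in begin/end boundary markers
and counts n-grams; the default order is 2. With on the order of 100
sequences per scenario, higher orders are not reasonably estimable, and
the bigram transition probability is precisely the quantity of
interest: the likelihood of an event to follow another.

- **Smoothing** defaults to raw maximum likelihood. Stimulus
  construction needs events with *exact* probability 0 given a context
  (the unpredictable condition), and only the unsmoothed model has
  them. Add-k smoothing is available (`smoothing = "add_k"`) for
  robustness experiments.
- **Zero probabilities** map to an explicit infinite-surprisal sentinel
  (`Inf`), never an exception, so chains and reports can carry them.
- **Boundary convention.** Begin/end markers give first events a
  defined conditional probability. They are excluded from the unigram
  vocabulary size; `vocab_stats()` excludes boundary bigrams by default
  (a single documented switch includes them).
- Conditional distributions are validated to sum to 1 within 1e-9 per
  context, in both smoothing modes.

`bits_to_percent()` converts surprisal to an intuitive probability
percentage, $100 \cdot 2^{-bits}$: 2.13 bits ≙ 22.8%, 2.18 bits ≙
22.1%.

## Chains and stimuli

`extract_chain()` performs a greedy walk: from a start event (by
default the most likely eligible opener, i.e. the argmax successor of
the begin marker — the start criterion is otherwise underdetermined),
repeatedly append the **eligible, not-yet-visited successor with
maximal conditional probability**. Three design choices make this
deterministic and terminating:

- **Eligibility**: events with unigram count below `min_count`
  (default 8) are never selected — a rare event mentioned by one
  contributor should not represent the population's script knowledge.
  The threshold applies to selection only, never to model fitting.
- **Ties** break lexicographically on the label string.
- **No revisits**: scripts are linear in intent; revisiting would loop
  on symmetric data. When no eligible unvisited successor has positive
  probability the chain stops early, flagged.

`build_stimulus()` takes the first three chain events as the context
story and the fourth as the predictable target, recording the target's
surprisal and the chain's mean surprisal; by default the context is a
contiguous chain prefix (re-seeding per position is possible by
extracting chains from different starts). `propose_unpredictable()`
screens human-proposed candidates down to those with probability 0
after the context (or absent from the scenario entirely) — judging
their intuitive plausibility remains a human task.

## Synthetic data: what it emulates, what it does not

`script_graph()` + `sample_esd_corpus()` generate corpora with known
truth: each ESD is a path through a row-stochastic transition matrix
with an explicit terminal state (so lengths vary realistically around
the 5–6 events typical of real ESDs), rendered as text through a noise
channel (synonym substitution, pronoun use, object ellipsis, event
skipping) with deterministic templates (`"<Verb> the <noun>"`). The
companion `graph_lexicon()` is constructed to invert that channel
exactly.

The generator emulates the *structural* properties that matter for the
pipeline — lexical variation, granularity differences, varying lengths,
transition stochasticity — and deliberately not naturalistic syntax,
morphology, or annotator misbehavior. A perfect round trip on synthetic
corpora therefore shows that labeling + modeling invert the modeled
noise; it does not certify parser accuracy on arbitrary natural text
(that is the parsing provider's job).

`sample_ratings()` generates 7-point Likert tables from a known
cumulative-logit mixed model: sum-coded ±1 fixed effects on a latent
logistic scale, independent normal random intercepts/slopes by subject
and by item, thresholds cutting the latent value into categories, and a
2 × 2 Latin square (each subject sees each item once, `n_items/4`
per condition). Generator defaults are fixed once as the study
conditions of the accompanying case study: 48 subjects, 24 items, fixed
effects at the reported estimates (Sententiality −0.958, Predictability
−0.554, ScriptFamiliarity −0.012, Position −0.021,
Sententiality:Predictability −0.22, Predictability:ScriptFamiliarity
−0.206; unreported terms 0), thresholds equally spaced −2.5…2.5
(symmetric, plausibly spanning the scale), random SDs 1.0/0.5
(subject intercept/Sententiality slope) and 0.5/0.25 (item) — values a
rating study of this size typically shows. Latent noise is standard
logistic so recovery tests are well-specified against the analysis
model. Five ungrammatical control trials per subject are generated from
a strongly negative latent shift to exercise the exclusion rule.

## The ordinal mixed model

`fit_clmm()` maximizes the cumulative-logit mixed likelihood:

$$P(Y_i \le k) = \mathrm{logit}^{-1}(\theta_k - x_i^\top\beta - z_i^\top b),
\qquad b \sim N(0, \Sigma)$$

with strictly ordered thresholds $\theta_1 < \dots < \theta_6$ and
crossed subject/item random effects. Numerical choices, all fixed for
reproducibility:

- **Laplace approximation.** For candidate random-effect SDs, the
  thresholds, coefficients and random effects are jointly profiled by a
  damped Newton solve of the penalized joint log-likelihood (the
  cumulative-logit log-likelihood is concave in $(\theta, \beta)$, and
  the Gaussian penalty keeps the joint problem well-behaved); the
  marginal likelihood is approximated at that mode and the outer
  optimizer (`nlminb`, relative tolerance 1e-8, box 1e-4…20 on the SD
  scale) works on the log-SD scale only.
- **Starting values**: thresholds at the marginal category logits,
  coefficients and random effects at 0, SDs at 0.5.
- **Diagonal $\Sigma$.** Random intercepts and slopes are independent
  (the `||` convention of mixed-model practice). Full correlation
  matrices of the case study's maximal structure are not reliably
  identifiable at 48 × 24, and the reduction keeps the outer
  optimization low-dimensional. This is the package's own reduction of
  the published model's structure.
- **Standard errors** come from the Schur complement of the joint
  Hessian (variance parameters held at their estimates) — the standard
  conditional covariance of mixed-model software. On 20 simulated
  replicates at design scale the estimates are unbiased and the SEs
  match the empirical spread.
- **Degenerate inputs**: categories unobserved at the scale ends are
  collapsed (their thresholds are not identifiable); step-halving
  guards threshold ordering; non-convergence is flagged on the fit,
  never silent.
- With zero random variance the fit reduces to a plain cumulative
  logit; the suite cross-checks this path against an independent
  proportional-odds implementation to 1e-3.

`prepare_design()` codes the predictors: the *marked* level (fragment,
unpredictable, adapted) is +1, so negative coefficients mean "the
marked level lowers ratings", matching the reported signs. Familiarity
is z-scored pooled over subject × scenario observations (the
within-subject alternative is a switch away); missing familiarity
scores are retained at the z-scale mean 0 with an auditable
missingness flag — a simple, explicit mechanism chosen because the
original analysis names none.

`exclude_subjects()` implements the control screen: a subject is
removed when *strictly more than* `min_flagged = 2` of their
ungrammatical controls received a rating ≥ 6. `backward_select()`
drops, at each step, the least significant droppable term whose LR
p-value is at or above `alpha` (0.05 default), respecting marginality
(a term is droppable only while no retained interaction contains it);
the random structure is held fixed, and the full decision trail is
returned. `alpha = 0` keeps the full model, `alpha >= 1` removes every
droppable term.

## Validation and problem sizes

The test suite validates each stage at sizes chosen to make the
statistical checks sharp yet quick to regenerate:

- event-model probabilities against an independent brute-force counter
  on 100+ random toy corpora (equality to 1e-12);
- every chain transition against a brute-force argmax over eligible
  unvisited successors on 100+ random models;
- lossless labeling round trips on noise-free and full-pronoun-noise
  synthetic corpora (100 ESDs);
- transition recovery on a 3-state graph with $p = 0.7/0.3$ branches
  at 2000 ESDs: maximum absolute error below 0.05 across 10 seeds, as
  the binomial standard error ($\approx \sqrt{0.21/2000} \approx 0.01$)
  predicts;
- CLMM recovery at 48 subjects × 24 items over 20 replicates: ~96% of
  fitted fixed effects fall within 2 SE of the generating values;
- the zero-variance reduction against the independent
  proportional-odds oracle.

One caveat worth stating: the spec-style intuition that raising
`min_count` can only shorten chains holds in the typical case but is
not a theorem — excluding a high-probability dead-end successor can in
principle reroute the greedy walk onto a longer path. The suite
exercises the typical-case monotonicity on randomized models; the
argmax property, which *is* invariant, is checked unconditionally.

## Known limitations

- The rule-based parser is a genre heuristic, not a general dependency
  parser; out-of-lexicon verbs in non-initial position are missed.
  The provider contract exists precisely so a trained parser can be
  substituted.
- Pronoun resolution is lexicon lookup, not coreference modeling; a
  pronoun maps to one canonical noun per scenario (or through
  verb-specific event mappings).
- The CLMM uses Laplace (one quadrature point); for very sparse
  categories adaptive quadrature would be more accurate.
- Reproducing a published scenario's absolute vocabulary or bigram
  counts requires that corpus and its curation lexicons; the package
  validates the machinery on generated data instead.
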