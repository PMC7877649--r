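# scriptsurp

Estimating the predictability of everyday events from **script
knowledge** corpora — and validating that the estimates behave like
predictability in a rating experiment.

Psycholinguistic predictability effects (reduction, omission, faster
reading) are usually quantified with *n*-gram models over words, which
only capture local linguistic context. Utterances can however be
predictable from the situation alone: a passenger entering a taxi will
probably name a destination. `scriptsurp` approximates such
extralinguistic context with scripts — stereotyped knowledge of the
events of everyday activities — estimated from crowd-sourced
**event-sequence descriptions** (ESDs). The pipeline:

1. **Corpus I/O** — ESD corpora in a documented XML dialect or a
   tabular TSV/CSV dialect (`read_corpus_xml()`, `read_corpus_table()`).
2. **Event labeling** — each description becomes a canonical
   *verb + noun* label (`pour pasta`) via a pluggable parser (a
   deterministic rule-based `fallback_parse()` is bundled) and a
   machine-readable normalization lexicon (synonyms, pronouns, default
   objects, event pooling), with a uniqueness-screening report
   (`label_corpus()`).
3. **Event language model** — bigram transition probabilities
   `p(e_j | e_i)` over event labels and **surprisal**
   `−log2 p(e_j | e_i)` in bits (`fit_ngram()`, `surprisal()`,
   `bits_to_percent()`).
4. **Event chains & stimuli** — greedy maximum-likelihood chains over
   the event network, with a frequency eligibility cutoff (n ≥ 8 by
   default), and 2 × 2 Predictability × Sententiality stimulus
   specifications: three context events, the argmax successor as the
   predictable target, zero-probability candidates as unpredictable
   targets (`extract_chain()`, `build_stimulus()`,
   `propose_unpredictable()`).
5. **Rating analysis** — control-based subject exclusion, sum coding
   and familiarity z-scoring, a **cumulative link mixed model**
   (Laplace approximation, crossed subject/item random effects,
   implemented in-package) and likelihood-ratio backward selection
   (`exclude_subjects()`, `prepare_design()`, `fit_clmm()`,
   `backward_select()`).
6. **Synthetic data with ground truth** — ESD corpora sampled from a
   known probabilistic script graph through a lexical noise channel,
   and Likert tables from a known ordinal mixed model
   (`script_graph()`, `sample_esd_corpus()`, `sample_ratings()`), so
   every stage is testable against truth.

## Worked example

A six-ESD demonstration corpus and its curation lexicon ship with the
package (both synthetic, hand-written):

```r
library(scriptsurp)

cp  <- read_corpus_xml(system.file("extdata", "demo_pasta_corpus.xml",
                                   package = "scriptsurp"))
lex <- read_lexicon(system.file("extdata", "demo_lexicon",
                                package = "scriptsurp"))
lc  <- label_corpus(cp, lex)
lc$sequences[["d02"]]
#> [1] "put water"   "turn stove"  "boil water"  "pour pasta"  "stir pasta"
#> [6] "drain pasta"
```

Raw descriptions as different as "Fill the pot", "Put the water in"
and "Put water in a pot" all normalize to `put water`, so the event's
probability mass is not split across lexicalizations. Fit the event
model and build a stimulus:

```r
m <- fit_ngram(lc)
m
#> <transition_model> scenario: cooking pasta
#>   order 2, smoothing mle, 6 sequences
#>   vocabulary 7 event labels, 8 distinct observed 2-grams

ch <- extract_chain(m, length = 4, min_count = 4)
ch
#> <event_chain> scenario: cooking pasta
#>   put water -> turn stove -> boil water -> pour pasta
#>   p: 0.667, 1.000, 1.000

st <- build_stimulus(m, ch, script_type = "adapted")
st
#> <stimulus_spec> scenario: cooking pasta
#>   context: put water -> turn stove -> boil water
#>   predictable target: pour pasta (0 bits, 100.0%)
#>   unpredictable target: (unset)

propose_unpredictable(m, "boil water", c("set table", "drain pasta"))
#> [1] "set table"   "drain pasta"
```

Read: after `boil water`, `pour pasta` is the most likely successor —
in this tiny corpus it is certain (surprisal 0 bits, probability
100%), so an utterance referring to it is maximally predictable in
context. Both proposed alternatives have probability 0 after `boil
water` and qualify as unpredictable targets; which of them is
*plausible* remains a human decision. Surprisal converts to an
intuitive probability with `bits_to_percent()`: e.g. 2.13 bits ≙
22.8%.

At the analysis end, simulate a rating experiment at its design size
(48 subjects × 24 items, 2 × 2 Latin square) and refit:

```r
tab <- sample_ratings(rating_sim_spec(), seed = 1)
des <- prepare_design(exclude_subjects(tab)$table)
fit_clmm(des, final_rating_spec())
#> Cumulative link mixed model (Laplace), logit link
#>   n = 1152, logLik = -1976.82
#>   random-effect SDs:
#>     subject_intercept            0.963
#>     subject_sententiality        0.449
#>     item_intercept               0.369
#>     item_sententiality           0.296
#>   fixed effects:
#>     sententiality                          -0.901  (SE 0.105)
#>     predictability                         -0.541  (SE 0.054)
#>     familiarity                            -0.085  (SE 0.061)
#>     position                               -0.023  (SE 0.008)
#>     sententiality:predictability           -0.242  (SE 0.053)
#>     predictability:familiarity             -0.272  (SE 0.055)
#>   thresholds: -2.50 -1.57 -0.52 0.44 1.47 2.45
```

Negative coefficients mean the marked level (fragment, unpredictable)
lowers the ratings; estimates land near the generator's coefficients.

A thin CLI wraps these functions: see `inst/cli/scriptsurp.R`
(`corpus summarize`, `label`, `fit`, `surprisal`, `chain`, `stimuli`,
`simulate`, `analyze`).

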