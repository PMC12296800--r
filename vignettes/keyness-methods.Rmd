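---
title: "Keyness analysis with an informative Dirichlet prior: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyness analysis with an informative Dirichlet prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warkeys)
```

## The problem

Witness testimony collected during an ongoing war carries a lexical
signature: some words are used far more often than in comparable peacetime
writing, others far less. *Keyness analysis* quantifies this by comparing
the lemma frequency list of a target corpus (here, wartime testimony
narratives with participant demographics and PTSD/moral-injury scores)
against a reference corpus of a similar genre collected before the war.
`warkeys` implements the whole chain: ingesting the two release formats of
such a corpus (a narrative-level CSV and a token-level CoNLL-U table),
participant exclusion, de-identification, stopword removal, lemma
counting, the zero-filled merge of two frequency lists, the keyness
statistic itself, and family-wise control over the tens of thousands of
simultaneous per-lemma tests.

## The statistic

For lemma $w$ with count $y^i_w$ in the target corpus of $n^i$ tokens and
$y^j_w$ in the reference corpus of $n^j$ tokens, the log-odds ratio with
informative Dirichlet prior (LORIDP) is

$$\delta_w = \log\frac{y^i_w + \alpha_w}{n^i + \alpha_0 - (y^i_w + \alpha_w)}
          - \log\frac{y^j_w + \alpha_w}{n^j + \alpha_0 - (y^j_w + \alpha_w)},$$

with prior pseudo-counts taken from the pooled corpora:
$\alpha_w = y^i_w + y^j_w$ and $\alpha_0 = n^i + n^j$. Its variance is
approximated by

$$\sigma^2(\delta_w) \approx \frac{1}{y^i_w + \alpha_w} + \frac{1}{y^j_w + \alpha_w},$$

and the keyness score is the standardized $z = \delta_w / \sigma(\delta_w)$.
Positive $z$ marks lemmas diagnostic of the target corpus, negative $z$
lemmas diagnostic of the reference. All logs are natural; the prior is
always recomputed from the two supplied tables — no externally estimated
prior is supported, because $\alpha_w$ and $\alpha_0$ are *defined* in
terms of the pooled corpora.

### What the pooled-count prior does to the estimate

This prior is as heavy as the data themselves: every lemma receives its
own pooled count as pseudo-counts. Two consequences matter for
interpretation and are verified by the test suite:

* **Shrinkage.** The point estimate does not converge to the raw
  population log-odds difference but to the log-odds difference of the
  *prior-blended* proportions. At equal corpus sizes, a true odds ratio
  $\rho$ yields $\delta \to \log\{(2\rho + 1)/(\rho + 2)\}$ in large
  samples — e.g. a four-fold enrichment appears as
  $\delta \approx \log 1.5$, not $\log 4$. `implied_loridp()` evaluates
  this large-sample target exactly from population probabilities, and the
  synthetic generator's truth record stores it alongside the unshrunken
  population log-odds, so parameter-recovery simulations compare the
  estimator against the value it actually estimates.
* **Conservative z.** Because $\alpha_w$ itself grows with the observed
  counts, the variance formula overstates the true sampling variance
  (roughly three-fold at the null with equal corpus sizes), deflating
  $|z|$. The Bonferroni bound on the family-wise error rate therefore
  holds with a wide margin; the score is best read as a conservative
  ranking statistic rather than a calibrated test statistic.

Neither property is a defect of the implementation — both follow from the
prior's definition, which this package reproduces exactly.

### Multiplicity and the tail convention

With $m$ lemmas tested jointly, `bonferroni_threshold(alpha, m, tail)`
returns the standard-normal quantile at $\alpha/m$ (one-sided, the
default) or $\alpha/(2m)$ (two-sided). The default is one-sided because
the widely used critical value $|z| = 5.10$ for $\alpha = 0.01$ over a
59,190-lemma combined list is the upper quantile at $0.01/59190$; the
two-sided quantile would be $\approx 5.23$. Both conventions are
implemented and the convention used is recorded in every `keyness_run`;
neither is presented as uniquely correct, and under either one the
selection rule is symmetric in the two corpora.

## Preprocessing conventions

* **Normalization.** Before any counting or comparison, text is NFC
  composed, Ukrainian apostrophe variants (`'`, `’`, `ʼ`) are unified to
  U+02BC, and lemmas are case folded. Counting is lemma-based so that
  inflectional variants collapse.
* **Stopwords.** A token is removed iff its POS is `PUNCT`, its POS is in
  the closed-class set (`ADP`, `PRON`, `CCONJ`, `SCONJ`, `PART`, `DET`,
  `AUX`), or its normalized lemma is on the stopword list. The packaged
  Ukrainian list (`inst/extdata/stopwords_uk.txt`) is a reconstruction
  assembled from closed-class categories plus common discourse items;
  users replicating a specific study should supply that study's own list.
  By default the same stopword list is also applied to the reference
  frequency list (`filter_reference_stopwords`), since a reference export
  carries no POS information; this is switchable per side.
* **Narrative length** is the number of non-punctuation tokens per
  narrative — the "words" of the descriptive summary.
* **Exclusion rules.** Participants are excluded, with one primary reason
  each in the fixed precedence *consent → invalid age → underage →
  duplicate*. "Invalid age" means unparseable or outside a 12–120 sanity
  band; "underage" means below 18. Duplicates are exact matches after
  normalization and whitespace collapse; near-duplicates are flagged by
  character 5-gram Jaccard similarity (default threshold 0.9, chosen so
  that verbatim resubmissions with light edits are caught while genuinely
  similar but independent narratives are not; configurable or disableable).
  The first occurrence by narrative ordinal is kept. Filtering is
  idempotent and partitions its input.
* **Score validation.** PCL-5 totals must lie in 0–80 and MISS totals in
  10–100 (the instruments' ranges); rows violating these, or with
  unparseable ages, are quarantined at read time with a per-row problem
  record rather than silently dropped. Psychometric summaries are computed
  over participants who completed both questionnaires.
* **Degenerate SD.** Sample standard deviations use the $n-1$
  denominator; a single observation reports SD 0 together with a flag.
* **De-identification** replaces whole-word alias matches with `[NAME]`/
  `[CITY]` tags, indexed `[CITY1]`, `[CITY2]`, … in order of first
  appearance when several entities of a kind occur, and reused
  consistently within a narrative. Alias lists are supplied by the user;
  no automatic named-entity recognition is attempted, mirroring manual
  practice in testimony corpora.

## The synthetic-data generator

Real testimony corpora are restricted; the generator provides corpora with
*known* statistical structure so that every stage is testable.

* **Lexicon.** Lemma probabilities follow a Zipf–Mandelbrot law
  $p_r \propto (r+q)^{-s}$ with defaults $s = 1.05$, $q = 2.7$ — values in
  the range typically fitted to natural-language rank profiles.
* **Corpus pairs.** Reference counts are multinomial at a fixed total
  (matching fixed corpus sizes; a per-lemma Poisson model would differ
  only in the total's variance). Target counts come from the base
  distribution tilted by $e^{\text{shift}}$ on designated lemmas and
  renormalized. The truth record stores the exact post-normalization
  probabilities, the population log-odds difference, and the estimator's
  exact expected-count target (`implied_loridp_delta`).
* **Release fixtures.** `generate_narratives()` writes both release
  formats. Narrative lengths are log-normal, moment-matched to mean 333
  and SD 237 words and truncated at one word; the displacement marginal is
  0.43, gender/education/marital-status/occupation/trauma marginals follow
  the same published sample profile, about 61% of participants complete
  both questionnaires, PCL-5 scores are truncated normal with mean 41 and
  SD 19, and MISS with mean 42 and SD 17 — the descriptive profile of a
  roughly 2,000-respondent wartime testimony collection. Metadata fields
  are sampled independently; no covariance between, say, displacement and
  region is modelled.
* **What it does not emulate.** The "text" is an i.i.d. lemma sequence:
  no grammar, no morphology (each word is its own lemma), no punctuation
  tokens, no topic structure, no temporal drift over submission dates.
  POS tags are assigned per lexicon rank (top ranks closed-class, the
  rest open-class). Passing tests therefore demonstrate correctness of
  the counting, merging and inference machinery under known frequency
  structure — not robustness to tokenizer or tagger errors in real data.
* **Determinism.** Every generator is a pure function of its seed;
  replicate seeds are derived from the master seed by a fixed integer
  recurrence, and generator calls save and restore the global RNG state.

## Numerical choices

* Ties in key rankings are broken alphabetically by lemma, making output
  files byte-reproducible.
* Merged tables are ordered by descending pooled count, ties alphabetical.
* A combined table in which a single lemma carries the entire mass of both
  corpora makes the odds denominator zero; this raises a domain error
  naming the lemma rather than returning infinities.
* Zero counts are never stored in a `frequency_table` (absence means
  zero); the merge zero-fills the union, so every merged row has
  $\alpha_w \ge 1$.
* Lemma totals are held as doubles: reference exports can exceed the
  32-bit integer range.

## Simulation scale

The packaged statistical checks run at: 500 null replicates with a
10,000-lemma vocabulary and $10^5$ tokens per corpus for the family-wise
error rate; 200 replicates at 1,000 lemmas and $10^5$ tokens with planted
shifts $\{\log 1.5, \log 2, \log 4\}$ on 10 lemmas each for parameter
recovery and power ordering; and a 2,000-narrative release fixture for the
descriptive marginals. These sizes give Monte-Carlo standard errors small
enough for four-standard-error acceptance bands while keeping a full run
in the tens of seconds on one core.

## Known limitations

* The keyness analysis is restricted to unigrams; reference corpus
  interfaces typically export only unigram lemma lists, and no bigram or
  trigram statistics are implemented.
* Exact reproduction of any specific published analysis additionally
  requires that study's own stopword list and reference frequency export;
  with the packaged reconstruction, counts will differ at the margin.
* The near-duplicate rule is a similarity heuristic; it cannot
  distinguish plagiarism from coincidental reuse of formulaic phrasing,
  and at its default threshold it targets only heavily overlapping texts.
* The variance formula is an approximation inherited from the statistic's
  definition; see the shrinkage discussion above for its consequences.
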