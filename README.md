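# warkeys

Keyness analysis of trauma testimony corpora with an informative Dirichlet
prior.

## What this is for

Testimony written by civilians during a war carries a measurable lexical
signature relative to comparable peacetime writing. `warkeys` is for
psycholinguists and corpus researchers who want to extract that signature
from a two-format corpus release — a narrative-level CSV (one row per
participant: demographics, displacement and occupation status,
collective-trauma history, PCL-5 and MISS totals, the narrative text) and a
token-level CoNLL-U table (lemma, POS, morphology, dependencies per word) —
compared against a reference-corpus lemma frequency export.

The pipeline applies the standard corpus hygiene first: participant
exclusion (consent, age validity, age ≥ 18, duplicate narratives),
de-identification tagging (`[NAME]`, `[CITY1]`, `[CITY2]`, …), removal of
punctuation and closed-class/stopword tokens, lemma-based frequency
counting, and a zero-filled merge of the two frequency lists.

## The statistic

Per lemma *w*, the log-odds ratio with informative Dirichlet prior
(LORIDP):

```
δ_w = log[(y_i + α_w) / (n_i + α_0 − (y_i + α_w))]
    − log[(y_j + α_w) / (n_j + α_0 − (y_j + α_w))]

σ²(δ_w) ≈ 1/(y_i + α_w) + 1/(y_j + α_w)

z = δ_w / σ(δ_w)
```

where `y_i`, `y_j` are the lemma's counts in the target and reference
corpus, `n_i`, `n_j` the corpus token totals, and the prior pseudo-counts
come from the pooled corpora: `α_w = y_i + y_j`, `α_0 = n_i + n_j`.
Large positive `z` marks lemmas diagnostic of the target corpus, large
negative `z` lemmas diagnostic of the reference. Significance is
controlled family-wise by Bonferroni: with `α = 0.01` over a 59,190-lemma
combined list the one-sided critical value is `|z| = 5.10`. See the
methods vignette (`vignettes/keyness-methods.Rmd`) for what the
pooled-count prior does to the estimate and why the z-score is
conservative.

## Worked example

Restricted corpus data are not needed to try the pipeline: the synthetic
module generates both release formats with known structure. Here ten
lemmas get a planted 16-fold odds enrichment in the target corpus:

```r
library(warkeys)

dir <- tempfile("demo-")
base <- generate_lexicon(600)                      # Zipf-Mandelbrot lexicon
planted <- setNames(rep(log(16), 10), sprintf("lemma%03d", 101:110))
tilted <- base
tilted[names(planted)] <- tilted[names(planted)] * exp(planted)
tilted <- tilted / sum(tilted)

p <- generate_narratives(150, dir, lexicon = tilted,
                         closed_class_ranks = 0L, seed = 42L)
set.seed(43)
y_ref <- rmultinom(1, 2e5, base)[, 1]              # reference corpus draw
write_frequency_list(frequency_table(y_ref[y_ref > 0]),
                     file.path(dir, "reference_freq.tsv"))
writeLines("# none", file.path(dir, "stopwords.txt"))

cfg <- run_config(p$narratives_path, p$tokens_path,
                  file.path(dir, "reference_freq.tsv"),
                  file.path(dir, "stopwords.txt"),
                  out_dir = file.path(dir, "out"), seed = 42L)
run <- run_pipeline(cfg)
#> [filter] participants retained: 150
#> [ingest] token rows read: 48,804
#> [merge] combined lemmas: 600
#> [keyness] target-diagnostic keys: 10
#> [keyness] reference-diagnostic keys: 2

run
#> <keyness_run> 600 lemmas tested; |z| threshold 4.15 (alpha = 0.01, one-sided)
#>   target-diagnostic keys:    10
#>   reference-diagnostic keys: 2

head(top_k_table(run$target_keys, 5))
#>    rank lemma    gloss abs_z
#> 1     1 lemma108 ""     25.2
#> 2     2 lemma106 ""     25.0
#> 3     3 lemma104 ""     24.5
#> 4     4 lemma103 ""     24.4
#> 5     5 lemma105 ""     24.4
```

All ten planted lemmas are recovered as target keys (the two extra
reference keys here are chance exceedances at this small scale, visible
because the tested family is only 600 lemmas). `run_pipeline()` also
writes `keyness_results.tsv`, ranked top-k tables for both panels,
plot-ready data for a two-panel ranked bar chart, an exclusion log
(JSON lines) and a metadata sidecar into `out_dir`.

A thin command-line wrapper with `ingest` / `simulate` / `keyness` /
`report` subcommands is at `inst/scripts/keyness_cli.R`.

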