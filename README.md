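# semsim

Semantic similarity of descriptive speech, with a default-prior Bayesian
analysis battery and a calibrated synthetic cohort generator.

## The problem

When a person describes a picture for one minute, the words they choose
sample a path through semantic space. In psychosis research, an open
question is whether patients sample that space too narrowly — choosing
words that co-occur too readily — and whether that narrowing tracks
cognition, symptoms and illness course. `semsim` implements the
computational core of such a study for researchers in clinical
computational linguistics:

- **Similarity metrics.** Given a word-embedding table (GloVe text format)
  and a transcript, the package computes **NW** (number of words after
  punctuation removal), **ASW-F** (average similarity of words over the
  full frame: the mean cosine similarity over all C(n,2) pairs of
  eligible word vectors) and **ASW-10** (the same statistic averaged over
  a 10-word moving window, step 1, full windows only). Eligible words are
  those found in the embedding vocabulary, excluding stop words by
  default; out-of-vocabulary words are ignored with a logged warning.
- **Cognitive scores.** Stroop interference by the Golden method,
  `IG = CW − W·C/(W + C)`, and the modified digit-symbol substitution
  total (mean of oral and written correct counts).
- **Default Bayes factors**, implemented by numeric integration and
  exact closed forms: JZS independent and paired t tests (Cauchy prior on
  the standardized effect, width `√2/2`), Jeffreys-style Pearson
  correlation (stretched-beta prior, width 1, from raw pairs or from
  `(r, n)` sufficiency), one-way ANOVA with a default g prior on
  standardized effects (scale 0.5), and Gunel–Dickey contingency tables
  (independent multinomial, concentration 1). Every result carries the
  Bayes factor, the posterior-median effect size with a 95% credible
  interval, the prior settings and the sample sizes.
- **A study pipeline**: cohort loading (plain-text or CHAT transcripts +
  a metadata CSV), baseline group tables, longitudinal paired/change
  analyses, correlation tables (including standardized change scores),
  and stratified robustness checks.
- **A synthetic cohort generator**: a clustered embedding plus a Markov
  cluster-walk transcript model whose stay probability is calibrated by
  bisection so group mean ASW-F hits configurable targets, with clinical
  covariates drawn to match configured group means/SDs and coupled to
  each subject's realized similarity. This makes every stage of the
  pipeline testable without clinical recordings.

## Worked example

```r
library(semsim)

# a tiny embedding table in GloVe text format
tf <- tempfile(fileext = ".txt")
writeLines(c("cat 1 0 0", "dog 0.9 0.1 0", "sat 0 1 0", "the 0 0 1"), tf)
tab <- read_glove(tf)

ann <- annotate_tokens(tokenize("The cat sat, the dog sat."),
                       stoplist = default_stoplist(), table = tab)
profile_transcript(ann, tab)
#>   subject_id picture_id timepoint NW n_eligible     ASW_F    ASW_10 pair_mode window
#> 1       <NA>       <NA>      <NA>  6          4 0.3691245 0.3691245 all_pairs     10
```

Six tokens survive punctuation removal (`NW = 6`); "the" (twice) is
stop-listed, leaving 4 eligible words, and the mean cosine over their 6
pairs is 0.369. With only 4 eligible words the single 10-word window is
the whole frame, so ASW-10 equals ASW-F.

A default Bayesian t test from printed summary statistics:

```r
bf_ttest_independent(m1 = 70.6, sd1 = 14.9, n1 = 36,
                     m2 = 68.4, sd2 = 30.3, n2 = 46)
#> <bayes_result> family: independent_t
#>   BF10 = 0.248  (BF01 = 4.032 )
#>   effect size = 0.0761  95% CI [ -0.328 , 0.485 ]
#>   prior: cauchy_width = 0.707106781186548
#>   n: n1 = 36, n2 = 46 [rounded-input summaries]
```

A Bayes factor of 0.25 is moderate evidence that the groups produce the
same number of words.

A full synthetic study in a few lines:

```r
cfg <- synth_config()                      # 46 FES / 36 HC, 3 pictures, follow-up 20/13
gen <- synth_embedding(cfg, seed = 7)
coh <- synth_cohort(cfg, seed = 7, gen = gen)   # calibrates p_stay, ~2 min
cohort <- load_cohort(coh$metadata, coh$transcripts, gen$table,
                      stoplist = gen$stop_tokens)
baseline_tables(cohort)                    # group means ± SD and BF10 per variable
longitudinal_tables(cohort)                # paired BFs and change comparisons
```

A command-line wrapper for the same steps is installed at
`inst/scripts/semsim.R` (`synth`, `score`, `stats` subcommands).

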