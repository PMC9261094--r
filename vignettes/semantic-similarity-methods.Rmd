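---
title: "Measuring semantic similarity in 1-minute descriptions: models, priors and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring semantic similarity in 1-minute descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsim)
```

This vignette is the package's account of its own methods: what the
similarity metrics measure and how they are computed, how the Bayesian
test battery is parameterized and integrated, what the synthetic cohort
generator emulates (and deliberately does not), and the numerical and
design choices that were genuinely open.

## The similarity model

A transcript is reduced to an ordered token sequence: whitespace
splitting with hyphens and slashes as separators, leading/trailing
punctuation stripped, internal apostrophes kept, digits kept, fillers
treated as ordinary tokens. Each token is then flagged against a stop
list and against the embedding vocabulary. **Eligible** tokens — in
vocabulary and not stop-listed — carry a vector; everything else is
ignored for similarity but still counted in NW (the number of words),
because a one-minute description at a natural speech rate of roughly 70
words owes most of its length to function words.

Three metrics summarize a description:

- **NW** — all tokens after punctuation removal.
- **ASW-F** — the mean cosine similarity over all unordered pairs of
  eligible word vectors in the full description. This is an order-free
  statistic: shuffling the words does not change it.
- **ASW-10** — a 10-token window slides with step 1 over the eligible
  sequence; ASW-F is computed within each window and averaged over all
  positions. Only full windows are used; when the sequence is no longer
  than the window, the single frame *is* the full sequence, so
  ASW-10 = ASW-F exactly. Unlike ASW-F, ASW-10 is order-sensitive: it
  measures local semantic clustering.

Both metrics accept an `adjacent` pair mode (mean over the n−1
successive pairs) as a sensitivity analysis; the default is all-pairs,
because "mean similarity over a frame" reads most naturally as the mean
over all pairs in that frame, and the all-pairs statistic is far less
noisy for ~35 eligible tokens. The mode used is recorded in every
output row. A metric with fewer than two eligible tokens is undefined
and propagates as `NA`, never as 0.

Stop words are excluded from similarity by default (the flag exists
because it is a one-line sensitivity analysis): function words occupy a
dense, semantically uninformative region of embedding space, and
including them compresses group differences toward stop-word
co-occurrence.

### Windowed-mean identity worth knowing

For sequences no longer than the window the two metrics coincide; for
longer sequences ASW-10 usually exceeds ASW-F whenever words are locally
clustered, because within-window pairs are closer in time, hence more
likely to come from the same semantic neighbourhood.

## Cognitive scores

The Stroop interference score follows the Golden method: with `W` words
read correctly, `C` colours named correctly and `CW` correct responses
in the incongruent condition,

$$\mathrm{IG} = CW - \frac{W\,C}{W + C}.$$

The predicted colour-word term is the harmonic composition of the two
card scores; it never exceeds `min(W, C)`, and IG is symmetric in `W`
and `C` and increases one-for-one with `CW`. The DSST total is the mean
of the oral and written correct counts.

## The Bayesian test battery

All tests are two-sided by default with the conventional default
priors, and every result records its prior and sample sizes.

- **t tests (independent and paired).** The JZS construction: a Cauchy
  prior of width $r = \sqrt2/2$ on the standardized effect
  $\delta$, equivalently a normal effect prior whose variance carries an
  inverse-gamma$(1/2, r^2/2)$ mixing parameter $g$. The Bayes factor is
  a one-dimensional integral over $g$, computed in log space on
  $u = \log g$ with adaptive quadrature (relative tolerance $10^{-10}$)
  after locating the integrand's mode; this keeps $t$ statistics of 15+
  (Bayes factors of $10^{20}$) finite and accurate. Summary-statistic
  input (means, SDs, ns) maps to the pooled-variance $t$ by default
  (Welch available) and is flagged `rounded-input` in the result. The
  effect-size posterior (median and central 95% interval) is computed on
  a dense $\delta$ grid from the noncentral-t likelihood times the
  Cauchy prior.
- **Correlation.** The exact sampling density of the Pearson $r$ given
  $\rho$ (Hotelling's single-hypergeometric form, with $_2F_1$ summed as
  a power series) is integrated against a stretched-beta prior of width
  1 (uniform on $(-1,1)$). This uses only $(r, n)$, so printed
  correlations are as analysable as raw data. One-sided factors fold the
  prior onto the positive or negative half; the two one-sided factors
  average to the two-sided one.
- **One-way ANOVA.** Group effects get a normal prior $N(0, g\sigma^2)$
  in an orthonormal sum-to-zero basis with $g$ mixed over
  inverse-gamma$(1/2, r^2/2)$, $r = 0.5$ for fixed effects. After
  integrating the mean and variance under the Jeffreys prior, the
  conditional Bayes factor reduces to $(k-1)\times(k-1)$ linear algebra
  (Woodbury in the reduced basis, which stays well conditioned for
  arbitrarily large $g$), and one more quadrature over $\log g$
  finishes the job. For two groups this construction reproduces the JZS
  t test at Cauchy width $\sqrt2 \times 0.5$ *exactly*, balanced or
  not — the standard correspondence between the ANOVA and t-test
  defaults. Data with zero within-group variance but distinct means
  make the integral diverge (perfect separation); the function returns
  an infinite Bayes factor with a warning rather than an arbitrary
  large number.
- **Contingency tables.** The Gunel–Dickey independent-multinomial
  Bayes factor with rows fixed: each row's cell probabilities get a
  symmetric Dirichlet(1) prior under association; under independence
  the rows share a common vector whose matched prior concentration is
  the column sum of the association priors. The factor is closed-form
  in log-gamma functions.

Every integrator is cross-checked in the test suite against an oracle
that takes a mathematically different route (noncentral-t likelihood
over $\delta$ instead of the $g$ integral; Euler-integral $_2F_1$
instead of the series; full $k\times k$ projection algebra and a
$g/(1+g)$ substitution for the ANOVA; direct beta integrals for 2×2
tables), to relative error $10^{-6}$ or better.

### A note on one-sided correlation values

Reported correlation Bayes factors in the clinical literature sometimes
correspond to the directional (one-sided) test even when described as
two-sided: at $r = 0.592$, $n = 20$, the exact two-sided factor is 9.43
while the positive-sided factor is 18.77, essentially double, because
nearly all posterior mass sits on $\rho > 0$. `bf_correlation()`
exposes `alternative` precisely so either convention can be reproduced
and compared.

## The synthetic cohort generator

The generator emulates a two-group, two-timepoint picture-description
study so that the full pipeline can be exercised and validated without
clinical recordings. Defaults (all overridable via `synth_config()`):

| Parameter | Default | Why |
|---|---|---|
| groups | 46 FES / 36 HC, 3 pictures each | the study design being emulated |
| follow-up | 20 FES / 13 HC | ditto (33 subjects, 99 transcripts) |
| words per transcript | HC 70.6 ± 14.9, FES 68.4 ± 30.3, ≥ 5 | the groups' observed word-count distributions |
| clusters | K = 20, 30 words each, dimension 50 | enough clusters that cluster identity ≈ topic; dimension large enough for near-orthogonal centers |
| base similarity | 0.30 | co-occurrence embeddings give arbitrary content-word pairs a positive cosine floor of roughly this size; implemented as a common direction blended into every content vector |
| within-cluster noise | 0.22 | puts within-cluster cosines near 0.50, so the within/between contrast (~0.2) matches what topical text shows in real embeddings |
| stop-word rate | 0.45 | function-word share of natural speech |
| OOV rate | 0.02 | proper nouns/neologisms absent from a vocabulary |
| ASW-F targets | HC 0.334, FES 0.352 at baseline; FES +0.016 at follow-up, HC flat | the group means being emulated, reached by calibrating p_stay |

A transcript is a Markov cluster walk: each content word stays in the
current semantic cluster with probability `p_stay`, else jumps to a
uniformly chosen other cluster; the word is uniform within its cluster;
stop words and OOV surfaces are interleaved at their rates. Higher
`p_stay` means longer same-topic runs and hence higher similarity —
`p_stay` is the generator's single semantic dial, and expected ASW-F is
monotone in it.

**Calibration.** `calibrate_p_stay()` bisects `p_stay` until the
simulated mean ASW-F hits a target. Evaluations share common random
numbers, which makes the simulated mean a smooth monotone function of
`p_stay`; the bisection therefore runs to convergence and the stated
tolerance (0.005) is verified at the end rather than used as an early
exit. With 500–2000 transcripts per evaluation the residual calibration
error is ~0.001–0.003 in ASW-F units.

**Covariates.** Clinical and cognitive variables are drawn per group
with Gaussian margins at configured means/SDs. Where the analysis needs
realistic couplings (processing speed and Stroop accuracy against
similarity; negative-symptom change against similarity change), the
draw is conditioned on the subject's *realized* standardized ASW-F
through a Gaussian copula, so recovery tests have a known ground truth.
Raw Stroop counts are generated so that the computed Golden score lands
on the configured IG distribution; DSST oral/written counts are split
around the configured total.

**Reproducibility.** One global seed fans out through deterministic
per-(subject, timepoint, picture) substreams, so any transcript can be
regenerated independently of generation order, and the same seed
reproduces the output tree byte for byte.

### What the generator does *not* emulate

- **No trait-level heterogeneity.** All subjects in a group share one
  `p_stay`; between-subject spread in subject-mean ASW-F arises only
  from transcript randomness (about 0.02 HC / 0.03 FES at the default
  settings), somewhat below what real cohorts show, where stable
  individual differences add variance. Consequently recovery
  simulations on synthetic data are mildly optimistic about detection
  power relative to a real cohort with the same group means.
- **The word-count/similarity confound is real here.** Under a Markov
  walk, shorter transcripts have intrinsically higher expected ASW-F
  (fewer pairs at long lags). Since the FES word-count distribution is
  much wider, two groups with *equal* `p_stay` still differ slightly in
  expected ASW-F. The package's null-calibration simulations therefore
  make the groups fully exchangeable (common `p_stay` *and* a common
  word-count distribution); analyses of real data should treat NW as a
  covariate of interest for the same reason.
- No syntax, no timing model (length is just a word count), no rater
  behaviour for the clinical instruments.

Passing recovery tests on this generator shows the pipeline correctly
extracts group structure a distributional model plants in word
sequences; it does not show that real patients differ, nor that the
embedding space of real speech behaves like clustered isotropic noise.

## Numerical choices and degenerate inputs

- Quadratures: `integrate()` at relative tolerance 1e-10 on transformed
  unbounded domains, integrands max-shifted in log space; failures stop
  with diagnostics rather than returning quietly.
- Undefined similarity (fewer than two eligible tokens) is `NA` and is
  excluded from subject means with a warning; a subject with no defined
  picture value aggregates to `NA`.
- Standardized change scores guard a zero baseline (missing, with
  warning).
- Degenerate variances, |r| = 1, zero-margin tables, zero-norm vectors
  and inconsistent embedding rows all raise domain errors naming the
  offending quantity (and line, for files).
- Case folding is a single configuration shared by the embedding table,
  the stop list and the tokens (`lower` by default, since spoken-language
  transcripts capitalize unreliably); `preserve` exists for
  case-sensitive vector sets.

## Problem sizes used in the shipped checks

The test suite and the acceptance script were sized to run comfortably
on one CPU: oracle equivalence uses 1,000 random sequences of length up
to 50; the recovery experiment uses one synthetic embedding, bisection
calibration at 2,000 transcripts per evaluation, and 200 replicate
cohorts (82 subjects × 3 transcripts each) for the effect and for the
exchangeable null; the credible-interval coverage check uses 500
simulated null datasets. These sizes give Monte-Carlo standard errors
well inside the margins they are tested against.

## Known limitations

- The stop list is a standard snowball-style English list; any specific
  historical tool's exact list differs slightly, so absolute ASW values
  are comparable only within a fixed stop-list choice (the list is
  versioned and overridable everywhere).
- Welch-variance Bayes factors reuse the JZS integrand at the
  Satterthwaite degrees of freedom — a pragmatic approximation, flagged
  in the result, not a calibrated default.
- The CHAT reader extracts main-tier participant utterances and strips
  common markup; it is not a full CLAN implementation.
- Effect-size posteriors are reported for t-family and correlation
  tests; the ANOVA and contingency families report the Bayes factor
  only (their detail slots carry $R^2$ and table dimensions).
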