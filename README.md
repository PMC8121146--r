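# harmonicsurprise

Information-theoretic analysis of harmonic surprise in chord-annotated
popular-music corpora, for corpus musicologists and researchers in music
cognition who want to test whether the *unexpectedness* of a song's
harmony — and its association with chart success — drifts over time.

## The quantity at the core

Every chord is normalized to its song's key (interval from the tonic
plus a quality), and scored against a reference chord distribution
estimated from a **baseline era** of the corpus. For unique chord
$C_j$ with count $M_j$ among $N$ unique chords,

$$P(C_j) = \frac{M_j}{\sum_{i=1}^{N} M_i}, \qquad
  S(C_j) = -\log_2 P(C_j) \ \text{bits},$$

a zeroth-order model: only marginal chord prevalence matters, never
chord order. Per song, **absolute surprise** is the mean of $S$ over
its chords and **contrastive surprise** is the sample SD of per-section
mean surprises. Songs are ranked by peak chart position (ties broken by
weeks on chart) into preference quartiles Q1 (top) and Q4 (bottom),
release dates fall into month-bounded time bins, and the package tests
for surprise *inflation*: monotone trends across bins
(Jonckheere–Terpstra), per-quartile OLS slopes in bits/year, a
two-slope equivalence test
$t = (b_1 - b_4)/\sqrt{s_1^2 + s_4^2} \sim T(n_1+n_2-4)$, Q1-vs-Q4
t-tests, and a χ² comparison of where newly introduced chords first
appear.

Because the public corpora this kind of analysis is usually run on are
not redistributable, the package includes a synthetic corpus generator
(`generate_corpus()`) with a Zipf chord baseline, calibrated per-tier
distributional drift in bits/year, section-level heterogeneity, and
chart ranks correlated with surprise — every stage of the pipeline is
tested against it.

## Worked example

```r
library(harmonicsurprise)

corp <- generate_corpus(synth_config(), seed = 1)
corp
#> <chord_corpus> 4000 songs, 289473 chord occurrences, 24 unique chords
#>   encoding: root_third; release years 1958-1977

fit <- harmonic_inflation(corp)
fit
#> Surprise-inflation analysis
#>   4000 songs scored against a 24-chord baseline (1958-01 to 1962-12)
#>   absolute surprise slopes (bits/year):    Q1 +0.0772  Q4 +0.0454
#>   contrastive surprise slopes (bits/year): Q1 +0.0072  Q4 +0.0069
#>   slope equality (absolute): t = 13.38, df = 1996, p = 3.48e-39

coef(fit)
#>                      Q1          Q4
#> absolute    0.077245917 0.045420929
#> contrastive 0.007240285 0.006886793
```

The generator drifted the top tier's chord distribution at 0.09
bits/year and the bottom tier's at 0.03. The fit re-derives quartiles
from the noisy chart ranks, scores every song against the first bin's
chord distribution, and recovers a strongly significant difference in
inflation rates: top-quartile songs gain absolute surprise at
0.077 bits/year versus 0.045 for the bottom quartile (rank-based
quartiles attenuate the tier-level rates toward each other; see the
vignette), with the equality of slopes rejected at $p \approx 10^{-39}$
on 1996 df. `summary(fit)` adds the per-bin means ± SE, the
Jonckheere–Terpstra trend tests, the t-tests and the new-chord report;
`plot(fit)` draws the per-bin quartile means.

Real annotation files are read with `read_annotation_file()` /
`read_annotation_corpus()` (a `# tonic:`-headed, bar-delimited
transcription dialect), tabular corpora with `read_corpus_table()`, and
a full config-driven run — report tables plus a manifest — with
`run_analysis()`.

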