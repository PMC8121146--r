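Package: harmonicsurprise
Title: Harmonic Surprise Analysis of Chart-Ranked Song Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic analysis of harmonic surprise in
    chord-annotated popular-music corpora. Chord labels are parsed,
    normalized to each song's key, and scored in bits against a reference
    chord distribution estimated from a baseline era. Per-song absolute
    surprise (mean chord surprisal) and contrastive surprise (standard
    deviation of per-section mean surprisal) are aggregated over chart
    quartiles and release-date time bins, and tested for temporal trends
    with the Jonckheere-Terpstra test, per-quartile linear regressions,
    a two-slope equivalence test, and a chi-square analysis of newly
    introduced chords. A synthetic corpus generator with controlled
    distributional drift makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
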