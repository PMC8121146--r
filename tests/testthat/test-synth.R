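test_that("generation is a pure function of (config, seed)", {
  cfg <- synth_config(n_years = 4L, songs_per_year = 20L)
  a <- generate_corpus(cfg, seed = 5)
  b <- generate_corpus(cfg, seed = 5)
  expect_identical(a$songs, b$songs)
  expect_identical(a$chords, b$chords)
  c2 <- generate_corpus(cfg, seed = 6)
  expect_false(identical(a$chords, c2$chords))
})

test_that("config validation rejects infeasible settings", {
  expect_error(synth_config(vocab_size = 1L))
  expect_error(synth_config(sections_per_song = c(5L, 2L)))
  expect_error(synth_config(drift_q1 = -0.1))
  expect_error(synth_config(w0 = 1))
})

test_that("zero drift produces flat trends", {
  hits <- 0L
  n_seeds <- 50L
  cfg <- synth_config(n_years = 10L, songs_per_year = 40L,
                      drift_q1 = 0, drift_q4 = 0)
  ref <- synth_reference(cfg)
  for (s in seq_len(n_seeds)) {
    corp <- generate_corpus(cfg, seed = 100 + s)
    prof <- corpus_surprise_profiles(corp, ref)
    m <- match(prof$song_id, corp$songs$song_id)
    tm <- corp$songs$release_year[m] +
      (corp$songs$release_month[m] - 1) / 12
    tr <- fit_trend(tm, prof$absolute)
    if (abs(tr$slope) < 2 * tr$slope_se) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("configured drift targets are recovered from tier trends", {
  cfg <- synth_config()  # 20 years x 200 songs, drifts 0.09 / 0.03
  corp <- generate_corpus(cfg, seed = 41)
  ref <- synth_reference(cfg)
  prof <- corpus_surprise_profiles(corp, ref)
  m <- match(prof$song_id, corp$songs$song_id)
  tm <- corp$songs$release_year[m] + (corp$songs$release_month[m] - 1) / 12
  tier <- corp$songs$tier[m]
  target <- c(q1 = 0.09, mid = 0.06, q4 = 0.03)
  for (tr_name in names(target)) {
    sel <- tier == tr_name
    tr <- fit_trend(tm[sel], prof$absolute[sel])
    expect_lt(abs(tr$slope - target[[tr_name]]) / target[[tr_name]], 0.15)
  }
})

test_that("zero contrast gives near-zero contrastive surprise", {
  base <- list(n_years = 2L, songs_per_year = 20L, w0 = 0.4,
               sections_per_song = c(4L, 4L),
               chords_per_section = c(400L, 400L))
  flat_cfg <- do.call(synth_config, c(base, contrast_q1 = 0,
                                      contrast_q4 = 0))
  flat <- generate_corpus(flat_cfg, seed = 3)
  ref <- synth_reference(flat_cfg)
  pf <- corpus_surprise_profiles(flat, ref)
  # homogeneous 400-chord sections leave only the sampling floor,
  # which shrinks as 1/sqrt(chords per section)
  expect_lt(max(pf$contrastive), 0.25)
  spread_cfg <- do.call(synth_config, c(base, contrast_q1 = 0.3,
                                        contrast_q4 = 0.3))
  spread <- generate_corpus(spread_cfg, seed = 3)
  ps <- corpus_surprise_profiles(spread, synth_reference(spread_cfg))
  expect_gt(mean(ps$contrastive), 2.5 * mean(pf$contrastive))
})

test_that("chart ranks track surprise within each year", {
  cfg <- synth_config(n_years = 6L, songs_per_year = 60L, rank_noise = 0.2)
  corp <- generate_corpus(cfg, seed = 8)
  ref <- synth_reference(cfg)
  prof <- corpus_surprise_profiles(corp, ref)
  m <- match(prof$song_id, corp$songs$song_id)
  last <- corp$songs$release_year[m] == max(corp$songs$release_year)
  r <- stats::cor(corp$songs$peak_position[m][last],
                  prof$absolute[last], method = "spearman")
  expect_lt(r, -0.5)  # better (smaller) peak position <-> higher surprise
  # peaks within a year are a permutation of 1..n
  yr1 <- corp$songs$release_year == min(corp$songs$release_year)
  expect_setequal(corp$songs$peak_position[yr1], seq_len(60L))
})

test_that("gradually revealed vocabulary concentrates in the fast tier", {
  cfg <- synth_config(novel_vocab = 60L, songs_per_year = 150L)
  corp <- generate_corpus(cfg, seed = 12)
  expect_equal(corp$encoding, "full")
  songs <- corp$songs
  ch <- corp$chords
  cc <- canonical_chord(ch$chord_interval, ch$chord_quality)
  base <- cc %in% root_third_vocabulary()
  yr <- songs$release_year[match(ch$song_id, songs$song_id)]
  tier <- songs$tier[match(ch$song_id, songs$song_id)]
  first_year <- tapply(yr[!base], cc[!base], min)
  intro <- !base & yr == first_year[cc]
  counts <- table(factor(tier[intro], levels = c("q1", "mid", "q4")))
  expect_gt(counts[["q1"]], counts[["q4"]])
})

test_that("fixtures have their documented shapes", {
  toy <- make_fixture("toy6")
  expect_equal(nrow(toy$songs), 6L)
  expect_equal(sort(unique(toy$songs$release_year)),
               c(1960L, 1970L, 1971L))
  tie <- make_fixture("tie_break")
  expect_equal(length(unique(tie$songs$peak_position)), 1L)
  oov <- make_fixture("oov")
  d <- build_distribution(oov, c("1960-01", "1960-12"))
  cc <- canonical_chord(oov$chords$chord_interval,
                        oov$chords$chord_quality)
  expect_true(any(!cc %in% names(d$counts)))
  expect_error(make_fixture("nope"))
})
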