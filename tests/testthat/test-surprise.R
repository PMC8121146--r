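# Expected values in this file are computed in place from the defining
# formulas (relative frequency, -log2, mean, sample SD), so every
# assertion is checkable by hand.

test_that("baseline distributions follow relative chord frequency", {
  songs <- songs_table(1L)
  chords <- uniform_chords(songs$song_id, iv = c(0, 0, 0, 7), q = "major")
  corp <- chord_corpus(songs, chords, encoding = "root_third")
  d <- build_distribution(corp)
  expect_equal(d$N, 2L)
  expect_equal(d$total, 4)
  expect_equal(unname(d$prob["0:major"]), 0.75)
  expect_equal(unname(d$prob["7:major"]), 0.25)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("the baseline window is month-inclusive and must be nonempty", {
  corp <- make_fixture("toy6")
  d <- build_distribution(corp, c("1960-01", "1960-12"))
  expect_equal(d$total, 8)
  # window ending the month before the March release excludes it
  d2 <- build_distribution(corp, c("1960-04", "1960-12"))
  expect_equal(d2$total, 4)
  expect_error(build_distribution(corp, c("1940-01", "1940-12")),
               "no chord occurrences")
})

test_that("chord surprise is -log2 of probability, in bits", {
  d <- chord_distribution(c("0:major" = 3, "7:major" = 1))
  expect_equal(chord_surprise(d, "7:major"), 2)           # P = 1/4
  expect_equal(chord_surprise(d, "0:major"), -log(0.75) / log(2),
               tolerance = 1e-12)
  expect_equal(round(chord_surprise(d, "0:major"), 4), 0.4150)
  d1 <- chord_distribution(c("0:major" = 5))
  expect_equal(chord_surprise(d1, "0:major"), 0)          # P = 1
  # uniform distribution over 24 chords
  u <- chord_distribution(stats::setNames(rep(2, 24),
                                          paste0(0:23, ":x")))
  expect_equal(unique(round(u$surprise, 10)), round(log2(24), 10))
})

test_that("out-of-vocabulary policies behave as declared", {
  d <- chord_distribution(c("0:major" = 3, "7:major" = 1))
  expect_true(is.na(chord_surprise(d, "5:minor", oov = "exclude")))
  expect_equal(chord_surprise(d, "5:minor", oov = "laplace"),
               -log2(1 / (4 + 2 + 1)))
  expect_equal(chord_surprise(d, "5:minor", oov = "cap"),
               -log2(1 / (4 + 1)))
})

test_that("toy corpus profiles match hand-worked values", {
  corp <- make_fixture("toy6")
  d <- build_distribution(corp, c("1960-01", "1960-12"))
  prof <- corpus_surprise_profiles(corp, d)
  s0 <- -log2(3 / 4); s7 <- 2

  get <- function(id, col) prof[prof$song_id == id, col]
  # song of chords {I,V,V,V}: mean and section-SD by hand
  expect_equal(get("toy3", "absolute"), (s0 + 3 * s7) / 4)
  expect_equal(get("toy3", "contrastive"),
               stats::sd(c((s0 + s7) / 2, s7)))
  expect_equal(get("toy4", "absolute"), (3 * s0 + s7) / 4)
  # one out-of-baseline chord: excluded and counted
  expect_equal(get("toy5", "absolute"), (2 * s0 + s7) / 3)
  expect_equal(get("toy5", "n_excluded"), 1L)
  expect_equal(get("toy5", "contrastive"),
               stats::sd(c(s0, (s0 + s7) / 2)))
  # single-section song: contrastive undefined
  expect_true(is.na(get("toy6", "contrastive")))
  expect_equal(get("toy6", "absolute"), (s0 + 2 * s7) / 3)
  expect_equal(get("toy1", "contrastive"),
               stats::sd(c(s0, (s0 + s7) / 2)))
  expect_equal(nrow(prof), 6L)

  # homogeneous sections give exactly zero contrastive surprise
  songs <- songs_table(1L)
  chords <- data.frame(song_id = "s001", section_index = rep(0:1, each = 2),
                       section_label = "s", chord_interval = c(0, 7, 0, 7),
                       chord_quality = "major", stringsAsFactors = FALSE)
  flat <- corpus_surprise_profiles(chord_corpus(songs, chords), d)
  expect_equal(flat$contrastive, 0)
})

test_that("single-song accessors agree with the corpus profiles", {
  corp <- make_fixture("toy6")
  d <- build_distribution(corp, c("1960-01", "1960-12"))
  prof <- corpus_surprise_profiles(corp, d)
  a <- song_absolute_surprise(corp, "toy5", d)
  expect_equal(a$absolute, prof$absolute[prof$song_id == "toy5"])
  expect_equal(a$n_excluded, prof$n_excluded[prof$song_id == "toy5"])
  expect_equal(song_contrastive_surprise(corp, "toy3", d),
               prof$contrastive[prof$song_id == "toy3"])
  expect_error(song_absolute_surprise(corp, "ghost", d), "ghost")
})

test_that("a song with every chord out of vocabulary is flagged NA", {
  songs <- songs_table(2L)
  chords <- rbind(uniform_chords("s001", iv = c(0, 0), q = "major"),
                  uniform_chords("s002", iv = c(3, 6), q = "minor"))
  corp <- chord_corpus(songs, chords, encoding = "root_third")
  d <- chord_distribution(c("0:major" = 4))
  prof <- corpus_surprise_profiles(corp, d)
  expect_true(is.na(prof$absolute[prof$song_id == "s002"]))
  expect_equal(prof$n_excluded[prof$song_id == "s002"], 2L)
})

test_that("self-scored baseline surprise equals entropy, below log2 N", {
  cfg <- synth_config(n_years = 2L, songs_per_year = 30L)
  corp <- generate_corpus(cfg, seed = 9)
  d <- build_distribution(corp)
  s <- chord_surprise(d, canonical_chord(corp$chords$chord_interval,
                                         corp$chords$chord_quality))
  expect_equal(mean(s), distribution_entropy(d), tolerance = 1e-12)
  expect_lte(distribution_entropy(d), log2(d$N))
})

test_that("more frequent chords are less surprising", {
  set.seed(4)
  counts <- stats::setNames(sample(1:50, 20), paste0("c", 1:20))
  d <- chord_distribution(counts)
  ord <- order(counts)
  expect_true(all(diff(d$surprise[names(counts)[ord]]) <= 1e-12))
})

test_that("surprise is invariant under whole-corpus transposition", {
  set.seed(11)
  roots <- sample(0:11, 40, replace = TRUE)
  quals <- sample(c("maj", "min", "maj7"), 40, replace = TRUE)
  tonic <- 2L
  for (shift in c(3L, 7L)) {
    iv_a <- (roots - tonic) %% 12L
    iv_b <- ((roots + shift) - (tonic + shift)) %% 12L
    expect_identical(iv_a, iv_b)
  }
  # and therefore the profiles of a transposed corpus are identical
  songs <- songs_table(2L)
  mk <- function(shift) {
    iv <- ((roots + shift) - (tonic + shift)) %% 12L
    chords <- data.frame(song_id = rep(songs$song_id, each = 20),
                         section_index = rep(c(0L, 1L), 20),
                         section_label = "s", chord_interval = iv,
                         chord_quality = quals, stringsAsFactors = FALSE)
    chord_corpus(songs, chords)
  }
  a <- mk(0L); b <- mk(5L)
  da <- build_distribution(a)
  expect_equal(corpus_surprise_profiles(a, da),
               corpus_surprise_profiles(b, build_distribution(b)))
})
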