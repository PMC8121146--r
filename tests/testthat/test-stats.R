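test_that("Jonckheere-Terpstra matches enumeration on ordered groups", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- jonckheere_terpstra(g)
  expect_equal(unname(res$statistic), 12)       # all 12 cross pairs concordant
  expect_equal(res$p.value, jt_oracle_exact_p(g))
  expect_equal(res$p.value, 1 / 90)             # 6!/(2!2!2!) arrangements
  expect_match(res$method, "exact")
})

test_that("tied values contribute half counts", {
  g <- list(c(2, 2), c(2, 2))
  res <- jonckheere_terpstra(g)
  expect_equal(unname(res$statistic), 2)        # half of 4 cross pairs
  expect_equal(res$p.value, 1)
})

test_that("reversing the group order flips the tail", {
  g <- list(c(1, 5), c(2, 6), c(7, 9))
  inc <- jonckheere_terpstra(g)
  dec <- jonckheere_terpstra(rev(g))
  # with no ties the two statistics partition the cross pairs
  expect_equal(unname(inc$statistic + dec$statistic), 12)
  expect_equal(dec$p.value,
               jonckheere_terpstra(g, alternative = "decreasing")$p.value)
})

test_that("exact p-values agree with the permutation oracle on random cases", {
  set.seed(31)
  size_sets <- list(c(2L, 2L, 2L), c(2L, 2L, 3L), c(3L, 2L, 2L),
                    c(2L, 3L, 2L), c(2L, 2L, 2L))
  for (rep in 1:5) {
    sizes <- size_sets[[rep]]
    g <- lapply(sizes, function(n) round(stats::runif(n, 0, 10), 1))
    res <- jonckheere_terpstra(g)
    expect_equal(unname(res$statistic), jt_oracle_statistic(g))
    expect_equal(res$p.value, jt_oracle_exact_p(g), tolerance = 1e-12)
  }
})

test_that("the normal approximation is used above the exact cutoff", {
  set.seed(7)
  g <- lapply(1:4, function(i) stats::rnorm(30, mean = 0.4 * i))
  res <- jonckheere_terpstra(g)
  expect_match(res$method, "normal")
  expect_lt(res$p.value, 1e-4)
  expect_error(jonckheere_terpstra(list(numeric(0), numeric(0))),
               "nonempty")
})

test_that("trend fits agree with the normal-equation oracle", {
  # exact line (summary.lm warns about the perfect fit)
  tr <- suppressWarnings(fit_trend(1:10, 2 * (1:10) + 1))
  expect_equal(tr$slope, 2)
  expect_equal(tr$slope_se, 0, tolerance = 1e-12)
  expect_equal(coef(tr), c(intercept = 1, slope = 2))
  # constant response
  expect_equal(suppressWarnings(fit_trend(1:10, rep(3, 10)))$slope, 0)
  # random fixture vs normal equations
  set.seed(13)
  x <- stats::runif(40, 0, 30)
  y <- 0.05 * x + stats::rnorm(40)
  tr <- fit_trend(x, y)
  X <- cbind(1, x)
  beta <- drop(solve(t(X) %*% X, t(X) %*% y))
  resid <- y - drop(X %*% beta)
  s2 <- sum(resid^2) / (40 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(tr$slope, unname(beta[2]), tolerance = 1e-10)
  expect_equal(tr$intercept, unname(beta[1]), tolerance = 1e-10)
  expect_equal(tr$slope_se, se, tolerance = 1e-10)
  # degenerate input
  expect_error(fit_trend(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_trend(1:2, 1:2), "at least 3")
})

test_that("the slope-equivalence test uses pooled SEs and n1+n2-4 df", {
  set.seed(17)
  x <- stats::runif(136, 0, 30)
  a <- fit_trend(x, 2 * x + stats::rnorm(136))
  b <- fit_trend(x, 2 * x + stats::rnorm(136))
  st <- compare_slopes(a, b)
  expect_equal(unname(st$parameter), 136 + 136 - 4)
  expect_equal(unname(st$statistic),
               (a$slope - b$slope) / sqrt(a$slope_se^2 + b$slope_se^2))
  # identical fits: t = 0, p = 1
  st0 <- compare_slopes(a, a)
  expect_equal(unname(st0$statistic), 0)
  expect_equal(st0$p.value, 1)
  # exact lines with different slopes: overwhelming evidence
  e1 <- suppressWarnings(fit_trend(1:10, 2 * (1:10)))
  e2 <- suppressWarnings(fit_trend(1:10, 3 * (1:10)))
  expect_lt(compare_slopes(e1, e2)$p.value, 1e-12)
  expect_equal(compare_slopes(e1, e1)$p.value, 1)
  # literally zero pooled SE: the declared degenerate branches
  mk <- function(slope) structure(list(slope = slope, slope_se = 0,
                                       n = 10L), class = "surprise_trend")
  z_eq <- compare_slopes(mk(2), mk(2))
  expect_equal(unname(z_eq$statistic), 0)
  expect_equal(z_eq$p.value, 1)
  z_ne <- compare_slopes(mk(2), mk(3))
  expect_true(z_ne$degenerate)
  expect_equal(z_ne$p.value, 0)
})

test_that("two-sample t matches the textbook computation", {
  x <- c(1, 2); y <- c(4, 6)
  ht <- two_sample_t(x, y)
  # Welch: t = (xbar - ybar) / sqrt(sx2/nx + sy2/ny)
  t_hand <- (1.5 - 5) / sqrt(0.5 / 2 + 2 / 2)
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-12)
  # identical samples give t = 0; swapping negates t
  expect_equal(unname(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic), 0)
  expect_equal(unname(two_sample_t(y, x)$statistic), -t_hand,
               tolerance = 1e-12)
  expect_error(two_sample_t(c(1), c(1, 2)), "n >= 2")
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "degenerate")
})

test_that("the two-count chi-square matches its closed form", {
  expect_equal(chi_square_two_counts(10, 10)$chi2, 0)
  expect_equal(chi_square_two_counts(20, 0)$chi2, 20)
  res <- chi_square_two_counts(133, 92)
  e <- (133 + 92) / 2
  expect_equal(res$chi2, (133 - e)^2 / e + (92 - e)^2 / e)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(res$chi2, 1, lower.tail = FALSE))
  expect_error(chi_square_two_counts(0, 0), "zero")
})


test_that("new-chord sets match the brute-force scan oracle", {
  set.seed(23)
  for (rep in 1:4) {
    n <- 30L
    songs <- songs_table(n, year = sample(1960:1964, n, replace = TRUE),
                         peak = sample(n))
    chords <- do.call(rbind, lapply(songs$song_id, function(id) {
      m <- sample(3:6, 1)
      data.frame(song_id = id, section_index = 0L, section_label = "s",
                 chord_interval = sample(0:11, m, replace = TRUE),
                 chord_quality = sample(c("major", "minor"), m,
                                        replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    corp <- chord_corpus(songs, chords, encoding = "root_third")
    rep_out <- new_chord_report(corp, classify_quartiles_global(corp))
    oracle <- new_chord_oracle(corp)
    oracle <- oracle[vapply(oracle, length, 1L) > 0]
    expect_equal(lapply(rep_out$by_year, sort), oracle)
    expect_equal(rep_out$total_new, length(unlist(oracle)))
  }
})

test_that("new-chord attribution counts quartile appearances in the intro year", {
  songs <- songs_table(8L, year = c(rep(1960L, 4L), rep(1961L, 4L)),
                       peak = 1:8)
  # quartiles: s001, s002 -> Q1? n=8 -> k=2: ranks 1,2 -> Q1; 7,8 -> Q4
  chords <- rbind(
    uniform_chords(songs$song_id[1:4], iv = c(0, 7), q = "major"),
    uniform_chords("s005", iv = c(0, 3), q = c("major", "minor")),  # new 3:minor, Q1? no: peak 5
    uniform_chords("s006", iv = c(0, 6), q = c("major", "minor")),
    uniform_chords("s007", iv = c(0, 7), q = "major"),
    uniform_chords("s008", iv = c(0, 7), q = "major"))
  corp <- chord_corpus(songs, chords, encoding = "root_third")
  q <- classify_quartiles_global(corp)
  out <- new_chord_report(corp, q)
  expect_equal(out$total_new, 2L)       # 3:minor and 6:minor in 1961
  expect_equal(out$count_Q1, 0L)        # both introduced by MID songs
  expect_equal(out$count_Q4, 0L)
  expect_true(is.na(out$chi2))

  # stationary vocabulary: no new chords
  stat <- chord_corpus(songs, uniform_chords(songs$song_id),
                       encoding = "root_third")
  out2 <- new_chord_report(stat, q)
  expect_equal(out2$total_new, 0L)
  expect_equal(length(out2$by_year), 0L)

  # per-occurrence mode counts every intro-year occurrence
  songs3 <- songs_table(8L, year = c(rep(1960L, 4L), rep(1961L, 4L)))
  chords3 <- rbind(uniform_chords(songs3$song_id[1:7]),
                   uniform_chords("s008", iv = c(5, 5, 5), q = "minor"))
  corp3 <- chord_corpus(songs3, chords3, encoding = "root_third")
  q3 <- classify_quartiles_global(corp3)
  # s008 has peak 8 -> Q4; 5:minor appears 3 times
  oc <- new_chord_report(corp3, q3, count = "per_occurrence")
  expect_equal(oc$count_Q4, 3L)
  pc <- new_chord_report(corp3, q3, count = "per_chord")
  expect_equal(pc$count_Q4, 1L)
})
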