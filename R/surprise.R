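# Zeroth-order harmonic surprise.
#
# A reference chord distribution is estimated from a baseline era: for
# each unique key-relative chord C_j with occurrence count M_j among N
# unique chords, P(C_j) = M_j / sum_i M_i, and the surprise of a chord is
# S(C_j) = -log2 P(C_j) in bits. The model is zeroth-order: chord order
# carries no information, only marginal prevalence.

#' Construct a chord distribution
#'
#' @param counts Named numeric vector of occurrence counts, names are
#'   canonical chord ids (see [canonical_chord()]). All counts must be
#'   >= 1 (chords with no occurrences are simply absent).
#' @param window Optional baseline window, `c("YYYY-MM", "YYYY-MM")`.
#' @return A `chord_distribution` with fields `counts`, `prob`,
#'   `surprise` (bits), `total` and `N` (number of unique chords).
#' @export
chord_distribution <- function(counts, window = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts > 0), !anyDuplicated(names(counts)))
  total <- sum(counts)
  prob <- counts / total
  structure(list(counts = counts, prob = prob,
                 surprise = -log2(prob), total = total,
                 N = length(counts), window = window),
            class = "chord_distribution")
}

#' @export
print.chord_distribution <- function(x, ...) {
  cat(sprintf("<chord_distribution> N=%d unique chords, %g occurrences\n",
              x$N, x$total))
  if (!is.null(x$window)) {
    cat(sprintf("  baseline window: %s to %s\n", x$window[1L], x$window[2L]))
  }
  cat(sprintf("  entropy %.3f bits (max %.3f)\n",
              distribution_entropy(x), log2(x$N)))
  invisible(x)
}

#' Shannon entropy of a chord distribution
#'
#' The entropy equals the expected surprise of a chord drawn from the
#' distribution itself, and is bounded above by `log2(N)`.
#'
#' @param dist A `chord_distribution`.
#' @return Entropy in bits.
#' @export
distribution_entropy <- function(dist) {
  stopifnot(inherits(dist, "chord_distribution"))
  sum(dist$prob * dist$surprise)
}

#' Estimate the baseline chord distribution from a corpus window
#'
#' Counts canonical chord occurrences over all songs whose release date
#' falls inside the (month-inclusive) window, and converts counts to
#' probabilities by relative frequency.
#'
#' @param corpus A `chord_corpus`.
#' @param window `c(start, end)` as `"YYYY-MM"` strings, both inclusive.
#'   `NULL` uses the whole corpus.
#' @return A `chord_distribution`.
#' @examples
#' corp <- make_fixture("toy6")
#' build_distribution(corp, c("1960-01", "1961-12"))
#' @export
build_distribution <- function(corpus, window = NULL) {
  stopifnot(inherits(corpus, "chord_corpus"))
  songs <- corpus$songs
  if (!is.null(window)) {
    s <- parse_ym(window[1L]); e <- parse_ym(window[2L])
    mi <- month_index(songs$release_year, songs$release_month)
    keep_ids <- songs$song_id[mi >= month_index(s[1L], s[2L]) &
                              mi <= month_index(e[1L], e[2L])]
  } else {
    keep_ids <- songs$song_id
  }
  rows <- corpus$chords$song_id %in% keep_ids
  if (!any(rows)) {
    stop("baseline window contains no chord occurrences", call. = FALSE)
  }
  cc <- canonical_chord(corpus$chords$chord_interval[rows],
                        corpus$chords$chord_quality[rows])
  counts <- table(cc)
  chord_distribution(stats::setNames(as.numeric(counts), names(counts)),
                     window = window)
}

#' Surprise of a chord under a distribution
#'
#' `-log2 P(C_j)` in bits. Chords outside the distribution's vocabulary
#' are handled per the out-of-vocabulary policy: `"exclude"` returns
#' `NA` (the caller drops and counts them), `"laplace"` scores them with
#' the add-one probability `1 / (total + N + 1)`, and `"cap"` bounds the
#' surprise at `-log2(1 / (total + 1))`.
#'
#' @param dist A `chord_distribution`.
#' @param chord Character vector of canonical chord ids.
#' @param oov Out-of-vocabulary policy.
#' @return Numeric vector of surprise values in bits (`NA` for excluded
#'   out-of-vocabulary chords).
#' @examples
#' d <- chord_distribution(c("0:maj" = 3, "7:maj" = 1))
#' chord_surprise(d, c("0:maj", "7:maj"))   # 0.415, 2 bits
#' @export
chord_surprise <- function(dist, chord,
                           oov = c("exclude", "laplace", "cap")) {
  stopifnot(inherits(dist, "chord_distribution"))
  oov <- match.arg(oov)
  s <- unname(dist$surprise[chord])
  if (anyNA(s)) {
    fill <- switch(oov,
                   exclude = NA_real_,
                   laplace = -log2(1 / (dist$total + dist$N + 1)),
                   cap = -log2(1 / (dist$total + 1)))
    s[is.na(s)] <- fill
  }
  s
}

#' Absolute and contrastive surprise of one song
#'
#' `song_absolute_surprise()` returns the mean surprise (bits) over the
#' song's in-vocabulary chords together with the number of excluded
#' out-of-vocabulary chords; `song_contrastive_surprise()` returns the
#' sample standard deviation of the per-section mean surprises (`NA`
#' when fewer than two sections have an in-vocabulary chord).
#'
#' @param corpus A `chord_corpus` containing the song.
#' @param song_id Id of the song to score.
#' @param dist Reference `chord_distribution`.
#' @param oov Out-of-vocabulary policy, see [chord_surprise()].
#' @return For the absolute measure, a list with `absolute` and
#'   `n_excluded`; for the contrastive measure, a single numeric value.
#' @export
song_absolute_surprise <- function(corpus, song_id, dist,
                                   oov = c("exclude", "laplace", "cap")) {
  prof <- song_profile_row(corpus, song_id, dist, match.arg(oov))
  list(absolute = prof$absolute, n_excluded = prof$n_excluded)
}

#' @rdname song_absolute_surprise
#' @export
song_contrastive_surprise <- function(corpus, song_id, dist,
                                      oov = c("exclude", "laplace",
                                              "cap")) {
  song_profile_row(corpus, song_id, dist, match.arg(oov))$contrastive
}

song_profile_row <- function(corpus, song_id, dist, oov) {
  stopifnot(inherits(corpus, "chord_corpus"))
  if (!song_id %in% corpus$songs$song_id) {
    stop("no song with id ", sQuote(song_id), call. = FALSE)
  }
  sub <- chord_corpus(corpus$songs[corpus$songs$song_id == song_id, ],
                      corpus$chords[corpus$chords$song_id == song_id, ],
                      encoding = corpus$encoding)
  corpus_surprise_profiles(sub, dist, oov = oov)
}

#' Per-song surprise profiles
#'
#' Computes, for every song, the absolute surprise (mean surprise over
#' its chords) and the contrastive surprise (sample standard deviation of
#' per-section mean surprises). Out-of-vocabulary chords are excluded and
#' counted under the default policy; a song whose chords are all
#' out-of-vocabulary gets `NA` absolute surprise, and a song with fewer
#' than two usable sections gets `NA` contrastive surprise.
#'
#' @param corpus A `chord_corpus`.
#' @param dist The reference `chord_distribution`.
#' @param oov Out-of-vocabulary policy, see [chord_surprise()].
#' @return A `data.frame` with one row per song: `song_id`, `absolute`,
#'   `contrastive`, `n_chords`, `n_excluded`, `n_sections` (usable
#'   sections).
#' @export
corpus_surprise_profiles <- function(corpus, dist,
                                     oov = c("exclude", "laplace", "cap")) {
  stopifnot(inherits(corpus, "chord_corpus"))
  oov <- match.arg(oov)
  ch <- corpus$chords
  s <- chord_surprise(dist, corpus_canonical(corpus), oov = oov)
  ids <- corpus$songs$song_id
  song <- factor(ch$song_id, levels = ids)
  ok <- !is.na(s)

  zero_if_na <- function(v) { v[is.na(v)] <- 0; v }
  n_chords <- as.integer(table(song))
  n_excl <- as.integer(zero_if_na(tapply(as.numeric(!ok), song, sum)))
  sums <- zero_if_na(tapply(ifelse(ok, s, 0), song, sum))
  n_ok <- n_chords - n_excl
  absolute <- ifelse(n_ok > 0, sums / n_ok, NA_real_)

  # per-section means, then their sample SD per song ("\r" cannot occur
  # in a song id, so the compound key splits back unambiguously)
  sec_key <- paste(ch$song_id, ch$section_index, sep = "\r")
  sec_n <- rowsum(as.numeric(ok), sec_key)[, 1L]
  sec_sum <- rowsum(ifelse(ok, s, 0), sec_key)[, 1L]
  usable <- sec_n > 0
  sec_song <- sub("\r.*$", "", names(sec_n))
  contrastive <- stats::setNames(rep(NA_real_, length(ids)), ids)
  n_sec <- stats::setNames(rep(0L, length(ids)), ids)
  if (any(usable)) {
    means <- sec_sum[usable] / sec_n[usable]
    by_song <- split(means, sec_song[usable])
    cs <- vapply(by_song, function(v) {
      if (length(v) >= 2L) stats::sd(v) else NA_real_
    }, 0)
    contrastive[names(cs)] <- cs
    tab <- table(sec_song[usable])
    n_sec[names(tab)] <- as.integer(tab)
  }

  data.frame(song_id = ids,
             absolute = unname(absolute),
             contrastive = unname(contrastive),
             n_chords = n_chords,
             n_excluded = n_excl,
             n_sections = unname(n_sec),
             row.names = NULL, stringsAsFactors = FALSE)
}
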