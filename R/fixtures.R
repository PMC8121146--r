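# Hand-sized corpora used in documentation and tests. Every value in
# "toy6" can be verified with pencil and paper: the 1960 baseline has
# six I-major and two V-major occurrences, so P = 3/4 and 1/4 and the
# two surprise values are -log2(3/4) ~ 0.415 and 2 bits.

#' Built-in miniature corpora
#'
#' * `"toy6"` — six songs over 1960-1971; the 1960 releases define a
#'   two-chord baseline (P(I-major) = 3/4, P(V-major) = 1/4). Song 5
#'   contains one out-of-baseline chord, song 6 has a single section.
#' * `"tie_break"` — four songs with tied peak positions that the
#'   weeks-on-chart and song-id tie-breaks must resolve.
#' * `"oov"` — two baseline songs plus one song with a chord absent
#'   from the baseline vocabulary.
#'
#' @param name Fixture name.
#' @return A `chord_corpus`.
#' @examples
#' make_fixture("toy6")
#' @export
make_fixture <- function(name = c("toy6", "tie_break", "oov")) {
  name <- match.arg(name)
  song_df <- function(id, year, month, peak, weeks) {
    data.frame(song_id = id, release_year = year, release_month = month,
               peak_position = peak, weeks_on_chart = weeks,
               genre = "pop", stringsAsFactors = FALSE)
  }
  chords_df <- function(id, sec, iv, q) {
    data.frame(song_id = id, section_index = sec,
               section_label = sprintf("sec%02d", sec),
               chord_interval = iv, chord_quality = q,
               stringsAsFactors = FALSE)
  }
  switch(name,
    toy6 = {
      songs <- song_df(paste0("toy", 1:6),
                       year = c(1960, 1960, 1970, 1970, 1971, 1971),
                       month = c(3, 9, 1, 6, 4, 11),
                       peak = c(1, 12, 3, 40, 7, 55),
                       weeks = c(20, 5, 15, 3, 10, 2))
      M <- "major"
      chords <- rbind(
        chords_df("toy1", c(0L, 0L, 1L, 1L), c(0, 0, 0, 7), M),
        chords_df("toy2", c(0L, 0L, 1L, 1L), c(7, 0, 0, 0), M),
        chords_df("toy3", c(0L, 0L, 1L, 1L), c(0, 7, 7, 7), M),
        chords_df("toy4", c(0L, 0L, 1L, 1L), c(0, 0, 0, 7), M),
        chords_df("toy5", c(0L, 0L, 1L, 1L), c(0, 3, 7, 0),
                  c(M, "minor", M, M)),
        chords_df("toy6", c(0L, 0L, 0L), c(0, 7, 7), M))
      chord_corpus(songs, chords, encoding = "root_third",
                   provenance = list(fixture = "toy6"))
    },
    tie_break = {
      songs <- song_df(c("tb_a", "tb_b", "tb_c", "tb_d"),
                       year = 1960, month = c(1, 2, 3, 4),
                       peak = c(5, 5, 5, 5),
                       weeks = c(10, 2, 10, 7))
      chords <- chords_df(rep(songs$song_id, each = 2L),
                          sec = 0L, iv = c(0, 7), q = "major")
      chord_corpus(songs, chords, encoding = "root_third",
                   provenance = list(fixture = "tie_break"))
    },
    oov = {
      songs <- song_df(c("base1", "base2", "late1"),
                       year = c(1960, 1960, 1965), month = c(1, 6, 3),
                       peak = c(1, 2, 3), weeks = c(5, 4, 3))
      chords <- rbind(
        chords_df("base1", 0L, c(0, 0, 7), "major"),
        chords_df("base2", 0L, c(0, 5), "major"),
        chords_df("late1", 0L, c(0, 6), c("major", "minor")))
      chord_corpus(songs, chords, encoding = "root_third",
                   provenance = list(fixture = "oov"))
    })
}
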