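# The chord_corpus container: a song-level metadata table plus a long
# chord table (one row per chord occurrence), mirroring the tab-separated
# interchange format on disk.

CORPUS_SONG_COLS <- c("song_id", "release_year", "release_month",
                      "peak_position", "weeks_on_chart", "genre")
CORPUS_CHORD_COLS <- c("song_id", "section_index", "section_label",
                       "chord_interval", "chord_quality")

#' Construct a chord corpus
#'
#' A corpus couples a song metadata table with a long table of
#' key-relative chord occurrences. Chord rows are kept in within-song
#' time order; `section_index` is 0-based and groups chords into the
#' sections whose mean surprisal the contrastive measure compares.
#'
#' @param songs `data.frame` with columns `song_id`, `release_year`,
#'   `release_month`, `peak_position`, `weeks_on_chart`, `genre`.
#' @param chords `data.frame` with columns `song_id`, `section_index`,
#'   `section_label`, `chord_interval` (0..11), `chord_quality`.
#' @param encoding `"full"` (qualities up to sevenths and beyond) or
#'   `"root_third"` (24-symbol alphabet, qualities `major`/`minor`).
#' @param provenance Free-form metadata list.
#' @return An object of class `chord_corpus`.
#' @export
chord_corpus <- function(songs, chords, encoding = c("full", "root_third"),
                         provenance = list()) {
  encoding <- match.arg(encoding)
  songs <- as.data.frame(songs, stringsAsFactors = FALSE)
  chords <- as.data.frame(chords, stringsAsFactors = FALSE)
  missing_s <- setdiff(CORPUS_SONG_COLS, names(songs))
  missing_c <- setdiff(CORPUS_CHORD_COLS, names(chords))
  if (length(missing_s) || length(missing_c)) {
    stop("missing required columns: ",
         paste(c(missing_s, missing_c), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(songs$song_id)) {
    stop("duplicate song_id in songs table", call. = FALSE)
  }
  if (any(songs$peak_position < 1L, na.rm = TRUE)) {
    stop("peak_position must be >= 1", call. = FALSE)
  }
  if (any(songs$release_month < 1L | songs$release_month > 12L)) {
    stop("release_month must lie in 1..12", call. = FALSE)
  }
  orphan <- setdiff(chords$song_id, songs$song_id)
  if (length(orphan)) {
    stop("chord rows reference unknown song_id: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  bad_iv <- chords$chord_interval < 0L | chords$chord_interval > 11L
  if (any(bad_iv)) stop("chord_interval must lie in 0..11", call. = FALSE)
  chords$chord_interval <- as.integer(chords$chord_interval)
  chords$section_index <- as.integer(chords$section_index)
  if (encoding == "root_third" &&
      !all(chords$chord_quality %in% c("major", "minor"))) {
    stop("root_third corpora admit only qualities 'major' and 'minor'",
         call. = FALSE)
  }
  rownames(songs) <- NULL
  rownames(chords) <- NULL
  structure(list(songs = songs, chords = chords, encoding = encoding,
                 provenance = provenance),
            class = "chord_corpus")
}

#' @export
print.chord_corpus <- function(x, ...) {
  span <- range(x$songs$release_year)
  cat(sprintf("<chord_corpus> %d songs, %d chord occurrences, %d unique chords\n",
              nrow(x$songs), nrow(x$chords),
              length(unique(canonical_chord(x$chords$chord_interval,
                                            x$chords$chord_quality)))))
  cat(sprintf("  encoding: %s; release years %d-%d\n",
              x$encoding, span[1L], span[2L]))
  invisible(x)
}

#' Number of songs in a corpus
#' @param x A `chord_corpus`.
#' @param ... Unused.
#' @export
length.chord_corpus <- function(x) nrow(x$songs)

# Canonical chord id for every chord row.
corpus_canonical <- function(corpus) {
  canonical_chord(corpus$chords$chord_interval, corpus$chords$chord_quality)
}

# Release date as fractional years (year + (month - 1)/12).
fractional_year <- function(year, month) year + (month - 1) / 12

# Release date as a month index, for window arithmetic.
month_index <- function(year, month) year * 12L + (month - 1L)

# Parse "YYYY-MM" into c(year, month).
parse_ym <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{1,2})$", x))[[1]]
  if (length(m) == 0L) stop("expected 'YYYY-MM', got ", sQuote(x), call. = FALSE)
  c(as.integer(m[2L]), as.integer(m[3L]))
}

#' Reduce a corpus to the root-third encoding
#'
#' Folds every chord onto the 24-symbol root-third alphabet using
#' [quality_third_map()]. Thirdless chords are dropped (they have no
#' major/minor image); the number dropped is recorded in the provenance.
#'
#' @param corpus A `chord_corpus` in `full` encoding.
#' @param table Quality fold table.
#' @return A `chord_corpus` with `encoding = "root_third"`.
#' @export
corpus_to_root_third <- function(corpus, table = quality_third_map()) {
  stopifnot(inherits(corpus, "chord_corpus"))
  third <- fold_thirds(corpus$chords$chord_quality, table)
  keep <- !is.na(third)
  chords <- corpus$chords[keep, , drop = FALSE]
  chords$chord_quality <- third[keep]
  prov <- corpus$provenance
  prov$n_thirdless_dropped <- sum(!keep)
  chord_corpus(corpus$songs, chords, encoding = "root_third",
               provenance = prov)
}

#' Split songs into fixed-length chord windows
#'
#' Replaces section structure with consecutive windows of `W` chords
#' (the final window may be shorter). Used when annotations carry no
#' section labels but a contrastive (between-section) measure is wanted.
#'
#' @param corpus A `chord_corpus`.
#' @param W Window length in chords (default 16).
#' @return A `chord_corpus` whose sections are the windows.
#' @export
window_sections <- function(corpus, W = 16L) {
  stopifnot(inherits(corpus, "chord_corpus"), W >= 1L)
  ch <- corpus$chords
  pos <- stats::ave(seq_len(nrow(ch)), ch$song_id, FUN = seq_along) - 1L
  ch$section_index <- pos %/% as.integer(W)
  ch$section_label <- sprintf("w%02d", ch$section_index)
  chord_corpus(corpus$songs, ch, encoding = corpus$encoding,
               provenance = corpus$provenance)
}

#' Read a corpus interchange table
#'
#' The interchange format is a UTF-8, tab-delimited long table with one
#' row per chord occurrence and a single header line; columns are
#' `song_id`, `release_year`, `release_month`, `peak_position`,
#' `weeks_on_chart`, `genre`, `section_index`, `section_label`,
#' `chord_interval`, `chord_quality`. Row order within a song is the
#' chord time order and is preserved.
#'
#' @param path File path.
#' @param encoding Chord encoding declared for the corpus.
#' @return A `chord_corpus`.
#' @seealso [write_corpus_table()]
#' @export
read_corpus_table <- function(path, encoding = c("full", "root_third")) {
  encoding <- match.arg(encoding)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                           quote = "", na.strings = "NA",
                           colClasses = c(song_id = "character",
                                          section_label = "character",
                                          chord_quality = "character",
                                          genre = "character"))
  required <- c(CORPUS_SONG_COLS, "section_index", "section_label",
                "chord_interval", "chord_quality")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("corpus table ", sQuote(path), " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    songs <- tab[, CORPUS_SONG_COLS]
    chords <- tab[, CORPUS_CHORD_COLS]
    return(chord_corpus(songs[0L, ], chords[0L, ], encoding = encoding))
  }
  songs <- unique(tab[, CORPUS_SONG_COLS])
  if (anyDuplicated(songs$song_id)) {
    stop("inconsistent song metadata across rows of the same song_id",
         call. = FALSE)
  }
  chords <- tab[, CORPUS_CHORD_COLS]
  chord_corpus(songs, chords, encoding = encoding,
               provenance = list(source = path))
}

#' Write a corpus interchange table
#'
#' Emits the tab-separated long format that [read_corpus_table()] reads
#' back; the two functions are inverses on valid corpora. An empty corpus
#' writes a header-only file.
#'
#' @param corpus A `chord_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_table <- function(corpus, path) {
  stopifnot(inherits(corpus, "chord_corpus"))
  idx <- match(corpus$chords$song_id, corpus$songs$song_id)
  tab <- cbind(corpus$songs[idx, CORPUS_SONG_COLS, drop = FALSE],
               corpus$chords[, c("section_index", "section_label",
                                 "chord_interval", "chord_quality"),
                             drop = FALSE])
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
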