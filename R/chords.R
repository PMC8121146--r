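# Chord-label parsing, key normalization, and encoding schemes.
#
# Pitch classes are integers 0..11 with C = 0; all enharmonic spellings
# (Db == C#) fold onto the same integer, so the root vocabulary is finite
# and transposition is plain mod-12 arithmetic.

.PC_LETTER <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Convert a note name to a pitch class
#'
#' Accepts letter names `A`..`G` with optional `#`/`b` accidentals (doubled
#' accidentals allowed), or an integer already in `0..11`. All enharmonic
#' spellings fold onto 12 integer pitch classes with C = 0.
#'
#' @param x Character note name(s) or integer pitch class(es).
#' @return Integer vector of pitch classes in `0..11`.
#' @examples
#' pitch_class(c("C", "Db", "C#", "Gb"))
#' @export
pitch_class <- function(x) {
  if (is.numeric(x)) {
    pc <- as.integer(x)
    if (any(is.na(pc) | pc < 0L | pc > 11L)) {
      stop("integer pitch classes must lie in 0..11", call. = FALSE)
    }
    return(pc)
  }
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-G])(#{1,2}|b{1,2})?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("not a note name: ", paste(sQuote(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  letter <- vapply(m, `[`, "", 2L)
  acc <- vapply(m, `[`, "", 3L)
  shift <- ifelse(acc == "", 0L,
                  nchar(acc) * ifelse(substr(acc, 1, 1) == "#", 1L, -1L))
  (unname(.PC_LETTER[letter]) + shift) %% 12L
}

.NOCHORD_TOKENS <- c("N", "&pause", "*")

#' Parse a chord annotation token
#'
#' Tokens follow the `ROOT(:QUALITY)?` grammar of hand-transcribed chart
#' annotations: a note name, optionally a colon and a quality token
#' (`maj7`, `min`, `7`, ...). A missing quality defaults to `maj`. An
#' inversion suffix (`/5`, `/b7`) is discarded. The no-chord tokens
#' (`N`, `&pause`, `*`) return a sentinel that downstream operations skip.
#'
#' @param text A single annotation token.
#' @return An object of class `chord_label` with fields `root` (pitch
#'   class 0..11), `quality` (character) and `raw` (the original token),
#'   or the no-chord sentinel (`is_no_chord()` is `TRUE`).
#' @examples
#' parse_chord_label("A:maj7")
#' parse_chord_label("C")      # quality defaults to maj
#' is_no_chord(parse_chord_label("N"))
#' @export
parse_chord_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text %in% .NOCHORD_TOKENS) {
    return(structure(list(root = NA_integer_, quality = NA_character_,
                          raw = text, no_chord = TRUE),
                     class = "chord_label"))
  }
  # strip inversion / bass-note suffix
  core <- sub("/.*$", "", text)
  m <- regexec("^([A-G](?:#{1,2}|b{1,2})?)(?::([A-Za-z0-9#b+()]+))?$", core)
  g <- regmatches(core, m)[[1]]
  if (length(g) == 0L) {
    stop("malformed chord token: ", sQuote(text), call. = FALSE)
  }
  quality <- if (is.na(g[3L]) || g[3L] == "") "maj" else g[3L]
  structure(list(root = pitch_class(g[2L]), quality = quality,
                 raw = text, no_chord = FALSE),
            class = "chord_label")
}

#' @rdname parse_chord_label
#' @param x An object returned by [parse_chord_label()].
#' @export
is_no_chord <- function(x) isTRUE(x$no_chord)

#' @export
print.chord_label <- function(x, ...) {
  if (is_no_chord(x)) {
    cat("<no-chord>\n")
  } else {
    cat(sprintf("<chord_label> root=%d quality=%s (raw %s)\n",
                x$root, x$quality, sQuote(x$raw)))
  }
  invisible(x)
}

#' Describe a key context
#'
#' @param tonic Tonic as a note name or pitch class `0..11`.
#' @param mode One of `"major"`, `"minor"`, `"unspecified"`.
#' @return A `key_context` object.
#' @examples
#' key_context("Eb")
#' @export
key_context <- function(tonic, mode = c("unspecified", "major", "minor")) {
  mode <- match.arg(mode)
  structure(list(tonic = pitch_class(tonic), mode = mode),
            class = "key_context")
}

#' Normalize a chord to its key
#'
#' Re-expresses a chord relative to a song's tonic: the root becomes the
#' interval-from-tonic in semitones, `(root - tonic) mod 12`, and the
#' quality is carried over unchanged. After normalization, chord
#' distributions are invariant under transposition of the whole corpus.
#'
#' @param chord A `chord_label` (not the no-chord sentinel).
#' @param key A [key_context()].
#' @return A `relative_chord` with fields `interval` (0..11) and `quality`.
#' @examples
#' normalize_to_key(parse_chord_label("G:maj"), key_context("C"))
#' @export
normalize_to_key <- function(chord, key) {
  stopifnot(inherits(chord, "chord_label"), inherits(key, "key_context"))
  if (is_no_chord(chord)) {
    stop("cannot normalize the no-chord sentinel", call. = FALSE)
  }
  relative_chord((chord$root - key$tonic) %% 12L, chord$quality)
}

#' Construct a key-relative chord
#'
#' @param interval Semitones from the tonic, in `0..11`.
#' @param quality Quality token.
#' @return A `relative_chord` object.
#' @export
relative_chord <- function(interval, quality) {
  interval <- as.integer(interval)
  stopifnot(length(interval) == 1L, !is.na(interval),
            interval >= 0L, interval <= 11L,
            is.character(quality), length(quality) == 1L)
  structure(list(interval = interval, quality = quality),
            class = "relative_chord")
}

#' @export
print.relative_chord <- function(x, ...) {
  cat(sprintf("<relative_chord> %s\n", canonical_chord(x$interval, x$quality)))
  invisible(x)
}

#' Canonical string form of a key-relative chord
#'
#' The canonical form `"<interval>:<quality>"` is unique per
#' (interval, quality) pair and is the unit whose corpus frequency the
#' surprise model measures.
#'
#' @param interval Integer vector of intervals `0..11`.
#' @param quality Character vector of quality tokens.
#' @return Character vector of canonical chord identifiers.
#' @examples
#' canonical_chord(7, "maj")
#' @export
canonical_chord <- function(interval, quality) {
  paste(as.integer(interval), quality, sep = ":")
}

#' Quality fold table for the root-third encoding
#'
#' Maps full quality tokens onto a major or minor third. Thirdless
#' qualities (suspensions, bare fifths/roots) have no image and map to
#' `NA`; the reducer's policy decides whether they are dropped or an
#' error. The table can be extended or overridden by the caller.
#'
#' @return Named character vector: quality token -> `"major"`/`"minor"`/`NA`.
#' @export
quality_third_map <- function() {
  majors <- c("maj", "maj7", "maj6", "6", "7", "9", "11", "13", "maj9",
              "maj13", "aug", "add9", "maj(9)", "7(#9)", "7(b9)")
  minors <- c("min", "min7", "min6", "min9", "min11", "min13", "dim",
              "dim7", "hdim7", "minmaj7", "min(9)")
  thirdless <- c("sus2", "sus4", "sus", "5", "1")
  c(stats::setNames(rep("major", length(majors)), majors),
    stats::setNames(rep("minor", length(minors)), minors),
    stats::setNames(rep(NA_character_, length(thirdless)), thirdless))
}

#' Reduce a chord to the root-third encoding
#'
#' Collapses the full quality vocabulary onto the 24-symbol alphabet of
#' 12 roots crossed with a major or minor third. Major-family qualities
#' (maj, maj7, dominant 7, aug, ...) fold to `major`; minor-family
#' qualities (min, min7, dim, ...) fold to `minor`. Thirdless chords have
#' no defined image: under `on_unmappable = "drop"` (default) they return
#' `NULL` so callers can skip them.
#'
#' @param chord A `relative_chord`.
#' @param table Quality fold table, as from [quality_third_map()].
#' @param on_unmappable `"drop"` (return `NULL`) or `"error"`.
#' @return A `relative_chord` with quality in `{major, minor}`, or `NULL`.
#' @examples
#' reduce_to_root_third(relative_chord(7, "maj7"))
#' @export
reduce_to_root_third <- function(chord, table = quality_third_map(),
                                 on_unmappable = c("drop", "error")) {
  stopifnot(inherits(chord, "relative_chord"))
  on_unmappable <- match.arg(on_unmappable)
  q <- chord$quality
  if (q %in% c("major", "minor")) return(chord)  # already reduced
  third <- if (q %in% names(table)) table[[q]] else NA_character_
  if (is.na(third)) {
    if (on_unmappable == "error") {
      stop("quality ", sQuote(q), " has no major/minor third image",
           call. = FALSE)
    }
    return(NULL)
  }
  relative_chord(chord$interval, third)
}

# Vectorized internals used by the corpus readers -------------------------

# Parse a character vector of chord tokens into a data.frame with columns
# root, quality, no_chord; malformed tokens raise with the token text.
parse_chord_tokens <- function(tokens) {
  n <- length(tokens)
  out <- data.frame(root = rep(NA_integer_, n),
                    quality = rep(NA_character_, n),
                    no_chord = tokens %in% .NOCHORD_TOKENS)
  todo <- which(!out$no_chord)
  if (length(todo)) {
    core <- sub("/.*$", "", tokens[todo])
    m <- regmatches(core,
                    regexec("^([A-G](?:#{1,2}|b{1,2})?)(?::([A-Za-z0-9#b+()]+))?$",
                            core))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) {
      stop("malformed chord token: ",
           paste(sQuote(tokens[todo][bad]), collapse = ", "), call. = FALSE)
    }
    root_txt <- vapply(m, `[`, "", 2L)
    qual <- vapply(m, `[`, "", 3L)
    qual[is.na(qual) | qual == ""] <- "maj"
    out$root[todo] <- pitch_class(root_txt)
    out$quality[todo] <- qual
  }
  out
}

# Vectorized root-third fold over quality tokens; returns "major"/"minor"/NA.
fold_thirds <- function(quality, table = quality_third_map()) {
  out <- rep(NA_character_, length(quality))
  out[quality %in% c("major", "maj")] <- "major"
  out[quality == "minor"] <- "minor"
  hit <- is.na(out) & quality %in% names(table)
  out[hit] <- unname(table[quality[hit]])
  out
}
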