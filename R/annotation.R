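# Reader for hand-transcription annotation files in the style of chart
# chord corpora: '#'-prefixed headers (title, artist, tonic, metre), then
# timestamped body lines with comma-terminated section labels and
# '|'-delimited bars of chord tokens. Chords are normalized at read time
# against the tonic in force at their position, so files that modulate
# mid-song are handled per chord.

#' Read one annotation file
#'
#' File dialect: header lines `# key: value` (a `tonic` header is
#' mandatory before the first chord and may recur to declare a
#' modulation), then body lines `time<TAB>content`. Content starts with
#' optional comma-terminated section-label tokens (`A,` `verse,`) that
#' open a new section, followed by bars delimited by `|` containing chord
#' tokens in `ROOT(:QUALITY)?` syntax. A `.` token repeats the previous
#' chord; `N` and `&pause` are no-chord tokens and are skipped.
#'
#' @param path Path to an annotation file.
#' @param id Song identifier; defaults to the file name without extension.
#' @return An `annotated_song`: a list with `id`, `title`, `artist`,
#'   `metre`, and a `chords` data.frame (`section_index`, `section_label`,
#'   `chord_interval`, `chord_quality`, `raw`, `tonic`).
#' @export
read_annotation_file <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  meta <- list(title = NA_character_, artist = NA_character_,
               metre = NA_character_)
  tonic <- NA_integer_
  sec_idx <- -1L
  sec_label <- NA_character_
  prev <- NULL  # previous chord row, for '.' repetition
  rows <- vector("list", 0L)

  fail <- function(lineno, msg) {
    stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*([A-Za-z]+)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0L) next  # bare comment
      key <- tolower(m[2L]); val <- trimws(m[3L])
      if (key == "tonic") {
        tonic <- tryCatch(pitch_class(val),
                          error = function(e) fail(i, conditionMessage(e)))
      } else if (key %in% names(meta)) {
        meta[[key]] <- val
      }
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) fail(i, "expected 'time<TAB>content'")
    if (is.na(suppressWarnings(as.numeric(parts[1L])))) {
      fail(i, paste0("invalid timestamp ", sQuote(parts[1L])))
    }
    content <- trimws(paste(parts[-1L], collapse = "\t"))
    if (content %in% c("", "silence", "end", "Z")) next

    bars <- strsplit(content, "|", fixed = TRUE)[[1]]
    # segment before the first '|' may carry section labels
    pre <- trimws(bars[1L])
    if (pre != "") {
      toks <- strsplit(pre, "\\s+")[[1]]
      labs <- toks[grepl(",$", toks)]
      if (length(labs) != length(toks)) {
        fail(i, "unexpected tokens before first bar")
      }
      if (length(labs)) {
        sec_idx <- sec_idx + 1L
        sec_label <- paste(sub(",$", "", labs), collapse = " ")
      }
    }
    bar_toks <- unlist(strsplit(trimws(bars[-1L]), "\\s+"))
    bar_toks <- bar_toks[!is.na(bar_toks) & bar_toks != ""]
    if (length(bar_toks) == 0L) next
    if (sec_idx < 0L) {  # chords before any section label: implicit section
      sec_idx <- 0L
      sec_label <- "s00"
    }
    for (tok in bar_toks) {
      if (tok == ".") {
        if (is.null(prev)) fail(i, "'.' with no previous chord")
        row <- prev
        row$section_index <- sec_idx
        row$section_label <- sec_label
        rows[[length(rows) + 1L]] <- row
        next
      }
      cl <- tryCatch(parse_chord_label(tok),
                     error = function(e) fail(i, conditionMessage(e)))
      if (is_no_chord(cl)) { prev <- NULL; next }
      if (is.na(tonic)) fail(i, "chord encountered before any '# tonic:' header")
      row <- list(section_index = sec_idx, section_label = sec_label,
                  chord_interval = (cl$root - tonic) %% 12L,
                  chord_quality = cl$quality, raw = tok, tonic = tonic)
      rows[[length(rows) + 1L]] <- row
      prev <- row
    }
  }
  if (is.na(tonic)) {
    stop(sprintf("%s: no '# tonic:' header; key normalization impossible", path),
         call. = FALSE)
  }
  chords <- if (length(rows)) {
    do.call(rbind, lapply(rows, as.data.frame))
  } else {
    data.frame(section_index = integer(), section_label = character(),
               chord_interval = integer(), chord_quality = character(),
               raw = character(), tonic = integer())
  }
  structure(c(list(id = id), meta, list(chords = chords)),
            class = "annotated_song")
}

#' @export
print.annotated_song <- function(x, ...) {
  cat(sprintf("<annotated_song> %s: %d chords in %d sections\n",
              x$id, nrow(x$chords),
              length(unique(x$chords$section_index))))
  invisible(x)
}

#' Assemble annotation files into a corpus
#'
#' Reads each file with [read_annotation_file()] and joins chart metadata
#' by song id to produce an analysable [chord_corpus()].
#'
#' @param paths Character vector of annotation file paths.
#' @param metadata `data.frame` with columns `song_id`, `release_year`,
#'   `release_month`, `peak_position`, `weeks_on_chart` and optionally
#'   `genre`, one row per file (matched on song id).
#' @param ids Song ids for the files; defaults to file names.
#' @return A `chord_corpus` in `full` encoding.
#' @export
read_annotation_corpus <- function(paths, metadata, ids = NULL) {
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(ids) == length(paths), !anyDuplicated(ids))
  if (!"genre" %in% names(metadata)) metadata$genre <- NA_character_
  missing <- setdiff(ids, metadata$song_id)
  if (length(missing)) {
    stop("no chart metadata for song(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  songs <- lapply(seq_along(paths),
                  function(k) read_annotation_file(paths[[k]], id = ids[[k]]))
  chords <- do.call(rbind, lapply(songs, function(s) {
    if (nrow(s$chords) == 0L) return(NULL)
    cbind(song_id = s$id,
          s$chords[, c("section_index", "section_label",
                       "chord_interval", "chord_quality")])
  }))
  meta <- metadata[match(ids, metadata$song_id), c(CORPUS_SONG_COLS)]
  chord_corpus(meta, chords, encoding = "full",
               provenance = list(source = "annotation files"))
}
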