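# Builders shared across test files.

# A minimal songs table with sequential peaks.
songs_table <- function(n, year = 1960, peak = seq_len(n),
                        weeks = rep(10L, n), genre = "pop",
                        month = rep(1L, n)) {
  data.frame(song_id = sprintf("s%03d", seq_len(n)),
             release_year = rep_len(year, n),
             release_month = rep_len(month, n),
             peak_position = rep_len(peak, n),
             weeks_on_chart = rep_len(weeks, n),
             genre = rep_len(genre, n), stringsAsFactors = FALSE)
}

# One chord row per (interval, quality), single section, for every song.
uniform_chords <- function(song_ids, iv = c(0, 7), q = "major") {
  k <- length(song_ids)
  data.frame(song_id = rep(song_ids, each = length(iv)),
             section_index = rep(0L, k * length(iv)),
             section_label = rep("sec00", k * length(iv)),
             chord_interval = rep(iv, times = k),
             chord_quality = rep(rep_len(q, length(iv)), times = k),
             stringsAsFactors = FALSE)
}

# Write annotation-file text and return its path.
write_annotation <- function(lines, file = tempfile(fileext = ".txt")) {
  writeLines(lines, file)
  file
}

# Small synthetic annotation corpus on disk: n songs spread over the
# given years, simple I-IV-V-vi progressions with occasional colour
# chords, two sections each. Returns list(paths, metadata).
synthetic_annotation_set <- function(n, years, seed = 1) {
  set.seed(seed)
  tonics <- c("C", "G", "D", "A", "E", "Bb", "F")
  qualities <- c("maj", "maj", "maj", "min", "maj7", "min7", "7")
  roots <- c("C", "F", "G", "A", "D", "E", "B")
  paths <- character(n); ids <- sprintf("song%03d", seq_len(n))
  for (i in seq_len(n)) {
    tonic <- sample(tonics, 1)
    bar <- function() {
      paste(paste0(sample(roots, 4, replace = TRUE), ":",
                   sample(qualities, 4, replace = TRUE)), collapse = " ")
    }
    lines <- c(sprintf("# title: synthetic %d", i),
               "# artist: none",
               sprintf("# tonic: %s", tonic),
               "# metre: 4/4",
               sprintf("0.0\tA, verse, | %s | %s |", bar(), bar()),
               sprintf("8.0\tB, chorus, | %s | %s |", bar(), bar()))
    paths[i] <- write_annotation(lines)
  }
  metadata <- data.frame(song_id = ids,
                         release_year = sample(years, n, replace = TRUE),
                         release_month = sample(1:12, n, replace = TRUE),
                         peak_position = sample(1:100, n, replace = TRUE),
                         weeks_on_chart = sample(1:40, n, replace = TRUE),
                         genre = sample(c("pop", "rock"), n, replace = TRUE),
                         stringsAsFactors = FALSE)
  list(paths = paths, ids = ids, metadata = metadata)
}
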