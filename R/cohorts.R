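# Chart-preference cohorts: songs are ordered by peak chart position
# (1 = best), ties broken by weeks on chart (more = better) and then by
# song id so the ordering is deterministic; the top and bottom floor(n/4)
# of the ordering form the preference quartiles Q1 and Q4. Release dates
# are mapped onto month-bounded, non-overlapping time bins.

#' Rank songs by chart preference
#'
#' Ascending peak chart position, ties broken by descending weeks on
#' chart, residual ties by song id (lexicographic) so the ranking is a
#' deterministic function of the metadata.
#'
#' @param songs Song metadata `data.frame` (columns `song_id`,
#'   `peak_position`, `weeks_on_chart`).
#' @return The same rows reordered best-first, with a `rank` column.
#' @export
rank_songs <- function(songs) {
  need <- c("song_id", "peak_position", "weeks_on_chart")
  stopifnot(all(need %in% names(songs)))
  bad <- songs$song_id[is.na(songs$peak_position) |
                       is.na(songs$weeks_on_chart)]
  if (length(bad)) {
    stop("missing chart metadata for song(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(songs$peak_position, -songs$weeks_on_chart, songs$song_id)
  out <- songs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify songs into preference quartiles (global rule)
#'
#' Orders the whole corpus with [rank_songs()]; the top `floor(n/4)`
#' songs are Q1, the bottom `floor(n/4)` are Q4, the rest MID. With 545
#' songs this yields 136 songs in each extreme quartile.
#'
#' @param corpus A `chord_corpus`, or a song metadata `data.frame`.
#' @return `data.frame` with `song_id`, `rank` and `quartile`
#'   (factor with levels `Q1`, `MID`, `Q4`).
#' @export
classify_quartiles_global <- function(corpus) {
  songs <- if (inherits(corpus, "chord_corpus")) corpus$songs else corpus
  n <- nrow(songs)
  if (n < 4L) stop("need at least 4 songs to form quartiles", call. = FALSE)
  ranked <- rank_songs(songs)
  k <- n %/% 4L
  quartile <- rep("MID", n)
  quartile[seq_len(k)] <- "Q1"
  quartile[seq(n - k + 1L, n)] <- "Q4"
  data.frame(song_id = ranked$song_id, rank = ranked$rank,
             quartile = factor(quartile, levels = c("Q1", "MID", "Q4")),
             stringsAsFactors = FALSE)
}

#' Classify songs into preference quartiles (grouped rule)
#'
#' Applies the global rule independently within each group (by default
#' release year crossed with genre) and takes the union of the per-group
#' Q1/Q4 sets. Groups with fewer than 4 songs contribute no extreme-
#' quartile members; they are reported via a warning.
#'
#' @param corpus A `chord_corpus` or song metadata `data.frame`.
#' @param keys Character vector of grouping columns
#'   (default `c("release_year", "genre")`).
#' @return `data.frame` with `song_id`, `group`, `rank` (within group)
#'   and `quartile`.
#' @export
classify_quartiles_grouped <- function(corpus,
                                       keys = c("release_year", "genre")) {
  songs <- if (inherits(corpus, "chord_corpus")) corpus$songs else corpus
  stopifnot(all(keys %in% names(songs)))
  grp <- interaction(songs[keys], drop = TRUE, sep = "/")
  pieces <- lapply(split(songs, grp), function(g) {
    n <- nrow(g)
    ranked <- rank_songs(g)
    k <- n %/% 4L
    quartile <- rep("MID", n)
    if (k >= 1L) {
      quartile[seq_len(k)] <- "Q1"
      quartile[seq(n - k + 1L, n)] <- "Q4"
    }
    data.frame(song_id = ranked$song_id, rank = ranked$rank,
               quartile = quartile, stringsAsFactors = FALSE)
  })
  small <- names(pieces)[vapply(pieces, nrow, 1L) < 4L]
  if (length(small)) {
    warning("group(s) with fewer than 4 songs contribute no Q1/Q4 members: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, Map(function(g, nm) cbind(group = nm, g),
                            pieces, names(pieces)))
  rownames(out) <- NULL
  out$quartile <- factor(out$quartile, levels = c("Q1", "MID", "Q4"))
  out
}

#' Define a set of release-date time bins
#'
#' @param name Bin names (character).
#' @param start,end Inclusive month boundaries as `"YYYY-MM"` strings.
#' @return A `data.frame` of class `time_bins`; bins must be ordered and
#'   non-overlapping.
#' @export
time_bins <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  s <- t(vapply(start, parse_ym, integer(2L)))
  e <- t(vapply(end, parse_ym, integer(2L)))
  smi <- month_index(s[, 1L], s[, 2L])
  emi <- month_index(e[, 1L], e[, 2L])
  if (any(emi < smi)) stop("bin end precedes bin start", call. = FALSE)
  if (is.unsorted(smi, strictly = TRUE) ||
      any(smi[-1L] <= emi[-length(emi)])) {
    stop("time bins must be ordered and non-overlapping", call. = FALSE)
  }
  structure(data.frame(name = as.character(name), start = start, end = end,
                       start_index = smi, end_index = emi,
                       stringsAsFactors = FALSE),
            class = c("time_bins", "data.frame"))
}

#' Default time bins for the 1958-1991 chart-transcription corpus
#'
#' Four bins: August 1958-January 1975 (the baseline era), then three
#' 5.5-year bins through November 1991.
#'
#' @return A [time_bins()] object.
#' @export
mcgill_bins <- function() {
  time_bins(c("bin1", "bin2", "bin3", "bin4"),
            start = c("1958-08", "1975-02", "1980-08", "1986-02"),
            end   = c("1975-01", "1980-07", "1986-01", "1991-11"))
}

#' Default time bins for the 2000-2019 chart corpus
#'
#' Four 5-year bins, January 2000-December 2019; the first
#' (2000-2004) is the baseline era.
#'
#' @return A [time_bins()] object.
#' @export
scl_bins <- function() {
  time_bins(c("bin1", "bin2", "bin3", "bin4"),
            start = c("2000-01", "2005-01", "2010-01", "2015-01"),
            end   = c("2004-12", "2009-12", "2014-12", "2019-12"))
}

#' Equal-width year bins spanning a corpus
#'
#' Splits the corpus release span into `k` consecutive bins of whole
#' years (the last takes any remainder). Convenient for synthetic
#' corpora whose span is configurable.
#'
#' @param corpus A `chord_corpus`.
#' @param k Number of bins (default 4).
#' @return A [time_bins()] object.
#' @export
span_bins <- function(corpus, k = 4L) {
  yrs <- range(corpus$songs$release_year)
  n_years <- yrs[2L] - yrs[1L] + 1L
  per <- n_years %/% k
  if (per < 1L) stop("corpus span too short for ", k, " bins", call. = FALSE)
  start_y <- yrs[1L] + per * (seq_len(k) - 1L)
  end_y <- c(start_y[-1L] - 1L, yrs[2L])
  time_bins(sprintf("bin%d", seq_len(k)),
            start = sprintf("%04d-01", start_y),
            end = sprintf("%04d-12", end_y))
}

#' Read time bins from a YAML config
#'
#' Expects a list of `{name, start: "YYYY-MM", end: "YYYY-MM"}` entries.
#'
#' @param x Path to a YAML file, or an already-parsed list.
#' @return A [time_bins()] object.
#' @export
bins_from_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x$bins)) x <- x$bins
  time_bins(vapply(x, `[[`, "", "name"),
            vapply(x, `[[`, "", "start"),
            vapply(x, `[[`, "", "end"))
}

#' Assign songs to time bins
#'
#' Month-granular, inclusive on both boundaries. Every song must fall in
#' exactly one bin; a song outside the bin span is an error naming it.
#'
#' @param corpus A `chord_corpus` or song metadata `data.frame`.
#' @param bins A [time_bins()] object.
#' @return `data.frame` with `song_id` and `bin` (factor ordered as the
#'   bins are).
#' @export
assign_time_bins <- function(corpus, bins) {
  songs <- if (inherits(corpus, "chord_corpus")) corpus$songs else corpus
  stopifnot(inherits(bins, "time_bins"))
  mi <- month_index(songs$release_year, songs$release_month)
  idx <- rep(NA_integer_, length(mi))
  for (b in seq_len(nrow(bins))) {
    hit <- mi >= bins$start_index[b] & mi <= bins$end_index[b]
    idx[hit] <- b
  }
  if (anyNA(idx)) {
    off <- songs$song_id[is.na(idx)]
    stop("song(s) outside the bin span: ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(song_id = songs$song_id,
             bin = factor(bins$name[idx], levels = bins$name),
             stringsAsFactors = FALSE)
}
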