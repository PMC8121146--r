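# The central fit: run the complete surprise-inflation analysis on a
# corpus and return one object holding every intermediate and
# inferential result, with the usual methods (print, summary, coef,
# plot) on top.

#' Fit the surprise-inflation analysis to a corpus
#'
#' Runs the full pipeline: estimates the reference chord distribution
#' from the baseline window (by default the first time bin — the
#' reference is never re-estimated for later bins), scores every song's
#' absolute surprise (mean chord surprisal in bits) and contrastive
#' surprise (SD of per-section mean surprisal), classifies preference
#' quartiles, and tests for temporal change: per-quartile
#' Jonckheere-Terpstra trends over the ordered time bins, per-song OLS
#' trends in bits/year, a two-slope equivalence test between Q1 and Q4,
#' Q1-vs-Q4 t-tests within the baseline bin and pooled over the later
#' bins, and the new-chord introduction analysis.
#'
#' @param corpus A [chord_corpus()].
#' @param bins A [time_bins()] set; default splits the corpus span into
#'   4 equal bins ([span_bins()]).
#' @param baseline Baseline window `c("YYYY-MM", "YYYY-MM")`; default is
#'   the first bin.
#' @param quartile_rule `"global"` (one ranking over the whole corpus)
#'   or `"grouped"` (independent rankings within `group_keys` cells).
#' @param group_keys Grouping columns for the grouped rule.
#' @param oov Out-of-vocabulary chord policy, see [chord_surprise()].
#' @param reference Optional pre-built [chord_distribution()] overriding
#'   the baseline estimate (used e.g. to score against a known
#'   generative distribution).
#' @param new_chord_count Attribution mode for [new_chord_report()].
#' @return An object of class `harmonic_inflation`; see Details.
#' @details The returned object contains `profiles` (per-song table with
#'   surprise values, bin, quartile and fractional release time),
#'   `distribution`, `bin_means` (per measure x bin x quartile mean and
#'   standard error), `jt`, `trends`, `slope_tests`, `t_tests`,
#'   `new_chords`, and the `bins`/`call` metadata.
#' @examples
#' corp <- generate_corpus(synth_config(n_years = 8, songs_per_year = 40),
#'                         seed = 42)
#' fit <- harmonic_inflation(corp)
#' coef(fit)
#' @export
harmonic_inflation <- function(corpus, bins = NULL, baseline = NULL,
                               quartile_rule = c("global", "grouped"),
                               group_keys = c("release_year", "genre"),
                               oov = c("exclude", "laplace", "cap"),
                               reference = NULL,
                               new_chord_count = c("per_chord",
                                                   "per_occurrence")) {
  stopifnot(inherits(corpus, "chord_corpus"))
  quartile_rule <- match.arg(quartile_rule)
  oov <- match.arg(oov)
  new_chord_count <- match.arg(new_chord_count)
  if (is.null(bins)) bins <- span_bins(corpus, 4L)
  if (is.null(baseline)) baseline <- c(bins$start[1L], bins$end[1L])

  dist <- if (is.null(reference)) build_distribution(corpus, baseline)
          else reference
  profiles <- corpus_surprise_profiles(corpus, dist, oov = oov)
  quart <- switch(quartile_rule,
                  global = classify_quartiles_global(corpus),
                  grouped = classify_quartiles_grouped(corpus, group_keys))
  binmap <- assign_time_bins(corpus, bins)

  songs <- corpus$songs
  m <- match(profiles$song_id, songs$song_id)
  profiles$time <- fractional_year(songs$release_year[m],
                                   songs$release_month[m])
  profiles$bin <- binmap$bin[match(profiles$song_id, binmap$song_id)]
  profiles$quartile <- quart$quartile[match(profiles$song_id,
                                            quart$song_id)]

  measures <- c("absolute", "contrastive")
  qs <- c("Q1", "Q4")

  # per-bin means and standard errors, the data behind the bin figures
  bin_means <- do.call(rbind, lapply(measures, function(ms) {
    do.call(rbind, lapply(levels(profiles$bin), function(b) {
      do.call(rbind, lapply(qs, function(q) {
        v <- profiles[[ms]][profiles$bin == b & profiles$quartile == q]
        v <- v[!is.na(v)]
        data.frame(measure = ms, bin = b, quartile = q, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   se = if (length(v) > 1L)
                          stats::sd(v) / sqrt(length(v)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(bin_means) <- NULL

  # an incomputable secondary test (sparse bin x quartile cell) is
  # recorded as an NA result rather than aborting the whole fit
  na_htest <- function(e) {
    structure(list(statistic = c(t = NA_real_), z = NA_real_,
                   parameter = c(df = NA_real_), p.value = NA_real_,
                   estimate = c(mean_x = NA_real_, mean_y = NA_real_),
                   method = "not computable", data.name = "",
                   error = conditionMessage(e)),
              class = "htest")
  }
  jt <- list(); trends <- list(); slope_tests <- list(); t_tests <- list()
  for (ms in measures) {
    for (q in qs) {
      sub <- profiles[profiles$quartile == q & !is.na(profiles[[ms]]), ]
      groups <- split(sub[[ms]], sub$bin)
      jt[[paste(ms, q, sep = "_")]] <-
        tryCatch(jonckheere_terpstra(groups, alternative = "increasing"),
                 error = na_htest)
      trends[[paste(ms, q, sep = "_")]] <- fit_trend(sub$time, sub[[ms]])
    }
    slope_tests[[ms]] <- compare_slopes(trends[[paste0(ms, "_Q1")]],
                                        trends[[paste0(ms, "_Q4")]])
    later <- profiles$bin != levels(profiles$bin)[1L]
    pick <- function(q, rows) {
      v <- profiles[[ms]][rows & profiles$quartile == q]
      v[!is.na(v)]
    }
    t_tests[[paste0(ms, "_bin1")]] <-
      tryCatch(two_sample_t(pick("Q1", !later), pick("Q4", !later)),
               error = na_htest)
    t_tests[[paste0(ms, "_later_bins")]] <-
      tryCatch(two_sample_t(pick("Q1", later), pick("Q4", later)),
               error = na_htest)
  }
  new_chords <- new_chord_report(corpus, quart, count = new_chord_count)

  structure(list(profiles = profiles, distribution = dist,
                 quartiles = quart, bins = bins, baseline = baseline,
                 bin_means = bin_means, jt = jt, trends = trends,
                 slope_tests = slope_tests, t_tests = t_tests,
                 new_chords = new_chords,
                 settings = list(quartile_rule = quartile_rule, oov = oov,
                                 new_chord_count = new_chord_count,
                                 external_reference = !is.null(reference)),
                 call = match.call()),
            class = "harmonic_inflation")
}

#' @export
print.harmonic_inflation <- function(x, ...) {
  cat("Surprise-inflation analysis\n")
  cat(sprintf("  %d songs scored against a %d-chord baseline (%s to %s)\n",
              nrow(x$profiles), x$distribution$N,
              x$baseline[1L], x$baseline[2L]))
  cf <- coef(x)
  cat(sprintf("  absolute surprise slopes (bits/year):    Q1 %+.4f  Q4 %+.4f\n",
              cf["absolute", "Q1"], cf["absolute", "Q4"]))
  cat(sprintf("  contrastive surprise slopes (bits/year): Q1 %+.4f  Q4 %+.4f\n",
              cf["contrastive", "Q1"], cf["contrastive", "Q4"]))
  cat(sprintf("  slope equality (absolute): t = %.2f, df = %d, p = %.3g\n",
              x$slope_tests$absolute$statistic,
              x$slope_tests$absolute$parameter,
              x$slope_tests$absolute$p.value))
  invisible(x)
}

#' Extract fitted surprise trend slopes
#'
#' @param object A `harmonic_inflation` fit.
#' @param ... Unused.
#' @return Matrix of slopes (bits/year): rows `absolute`/`contrastive`,
#'   columns `Q1`/`Q4`.
#' @export
coef.harmonic_inflation <- function(object, ...) {
  out <- matrix(NA_real_, 2L, 2L,
                dimnames = list(c("absolute", "contrastive"),
                                c("Q1", "Q4")))
  for (ms in rownames(out)) {
    for (q in colnames(out)) {
      out[ms, q] <- object$trends[[paste(ms, q, sep = "_")]]$slope
    }
  }
  out
}

#' @export
summary.harmonic_inflation <- function(object, ...) {
  structure(object, class = c("summary.harmonic_inflation",
                              class(object)))
}

#' @export
print.summary.harmonic_inflation <- function(x, ...) {
  print.harmonic_inflation(x)
  cat("\nPer-bin means (+/- SE):\n")
  print(x$bin_means, digits = 4)
  cat("\nTrend tests over ordered bins (Jonckheere-Terpstra, increasing):\n")
  for (nm in names(x$jt)) {
    cat(sprintf("  %-16s J = %10.1f   p = %.3g\n", nm,
                x$jt[[nm]]$statistic, x$jt[[nm]]$p.value))
  }
  cat("\nQ1 vs Q4 t-tests:\n")
  for (nm in names(x$t_tests)) {
    ht <- x$t_tests[[nm]]
    cat(sprintf("  %-24s t = %6.2f   p = %.3g   means %.3f / %.3f\n",
                nm, ht$statistic, ht$p.value,
                ht$estimate[1L], ht$estimate[2L]))
  }
  cat("\nNew-chord introductions:\n")
  print(x$new_chords)
  invisible(x)
}

#' Plot per-bin mean surprise for Q1 and Q4
#'
#' Draws the per-bin quartile means with standard-error bars, one panel
#' per measure (absolute and contrastive surprise), in base graphics.
#'
#' @param x A `harmonic_inflation` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.harmonic_inflation <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ms in c("absolute", "contrastive")) {
    bm <- x$bin_means[x$bin_means$measure == ms, ]
    xi <- as.integer(factor(bm$bin, levels = unique(bm$bin)))
    off <- ifelse(bm$quartile == "Q1", -0.06, 0.06)
    ylim <- range(bm$mean - bm$se, bm$mean + bm$se, na.rm = TRUE)
    graphics::plot(xi + off, bm$mean, pch = ifelse(bm$quartile == "Q1", 19, 1),
                   xaxt = "n", xlab = "time bin",
                   ylab = sprintf("%s surprise (bits)", ms),
                   ylim = ylim, main = ms, ...)
    graphics::axis(1, at = unique(xi), labels = unique(bm$bin))
    graphics::arrows(xi + off, bm$mean - bm$se, xi + off, bm$mean + bm$se,
                     angle = 90, code = 3, length = 0.03)
    for (q in c("Q1", "Q4")) {
      sel <- bm$quartile == q
      graphics::lines(xi[sel] + off[sel], bm$mean[sel],
                      lty = if (q == "Q1") 1 else 2)
    }
    graphics::legend("topleft", legend = c("Q1", "Q4"), pch = c(19, 1),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
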