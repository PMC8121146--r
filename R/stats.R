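# Inferential layer: a monotone-trend test across a priori ordered
# groups (Jonckheere-Terpstra), per-quartile OLS trends of surprise on
# release time, a two-slope equivalence test pooling the two slope
# standard errors, a two-sample t-test, and a chi-square comparison of
# two counts for the new-chord analysis. No multiple-testing correction
# is applied anywhere.

# Mann-Whitney concordance count between two samples, ties at 1/2.
mw_count <- function(x, y) {
  # counts pairs (x_i, y_j) with x_i < y_j, plus half the ties
  sum(vapply(y, function(v) sum(x < v) + 0.5 * sum(x == v), 0))
}

jt_statistic <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      J <- J + mw_count(groups[[i]], groups[[j]])
    }
  }
  J
}

# Enumerate all distinct assignments of the pooled values into groups of
# the given sizes and return the exact null distribution of J.
jt_exact_distribution <- function(pooled, sizes) {
  J_values <- numeric(0L)
  recurse <- function(remaining, si) {
    if (si == length(sizes)) {
      grps <- list(pooled[remaining])
      return(list(grps))
    }
    out <- list()
    cmb <- utils::combn(length(remaining), sizes[si], simplify = FALSE)
    for (pick in cmb) {
      rest <- recurse(remaining[-pick], si + 1L)
      g <- pooled[remaining[pick]]
      out <- c(out, lapply(rest, function(r) c(list(g), r)))
    }
    out
  }
  assignments <- recurse(seq_along(pooled), 1L)
  vapply(assignments, jt_statistic, 0)
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend across groups ordered a priori. The
#' statistic J sums Mann-Whitney concordance counts over all ordered
#' group pairs (ties count 1/2). For small samples (total n at most
#' `exact_max`) the p-value is exact, from complete enumeration of all
#' assignments of the pooled values to groups; otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param groups List of numeric vectors in their a priori order.
#' @param alternative `"increasing"` (default) or `"decreasing"`.
#' @param exact_max Largest total sample size for the exact path
#'   (default 12).
#' @return An object of classes `jt_test` and `htest` with fields
#'   `statistic` (J), `z` (normal path only), `p.value` and `method`.
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing"),
                                exact_max = 12L) {
  alternative <- match.arg(alternative)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- Filter(length, groups)
  if (length(groups) < 2L) {
    stop("need at least 2 nonempty groups", call. = FALSE)
  }
  if (alternative == "decreasing") groups <- rev(groups)
  sizes <- lengths(groups)
  n <- sum(sizes)
  J <- jt_statistic(groups)

  if (n <= exact_max) {
    dist <- jt_exact_distribution(unlist(groups), sizes)
    p <- mean(dist >= J - 1e-9)
    method <- "exact"
    z <- NA_real_
  } else {
    mean_J <- (n^2 - sum(sizes^2)) / 4
    t_j <- as.numeric(table(unlist(groups)))  # tie-group sizes
    f1 <- function(v) sum(v * (v - 1) * (2 * v + 5))
    f2 <- function(v) sum(v * (v - 1) * (v - 2))
    f3 <- function(v) sum(v * (v - 1))
    var_J <- (n * (n - 1) * (2 * n + 5) - f1(sizes) - f1(t_j)) / 72 +
      f2(sizes) * f2(t_j) / (36 * n * (n - 1) * (n - 2)) +
      f3(sizes) * f3(t_j) / (8 * n * (n - 1))
    z <- (J - mean_J) / sqrt(var_J)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  structure(list(statistic = c(J = J), z = z,
                 p.value = p, method = paste("Jonckheere-Terpstra test,",
                                             method, "p-value"),
                 alternative = alternative,
                 data.name = deparse(substitute(groups))),
            class = c("jt_test", "htest"))
}

#' Fit a linear surprise-versus-time trend
#'
#' Ordinary least squares of per-song surprise (bits) on release time in
#' fractional years (`year + (month - 1)/12`), so the slope is in
#' bits/year. Fit to per-song points, not bin means.
#'
#' @param time Numeric release times (fractional years).
#' @param y Per-song surprise values (bits); `NA` pairs are dropped.
#' @return A `surprise_trend` object: `slope`, `intercept`, `slope_se`,
#'   `n`, `df`, plus the underlying `lm` fit.
#' @export
fit_trend <- function(time, y) {
  keep <- !is.na(time) & !is.na(y)
  time <- time[keep]; y <- y[keep]
  if (length(y) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(unique(time)) < 2L) {
    stop("degenerate time values: all identical", call. = FALSE)
  }
  fit <- stats::lm(y ~ time)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["time", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["time", "Std. Error"]),
                 n = length(y), df = fit$df.residual, fit = fit),
            class = "surprise_trend")
}

#' @export
print.surprise_trend <- function(x, ...) {
  cat(sprintf("<surprise_trend> slope %.4f bits/year (SE %.4f), n = %d\n",
              x$slope, x$slope_se, x$n))
  invisible(x)
}

#' @export
coef.surprise_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Test the equality of two regression slopes
#'
#' The statistic `t = (slope_a - slope_b) / sqrt(se_a^2 + se_b^2)` is
#' referred to a Student's t distribution with `n_a + n_b - 4` degrees
#' of freedom (two regressions, two parameters each); the p-value is
#' two-sided. With a zero pooled standard error the comparison is
#' degenerate: equal slopes give `t = 0, p = 1`, unequal slopes are
#' flagged with `p = 0`.
#'
#' @param a,b `surprise_trend` fits.
#' @return Classes `slope_test` and `htest`: `statistic` (t),
#'   `parameter` (df), `p.value`.
#' @export
compare_slopes <- function(a, b) {
  stopifnot(inherits(a, "surprise_trend"), inherits(b, "surprise_trend"))
  df <- a$n + b$n - 4L
  if (df < 2L) stop("too few points to compare slopes", call. = FALSE)
  pooled <- sqrt(a$slope_se^2 + b$slope_se^2)
  degenerate <- FALSE
  if (pooled == 0) {
    degenerate <- TRUE
    if (a$slope == b$slope) { t <- 0; p <- 1 } else {
      t <- sign(a$slope - b$slope) * Inf; p <- 0
    }
  } else {
    t <- (a$slope - b$slope) / pooled
    p <- 2 * stats::pt(-abs(t), df = df)
  }
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = p, degenerate = degenerate,
                 slopes = c(a = a$slope, b = b$slope),
                 method = "Two-slope equivalence test (pooled slope SEs)",
                 data.name = "surprise trends"),
            class = c("slope_test", "htest"))
}

#' Two-sample t-test on surprise values
#'
#' Welch's t by default (no equal-variance assumption); set
#' `var_equal = TRUE` for the pooled-variance variant.
#'
#' @param x,y Numeric samples (each n >= 2 after dropping `NA`).
#' @param var_equal Use pooled variance.
#' @return The `htest` from [stats::t.test()].
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && isTRUE(all.equal(mean(x), mean(y)))) {
    stop("degenerate samples: both constant and equal", call. = FALSE)
  }
  stats::t.test(x, y, var.equal = var_equal)
}

#' Chi-square test of two counts against equal expectation
#'
#' Goodness of fit of `(c1, c2)` to equal expected counts
#' `(c1 + c2)/2`, with 1 degree of freedom and no continuity correction.
#'
#' @param c1,c2 Nonnegative counts, not both zero.
#' @return List with `chi2`, `df` and `p`.
#' @examples
#' chi_square_two_counts(20, 0)   # chi2 = 20
#' @export
chi_square_two_counts <- function(c1, c2) {
  stopifnot(c1 >= 0, c2 >= 0)
  if (c1 + c2 == 0) stop("both counts are zero", call. = FALSE)
  # chisq.test warns when expected counts are below 5; the asymptotic
  # p-value is reported regardless and callers see the raw counts
  ht <- suppressWarnings(stats::chisq.test(c(c1, c2), p = c(0.5, 0.5)))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' First appearances of chords and their quartile attribution
#'
#' For every calendar year after the corpus's first, finds the canonical
#' chords whose first occurrence anywhere in the corpus falls in that
#' year. Each newly introduced chord is attributed to the preference
#' quartiles in whose songs it appears during its introduction year:
#' once per quartile under `count = "per_chord"` (default), or once per
#' occurrence under `count = "per_occurrence"`. Percentages are relative
#' to the total number of newly introduced chords (or occurrences), and
#' the Q1/Q4 counts are compared with [chi_square_two_counts()].
#'
#' @param corpus A `chord_corpus`.
#' @param quartiles Quartile assignment from
#'   [classify_quartiles_global()] or [classify_quartiles_grouped()].
#' @param count Attribution mode.
#' @return A `new_chord_report`: `by_year` (named list of chord sets),
#'   `count_Q1`, `count_Q4`, `total_new`, `pct_Q1`, `pct_Q4`, `chi2`,
#'   `df`, `p`.
#' @export
new_chord_report <- function(corpus, quartiles,
                             count = c("per_chord", "per_occurrence")) {
  stopifnot(inherits(corpus, "chord_corpus"))
  count <- match.arg(count)
  songs <- corpus$songs
  if (length(unique(songs$release_year)) < 2L) {
    stop("corpus must span at least 2 calendar years", call. = FALSE)
  }
  ch <- corpus$chords
  year <- songs$release_year[match(ch$song_id, songs$song_id)]
  cc <- corpus_canonical(corpus)
  first_year <- tapply(year, cc, min)
  y0 <- min(songs$release_year)
  new_chords <- names(first_year)[first_year > y0]
  by_year <- split(new_chords, first_year[new_chords])

  q <- quartiles$quartile[match(ch$song_id, quartiles$song_id)]
  intro <- cc %in% new_chords & year == first_year[cc]
  tally <- function(which_q) {
    sel <- intro & !is.na(q) & q == which_q
    if (count == "per_chord") length(unique(cc[sel])) else sum(sel)
  }
  c1 <- tally("Q1"); c4 <- tally("Q4")
  total <- if (count == "per_chord") length(new_chords) else sum(intro)
  chi <- if (c1 + c4 > 0) chi_square_two_counts(c1, c4) else
    list(chi2 = NA_real_, df = 1L, p = NA_real_)
  structure(list(by_year = by_year, count_Q1 = c1, count_Q4 = c4,
                 total_new = total,
                 pct_Q1 = if (total > 0) 100 * c1 / total else NA_real_,
                 pct_Q4 = if (total > 0) 100 * c4 / total else NA_real_,
                 chi2 = chi$chi2, df = chi$df, p = chi$p,
                 count = count),
            class = "new_chord_report")
}

#' @export
print.new_chord_report <- function(x, ...) {
  cat(sprintf("<new_chord_report> %d newly introduced chords (%s)\n",
              x$total_new, x$count))
  cat(sprintf("  Q1: %d (%.1f%%)   Q4: %d (%.1f%%)\n",
              x$count_Q1, x$pct_Q1, x$count_Q4, x$pct_Q4))
  if (!is.na(x$chi2)) {
    cat(sprintf("  chi-square = %.2f, df = %d, p = %.3g\n",
                x$chi2, x$df, x$p))
  } else {
    cat("  chi-square undefined (no new chords in Q1 or Q4)\n")
  }
  invisible(x)
}
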