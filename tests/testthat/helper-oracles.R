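# Independent oracles used here: complete enumeration over value
# permutations (Jonckheere-Terpstra), pairwise wilcox statistics (J),
# the normal equations (OLS), and a brute-force year-by-year scan
# (new-chord sets).

# Oracle: J computed as a sum of Mann-Whitney statistics from wilcox.test
jt_oracle_statistic <- function(groups) {
  k <- length(groups); J <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      J <- J + suppressWarnings(
        stats::wilcox.test(groups[[j]], groups[[i]])$statistic)
    }
  }
  unname(J)
}

# cheap concordance count used inside the enumeration (outer-based, a
# different code path from the package's counting loops)
jt_outer_statistic <- function(groups) {
  k <- length(groups); J <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      J <- J + sum(outer(groups[[i]], groups[[j]], "<")) +
        0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
    }
  }
  J
}

# Oracle: exact p by enumerating every permutation of the pooled values
# (keep total n <= 7 so the n! enumeration stays fast)
jt_oracle_exact_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  J_obs <- jt_outer_statistic(groups)
  perms <- gtools_perms(length(pooled))
  Js <- apply(perms, 1, function(ix) {
    g <- lapply(seq_along(sizes),
                function(i) pooled[ix[starts[i]:ends[i]]])
    jt_outer_statistic(g)
  })
  mean(Js >= J_obs - 1e-9)
}

# all permutations of 1..n (n small), without external packages
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}


# Brute-force oracle: first-appearance year of every chord by full scan
new_chord_oracle <- function(corpus) {
  songs <- corpus$songs
  ch <- corpus$chords
  cc <- canonical_chord(ch$chord_interval, ch$chord_quality)
  yr <- songs$release_year[match(ch$song_id, songs$song_id)]
  years <- sort(unique(songs$release_year))
  seen <- character(0)
  out <- list()
  for (y in years) {
    now <- unique(cc[yr == y])
    if (y > years[1]) out[[as.character(y)]] <- sort(setdiff(now, seen))
    seen <- union(seen, now)
  }
  out
}
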