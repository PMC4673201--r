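# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the package implementation.

# Brute-force tandem-repeat oracle: enumerate right-maximal windows per
# start via cumulative mismatch counts, keep left-maximal ones, merge
# overlapping windows of the same period, filter span >= 2p, drop runs that
# are exactly periodic at a proper divisor of p.
oracle_repeats <- function(seq, min_period = 15L, max_period = 150L,
                           resolution = 1L) {
  v <- strsplit(toupper(seq), "")[[1]]
  n <- length(v)
  rows <- list()
  pmax <- min(max_period, n %/% 2L)
  p <- min_period
  while (p <= pmax) {
    m <- n - p
    mm <- as.integer(v[seq_len(m)] != v[seq_len(m) + p])
    zc <- cumsum(mm)
    zc0 <- c(0L, zc)
    a <- seq_len(m)
    # largest b with zeros(a..b) <= resolution
    b <- findInterval(zc0[a] + resolution + 0.5, zc)
    valid <- b >= a
    # left-maximal: extending to a-1 would add mm[a-1] and exceed the budget
    ext <- rep(TRUE, m)
    ext[a > 1L] <- (zc[b[a > 1L]] - zc0[a[a > 1L] - 1L] +
                      mm[a[a > 1L] - 1L]) > resolution
    keep <- which(valid & ext)
    if (length(keep)) {
      win <- unique(data.frame(a = a[keep], b = b[keep]))
      win <- win[order(win$a), , drop = FALSE]
      # merge windows sharing positions
      merged <- list()
      cur <- c(win$a[1], win$b[1])
      for (i in seq_len(nrow(win))[-1]) {
        if (win$a[i] <= cur[2]) {
          cur[2] <- max(cur[2], win$b[i])
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- c(win$a[i], win$b[i])
        }
      }
      merged[[length(merged) + 1L]] <- cur
      for (w in merged) {
        len <- w[2] - w[1] + 1L
        if (len < p) next
        span <- len + p
        # longest exact-match run of comparisons inside the window
        match_run <- rle(mm[w[1]:w[2]] == 0L)
        best_i <- which(match_run$values & match_run$lengths ==
                          max(match_run$lengths[match_run$values]))[1]
        rl <- match_run$lengths[best_i]
        rs <- w[1] + c(0L, cumsum(match_run$lengths))[best_i]
        # primitivity of the exact core segment at proper divisors
        prim <- TRUE
        for (d in seq_len(p %/% 2L)) {
          if (p %% d != 0L) next
          idx <- rs:(rs + rl + p - 1L - d)
          if (all(v[idx] == v[idx + d])) { prim <- FALSE; break }
        }
        if (!prim) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = w[1] - 1L, period = p, span = span,
          copies = span / p, mismatches = NA_integer_)
      }
    }
    p <- p + 1L
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), period = integer(0),
                      span = integer(0), copies = numeric(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  # mismatches recomputed directly for clarity
  out$mismatches <- mapply(function(s0, p, sp) {
    idx <- (s0 + 1L):(s0 + sp - p)
    sum(v[idx] != v[idx + p])
  }, out$start, out$period, out$span)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hypergeometric tail: one-sided ("greater") Fisher p for the 2x2 table
# [[a, b], [c, d]] without calling fisher.test().
oracle_fisher_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# Brute-force overlap scan between the end of s1 and the start of
# revcomp(s2), as plain R: among overlaps within the mismatch budget, the
# best (matches - mismatches) score wins, ties to the larger overlap.
oracle_best_overlap <- function(s1, s2, min_overlap = 10L,
                                max_mismatch_frac = 0.1) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  b <- rc(s2)
  v1 <- strsplit(s1, "")[[1]]
  v2 <- strsplit(b, "")[[1]]
  la <- length(v1); lb <- length(v2)
  best <- list(score = -Inf, o = NA_integer_, mm = NA_integer_,
               mergeable = FALSE)
  for (o in min_overlap:min(la, lb)) {
    mm <- sum(v1[(la - o + 1):la] != v2[1:o])
    if (mm / o > max_mismatch_frac) next
    sc <- o - 2 * mm
    if (sc > best$score || (sc == best$score && o > best$o)) {
      best <- list(score = sc, o = o, mm = mm, mergeable = TRUE)
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
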