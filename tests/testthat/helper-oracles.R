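# Independent brute-force oracles and small fixture builders. The oracles
# share no code with the implementation: plain nested loops over explicit
# substring pairs.

randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Brute-force terminal self-repeat: enumerate every equal-length substring
# pair with one copy in the first `window` bases and one in the last
# `window` bases; score = matches - penalty * mismatches; keep pairs with
# length >= minLen and mismatch fraction <= maxDiv. Returns the set of
# maximal-score pairs (there may be ties) as a data.frame, or NULL.
oracleSelfRepeat <- function(seq, window, minLen, maxDiv, penalty = 4) {
  n <- nchar(seq)
  rows <- list()
  for (L in minLen:window) {
    for (i in 0:(window - L)) {
      a <- substr(seq, i + 1, i + L)
      for (j in (n - window):(n - L)) {
        b <- substr(seq, j + 1, j + L)
        h <- hamming(a, b)
        if (h > maxDiv * L) next
        rows[[length(rows) + 1]] <-
          data.frame(i = i, j = j, L = L, mism = h,
                     score = (L - h) - penalty * h)
      }
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df[df$score == max(df$score), , drop = FALSE]
}

# Brute-force adjacent tandem-pair scan over a whole sequence, with the
# same post-processing rules as the detector (best-of-run for shifted
# same-unit candidates, containment suppression for sub-repeats), computed
# with explicit loops.
oracleTandem <- function(seq, unitRange, maxDiv) {
  n <- nchar(seq)
  rows <- list()
  for (u in unitRange[1]:unitRange[2]) {
    if (2 * u > n) break
    for (i in 0:(n - 2 * u)) {
      h <- hamming(substr(seq, i + 1, i + u),
                   substr(seq, i + u + 1, i + 2 * u))
      if (h <= floor(maxDiv * u))
        rows[[length(rows) + 1]] <- data.frame(start1 = i, unit = u,
                                               ham = h)
    }
  }
  if (!length(rows))
    return(data.frame(start1 = integer(0), unit = integer(0),
                      ham = integer(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$unit, df$start1), , drop = FALSE]
  # best-of-run within consecutive starts of the same unit
  keepRows <- list()
  runStart <- 1
  for (k in seq_len(nrow(df))) {
    lastOfRun <- k == nrow(df) || df$unit[k + 1] != df$unit[k] ||
      df$start1[k + 1] != df$start1[k] + 1
    if (lastOfRun) {
      run <- df[runStart:k, , drop = FALSE]
      best <- run[order(run$ham, run$start1)[1], , drop = FALSE]
      keepRows[[length(keepRows) + 1]] <- best
      runStart <- k + 1
    }
  }
  df <- do.call(rbind, keepRows)
  # containment suppression under longer units
  df <- df[order(-df$unit, df$start1), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (k in seq_len(nrow(df))) {
    for (m in seq_len(k - 1)) {
      if (!keep[m] || df$unit[m] <= df$unit[k]) next
      if (df$start1[m] <= df$start1[k] &&
          df$start1[m] + 2 * df$unit[m] >= df$start1[k] + 2 * df$unit[k]) {
        keep[k] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start1), , drop = FALSE]
}

# Manual alignment-set builder for toy cases.
toyAlignments <- function(refId, refLen, ..., seqs = NULL) {
  recs <- list(...)
  df <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    data.frame(read_id = r$id %||% paste0("r", i), ref_id = refId,
               ref_start = r$start, strand = r$strand %||% "+",
               cigar = r$cigar, seq = r$seq %||% NA_character_,
               qual = NA_character_, secondary = isTRUE(r$secondary),
               supplementary = isTRUE(r$supplementary))
  }))
  phageAlignments(df, stats::setNames(refLen, refId))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
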