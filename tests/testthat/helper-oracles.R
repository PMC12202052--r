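# Independent oracles and small fixture builders used across the suite.

# --- SSR brute-force oracle -------------------------------------------------
# Regex route: for each period p, find maximal runs of >= min_repeats full
# units with a backreference, extend any trailing partial unit by direct
# character comparison, then apply the same period-minimality and greedy
# overlap rules as the scanner contract. Mechanically independent of the
# shifted-byte match-run scanner in the package.

oracle_minimal <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(max(p - 1L, 0L))) {
    if (p %% d == 0L) {
      unit <- substr(motif, 1L, d)
      if (paste(rep(unit, p / d), collapse = "") == motif) return(FALSE)
    }
  }
  TRUE
}

oracle_ssrs <- function(sequence, min_len = 2, max_len = 10, min_repeats = 5) {
  n <- nchar(sequence)
  cand <- list()
  for (p in min_len:max_len) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, min_repeats - 1L)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      i <- m[j]
      end <- i + attr(m, "match.length")[j] - 1L
      while (end < n) {
        nxt <- substr(sequence, end + 1L, end + 1L)
        prev <- substr(sequence, end + 1L - p, end + 1L - p)
        if (nxt != "N" && nxt == prev) end <- end + 1L else break
      }
      motif <- substr(sequence, i, i + p - 1L)
      if (!oracle_minimal(motif)) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = i - 1L, end = end, period = p, motif = motif,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      motif = character(), units = integer()))
  }
  cand <- do.call(rbind, cand)
  # greedy resolution: longest span, then smallest period, then leftmost
  ord <- order(-(cand$end - cand$start), cand$period, cand$start)
  keep <- rep(FALSE, nrow(cand))
  acc <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    if (nrow(acc) == 0 ||
        !any(cand$start[i] < acc[, 2] & cand$end[i] > acc[, 1])) {
      keep[i] <- TRUE
      acc <- rbind(acc, c(cand$start[i], cand$end[i]))
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  cand$units <- (cand$end - cand$start) %/% cand$period
  rownames(cand) <- NULL
  cand
}

# Random test sequences with varied composition so repeats actually occur.
random_test_seq <- function(len, mode = c("uniform", "at_rich", "gc_rich")) {
  mode <- match.arg(mode)
  prob <- switch(mode,
                 uniform = rep(0.25, 4),
                 at_rich = c(0.4, 0.1, 0.1, 0.4),
                 gc_rich = c(0.1, 0.4, 0.4, 0.1))
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

expect_ssrs_match_oracle <- function(sequence, min_repeats = 5) {
  got <- find_ssrs(tibble::tibble(scaffold_id = "s", sequence = sequence),
                   min_repeats = min_repeats)
  want <- oracle_ssrs(sequence, min_repeats = min_repeats)
  expect_equal(nrow(got), nrow(want), info = sequence)
  if (nrow(want) > 0) {
    expect_equal(got$start, want$start, info = sequence)
    expect_equal(got$end, want$end, info = sequence)
    expect_equal(got$period, want$period, info = sequence)
    expect_equal(got$motif, want$motif, info = sequence)
    expect_equal(got$units, want$units, info = sequence)
  }
}

# --- Fisher enumeration oracle ----------------------------------------------
# Pure choose()-arithmetic enumeration over all tables with the observed
# margins; no dhyper, no stats::fisher.test.

oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  denom <- choose(n, c1)
  prob_of <- function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / denom
  }
  probs <- vapply(lo:hi, prob_of, numeric(1))
  p_obs <- probs[(lo:hi) == a]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

# --- misc -------------------------------------------------------------------

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) {
           paste(rev(strsplit(x, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
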