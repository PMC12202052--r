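#' Canonical microsatellite motif
#'
#' A tandem repeat can be written starting at any phase of its motif and read
#' from either strand, so each motif belongs to an equivalence class under
#' rotation and reverse complementation (for example TG, GT, CA and AC all
#' describe the same dinucleotide repeat). The canonical representative is
#' the lexicographically smallest member of that class, which is how motif
#' spectra collapse the two strands: each genomic locus is counted once.
#'
#' @param motif Character vector of DNA motifs over `A`, `C`, `G`, `T`.
#' @return Character vector of canonical motifs, same length as `motif`.
#'   The function is idempotent.
#' @examples
#' canonical_motif(c("TG", "TA", "AC")) # "AC" "AT" "AC"
#' @export
canonical_motif <- function(motif) {
  assert_dna_motif(motif)
  vapply(motif, function(m) {
    p <- nchar(m)
    doubled <- paste0(m, m)
    rots <- substring(doubled, seq_len(p), seq_len(p) + p - 1L)
    rc <- revcomp(m)
    doubled_rc <- paste0(rc, rc)
    rots_rc <- substring(doubled_rc, seq_len(p), seq_len(p) + p - 1L)
    min(c(rots, rots_rc))
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if motif is a whole-number repetition of a shorter unit
# (i.e. its minimal period is a proper divisor of its length).
is_period_minimal <- function(motif) {
  vapply(motif, function(m) {
    p <- nchar(m)
    if (p == 1L) return(TRUE)
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && m == strrep(substr(m, 1L, d), p / d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Greedy overlap resolution shared contract: longer span wins, then smaller
# period, then leftmost start. `cand` is a data.frame for ONE scaffold with
# start/end/period columns; returns the retained row indices.
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(seq_len(nrow(cand)))
  span <- cand$end - cand$start
  ord <- order(-span, cand$period, cand$start)
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- integer(0)
  for (i in ord) {
    if (!any(cand$start[i] < acc_end & cand$end[i] > acc_start)) {
      keep <- c(keep, i)
      acc_start <- c(acc_start, cand$start[i])
      acc_end <- c(acc_end, cand$end[i])
    }
  }
  sort(keep)
}

# Scan one sequence string for maximal perfect tandem runs.
# Core mechanism: for each period p, compare the sequence against itself
# shifted by p bases; a run of L consecutive matches is a perfectly periodic
# region of length L + p. Runs touching N never match because N positions are
# masked, so repeats are split at N.
find_ssrs_one <- function(sequence, min_len, max_len, min_repeats) {
  n <- nchar(sequence)
  empty <- tibble(start = integer(), end = integer(), period = integer(),
                  motif = character())
  if (n < min_len * min_repeats) return(empty)
  x <- charToRaw(sequence)
  not_n <- x != charToRaw("N")
  out <- vector("list", max_len - min_len + 1L)
  for (p in min_len:max_len) {
    if (n < p * min_repeats) break
    idx <- seq_len(n - p)
    m <- (x[idx] == x[idx + p]) & not_n[idx] & not_n[idx + p]
    r <- rle(m)
    len <- r$lengths
    run_end <- cumsum(len)
    run_start <- run_end - len + 1L
    hit <- r$values & len >= p * (min_repeats - 1L)
    if (!any(hit)) next
    s0 <- run_start[hit]               # 1-based position of region start
    span_len <- len[hit] + p           # includes trailing partial unit
    motif <- substring(sequence, s0, s0 + p - 1L)
    ok <- is_period_minimal(motif)
    if (!any(ok)) next
    out[[p - min_len + 1L]] <- tibble(
      start = s0[ok] - 1L,             # to 0-based half-open
      end = s0[ok] - 1L + span_len[ok],
      period = p,
      motif = motif[ok]
    )
  }
  cand <- dplyr::bind_rows(out)
  if (nrow(cand) == 0) return(empty)
  cand[resolve_overlaps(cand), , drop = FALSE]
}

#' Find simple sequence repeats (perfect microsatellites)
#'
#' Detects every maximal perfect tandem repeat with motif length between
#' `min_len` and `max_len` bp and at least `min_repeats` complete units.
#' Detection is exact (no mismatches or indels). A reported span cannot be
#' extended by a single base of a further (partial) unit on either side;
#' partial trailing units extend the span but do not count towards `units`.
#' Motifs are period-minimal (a poly-A run is never reported as an "AA"
#' dinucleotide repeat), runs are split at `N`, and both strands are covered
#' by canonicalisation rather than double scanning, so each genomic locus
#' appears exactly once, on forward-strand coordinates. Overlapping candidate
#' runs of different periods are resolved by longest span, then smallest
#' period, then leftmost start.
#'
#' @param genome A genome tibble ([read_genome_fasta()]) or a named character
#'   vector/list of sequences.
#' @param min_len,max_len Motif length bounds in bp (defaults 2 and 10).
#' @param min_repeats Minimum number of complete units (default 5).
#' @return A tibble of SSR loci sorted by scaffold then start, with columns
#'   `scaffold_id`, `start`, `end` (0-based half-open), `period`, `motif`
#'   (forward strand, as at the locus start), `canonical_motif`, `units`.
#' @examples
#' g <- tibble::tibble(scaffold_id = "s1", sequence = "ATATATATAT")
#' find_ssrs(g)
#' @export
find_ssrs <- function(genome, min_len = 2, max_len = 10, min_repeats = 5) {
  if (min_len < 1 || max_len < min_len) abort("need 1 <= min_len <= max_len")
  if (min_repeats < 2) abort("min_repeats must be at least 2")
  if (!is.data.frame(genome)) {
    genome <- tibble(scaffold_id = names(genome),
                     sequence = unname(unlist(genome)))
  }
  res <- purrr::map2(genome$scaffold_id, genome$sequence, function(id, s) {
    loci <- find_ssrs_one(s, as.integer(min_len), as.integer(max_len),
                          as.integer(min_repeats))
    if (nrow(loci) > 0) loci$scaffold_id <- id
    loci
  })
  loci <- dplyr::bind_rows(res)
  if (nrow(loci) == 0) {
    return(tibble(scaffold_id = character(), start = integer(), end = integer(),
                  period = integer(), motif = character(),
                  canonical_motif = character(), units = integer()))
  }
  loci$canonical_motif <- canonical_motif(loci$motif)
  loci$units <- (loci$end - loci$start) %/% loci$period
  loci <- loci[order(loci$scaffold_id, loci$start), ]
  loci <- loci[, c("scaffold_id", "start", "end", "period", "motif",
                   "canonical_motif", "units")]
  attr(loci, "scan_params") <- list(min_len = min_len, max_len = max_len,
                                    min_repeats = min_repeats)
  loci
}

#' Genome-wide SSR statistics
#'
#' Summarises a set of SSR loci against the assembly size, in the units used
#' for comparative genome tables: density is bases covered by SSRs per Mb of
#' genome, coverage is the percent of the genome covered, and frequency is
#' loci per Mb. Bases covered is the length of the union of spans, so
#' overlapping loci are not double-counted; `merged_count` additionally
#' reports the number of loci after merging book-ended (zero-gap compound)
#' and overlapping spans, since published totals can follow either counting
#' convention.
#'
#' @param loci An SSR tibble from [find_ssrs()].
#' @param genome_length Assembly length in bp (> 0).
#' @param gc GC percent of the assembly, carried through to the output
#'   (optional).
#' @return A one-row tibble: `total_count`, `merged_count`, `bases_covered`,
#'   `density_per_mb`, `coverage_percent`, `frequency_per_mb`, `gc_percent`.
#' @export
ssr_statistics <- function(loci, genome_length, gc = NA_real_) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    abort("genome_length must be a positive number of bp")
  }
  mb <- genome_length / 1e6
  if (nrow(loci) == 0) {
    return(tibble(total_count = 0L, merged_count = 0L, bases_covered = 0L,
                  density_per_mb = 0, coverage_percent = 0,
                  frequency_per_mb = 0, gc_percent = gc))
  }
  ir <- GenomicRanges::GRanges(loci$scaffold_id,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  merged <- GenomicRanges::reduce(ir)
  covered <- sum(GenomicRanges::width(merged))
  tibble(
    total_count = nrow(loci),
    merged_count = length(merged),
    bases_covered = as.integer(covered),
    density_per_mb = covered / mb,
    coverage_percent = covered / genome_length * 100,
    frequency_per_mb = nrow(loci) / mb,
    gc_percent = gc
  )
}

# All canonical motifs of period exactly k (minimal period, smallest member
# of each rotation/reverse-complement class).
canonical_motif_universe <- function(k) {
  if (k > 6) abort("fixed motif universe supported for k <= 6 only")
  alphabet <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(alphabet), k),
                                 stringsAsFactors = FALSE))
  motifs <- do.call(paste0, grid)
  motifs <- motifs[is_period_minimal(motifs)]
  sort(unique(canonical_motif(motifs)))
}

#' Motif spectrum of an SSR set
#'
#' Counts loci per canonical motif for each requested period and normalises
#' as motifs per Mb of genome, the form used for cross-genome heatmaps.
#' With `full_universe = TRUE` every canonical motif of the period appears,
#' absent ones with count zero, so spectra from different genomes align
#' row-for-row (and genuinely missing repeats, such as CA/TG in some
#' genomes, show as explicit zeros).
#'
#' @param loci An SSR tibble from [find_ssrs()] (must carry
#'   `canonical_motif` and `period`).
#' @param genome_length Assembly length in bp.
#' @param k_values Periods to tabulate (default dimers to tetramers, `2:4`).
#' @param full_universe If `TRUE`, include zero rows for unobserved motifs
#'   (supported for k at most 6).
#' @return A tibble with columns `k`, `canonical_motif`, `count`, `per_mb`.
#' @export
motif_spectrum <- function(loci, genome_length, k_values = 2:4,
                           full_universe = FALSE) {
  scan <- attr(loci, "scan_params")
  if (!is.null(scan) &&
      any(k_values < scan$min_len | k_values > scan$max_len)) {
    abort("k_values outside the scanned period range")
  }
  mb <- genome_length / 1e6
  spec <- purrr::map(k_values, function(k) {
    sub <- loci[loci$period == k, , drop = FALSE]
    counts <- if (nrow(sub) > 0) {
      dplyr::count(sub, .data$canonical_motif, name = "count")
    } else {
      tibble(canonical_motif = character(), count = integer())
    }
    if (full_universe) {
      univ <- tibble(canonical_motif = canonical_motif_universe(k))
      counts <- dplyr::left_join(univ, counts, by = "canonical_motif")
      counts$count[is.na(counts$count)] <- 0L
    }
    counts$k <- as.integer(k)
    counts
  })
  out <- dplyr::bind_rows(spec)
  out$per_mb <- out$count / mb
  out[order(out$k, out$canonical_motif),
      c("k", "canonical_motif", "count", "per_mb")]
}

#' Share of SSR loci by motif-length class
#'
#' Percentage of all loci in each period class (dimers, trimers, ...). In
#' fungal assemblies the 2-4 bp classes typically dominate the repeat
#' landscape.
#'
#' @param loci An SSR tibble from [find_ssrs()], or a motif spectrum tibble
#'   from [motif_spectrum()] covering all scanned periods.
#' @return A tibble with columns `k`, `count`, `percent` (summing to 100);
#'   empty, with a warning, if there are no loci.
#' @export
ssr_class_proportions <- function(loci) {
  counts <- if ("period" %in% names(loci)) {
    dplyr::count(loci, k = .data$period, name = "count")
  } else {
    dplyr::summarise(dplyr::group_by(loci, .data$k),
                     count = sum(.data$count), .groups = "drop")
  }
  total <- sum(counts$count)
  if (total == 0) {
    warn("no SSR loci; class proportions undefined")
    return(tibble(k = integer(), count = integer(), percent = numeric()))
  }
  counts$percent <- counts$count / total * 100
  counts[order(counts$k), ]
}
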