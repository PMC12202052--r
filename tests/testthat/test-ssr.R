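test_that("canonical_motif returns the smallest rotation over both strands", {
  # hand enumeration: TG -> rotations TG, GT; revcomp CA -> CA, AC; min AC
  expect_equal(canonical_motif("TG"), "AC")
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("AC"), "AC")
  expect_equal(canonical_motif(c("GGT", "ACC")), c("ACC", "ACC"))
  expect_error(canonical_motif("ANT"), "A, C, G, T")
})

test_that("canonical_motif is idempotent and class-invariant", {
  withr::local_seed(5)
  motifs <- c(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1, paste,
          collapse = ""),
    replicate(40, paste(sample(c("A","C","G","T"), sample(3:6, 1),
                               replace = TRUE), collapse = ""))
  )
  canon <- canonical_motif(motifs)
  expect_equal(canonical_motif(canon), canon)
  # every rotation and the reverse complement map to the same representative
  for (m in sample(motifs, 12)) {
    p <- nchar(m)
    rot <- substr(paste0(m, m), 2, 1 + p)
    expect_equal(canonical_motif(rot), canonical_motif(m))
    expect_equal(canonical_motif(revcomp_chr(m)), canonical_motif(m))
  }
})

test_that("find_ssrs detects maximal perfect repeats with the stated rules", {
  scan1 <- function(s, ...) {
    find_ssrs(tibble::tibble(scaffold_id = "s1", sequence = s), ...)
  }
  # one clean locus
  loci <- scan1("ATATATATAT")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 0L)
  expect_equal(loci$end, 10L)
  expect_equal(loci$period, 2L)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$units, 5L)

  # homopolymers are excluded by period-minimality at min_len = 2
  expect_equal(nrow(scan1("AAAAAAAAAA")), 0L)
  # below the unit threshold
  expect_equal(nrow(scan1("ACGACGACGACG")), 0L)
  # a trailing partial unit extends the span but not the unit count
  loci <- scan1("CCATATATATATACC")
  expect_equal(loci$start, 2L)
  expect_equal(loci$end, 13L)
  expect_equal(loci$units, 5L)
  # N splits runs and never appears inside a locus
  expect_equal(nrow(scan1("ATATATNATATAT")), 0L)
  split <- scan1(paste0(strrep("AT", 5), "N", strrep("AT", 6)))
  expect_equal(nrow(split), 2L)
  expect_equal(split$start, c(0L, 11L))
  # adjacent compound repeats are separate loci with zero-gap adjacency
  comp <- scan1(paste0(strrep("AT", 5), strrep("CGA", 5)))
  expect_equal(nrow(comp), 2L)
  expect_equal(comp$end[1], comp$start[2])
  # empty / too-short input
  expect_equal(nrow(scan1("")), 0L)
  expect_error(find_ssrs(tibble::tibble(scaffold_id = "s", sequence = "A"),
                         min_repeats = 1), "min_repeats")
})

test_that("find_ssrs agrees with the brute-force oracle on random sequences", {
  withr::local_seed(101)
  modes <- c("uniform", "at_rich", "gc_rich")
  for (i in 1:120) {
    s <- random_test_seq(sample(100:1500, 1), sample(modes, 1))
    expect_ssrs_match_oracle(s)
  }
  # lower unit threshold exercises denser candidate overlap resolution
  for (i in 1:40) {
    s <- random_test_seq(sample(100:500, 1), "at_rich")
    expect_ssrs_match_oracle(s, min_repeats = 3)
  }
})

test_that("scanning the reverse complement mirrors loci exactly", {
  withr::local_seed(77)
  for (i in 1:25) {
    s <- random_test_seq(800, sample(c("at_rich", "gc_rich"), 1))
    fwd <- find_ssrs(tibble::tibble(scaffold_id = "s", sequence = s))
    rev <- find_ssrs(tibble::tibble(scaffold_id = "s",
                                    sequence = revcomp_chr(s)))
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd) > 0) {
      n <- nchar(s)
      expect_equal(sort(fwd$canonical_motif), sort(rev$canonical_motif))
      expect_equal(sort(fwd$end - fwd$start), sort(rev$end - rev$start))
      # coordinates mirror: start' = n - end
      expect_equal(sort(rev$start), sort(n - fwd$end))
    }
  }
})

test_that("ssr_statistics computes density, coverage and frequency", {
  loci <- tibble::tibble(scaffold_id = "s1", start = 100L, end = 3000L,
                         period = 2L, motif = "AT", canonical_motif = "AT",
                         units = 1450L)
  st <- ssr_statistics(loci, 1e6)
  expect_equal(st$bases_covered, 2900L)
  expect_equal(st$coverage_percent, 0.29)
  expect_equal(st$density_per_mb, 2900)
  expect_equal(st$frequency_per_mb, 1)
  expect_equal(st$total_count, 1L)

  empty <- ssr_statistics(loci[0, ], 1e6)
  expect_equal(empty$total_count, 0L)
  expect_equal(empty$coverage_percent, 0)
  expect_error(ssr_statistics(loci, 0), "positive")

  # overlapping loci: bases covered is the span union; merged_count merges
  two <- tibble::tibble(scaffold_id = "s1", start = c(0L, 5L), end = c(10L, 15L),
                        period = c(2L, 3L), motif = c("AT", "CGA"),
                        canonical_motif = c("AT", "ACG"), units = c(5L, 3L))
  st2 <- ssr_statistics(two, 1000)
  expect_equal(st2$bases_covered, 15L)
  expect_equal(st2$total_count, 2L)
  expect_equal(st2$merged_count, 1L)
})

test_that("motif spectrum partitions counts by period and preserves totals", {
  withr::local_seed(13)
  s <- paste0(random_test_seq(400), strrep("AT", 6), random_test_seq(400),
              strrep("AAG", 7), random_test_seq(400), strrep("ACGT", 5),
              random_test_seq(400))
  loci <- find_ssrs(tibble::tibble(scaffold_id = "s", sequence = s))
  spec <- motif_spectrum(loci, nchar(s), k_values = 2:10)
  expect_equal(sum(spec$count), nrow(loci))
  # per-period recount oracle
  for (k in unique(spec$k)) {
    expect_equal(sum(spec$count[spec$k == k]), sum(loci$period == k))
  }
  expect_equal(spec$per_mb, spec$count / (nchar(s) / 1e6))
  expect_error(motif_spectrum(loci, nchar(s), k_values = 11), "outside")
})

test_that("fixed motif universe reports absent motifs as zero", {
  # genome with only an AT repeat: AC (the canonical form of CA/TG) is zero
  g <- tibble::tibble(scaffold_id = "s", sequence = strrep("AT", 10))
  loci <- find_ssrs(g)
  spec <- motif_spectrum(loci, 20, k_values = 2, full_universe = TRUE)
  expect_true("AC" %in% spec$canonical_motif)
  expect_equal(spec$count[spec$canonical_motif == "AC"], 0L)
  expect_equal(spec$count[spec$canonical_motif == "AT"], 1L)
  # dimer universe: 4 rotation/reverse-complement classes
  expect_equal(nrow(spec), 4L)
})

test_that("class proportions sum to 100 and reproduce hand arithmetic", {
  counts <- tibble::tibble(k = c(2L, 3L, 4L, 5L),
                           canonical_motif = c("AT", "AAG", "AAAT", "AAAAC"),
                           count = c(46L, 30L, 16L, 8L),
                           per_mb = 0)
  prop <- ssr_class_proportions(counts)
  expect_equal(prop$percent, c(46, 30, 16, 8))
  expect_equal(sum(prop$percent), 100)
  expect_equal(sum(prop$percent[prop$k %in% 2:4]), 92)

  single <- ssr_class_proportions(counts[1, ])
  expect_equal(single$percent, 100)

  expect_warning(none <- ssr_class_proportions(counts[0, ]), "no SSR loci")
  expect_equal(nrow(none), 0L)
})
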