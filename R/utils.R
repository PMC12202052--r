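# Internal helpers shared across modules.

# Reverse complement of a plain character vector of DNA strings.
# Biostrings handles the heavy lifting; inputs are short motifs or scaffolds.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna_motif <- function(motif, arg = "motif") {
  bad <- grepl("[^ACGT]", motif)
  if (any(bad)) {
    abort(sprintf(
      "%s must contain only A, C, G, T; offending value(s): %s",
      arg, paste(utils::head(motif[bad], 3), collapse = ", ")
    ))
  }
  invisible(motif)
}

# GC percent over non-N bases of a character vector of sequences.
# Returns NaN for sequences with no non-N base.
gc_percent <- function(sequence) {
  s <- Biostrings::DNAStringSet(sequence)
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  n <- Biostrings::letterFrequency(s, letters = "N")[, 1]
  denom <- Biostrings::width(s) - n
  unname(rowSums(gc) / denom * 100)
}

# Random DNA of length n at a target GC fraction (i.i.d. bases).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Round half up to `digits` decimals, matching printed-table formatting.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Resolve scaffold lengths from either a genome tibble or a named vector.
scaffold_length_lookup <- function(scaffold_lengths) {
  if (is.data.frame(scaffold_lengths)) {
    stopifnot(all(c("scaffold_id", "length") %in% names(scaffold_lengths)))
    stats::setNames(scaffold_lengths$length, scaffold_lengths$scaffold_id)
  } else if (is.numeric(scaffold_lengths) && !is.null(names(scaffold_lengths))) {
    scaffold_lengths
  } else {
    abort("scaffold_lengths must be a genome tibble or a named numeric vector")
  }
}
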