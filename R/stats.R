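#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table. The
#' two-sided p-value follows the probability-mass rule: with the margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (an absolute
#' 1e-12 slack absorbs floating-point ties). The reported odds ratio is the
#' sample odds ratio `(a*d)/(b*c)`, with 0.5 added to every cell (Haldane
#' correction) if and only if some cell is zero; note this differs from the
#' conditional maximum-likelihood estimate printed by
#' [stats::fisher.test()], whose p-value it otherwise matches.
#'
#' @param a,b,c,d Cell counts, row-wise (`a`, `b` top row); alternatively
#'   `a` may be a 2x2 matrix and the rest omitted.
#' @return A list with elements `p_two_sided` and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3) # p = 0.1
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) abort("all-zero table")
  r1 <- a + b
  c1 <- a + c
  # support of the (1,1) cell given fixed margins
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs + 1e-12]))
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(p_two_sided = p, odds_ratio = or)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up conversion of p-values to q-values: the q-value of the i-th
#' smallest p is `min over j >= i of (m * p_(j) / j)`, capped at 1.
#' Thresholding q-values at a level alpha controls the FDR at alpha.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_correct <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Normalise a count per 10,000 genes
#'
#' Gene-class counts from genomes with different gene totals are compared on
#' a common per-10,000-gene scale.
#'
#' @param count Count(s) to normalise.
#' @param total_genes Total number of genes in the genome (> 0).
#' @return `count / total_genes * 10000`.
#' @export
normalize_per_10k <- function(count, total_genes) {
  if (any(total_genes <= 0)) abort("total_genes must be positive")
  count / total_genes * 10000
}

#' Coding fraction of a genome
#'
#' Total annotated gene length over genome length, as the percent printed in
#' assembly feature tables (two decimals, half-up).
#'
#' @param total_gene_length_bp Summed gene length in bp (> 0).
#' @param genome_length_bp Assembly length in bp (> 0).
#' @return Percent, rounded half-up to 2 decimals.
#' @examples
#' coding_fraction(19672515, 46686835) # 42.14
#' @export
coding_fraction <- function(total_gene_length_bp, genome_length_bp) {
  if (any(total_gene_length_bp <= 0) || any(genome_length_bp <= 0)) {
    abort("lengths must be positive")
  }
  if (any(total_gene_length_bp > genome_length_bp)) {
    abort("total gene length exceeds genome length")
  }
  round_half_up(total_gene_length_bp / genome_length_bp * 100, 2)
}

#' Glycoside hydrolase activity in enzyme units per ml
#'
#' One enzyme unit (U) catalyses 1 umol of substrate per minute, so activity
#' is the micromoles of glucose released per minute per millilitre of
#' reaction.
#'
#' @param umol_glucose Micromoles of glucose released (>= 0).
#' @param time_min Reaction time in minutes (> 0).
#' @param volume_ml Reaction volume in ml (> 0).
#' @return Activity in U/ml.
#' @export
enzyme_activity <- function(umol_glucose, time_min, volume_ml) {
  if (any(time_min <= 0) || any(volume_ml <= 0)) {
    abort("time and volume must be positive")
  }
  umol_glucose / (time_min * volume_ml)
}

#' Totals and singleton share of a protein-cluster table
#'
#' Column sums of an orthology cluster table (one row per organism with its
#' protein, cluster and singleton counts) plus the singleton share expressed
#' as singleton clusters per total proteins, the convention of published
#' cluster summaries.
#'
#' @param rows A tibble/data frame with columns `n_proteins`, `n_clusters`,
#'   `n_singletons` (one row per organism).
#' @return A one-row tibble: `total_proteins`, `total_singleton_clusters`,
#'   `singleton_percent` (2 decimals, half-up).
#' @export
cluster_table_checks <- function(rows) {
  need <- c("n_proteins", "n_clusters", "n_singletons")
  if (!all(need %in% names(rows))) {
    abort(sprintf("rows must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(rows) == 0) abort("need at least one row")
  if (any(rows[need] < 0)) abort("negative counts are invalid")
  if (any(rows$n_singletons > rows$n_proteins)) {
    abort("n_singletons cannot exceed n_proteins")
  }
  total_proteins <- sum(rows$n_proteins)
  total_singletons <- sum(rows$n_singletons)
  tibble(
    total_proteins = total_proteins,
    total_singleton_clusters = total_singletons,
    singleton_percent = round_half_up(total_singletons / total_proteins * 100, 2)
  )
}
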