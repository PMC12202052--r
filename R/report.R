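#' Run the full architecture analysis on one genome
#'
#' Composes the whole pipeline — SSR scan and motif spectrum, telomere
#' end-calling, FIR computation, two-speed compartment classification and
#' category enrichment — and collects per-module results plus a one-row
#' comparative summary. Inputs may be file paths (FASTA / GFF3 / label TSV)
#' or the corresponding tibbles.
#'
#' @param genome FASTA path or genome tibble ([read_genome_fasta()]).
#' @param genes GFF3 path or gene tibble ([read_gene_gff3()]).
#' @param labels Label TSV path, label tibble, or `NULL` (all genes core;
#'   enrichment is then skipped).
#' @param name Genome name used in the summary row (defaults to the FASTA
#'   file name or `"genome"`).
#' @param min_len,max_len,min_repeats SSR scan parameters (defaults 2, 10, 5).
#' @param k_values Motif-spectrum periods (default `2:4`).
#' @param telomere_unit,telomere_min_copies,telomere_window Telomere calling
#'   parameters (defaults `TTAGGG`, 5, 200).
#' @param threshold Compartment threshold, bp or `"qNN"` (default `"q75"`).
#' @param n_bins,fir_range FIR density binning (defaults 30 bins over
#'   1-100,000 bp).
#' @return An object of class `genarch_report`: a list with elements
#'   `summary` (one-row tibble), `ssr_loci`, `ssr_stats`, `spectrum`,
#'   `class_proportions`, `telomere_calls`, `telomere_summary`, `firs`
#'   (with compartment calls joined), `fir_density`, `category_summary`,
#'   `enrichment`, `parameters`, `inputs`. Supports [glance()] and [tidy()].
#' @export
run_genome_report <- function(genome, genes, labels = NULL, name = NULL,
                              min_len = 2, max_len = 10, min_repeats = 5,
                              k_values = 2:4,
                              telomere_unit = "TTAGGG",
                              telomere_min_copies = 5, telomere_window = 200,
                              threshold = "q75", n_bins = 30,
                              fir_range = c(1, 1e5)) {
  inputs <- list()
  if (is.character(genome)) {
    inputs$fasta <- genome
    if (is.null(name)) name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                   basename(genome))
    genome <- read_genome_fasta(genome)
  }
  if (is.character(genes)) {
    inputs$gff3 <- genes
    genes <- read_gene_gff3(genes)
  }
  if (is.character(labels)) {
    inputs$labels <- labels
    labels <- read_category_labels(labels, gene_ids = genes$gene_id)
  }
  if (is.null(name)) name <- "genome"
  missing_scaf <- setdiff(genes$scaffold_id, genome$scaffold_id)
  if (length(missing_scaf) > 0) {
    abort(sprintf("gene scaffold(s) not in the assembly: %s",
                  paste(utils::head(missing_scaf, 3), collapse = ", ")))
  }
  genome_length <- sum(genome$length)
  gc <- sum(genome$gc_percent * genome$length) / genome_length

  loci <- find_ssrs(genome, min_len = min_len, max_len = max_len,
                    min_repeats = min_repeats)
  stats_row <- ssr_statistics(loci, genome_length, gc = gc)
  spectrum <- motif_spectrum(loci, genome_length, k_values = k_values,
                             full_universe = TRUE)
  props <- ssr_class_proportions(loci)
  tel <- find_telomeres(genome, unit = telomere_unit,
                        min_copies = telomere_min_copies,
                        window = telomere_window)
  tel_sum <- telomere_summary(tel)
  firs <- compute_firs(genes, genome)
  calls <- classify_compartments(firs, threshold = threshold)
  firs <- dplyr::left_join(firs, calls, by = "gene_id")
  density <- bin_fir_density(firs, n_bins = n_bins, fir_range = fir_range)
  cat_sum <- category_fir_summary(firs, labels)
  enrich <- NULL
  if (!is.null(labels) && nrow(labels) > 0) {
    enrich <- compartment_enrichment(calls, labels)
  }
  sparse_pct <- mean(calls$compartment == "sparse") * 100
  get_enrich <- function(cc, col) {
    if (is.null(enrich) || !cc %in% enrich$category) return(NA_real_)
    enrich[[col]][enrich$category == cc]
  }
  summary <- tibble(
    genome = name,
    length_bp = genome_length,
    gc_percent = gc,
    n_scaffolds = nrow(genome),
    n_genes = nrow(genes),
    coding_percent = coding_fraction(sum(genes$end - genes$start),
                                     genome_length),
    ssr_count = stats_row$total_count,
    ssr_merged_count = stats_row$merged_count,
    ssr_density_per_mb = stats_row$density_per_mb,
    ssr_coverage_percent = stats_row$coverage_percent,
    ssr_frequency_per_mb = stats_row$frequency_per_mb,
    telomere_complete = tel_sum$complete,
    telomere_one_end = tel_sum$one_end,
    telomere_none = tel_sum$none,
    sparse_gene_percent = sparse_pct,
    effector_odds_ratio = get_enrich("effector", "odds_ratio"),
    effector_q = get_enrich("effector", "q_value"),
    cazyme_odds_ratio = get_enrich("cazyme", "odds_ratio"),
    cazyme_q = get_enrich("cazyme", "q_value")
  )
  structure(
    list(summary = summary, ssr_loci = loci, ssr_stats = stats_row,
         spectrum = spectrum, class_proportions = props,
         telomere_calls = tel, telomere_summary = tel_sum,
         firs = firs, fir_density = density, category_summary = cat_sum,
         enrichment = enrich,
         parameters = list(
           min_len = min_len, max_len = max_len, min_repeats = min_repeats,
           k_values = k_values, telomere_unit = telomere_unit,
           telomere_min_copies = telomere_min_copies,
           telomere_window = telomere_window, threshold = threshold,
           n_bins = n_bins, fir_range = fir_range
         ),
         inputs = inputs),
    class = "genarch_report"
  )
}

#' @export
print.genarch_report <- function(x, ...) {
  cat(sprintf("Genome architecture report for '%s'\n", x$summary$genome))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @rdname run_genome_report
#' @param x A `genarch_report`.
#' @param ... Unused.
#' @export
glance.genarch_report <- function(x, ...) x$summary

#' @rdname run_genome_report
#' @export
tidy.genarch_report <- function(x, ...) {
  if (is.null(x$enrichment)) {
    tibble(category = character(), odds_ratio = numeric(),
           p_value = numeric(), q_value = numeric())
  } else {
    x$enrichment
  }
}

#' Write a report directory
#'
#' Writes every per-module table of a [run_genome_report()] result as TSV
#' (plus the SSR loci as BED6 and the density matrix with bin-edge headers),
#' together with a single `manifest.json` recording the command, parameters,
#' md5 digests of any file inputs, package version and timestamp. All tables
#' are deterministic for identical inputs; only the manifest carries a
#' timestamp.
#'
#' @param report A `genarch_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_genome_report <- function(report, dir) {
  stopifnot(inherits(report, "genarch_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  write_bed(report$ssr_loci, file.path(dir, "ssr_loci.bed"))
  readr::write_tsv(report$ssr_stats, file.path(dir, "ssr_stats.tsv"))
  readr::write_tsv(report$spectrum, file.path(dir, "spectrum.tsv"))
  readr::write_tsv(report$telomere_calls, file.path(dir, "telomeres.tsv"))
  readr::write_tsv(report$firs, file.path(dir, "firs.tsv"))
  readr::write_tsv(report$category_summary, file.path(dir, "category_summary.tsv"))
  if (!is.null(report$enrichment)) {
    readr::write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  }
  dens <- report$fir_density
  mat <- as.data.frame(dens$matrix)
  names(mat) <- sprintf("fir3_le_%g", dens$bin_edges[-1])
  mat <- cbind(tibble(fir5_le = dens$bin_edges[-1]), mat)
  readr::write_tsv(mat, file.path(dir, "density.tsv"))
  digests <- purrr::map(report$inputs,
                        function(f) unname(tools::md5sum(f)))
  manifest <- list(
    command = "run_genome_report",
    parameters = report$parameters,
    input_digests = digests,
    tool_version = as.character(utils::packageVersion("genarch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Combine per-genome reports into cross-genome matrices
#'
#' Stacks the summary rows of several reports into one comparative table
#' (input order preserved) and aligns their canonical-motif spectra into a
#' motif-by-genome per-Mb matrix suitable for heatmaps; motifs absent from a
#' genome appear as zeros.
#'
#' @param reports A list of `genarch_report` objects (at least two for a
#'   comparison; one is allowed and yields single-column matrices).
#' @return A list of class `genarch_comparison` with elements `stats`
#'   (stacked summary tibble) and `spectrum` (tibble: `k`,
#'   `canonical_motif`, one per-Mb column per genome).
#' @export
compare_genomes <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "genarch_report")))
  k_sets <- purrr::map(reports, function(r) sort(unique(r$spectrum$k)))
  if (length(unique(purrr::map_chr(k_sets, paste, collapse = ","))) > 1) {
    abort("reports tabulate different motif-length (k) ranges")
  }
  stats <- dplyr::bind_rows(purrr::map(reports, "summary"))
  if (anyDuplicated(stats$genome)) {
    abort("duplicate genome names across reports")
  }
  spec <- purrr::reduce(purrr::map(reports, function(r) {
    out <- r$spectrum[, c("k", "canonical_motif", "per_mb")]
    names(out)[3] <- r$summary$genome
    out
  }), dplyr::full_join, by = c("k", "canonical_motif"))
  spec[is.na(spec)] <- 0
  spec <- spec[order(spec$k, spec$canonical_motif), ]
  structure(list(stats = stats, spectrum = spec),
            class = "genarch_comparison")
}

#' @export
print.genarch_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %d genome(s); %d canonical motifs tabulated\n",
              nrow(x$stats), nrow(x$spectrum)))
  print(as.data.frame(x$stats), row.names = FALSE)
  invisible(x)
}
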