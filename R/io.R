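#' Read a genome assembly from FASTA
#'
#' Reads a (possibly gzip-compressed, possibly multi-line) FASTA file into a
#' tibble with one row per scaffold. Sequences are uppercased; any character
#' outside `A`, `C`, `G`, `T`, `N` (IUPAC ambiguity codes, gaps, ...) is
#' replaced by `N`, with a warning giving the replacement count. GC percent is
#' computed over non-N bases only.
#'
#' @param path Path to a FASTA file, plain or `.gz`.
#' @return A tibble with columns `scaffold_id`, `sequence`, `length`
#'   (bp) and `gc_percent`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("not readable as FASTA: %s (%s)", path, conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(sprintf("FASTA file contains no records: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA header(s): %s", paste(unique(dup), collapse = ", ")))
  }
  s <- unname(toupper(as.character(seqs)))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", s), function(m) sum(m > 0), integer(1)))
  if (n_bad > 0) {
    warn(sprintf("%d non-ACGTN character(s) replaced by N", n_bad))
    s <- gsub("[^ACGTN]", "N", s)
  }
  tibble(
    scaffold_id = unname(ids),
    sequence = s,
    length = nchar(s),
    gc_percent = gc_percent(s)
  )
}

#' Write a genome tibble to FASTA
#'
#' @param genome A genome tibble as returned by [read_genome_fasta()].
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(all(c("scaffold_id", "sequence") %in% names(genome)))
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- genome$scaffold_id
  Biostrings::writeXStringSet(s, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps rows of one feature type and converts the 1-based inclusive GFF3
#' coordinates to the package-internal 0-based half-open convention, so that
#' `end - start` is the feature length for every record.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to retain; default `"gene"`.
#' @return A tibble with columns `gene_id`, `scaffold_id`, `start` (0-based,
#'   inclusive), `end` (exclusive) and `strand`.
#' @export
read_gene_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  g <- rtracklayer::readGFF(path, columns = c("seqid", "type", "start", "end", "strand"),
                            tags = "ID")
  g <- as.data.frame(g)
  keep <- g$type == feature_type
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble(gene_id = character(), scaffold_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  if (any(g$end < g$start)) {
    i <- which(g$end < g$start)[1]
    abort(sprintf("GFF3 record with end < start (%s:%d-%d)",
                  g$seqid[i], g$start[i], g$end[i]))
  }
  missing_id <- is.na(g$ID) | g$ID == ""
  if (any(missing_id)) {
    rows <- which(keep)[which(missing_id)]
    abort(sprintf("GFF3 '%s' feature without an ID attribute at feature row %d",
                  feature_type, rows[1]))
  }
  tibble(
    gene_id = as.character(g$ID),
    scaffold_id = as.character(g$seqid),
    start = as.integer(g$start - 1L),
    end = as.integer(g$end),
    strand = as.character(g$strand)
  )
}

#' Write gene models to GFF3
#'
#' The inverse of [read_gene_gff3()]: internal 0-based half-open coordinates
#' are converted back to 1-based inclusive on output.
#'
#' @param genes A gene tibble (`gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`).
#' @param path Output path.
#' @param feature_type Feature type to write; default `"gene"`.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path, feature_type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- feature_type
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene-category labels
#'
#' Reads a tab-separated file with columns `gene_id`, `category` and optional
#' `subfamily` (for example a CAZyme family such as GH5). The category
#' vocabulary is closed: `effector`, `cazyme`, `core`. If `gene_ids` is given,
#' labels for unknown genes are dropped with a warning; genes without a label
#' are treated as `core` by downstream summaries.
#'
#' @param path Path to a TSV file with a header row.
#' @param gene_ids Optional character vector of valid gene ids.
#' @return A tibble with columns `gene_id`, `category`, `subfamily`.
#' @export
read_category_labels <- function(path, gene_ids = NULL) {
  lab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "category") %in% names(lab))) {
    abort("label file must have columns gene_id and category")
  }
  if (!"subfamily" %in% names(lab)) lab$subfamily <- NA_character_
  bad <- setdiff(unique(lab$category), c("effector", "cazyme", "core"))
  if (length(bad) > 0) {
    abort(sprintf("unknown category value(s): %s (allowed: effector, cazyme, core)",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(gene_ids)) {
    unknown <- !lab$gene_id %in% gene_ids
    if (any(unknown)) {
      warn(sprintf("%d label row(s) reference genes absent from the gene set; dropped",
                   sum(unknown)))
      lab <- lab[!unknown, , drop = FALSE]
    }
  }
  as_tibble(lab[, c("gene_id", "category", "subfamily")])
}

#' Write labelled intervals to BED6
#'
#' Writes SSR loci (or any tibble of 0-based half-open spans) as BED6:
#' scaffold, start, end, name, score, strand, sorted by scaffold then start.
#' For SSR loci the name is the motif and the score the unit count.
#'
#' @param x A tibble with columns `scaffold_id`, `start`, `end`, and
#'   optionally `name`/`motif`, `score`/`units`, `strand`.
#' @param path Output path.
#' @param scaffold_lengths Optional genome tibble or named vector; if given,
#'   spans beyond scaffold ends raise an error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, scaffold_lengths = NULL) {
  x <- as_tibble(x)
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else if ("motif" %in% names(x)) x$motif else "."
  score <- if ("score" %in% names(x)) x$score else if ("units" %in% names(x)) x$units else 0
  strand <- if ("strand" %in% names(x)) x$strand else "+"
  if (!is.null(scaffold_lengths)) {
    lens <- scaffold_length_lookup(scaffold_lengths)
    over <- x$end > lens[x$scaffold_id]
    if (any(is.na(over)) || any(over)) {
      abort("BED span beyond scaffold length (or unknown scaffold)")
    }
  }
  ord <- order(x$scaffold_id, x$start, x$end)
  gr <- GenomicRanges::GRanges(
    seqnames = x$scaffold_id[ord],
    ranges = IRanges::IRanges(start = x$start[ord] + 1L, end = x$end[ord]),
    strand = strand[if (length(strand) > 1) ord else 1]
  )
  gr$name <- name[if (length(name) > 1) ord else 1]
  gr$score <- score[if (length(score) > 1) ord else 1]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
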