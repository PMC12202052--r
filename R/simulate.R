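#' Configuration for the synthetic-assembly simulator
#'
#' Captures every tunable of [simulate_assembly()] with defaults that mirror
#' a small fungal assembly with a bipartite ("two-speed") architecture:
#' scaffolds carry alternating blocks of gene-dense and gene-sparse genes
#' whose intergenic gaps follow short and long log-normal distributions,
#' effectors and CAZymes are placed preferentially in the sparse blocks,
#' perfect microsatellites are planted into intergenic gaps, and telomeric
#' repeat arrays are written at configured scaffold termini. Gaps at block
#' transitions are drawn from the sparse distribution, so every gene's two
#' flanking gaps are consistent with its own block.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output files.
#' @param n_scaffolds,genes_per_scaffold Assembly layout (defaults 5 x 100).
#' @param gc_target Background GC fraction (default 0.525).
#' @param gene_length Named vector `c(mean, sd)` of gene lengths in bp,
#'   normal, clipped at 300 bp (default mean 1500, sd 300).
#' @param dense_gap,sparse_gap Named vectors `c(log_mean, log_sd)` of the
#'   log-normal intergenic gap distributions (defaults `log(200)`/0.5 and
#'   `log(5000)`/0.5).
#' @param block_layout Named vector `c(dense, sparse)`: genes per alternating
#'   block (default 30 dense / 10 sparse, i.e. 20 percent sparse genes).
#' @param p_effector_sparse,p_effector_dense Per-gene probability of an
#'   effector label by compartment (defaults 0.75 / 0.05).
#' @param p_cazyme_sparse,p_cazyme_dense Same for CAZyme labels (defaults
#'   0.25 / 0.10); categories are mutually exclusive, effector drawn first.
#' @param planted_ssrs Tibble with columns `motif`, `units`, `count`: perfect
#'   repeats planted into intergenic gaps, flanked so they stay maximal at
#'   exactly the planted span.
#' @param telomere_plan Tibble with columns `scaffold`, `end5`, `end3`
#'   (logical) naming which termini receive a telomere array; default:
#'   scaffold 1 both ends, middle scaffolds 3' only, last scaffold none.
#' @param telomere_unit,telomere_copies Telomere repeat and array size
#'   (defaults `TTAGGG` x 8).
#' @param margin_bp Geneless margin at each scaffold end (default 2000 bp).
#' @return A list of class `genarch_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_scaffolds = 5L,
                              genes_per_scaffold = 100L,
                              gc_target = 0.525,
                              gene_length = c(mean = 1500, sd = 300),
                              dense_gap = c(log_mean = log(200), log_sd = 0.5),
                              sparse_gap = c(log_mean = log(5000), log_sd = 0.5),
                              block_layout = c(dense = 30L, sparse = 10L),
                              p_effector_sparse = 0.75,
                              p_effector_dense = 0.05,
                              p_cazyme_sparse = 0.25,
                              p_cazyme_dense = 0.10,
                              planted_ssrs = tibble(
                                motif = c("AT", "AAG", "ACAT"),
                                units = c(10L, 7L, 6L),
                                count = c(15L, 10L, 8L)
                              ),
                              telomere_plan = NULL,
                              telomere_unit = "TTAGGG",
                              telomere_copies = 8L,
                              margin_bp = 2000L) {
  probs <- c(p_effector_sparse, p_effector_dense,
             p_cazyme_sparse, p_cazyme_dense)
  if (any(probs < 0 | probs > 1)) abort("category probabilities must be in [0, 1]")
  if (gc_target <= 0 || gc_target >= 1) abort("gc_target must be in (0, 1)")
  assert_dna_motif(telomere_unit, "telomere_unit")
  if (!is.null(planted_ssrs) && nrow(planted_ssrs) > 0) {
    assert_dna_motif(planted_ssrs$motif, "planted motif")
  }
  if (is.null(telomere_plan)) {
    telomere_plan <- tibble(
      scaffold = seq_len(n_scaffolds),
      end5 = seq_len(n_scaffolds) == 1L,
      end3 = seq_len(n_scaffolds) < n_scaffolds
    )
  }
  structure(
    list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
         genes_per_scaffold = as.integer(genes_per_scaffold),
         gc_target = gc_target, gene_length = gene_length,
         dense_gap = dense_gap, sparse_gap = sparse_gap,
         block_layout = block_layout,
         p_effector_sparse = p_effector_sparse,
         p_effector_dense = p_effector_dense,
         p_cazyme_sparse = p_cazyme_sparse,
         p_cazyme_dense = p_cazyme_dense,
         planted_ssrs = planted_ssrs,
         telomere_plan = telomere_plan,
         telomere_unit = telomere_unit,
         telomere_copies = as.integer(telomere_copies),
         margin_bp = as.integer(margin_bp)),
    class = "genarch_sim_config"
  )
}

# Replace a 0-based half-open span of a sequence string.
splice_seq <- function(s, start0, replacement) {
  substr(s, start0 + 1L, start0 + nchar(replacement)) <- replacement
  s
}

# Set the single base at 0-based position pos0 to any base != `avoid`.
break_base <- function(s, pos0, avoid) {
  if (pos0 < 0 || pos0 >= nchar(s)) return(s)
  choices <- setdiff(c("A", "C", "G", "T"), avoid)
  splice_seq(s, pos0, sample(choices, 1))
}

#' Simulate a synthetic assembly with ground truth
#'
#' Generates a fully specified assembly (scaffold sequences, gene models,
#' category labels) together with a ground-truth record of every planted
#' feature, so SSR scanning, telomere calling and compartment analysis can
#' all be validated against known answers. See [simulation_config()] for the
#' generative model. All randomness flows from the single configured seed;
#' the same configuration always yields byte-identical files.
#'
#' Planted SSRs are placed into intergenic gaps large enough to hold them
#' (never overlapping genes or each other, with a 2 bp guard), and the bases
#' immediately flanking each planted array are chosen to interrupt the
#' periodicity, so the array is maximal at exactly its planted span.
#' Telomere arrays overwrite the terminal bases of the configured ends
#' (reverse-complement units at the 5' end).
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Optional directory; if given, writes `assembly.fasta`,
#'   `genes.gff3`, `labels.tsv` and `truth.json` and returns their paths in
#'   `$files`. Feasibility is checked before any file is written.
#' @return A list with elements `genome` (tibble as from
#'   [read_genome_fasta()]), `genes`, `labels`, `truth` (list: `genes` with
#'   planted compartment and category, `ssr_loci`, `telomeres`), `config`,
#'   and `files` (if written).
#' @export
simulate_assembly <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "genarch_sim_config"))
  set.seed(config$seed)
  n_genes <- config$genes_per_scaffold
  block <- rep(c("dense", "sparse"),
               times = c(config$block_layout[["dense"]],
                         config$block_layout[["sparse"]]))

  scaffolds <- vector("list", config$n_scaffolds)
  for (sc in seq_len(config$n_scaffolds)) {
    scaffold_id <- sprintf("scf%02d", sc)
    comp <- rep(block, length.out = n_genes)
    glen <- pmax(300L, as.integer(round(stats::rnorm(
      n_genes, config$gene_length[["mean"]], config$gene_length[["sd"]]))))
    # gap preceding gene i (i >= 2); block transitions use the sparse law
    gap_law <- ifelse(comp[-1] != comp[-n_genes], "sparse", comp[-1])
    draw_gap <- function(law) {
      par <- if (law == "sparse") config$sparse_gap else config$dense_gap
      max(1L, as.integer(round(stats::rlnorm(1, par[["log_mean"]],
                                             par[["log_sd"]]))))
    }
    gaps <- vapply(gap_law, draw_gap, integer(1))
    start <- integer(n_genes)
    start[1] <- config$margin_bp
    for (i in seq_len(n_genes - 1L)) {
      start[i + 1L] <- start[i] + glen[i] + gaps[i]
    }
    end <- start + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    scaffold_length <- end[n_genes] + config$margin_bp
    u_eff <- stats::runif(n_genes)
    u_caz <- stats::runif(n_genes)
    p_eff <- ifelse(comp == "sparse", config$p_effector_sparse,
                    config$p_effector_dense)
    p_caz <- ifelse(comp == "sparse", config$p_cazyme_sparse,
                    config$p_cazyme_dense)
    category <- ifelse(u_eff < p_eff, "effector",
                       ifelse(u_caz < p_caz, "cazyme", "core"))
    scaffolds[[sc]] <- list(
      genes = tibble(
        gene_id = sprintf("%s_g%04d", scaffold_id, seq_len(n_genes)),
        scaffold_id = scaffold_id,
        start = start, end = end, strand = strand,
        compartment = comp, category = category
      ),
      length = scaffold_length
    )
  }
  genes_truth <- dplyr::bind_rows(purrr::map(scaffolds, "genes"))
  scaffold_lengths <- vapply(scaffolds, `[[`, numeric(1), "length")
  scaffold_ids <- sprintf("scf%02d", seq_len(config$n_scaffolds))

  # choose homes for planted SSRs before generating sequence, so an
  # infeasible configuration fails before any work or file output
  gaps_tbl <- genes_truth %>%
    dplyr::group_by(.data$scaffold_id) %>%
    dplyr::reframe(gap_start = .data$end[-dplyr::n()],
                   gap_end = .data$start[-1]) %>%
    dplyr::mutate(width = .data$gap_end - .data$gap_start)
  plan <- config$planted_ssrs
  planted <- NULL
  if (!is.null(plan) && nrow(plan) > 0) {
    items <- plan[rep(seq_len(nrow(plan)), plan$count), c("motif", "units")]
    items$len <- nchar(items$motif) * items$units
    eligible <- gaps_tbl[gaps_tbl$width >= max(items$len) + 4L, , drop = FALSE]
    if (nrow(eligible) < nrow(items)) {
      abort(sprintf(
        "infeasible config: %d planted SSRs but only %d intergenic gaps large enough",
        nrow(items), nrow(eligible)))
    }
    homes <- eligible[sample.int(nrow(eligible), nrow(items)), , drop = FALSE]
    offset <- vapply(homes$width - items$len - 4L, function(w) {
      sample.int(w + 1L, 1L) - 1L
    }, integer(1))
    planted <- tibble(
      scaffold_id = homes$scaffold_id,
      start = homes$gap_start + 2L + offset,
      end = homes$gap_start + 2L + offset + items$len,
      period = nchar(items$motif),
      motif = items$motif,
      canonical_motif = canonical_motif(items$motif),
      units = items$units
    )
    planted <- planted[order(planted$scaffold_id, planted$start), ]
  }

  # background sequence, then planted features spliced in
  sequences <- vapply(scaffold_lengths, random_dna, character(1),
                      gc = config$gc_target)
  names(sequences) <- scaffold_ids
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      sid <- planted$scaffold_id[i]
      p <- planted$period[i]
      s <- splice_seq(sequences[[sid]], planted$start[i],
                      strrep(planted$motif[i], planted$units[i]))
      s <- break_base(s, planted$start[i] - 1L, substr(planted$motif[i], p, p))
      s <- break_base(s, planted$end[i], substr(planted$motif[i], 1L, 1L))
      sequences[[sid]] <- s
    }
  }
  unit <- config$telomere_unit
  unit5 <- revcomp(unit)
  k <- nchar(unit)
  copies <- config$telomere_copies
  tel_truth <- config$telomere_plan
  tel_truth$scaffold_id <- scaffold_ids[tel_truth$scaffold]
  for (i in seq_len(nrow(tel_truth))) {
    sid <- tel_truth$scaffold_id[i]
    s <- sequences[[sid]]
    if (tel_truth$end5[i]) {
      s <- splice_seq(s, 0L, strrep(unit5, copies))
      s <- break_base(s, k * copies, substr(unit5, 1L, 1L))
    }
    if (tel_truth$end3[i]) {
      L <- nchar(s)
      s <- splice_seq(s, L - k * copies, strrep(unit, copies))
      s <- break_base(s, L - k * copies - 1L, substr(unit, k, k))
    }
    sequences[[sid]] <- s
  }
  tel_truth$copies5 <- ifelse(tel_truth$end5, copies, 0L)
  tel_truth$copies3 <- ifelse(tel_truth$end3, copies, 0L)
  tel_truth <- tel_truth[, c("scaffold_id", "end5", "copies5", "end3", "copies3")]

  genome <- tibble(
    scaffold_id = scaffold_ids,
    sequence = unname(sequences),
    length = nchar(sequences),
    gc_percent = gc_percent(unname(sequences))
  )
  genes <- genes_truth[, c("gene_id", "scaffold_id", "start", "end", "strand")]
  labelled <- genes_truth[genes_truth$category != "core", , drop = FALSE]
  cazy_families <- c("GH3", "GH5", "GH16", "GH18", "GH43", "GT1", "GT2",
                     "CE5", "AA7", "PL4", "CBM18")
  labels <- tibble(
    gene_id = labelled$gene_id,
    category = labelled$category,
    subfamily = ifelse(labelled$category == "cazyme",
                       sample(cazy_families, nrow(labelled), replace = TRUE),
                       NA_character_)
  )
  truth <- list(
    genes = genes_truth,
    ssr_loci = if (is.null(planted)) tibble() else planted,
    telomeres = tel_truth
  )
  out <- list(genome = genome, genes = genes, labels = labels,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      fasta = file.path(out_dir, "assembly.fasta"),
      gff3 = file.path(out_dir, "genes.gff3"),
      labels = file.path(out_dir, "labels.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_genome_fasta(genome, files$fasta)
    write_gene_gff3(genes, files$gff3)
    readr::write_tsv(labels, files$labels)
    jsonlite::write_json(truth, files$truth, dataframe = "columns",
                         digits = NA)
    out$files <- files
  }
  out
}

#' Compare observed loci or calls to simulator ground truth
#'
#' A planted SSR is recovered when an observed locus matches its scaffold,
#' exact span and canonical motif; a planted telomere when the scaffold end
#' is called. Precision counts discoveries that are not planted (random
#' background repeats, and for SSRs also the planted telomere arrays, which
#' are genuine tandem repeats) against the observation total.
#'
#' @param truth The `truth` element of a [simulate_assembly()] result (or
#'   the corresponding tibble).
#' @param observed An SSR tibble from [find_ssrs()] or a call tibble from
#'   [find_telomeres()].
#' @param type `"ssr"` or `"telomere"`.
#' @return A one-row tibble: `n_truth`, `n_observed`, `n_recovered`,
#'   `recall`, `precision`, `exact_match_fraction`.
#' @export
truth_compare <- function(truth, observed, type = c("ssr", "telomere")) {
  type <- match.arg(type)
  if (type == "ssr") {
    planted <- if (is.data.frame(truth)) truth else truth$ssr_loci
    n_truth <- nrow(planted)
    n_obs <- nrow(observed)
    if (n_truth > 0 && n_obs > 0 &&
        length(intersect(planted$scaffold_id, observed$scaffold_id)) == 0) {
      abort("truth and observed loci share no scaffold ids")
    }
    hits <- dplyr::inner_join(
      planted[, c("scaffold_id", "start", "end", "canonical_motif")],
      observed[, c("scaffold_id", "start", "end", "canonical_motif")],
      by = c("scaffold_id", "start", "end", "canonical_motif")
    )
    n_rec <- nrow(hits)
  } else {
    planted <- if (is.data.frame(truth)) truth else truth$telomeres
    if (nrow(planted) > 0 && nrow(observed) > 0 &&
        length(intersect(planted$scaffold_id, observed$scaffold_id)) == 0) {
      abort("truth and observed calls share no scaffold ids")
    }
    long <- function(x) {
      dplyr::bind_rows(
        tibble(scaffold_id = x$scaffold_id, terminus = "end5", called = x$end5),
        tibble(scaffold_id = x$scaffold_id, terminus = "end3", called = x$end3)
      )
    }
    t_long <- long(planted)
    o_long <- long(observed)
    joined <- dplyr::left_join(t_long, o_long,
                               by = c("scaffold_id", "terminus"),
                               suffix = c("_truth", "_obs"))
    n_truth <- sum(t_long$called)
    n_obs <- sum(o_long$called)
    n_rec <- sum(joined$called_truth & !is.na(joined$called_obs) &
                   joined$called_obs)
  }
  tibble(
    n_truth = n_truth,
    n_observed = n_obs,
    n_recovered = n_rec,
    recall = if (n_truth > 0) n_rec / n_truth else NA_real_,
    precision = if (n_obs > 0) n_rec / n_obs else NA_real_,
    exact_match_fraction = if (n_truth > 0) n_rec / n_truth else NA_real_
  )
}
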