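#' Per-gene flanking intergenic regions (FIRs)
#'
#' For each gene, the number of bases strictly between its span and the
#' nearest gene on either side, assigned to the gene's own 5' and 3' sides
#' according to its strand: for a `+` gene the 5' FIR is the gap to the left
#' neighbour and the 3' FIR the gap to the right; for a `-` gene the two are
#' swapped. Overlapping or nested neighbours give a gap of 0. A gene with no
#' neighbour on one side (scaffold-terminal) gets the distance to the
#' scaffold end on that side, with the corresponding boundary flag set;
#' boundary FIRs are truncated by the assembly, not true intergenic
#' distances, and are excluded from densities, summaries and classification
#' downstream.
#'
#' @param genes A gene tibble ([read_gene_gff3()]): `gene_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param scaffold_lengths A genome tibble or named vector of scaffold
#'   lengths in bp.
#' @return A tibble with columns `gene_id`, `scaffold_id`, `strand`, `fir5`,
#'   `fir3`, `boundary5`, `boundary3`.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3"), scaffold_id = "s1",
#'   start = c(100, 500, 1500), end = c(200, 700, 1600),
#'   strand = c("+", "+", "-")
#' )
#' compute_firs(genes, c(s1 = 2000))
#' @export
compute_firs <- function(genes, scaffold_lengths) {
  lens <- scaffold_length_lookup(scaffold_lengths)
  missing_scaf <- setdiff(genes$scaffold_id, names(lens))
  if (length(missing_scaf) > 0) {
    abort(sprintf("gene scaffold(s) absent from assembly: %s",
                  paste(utils::head(missing_scaf, 3), collapse = ", ")))
  }
  if (any(genes$end > lens[genes$scaffold_id])) {
    abort("gene extends past scaffold length")
  }
  ord <- order(genes$scaffold_id, genes$start, genes$end, genes$gene_id)
  if (!identical(ord, seq_len(nrow(genes)))) {
    warn("genes were not sorted by scaffold and start; sorted internally")
    genes <- genes[ord, ]
  }
  out <- genes %>%
    dplyr::group_by(.data$scaffold_id) %>%
    dplyr::mutate(
      gap_left = pmax(0L, .data$start - dplyr::lag(.data$end)),
      gap_right = pmax(0L, dplyr::lead(.data$start) - .data$end),
      boundary_left = is.na(.data$gap_left),
      boundary_right = is.na(.data$gap_right),
      gap_left = dplyr::if_else(.data$boundary_left, .data$start,
                                .data$gap_left),
      gap_right = dplyr::if_else(
        .data$boundary_right,
        as.integer(lens[.data$scaffold_id[1]]) - .data$end,
        .data$gap_right
      )
    ) %>%
    dplyr::ungroup()
  plus <- out$strand == "+"
  tibble(
    gene_id = out$gene_id,
    scaffold_id = out$scaffold_id,
    strand = out$strand,
    fir5 = as.integer(ifelse(plus, out$gap_left, out$gap_right)),
    fir3 = as.integer(ifelse(plus, out$gap_right, out$gap_left)),
    boundary5 = ifelse(plus, out$boundary_left, out$boundary_right),
    boundary3 = ifelse(plus, out$boundary_right, out$boundary_left)
  )
}

non_boundary <- function(firs) {
  firs[!firs$boundary5 & !firs$boundary3, , drop = FALSE]
}

#' Two-dimensional FIR density surface
#'
#' Bins the (5' FIR, 3' FIR) pairs of all non-boundary genes into a matrix
#' over log10-spaced bin edges, the surface behind two-speed genome contour
#' plots: a bipartite architecture shows one mode of short-by-short gaps
#' (gene-dense compartment) and one of long-by-long gaps (gene-sparse).
#' Zero-bp FIRs are shifted by a +1 bp pseudo-count before the log; values
#' outside the range are clamped into the first/last bin, so the matrix
#' total always equals the number of genes binned.
#'
#' @param firs A FIR tibble from [compute_firs()]; boundary genes are
#'   dropped.
#' @param n_bins Number of bins per axis (default 30, minimum 2).
#' @param fir_range Range in bp covered by the log-spaced edges (default
#'   `c(1, 1e5)`).
#' @return An object of class `genarch_fir_density`: a list with
#'   `bin_edges` (length `n_bins + 1`, bp), `matrix` (rows = 5' FIR bin,
#'   columns = 3' FIR bin) and `n_genes`. Supports [tidy()] and
#'   [autoplot()].
#' @export
bin_fir_density <- function(firs, n_bins = 30, fir_range = c(1, 1e5)) {
  if (n_bins < 2) abort("n_bins must be at least 2")
  firs <- non_boundary(firs)
  edges <- 10^seq(log10(fir_range[1]), log10(fir_range[2]),
                  length.out = n_bins + 1)
  bin_of <- function(v) {
    x <- pmin(pmax(v + 1, fir_range[1]), fir_range[2])
    pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  }
  b5 <- factor(bin_of(firs$fir5), levels = seq_len(n_bins))
  b3 <- factor(bin_of(firs$fir3), levels = seq_len(n_bins))
  m <- matrix(as.integer(table(b5, b3)), nrow = n_bins, ncol = n_bins)
  structure(
    list(bin_edges = edges, matrix = m, n_genes = nrow(firs)),
    class = "genarch_fir_density"
  )
}

#' @export
print.genarch_fir_density <- function(x, ...) {
  cat(sprintf("FIR density surface: %d x %d bins over [%g, %g] bp, %d genes\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$bin_edges), max(x$bin_edges), x$n_genes))
  invisible(x)
}

#' Classify genes into dense and sparse compartments
#'
#' Formalises the visual two-speed assignment: a gene is `sparse` when both
#' its 5' and its 3' FIR reach the threshold, `dense` otherwise. The
#' threshold can be a fixed value in bp or a quantile token such as `"q75"`,
#' evaluated on the pooled non-boundary 5' and 3' FIR values; with a
#' bipartite architecture and a minority sparse compartment the upper
#' quartile of pooled gaps falls in the trough between the two gap modes.
#'
#' @param firs A FIR tibble from [compute_firs()]; boundary genes are
#'   excluded.
#' @param threshold A number of bp, or `"qNN"` for the NN-th percentile of
#'   pooled FIR values (default `"q75"`).
#' @return A tibble with columns `gene_id`, `compartment`
#'   (`"dense"`/`"sparse"`) and `threshold_bp` (the resolved threshold).
#' @export
classify_compartments <- function(firs, threshold = "q75") {
  firs <- non_boundary(firs)
  if (nrow(firs) == 0) abort("no non-boundary genes to classify")
  if (is.character(threshold)) {
    if (!grepl("^q[0-9]{1,2}$", threshold)) {
      abort("threshold must be a bp value or a quantile token like 'q75'")
    }
    q <- as.numeric(sub("^q", "", threshold)) / 100
    thr <- unname(stats::quantile(c(firs$fir5, firs$fir3), q))
  } else {
    thr <- threshold
  }
  tibble(
    gene_id = firs$gene_id,
    compartment = ifelse(firs$fir5 >= thr & firs$fir3 >= thr,
                         "sparse", "dense"),
    threshold_bp = thr
  )
}

# Join category labels onto a gene table; unlabeled genes are core.
# `collapse` keeps one row per gene, effector taking precedence over cazyme
# (the rarer class) when a gene carries both.
join_categories <- function(x, labels, collapse = TRUE) {
  if (is.null(labels) || nrow(labels) == 0) {
    x$category <- "core"
    return(x)
  }
  lab <- labels[, c("gene_id", "category")]
  if (collapse) {
    lab <- lab %>%
      dplyr::mutate(rank = match(.data$category,
                                 c("effector", "cazyme", "core"))) %>%
      dplyr::arrange(.data$rank) %>%
      dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
      dplyr::select("gene_id", "category")
  }
  out <- dplyr::left_join(x, lab, by = "gene_id")
  out$category[is.na(out$category)] <- "core"
  out
}

#' FIR summaries per gene category
#'
#' Mean and median 5'/3' FIRs for core genes, effectors and CAZymes, the
#' numbers behind category boxplots: effector compartmentalisation shows as
#' larger mean FIRs for effectors than for core genes. Boundary genes are
#' excluded; genes without a label count as core; a gene labelled both
#' effector and CAZyme contributes to both category rows.
#'
#' @param firs A FIR tibble from [compute_firs()].
#' @param labels A label tibble ([read_category_labels()]), or `NULL` for
#'   all-core.
#' @return A tibble with one row per category: `category`, `n`, `mean_fir5`,
#'   `mean_fir3`, `median_fir5`, `median_fir3` (`NA` statistics when
#'   `n = 0`).
#' @export
category_fir_summary <- function(firs, labels = NULL) {
  firs <- non_boundary(firs)
  cats <- c("core", "effector", "cazyme")
  rows <- purrr::map(cats, function(cc) {
    ids <- if (cc == "core") {
      labelled <- if (is.null(labels)) character(0) else
        labels$gene_id[labels$category %in% c("effector", "cazyme")]
      setdiff(firs$gene_id, labelled)
    } else {
      if (is.null(labels)) character(0) else
        labels$gene_id[labels$category == cc]
    }
    sub <- firs[firs$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) {
      tibble(category = cc, n = 0L, mean_fir5 = NA_real_, mean_fir3 = NA_real_,
             median_fir5 = NA_real_, median_fir3 = NA_real_)
    } else {
      tibble(category = cc, n = nrow(sub),
             mean_fir5 = mean(sub$fir5), mean_fir3 = mean(sub$fir3),
             median_fir5 = stats::median(sub$fir5),
             median_fir3 = stats::median(sub$fir3))
    }
  })
  dplyr::bind_rows(rows)
}

#' Test category enrichment in the sparse compartment
#'
#' For each category, builds the 2x2 table (category in sparse, category in
#' dense; others in sparse, others in dense), applies the two-sided Fisher
#' exact test ([fisher_exact_2x2()]) and corrects across the tested
#' categories with Benjamini-Hochberg. The odds ratio is the sample odds
#' ratio `(a*d)/(b*c)`, with a 0.5 Haldane correction if and only if any
#' cell is zero.
#'
#' @param calls A compartment tibble from [classify_compartments()].
#' @param labels A label tibble ([read_category_labels()]).
#' @param categories Categories to test (default effector and cazyme).
#' @return A tibble with one row per category: the four table cells
#'   (`n_sparse_in`, `n_dense_in`, `n_sparse_out`, `n_dense_out`),
#'   `odds_ratio`, `p_value`, `q_value`.
#' @export
compartment_enrichment <- function(calls, labels,
                                   categories = c("effector", "cazyme")) {
  if (!any(calls$compartment == "sparse") ||
      !any(calls$compartment == "dense")) {
    abort("compartment margin is zero; enrichment is undefined")
  }
  rows <- purrr::map(categories, function(cc) {
    in_cat <- calls$gene_id %in% labels$gene_id[labels$category == cc]
    sparse <- calls$compartment == "sparse"
    a <- sum(in_cat & sparse)
    b <- sum(in_cat & !sparse)
    c_ <- sum(!in_cat & sparse)
    d <- sum(!in_cat & !sparse)
    ft <- fisher_exact_2x2(a, b, c_, d)
    tibble(category = cc, n_sparse_in = a, n_dense_in = b,
           n_sparse_out = c_, n_dense_out = d,
           odds_ratio = ft$odds_ratio, p_value = ft$p_two_sided)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_correct(out$p_value)
  out
}
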