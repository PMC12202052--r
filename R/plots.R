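#' @rdname bin_fir_density
#' @param x A `genarch_fir_density` object.
#' @param ... Unused.
#' @export
tidy.genarch_fir_density <- function(x, ...) {
  n <- nrow(x$matrix)
  mid <- sqrt(x$bin_edges[-1] * x$bin_edges[-(n + 1)]) # geometric midpoints
  grid <- tidyr::expand_grid(bin5 = seq_len(n), bin3 = seq_len(n))
  grid$fir5_mid <- mid[grid$bin5]
  grid$fir3_mid <- mid[grid$bin3]
  grid$count <- x$matrix[cbind(grid$bin5, grid$bin3)]
  grid
}

#' Plot methods for architecture results
#'
#' `autoplot()` on a FIR density draws the two-speed genome surface: binned
#' counts of 5' versus 3' flanking intergenic distance on log-log axes,
#' where a bipartite genome shows two modes, short-by-short (gene-dense) and
#' long-by-long (gene-sparse).
#'
#' @param object A `genarch_fir_density` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genarch_fir_density <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fir3_mid, y = .data$fir5_mid,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "3' FIR (bp)", y = "5' FIR (bp)", fill = "genes") +
    ggplot2::theme_minimal()
}

#' FIR boxplots per gene category
#'
#' Boxplots of the 5' and 3' flanking intergenic distances of core genes,
#' effectors and CAZymes (log scale). Compartmentalised effectors show
#' systematically larger FIRs than core genes.
#'
#' @param firs A FIR tibble from [compute_firs()].
#' @param labels A label tibble ([read_category_labels()]), or `NULL`.
#' @return A ggplot object.
#' @export
plot_fir_categories <- function(firs, labels = NULL) {
  firs <- non_boundary(firs)
  d <- join_categories(firs, labels, collapse = TRUE) %>%
    tidyr::pivot_longer(c("fir5", "fir3"), names_to = "side",
                        values_to = "fir")
  d$side <- factor(d$side, c("fir5", "fir3"), c("5' FIR", "3' FIR"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fir + 1,
                                  fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = NULL, y = "FIR + 1 (bp)") +
    ggplot2::theme_minimal()
}

#' Cross-genome motif spectrum heatmap
#'
#' Heatmap of canonical SSR motif abundance (motifs per Mb) across genomes,
#' one panel per motif length class.
#'
#' @param comparison A `genarch_comparison` from [compare_genomes()], or its
#'   `spectrum` tibble.
#' @return A ggplot object.
#' @export
plot_motif_spectrum <- function(comparison) {
  spec <- if (inherits(comparison, "genarch_comparison")) {
    comparison$spectrum
  } else {
    comparison
  }
  d <- tidyr::pivot_longer(spec, -c("k", "canonical_motif"),
                           names_to = "genome", values_to = "per_mb")
  d$genome <- factor(d$genome, unique(d$genome))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genome,
                                  y = .data$canonical_motif,
                                  fill = .data$per_mb)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_grid(k ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = "canonical motif", fill = "per Mb") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
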