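three_gene_fixture <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"), scaffold_id = "s1",
    start = c(100L, 500L, 1500L), end = c(200L, 700L, 1600L),
    strand = c("+", "+", "-")
  )
}

test_that("FIRs follow the strand-aware manual oracle", {
  firs <- compute_firs(three_gene_fixture(), c(s1 = 2000))
  g2 <- firs[firs$gene_id == "g2", ]
  expect_equal(g2$fir5, 300L)   # gap to left neighbour (plus strand)
  expect_equal(g2$fir3, 800L)
  expect_false(g2$boundary5 || g2$boundary3)
  g3 <- firs[firs$gene_id == "g3", ] # minus strand: sides swapped
  expect_equal(g3$fir5, 400L)   # to the scaffold end
  expect_true(g3$boundary5)
  expect_equal(g3$fir3, 800L)
  expect_false(g3$boundary3)
  g1 <- firs[firs$gene_id == "g1", ]
  expect_equal(g1$fir5, 100L)
  expect_true(g1$boundary5)
  expect_equal(g1$fir3, 300L)
})

test_that("overlapping, nested and solitary genes are handled", {
  overlapping <- tibble::tibble(
    gene_id = c("a", "b"), scaffold_id = "s",
    start = c(100L, 250L), end = c(300L, 400L), strand = "+"
  )
  firs <- compute_firs(overlapping, c(s = 1000))
  expect_equal(firs$fir3[firs$gene_id == "a"], 0L)
  expect_equal(firs$fir5[firs$gene_id == "b"], 0L)

  nested <- tibble::tibble(
    gene_id = c("outer", "inner"), scaffold_id = "s",
    start = c(100L, 150L), end = c(500L, 250L), strand = "+"
  )
  nf <- compute_firs(nested, c(s = 1000))
  expect_equal(nf$fir3[nf$gene_id == "outer"], 0L)
  expect_equal(nf$fir5[nf$gene_id == "inner"], 0L)

  single <- tibble::tibble(gene_id = "only", scaffold_id = "s",
                           start = 400L, end = 600L, strand = "+")
  sf <- compute_firs(single, c(s = 1000))
  expect_true(sf$boundary5 && sf$boundary3)
  expect_equal(sf$fir5, 400L)
  expect_equal(sf$fir3, 400L)

  bad <- single
  bad$end <- 1200L
  expect_error(compute_firs(bad, c(s = 1000)), "past scaffold length")
  expect_warning(compute_firs(three_gene_fixture()[c(2, 1, 3), ],
                              c(s1 = 2000)), "sorted internally")
})

test_that("adjacency, strand-flip and translation invariances hold", {
  withr::local_seed(31)
  sim <- simulate_assembly(simulation_config(seed = 31, n_scaffolds = 2,
                                             genes_per_scaffold = 60))
  genes <- sim$genes
  firs <- compute_firs(genes, sim$genome)
  # consecutive plus-strand genes share the intervening gap
  by_pos <- genes[order(genes$scaffold_id, genes$start), ]
  f <- firs[match(by_pos$gene_id, firs$gene_id), ]
  for (i in which(by_pos$strand[-nrow(by_pos)] == "+" &
                  by_pos$strand[-1] == "+" &
                  by_pos$scaffold_id[-nrow(by_pos)] == by_pos$scaffold_id[-1] &
                  !f$boundary3[-nrow(f)])) {
    expect_equal(f$fir3[i], f$fir5[i + 1])
  }
  # flipping every strand swaps fir5 and fir3 per gene
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  ff <- compute_firs(flipped, sim$genome)
  ff <- ff[match(firs$gene_id, ff$gene_id), ]
  expect_equal(ff$fir5, firs$fir3)
  expect_equal(ff$fir3, firs$fir5)
  expect_equal(ff$boundary5, firs$boundary3)
  # shifting all coordinates leaves FIRs of interior genes unchanged
  shifted <- genes
  shifted$start <- genes$start + 137L
  shifted$end <- genes$end + 137L
  lens <- stats::setNames(sim$genome$length + 200L, sim$genome$scaffold_id)
  sf <- compute_firs(shifted, lens)
  sf <- sf[match(firs$gene_id, sf$gene_id), ]
  interior <- !firs$boundary5 & !firs$boundary3
  expect_equal(sf$fir5[interior], firs$fir5[interior])
  expect_equal(sf$fir3[interior], firs$fir3[interior])
})

test_that("FIR density conserves gene counts and places equal FIRs on the diagonal", {
  firs <- tibble::tibble(
    gene_id = c("a", "b", "c"), scaffold_id = "s", strand = "+",
    fir5 = c(10L, 100L, 1000L), fir3 = c(10L, 100L, 1000L),
    boundary5 = FALSE, boundary3 = FALSE
  )
  d <- bin_fir_density(firs, n_bins = 10)
  expect_s3_class(d, "genarch_fir_density")
  expect_equal(sum(d$matrix), 3)
  expect_equal(sum(diag(d$matrix)), 3) # fir5 == fir3 stays on the diagonal
  expect_equal(length(d$bin_edges), 11L)
  expect_error(bin_fir_density(firs, n_bins = 1), "at least 2")

  # out-of-range and zero FIRs are clamped, never dropped
  extreme <- firs
  extreme$fir5 <- c(0L, 1L, 10000000L)
  d2 <- bin_fir_density(extreme, n_bins = 5)
  expect_equal(sum(d2$matrix), 3)

  td <- tidy(d)
  expect_equal(sum(td$count), 3)
  expect_s3_class(autoplot(d), "ggplot")
})

test_that("compartment classification matches its definition", {
  firs <- tibble::tibble(
    gene_id = c("sparse_gene", "dense_gene", "mixed_gene"),
    scaffold_id = "s", strand = "+",
    fir5 = c(2000L, 100L, 2000L), fir3 = c(3000L, 50L, 100L),
    boundary5 = FALSE, boundary3 = FALSE
  )
  calls <- classify_compartments(firs, threshold = 1500)
  expect_equal(calls$compartment,
               c("sparse", "dense", "dense")) # sparse needs BOTH sides
  expect_equal(unique(calls$threshold_bp), 1500)
  expect_error(classify_compartments(firs[0, ]), "no non-boundary")
  expect_error(classify_compartments(firs, "q750"), "quantile token")
})

test_that("q75 classification recovers planted compartments", {
  sim <- simulate_assembly(simulation_config(seed = 42))
  firs <- compute_firs(sim$genes, sim$genome)
  calls <- classify_compartments(firs, "q75")
  truth <- sim$truth$genes
  acc <- mean(calls$compartment ==
                truth$compartment[match(calls$gene_id, truth$gene_id)])
  expect_gte(acc, 0.90)
})

test_that("category FIR summaries separate planted effectors from core", {
  sim <- simulate_assembly(simulation_config(seed = 8))
  firs <- compute_firs(sim$genes, sim$genome)
  cs <- category_fir_summary(firs, sim$labels)
  expect_equal(cs$category, c("core", "effector", "cazyme"))
  expect_gt(cs$mean_fir5[cs$category == "effector"],
            cs$mean_fir5[cs$category == "core"])
  expect_gt(cs$mean_fir3[cs$category == "effector"],
            cs$mean_fir3[cs$category == "core"])
  expect_equal(sum(cs$n), nrow(dplyr::filter(firs, !boundary5, !boundary3)))

  all_core <- category_fir_summary(firs, labels = NULL)
  expect_equal(all_core$n[all_core$category == "core"],
               nrow(dplyr::filter(firs, !boundary5, !boundary3)))
  expect_equal(all_core$n[all_core$category == "effector"], 0L)
  expect_true(is.na(all_core$mean_fir5[all_core$category == "effector"]))
})

test_that("compartment enrichment reproduces the sample odds ratio", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    compartment = rep(c("sparse", "dense"), c(220, 780)),
    threshold_bp = 1500
  )
  # effectors: 30 sparse, 10 dense -> OR = (30*770)/(10*190)
  labels <- tibble::tibble(
    gene_id = c(calls$gene_id[1:30], calls$gene_id[221:230]),
    category = "effector", subfamily = NA_character_
  )
  enr <- compartment_enrichment(calls, labels, categories = "effector")
  expect_equal(enr$n_sparse_in, 30L)
  expect_equal(enr$n_dense_in, 10L)
  expect_equal(enr$odds_ratio, (30 * 770) / (10 * 190))
  expect_lt(enr$p_value, 1e-10)
  expect_equal(enr$q_value, enr$p_value) # single category tested

  # independence: equal proportions in both compartments
  labels2 <- tibble::tibble(
    gene_id = c(calls$gene_id[1:22], calls$gene_id[221:298]),
    category = "effector", subfamily = NA_character_
  )
  enr2 <- compartment_enrichment(calls, labels2, categories = "effector")
  expect_equal(enr2$odds_ratio, 1, tolerance = 0.01)
  expect_gt(enr2$p_value, 0.9)

  no_sparse <- calls
  no_sparse$compartment <- "dense"
  expect_error(compartment_enrichment(no_sparse, labels), "margin is zero")
})
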