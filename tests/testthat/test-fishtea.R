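# Gene/TE overlap, genic-region enrichment, layout and count stages.

`%||%` <- function(x, y) if (is.null(x)) y else x

mk_genes <- function(...) {
  g <- tibble::tibble(...)
  g$significant <- g$significant %||% TRUE
  g
}

test_that("family-level DE status propagates onto loci", {
  ann <- tibble::tibble(
    chrom = "chr1", start = c(0, 100, 200, 300, 400),
    end = c(50, 150, 250, 350, 450), strand = "+",
    te_name = paste0("L", 1:5),
    te_gene = c("Gypsy1", "Gypsy1", "Gypsy1", "hAT1", "hAT1"),
    te_family = c("Gypsy", "Gypsy", "Gypsy", "hAT", "hAT"),
    te_class = c("LTR", "LTR", "LTR", "DNA", "DNA")
  )
  fam <- tibble::tibble(
    name = c("Gypsy1", "NoLocusFam"),
    log2_fold_change = c(2, 1), padj = c(0.01, 0.02),
    significant = TRUE
  )
  expect_message(
    loci <- expand_families_to_loci(ann, fam),
    regexp = "no annotated locus"
  )
  expect_identical(nrow(loci), 5L)
  expect_identical(sum(loci$is_de), 3L)
  expect_identical(unique(loci$family_log2fc[loci$is_de]), 2)

  none <- expand_families_to_loci(ann, fam[0, ], quiet = TRUE)
  expect_false(any(none$is_de))
  expect_error(expand_families_to_loci(ann[0, ], fam),
               class = "srnalink_contract_error")
})

test_that("overlap summary counts distinct genes and families", {
  genes <- mk_genes(
    gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
    start = c(0, 0), end = c(1000, 1000), strand = "+",
    significant = TRUE
  )
  loci <- tibble::tibble(
    chrom = "chr1", start = c(10, 500), end = c(60, 600), strand = "+",
    te_name = c("L1", "L2"), te_gene = c("famA", "famB"),
    te_family = c("A", "B"), te_class = c("DNA", "LTR"),
    is_de = TRUE, family_log2fc = 1, family_padj = 0.01
  )
  ov <- overlap_de_genes_tes(genes, loci)
  expect_identical(ov$summary$n_de_genes_overlapping, 1L)
  expect_identical(ov$summary$n_de_te_families_overlapping, 2L)

  far <- loci |> dplyr::mutate(chrom = "chr9")
  ov0 <- overlap_de_genes_tes(genes, far)
  expect_identical(ov0$summary$n_de_genes_overlapping, 0L)
  expect_identical(ov0$summary$n_de_te_families_overlapping, 0L)

  expect_error(
    overlap_de_genes_tes(tibble::tibble(gene_id = "g", significant = TRUE),
                         loci),
    regexp = "attach_gene_coords"
  )
})

test_that("overlap counts match the planted simulation truth", {
  sim <- simulate_all(tiny_cfg(seed = 77))
  loci <- expand_families_to_loci(
    sim$te_loci,
    tibble::tibble(
      name = sim$truth$de_families, log2_fold_change = 1, padj = 0.01
    ),
    quiet = TRUE
  )
  genes <- sim$genes |>
    dplyr::mutate(significant = .data$gene_id %in% sim$truth$de_genes)
  ov <- overlap_de_genes_tes(genes, loci)
  # brute-force oracle over the same DE gene / DE locus sets
  q <- genes |> dplyr::filter(.data$significant) |>
    dplyr::mutate(name = .data$gene_id)
  s <- loci |> dplyr::filter(.data$is_de) |>
    dplyr::mutate(name = .data$te_name)
  keys <- sort(paste(ov$overlaps$query_name, ov$overlaps$subject_name,
                     sep = "|"))
  expect_identical(keys, oracle_overlap_keys(q, s))
})

test_that("genic region enrichment reproduces hand-derived hypergeometrics", {
  # one gene containing 5 loci of which 4 DE; population 20 loci, 8 DE
  loci <- tibble::tibble(
    chrom = "chr1",
    start = c(seq(100, 140, by = 10), seq(5000, 5140, by = 10)),
    end = c(seq(105, 145, by = 10), seq(5005, 5145, by = 10)),
    strand = "+",
    te_name = paste0("L", 1:20),
    te_gene = "fam", te_family = "fam", te_class = "DNA",
    is_de = c(rep(TRUE, 4), FALSE, rep(TRUE, 4), rep(FALSE, 11))
  )
  gene <- mk_genes(gene_id = "g1", chrom = "chr1", start = 90, end = 150,
                   strand = "+", significant = TRUE)
  enr <- genic_region_enrichment(gene, loci, quiet = TRUE)
  expect_identical(enr$k, 4L)
  expect_identical(enr$n, 5L)
  expect_identical(enr$K, 8L)
  expect_identical(enr$N, 20L)
  expect_equal(enr$p, 896 / 15504, tolerance = 1e-12)
  expect_equal(enr$p, oracle_hyper_tail(4, 5, 8, 20), tolerance = 1e-12)

  # everything DE and in the region: the certain event
  all_de <- loci |> dplyr::mutate(is_de = TRUE)
  wide <- mk_genes(gene_id = "g1", chrom = "chr1", start = 0, end = 6000,
                   strand = "+", significant = TRUE)
  enr2 <- genic_region_enrichment(wide, all_de, quiet = TRUE)
  expect_equal(enr2$p, 1)

  # K = 0 warns and returns p = 1
  expect_warning(
    enr3 <- genic_region_enrichment(
      gene, loci |> dplyr::mutate(is_de = FALSE), quiet = TRUE
    ),
    regexp = "K = 0"
  )
  expect_equal(enr3$p, 1)
})

test_that("alpha extremes and BH mode drive the significance call", {
  sim <- simulate_all(tiny_cfg(seed = 99))
  loci <- expand_families_to_loci(
    sim$te_loci,
    tibble::tibble(name = sim$truth$de_families, log2_fold_change = 1,
                   padj = 0.01),
    quiet = TRUE
  )
  genes <- sim$genes |>
    dplyr::mutate(significant = .data$gene_id %in% sim$truth$de_genes)
  hi <- genic_region_enrichment(genes, loci, alpha = 1 - 1e-12, quiet = TRUE)
  # p-values strictly below 1 are all called at alpha -> 1; regions with
  # the degenerate p = 1 (k = 0) never are under the strict cut-off
  expect_true(all(hi$significant[hi$p < 1 - 1e-9]))
  lo <- genic_region_enrichment(genes, loci, alpha = 0, quiet = TRUE)
  expect_false(any(lo$significant))
  bh <- genic_region_enrichment(genes, loci, correction = "bh", quiet = TRUE)
  expect_true(all(bh$p_adj >= bh$p))
  expect_identical(bh$significant, bh$p_adj < 0.05)
  # sorted by p then region id; K and N constant within a run
  expect_true(all(diff(bh$p) >= 0))
  expect_identical(unique(bh$K), bh$K[1])
})

test_that("overlapping genic regions count shared loci independently", {
  loci <- tibble::tibble(
    chrom = "chr1", start = 100, end = 120, strand = "+",
    te_name = "shared", te_gene = "fam", te_family = "fam",
    te_class = "DNA", is_de = TRUE
  )
  genes <- mk_genes(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(0, 50), end = c(200, 300), strand = "+", significant = TRUE
  )
  enr <- genic_region_enrichment(genes, loci, quiet = TRUE)
  expect_identical(nrow(enr), 2L)
  expect_identical(enr$k, c(1L, 1L))          # the locus counts in both
  expect_identical(sum(enr$k), 2L)            # sum over regions exceeds K
  expect_identical(enr$K[1], 1L)
})

test_that("null labelling keeps raw region p-values super-uniform", {
  sim <- simulate_annotation(tiny_cfg(seed = 123, n_genes = 400,
                                      n_te_loci = 20000,
                                      n_de_genes = 400,
                                      n_enriched_regions = 0))
  loci <- sim$te_loci
  withr::with_seed(5, {
    loci$is_de <- sample(rep(c(TRUE, FALSE), length.out = nrow(loci)))
  })
  genes <- all_significant_genes(sim$genes)
  enr <- genic_region_enrichment(genes, loci, quiet = TRUE)
  expect_gt(nrow(enr), 300)
  for (t in c(0.01, 0.05, 0.25)) {
    frac <- mean(enr$p < t)
    expect_lt(frac, t + 3 * sqrt(t * (1 - t) / nrow(enr)) + 0.01)
  }
})

test_that("chromosomal layout uses cumulative midpoints and natural order", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(1000, 500))
  genes <- mk_genes(gene_id = "g1", chrom = "chr1", start = 100, end = 200,
                    strand = "+", significant = TRUE)
  loci <- tibble::tibble(
    chrom = "chr2", start = 0, end = 10, strand = "+",
    te_name = "L1", te_gene = "fam", te_family = "fam", te_class = "LTR",
    is_de = TRUE
  )
  lay <- chromosomal_layout(genes, loci, sizes)
  expect_identical(lay$cumulative_pos[lay$feature_id == "g1"], 150)
  expect_identical(lay$cumulative_pos[lay$feature_id == "L1"], 1005)
  expect_identical(lay$track[lay$feature_id == "L1"], "DE TE Class II")

  enr <- tibble::tibble(region_id = "g1", significant = TRUE)
  lay2 <- chromosomal_layout(genes, loci, sizes, enrichment = enr)
  expect_true(lay2$significant_region[lay2$feature_id == "g1"])

  shuffled <- chromosomal_layout(genes[1, ], loci, sizes)
  expect_identical(shuffled, lay)

  expect_error(
    chromosomal_layout(genes |> dplyr::mutate(chrom = "chrZ"), loci, sizes),
    regexp = "chrZ"
  )
})

test_that("family/class counts conserve totals", {
  sim <- simulate_all(tiny_cfg(seed = 131))
  loci <- expand_families_to_loci(
    sim$te_loci,
    tibble::tibble(name = sim$truth$de_families, log2_fold_change = 1,
                   padj = 0.01),
    quiet = TRUE
  )
  genes <- sim$genes |>
    dplyr::mutate(significant = .data$gene_id %in% sim$truth$de_genes)
  ov <- overlap_de_genes_tes(genes, loci)
  counts <- family_class_counts(ov)
  expect_identical(sum(counts$by_family$n_loci), sum(counts$by_class$n_loci))
  expect_identical(
    sum(counts$by_class$n_loci),
    dplyr::n_distinct(ov$overlaps$subject_name)
  )
  empty <- family_class_counts(ov$overlaps[0, ])
  expect_identical(nrow(empty$by_family), 0L)
  expect_identical(nrow(empty$by_class), 0L)
})
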