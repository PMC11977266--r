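# Small simulation configurations shared across test files.

tiny_cfg <- function(seed = 11, ...) {
  defaults <- list(
    seed = seed,
    n_chroms = 3, chrom_length = 4e5,
    n_genes = 150, gene_length_range = c(800, 3000),
    n_te_loci = 2500, n_te_families = 30,
    n_de_genes = 25, n_de_families = 8,
    n_enriched_regions = 3, enrichment_multiplier = 8,
    n_targeted_genes = 30, planted_or = 20,
    n_te_seqs = 80, te_seq_length_range = c(200, 500),
    n_pirnas = 2, n_mirnas = 3
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

# A dense-TE annotation in which every genic region overlaps hundreds of TE
# loci, so null hypergeometric p-values are nearly continuous (discreteness
# would otherwise keep the detected fraction below nominal).
dense_cfg <- function(seed, n_genes = 2000, n_te_loci = 1e6, ...) {
  defaults <- list(
    seed = seed,
    n_chroms = 4, chrom_length = 2.4e6,
    n_genes = n_genes, gene_length_range = c(3000, 3700),
    n_te_loci = n_te_loci, te_locus_length_range = c(80, 120),
    n_te_families = 400,
    n_de_genes = n_genes, n_de_families = 200,
    n_enriched_regions = 0, enrichment_multiplier = 1,
    n_targeted_genes = 0,
    n_te_seqs = 10, te_seq_length_range = c(200, 300),
    n_pirnas = 0, n_mirnas = 0, utr_length = 30
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

all_significant_genes <- function(genes) {
  dplyr::mutate(
    genes,
    log2_fold_change = 0, pvalue = 1e-4, padj = 1e-3, significant = TRUE
  )
}
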