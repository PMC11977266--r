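# Differential-gene / differential-TE overlap pipeline, five stages:
#   1. attach TE locus coordinates to family-level DE calls,
#   2. overlap significant DE genes with DE TE loci,
#   3. hypergeometric enrichment of DE TE loci per genic region,
#   4. chromosome-wide layout (with significant regions flagged),
#   5. family/class count tables.
# DE status of a TE locus is inherited from its family (family-level testing
# in the style of TEtranscripts); locus-level DE is explicitly not implied.

#' Propagate family-level DE calls onto TE loci
#'
#' Every annotated locus is returned; loci whose TE name appears in the
#' significant family-level set carry `is_de = TRUE` together with the
#' family's statistics. The join key is the TE name (`te_gene`, the
#' `gene_id` of the rmsk GTF), which is the unit TEtranscripts tests.
#'
#' @param annotation TE locus table from [read_te_gtf()].
#' @param de_families Family-level DE table from
#'   `read_de_table(type = "te_family")`.
#' @param alpha Significance cut-off re-applied to `padj` (strict `<`).
#' @param quiet Suppress the zero-locus-family message.
#' @return `annotation` with `is_de`, `family_log2fc`, `family_padj`
#'   appended.
#' @export
expand_families_to_loci <- function(annotation, de_families, alpha = 0.05,
                                    quiet = FALSE) {
  if (!is.data.frame(annotation) || nrow(annotation) == 0) {
    stop_contract("TE annotation is empty")
  }
  if (!all(c("te_gene", "chrom", "start", "end") %in% names(annotation))) {
    stop_contract("TE annotation needs te_gene, chrom, start, end")
  }
  if (!all(c("name", "padj") %in% names(de_families))) {
    stop_contract("family-level DE table needs 'name' and 'padj'")
  }
  sig <- de_families %>%
    filter(!is.na(.data$padj), .data$padj < alpha) %>%
    distinct(.data$name, .keep_all = TRUE)
  out <- as_tibble(annotation) %>%
    left_join(
      sig %>%
        select(
          te_gene = "name",
          family_log2fc = "log2_fold_change",
          family_padj = "padj"
        ),
      by = "te_gene"
    ) %>%
    mutate(is_de = !is.na(.data$family_padj))
  zero <- setdiff(sig$name, annotation$te_gene)
  if (!quiet && length(zero) > 0) {
    inform(sprintf(
      "%d significantly DE TE famil(ies) have no annotated locus", length(zero)
    ))
  }
  out
}

#' Overlap significant DE genes with DE TE loci
#'
#' Stage 2: only significantly DE genes (with coordinates attached, see
#' [attach_gene_coords()]) enter on the gene side and only `is_de` loci on
#' the TE side. Overlap is strand-blind with a 1 bp minimum by default.
#'
#' @param de_genes DE gene table with interval columns.
#' @param te_loci TE locus table with `is_de` (see
#'   [expand_families_to_loci()]).
#' @param min_bp Minimum overlap width.
#' @return List of class `fishtea_overlap`: `overlaps` (one row per
#'   gene/locus pair, see [find_overlaps()], plus locus taxonomy columns)
#'   and `summary` (distinct DE genes with >= 1 DE-TE overlap, distinct DE
#'   TE families represented among overlapping loci).
#' @export
overlap_de_genes_tes <- function(de_genes, te_loci, min_bp = 1) {
  if (!all(c("chrom", "start", "end") %in% names(de_genes))) {
    stop_contract(paste(
      "DE genes carry no coordinates; attach them from a gene annotation",
      "with attach_gene_coords()"
    ))
  }
  if (!"is_de" %in% names(te_loci)) {
    stop_contract("TE loci lack 'is_de'; run expand_families_to_loci() first")
  }
  genes <- de_genes
  if ("significant" %in% names(genes)) {
    genes <- genes %>% filter(.data$significant)
  }
  genes <- genes %>% mutate(name = .data$gene_id)
  loci <- te_loci %>%
    filter(.data$is_de) %>%
    mutate(name = .data$te_name)
  overlaps <- find_overlaps(genes, loci, min_bp = min_bp)
  overlaps <- overlaps %>%
    left_join(
      loci %>%
        select("te_name", "te_gene", "te_family", "te_class") %>%
        distinct(.data$te_name, .keep_all = TRUE),
      by = c(subject_name = "te_name")
    )
  summary <- tibble(
    n_de_genes_overlapping = n_distinct(overlaps$query_name),
    n_de_te_families_overlapping = n_distinct(overlaps$te_gene)
  )
  structure(
    list(overlaps = overlaps, summary = summary),
    class = "fishtea_overlap"
  )
}

#' @export
print.fishtea_overlap <- function(x, ...) {
  cat(sprintf(
    "DE gene / DE TE overlap: %d pair(s); %d distinct DE gene(s) overlap %d DE TE famil(ies)\n",
    nrow(x$overlaps),
    x$summary$n_de_genes_overlapping,
    x$summary$n_de_te_families_overlapping
  ))
  invisible(x)
}

#' Hypergeometric enrichment of DE TE loci in genic regions
#'
#' Stage 3. The tested unit is the genic region of a significantly DE gene
#' (the gene interval, optionally extended by `flank` on both sides and
#' clipped to the chromosome) that overlaps at least one annotated TE locus.
#' Per region, `n` is the number of overlapping annotated loci and `k` the
#' number of those from significantly DE families; genome-wide, `N` is the
#' total annotated locus count and `K` the DE locus count, identical across
#' all regions of a run. The p-value is the hypergeometric upper tail
#' `P(X >= k)` (see [hyper_upper_tail()]).
#'
#' Overlapping genic regions are tested independently and may count shared
#' loci more than once across regions.
#'
#' Significance defaults to the raw p-value at `alpha` (strict `<`);
#' `correction = "bh"` applies [bh_adjust()] and calls significance on the
#' adjusted values instead.
#'
#' @param de_genes DE gene table with coordinates.
#' @param te_loci All annotated TE loci with `is_de` (DE and non-DE; the
#'   population is taken genome-wide from this table).
#' @param alpha Significance cut-off.
#' @param flank Symmetric extension of each genic region, bp.
#' @param correction `"none"` (default) or `"bh"`.
#' @param chrom_sizes Optional chrom.sizes tibble used to clip flanked
#'   regions at chromosome ends.
#' @param quiet Suppress the significant-region count message.
#' @return Tibble of class `te_enrichment`, one row per tested region:
#'   `region_id`, `chrom`, `start`, `end`, `k`, `n`, `K`, `N`, `p`,
#'   (`p_adj`,) `significant`; sorted by `p` then `region_id`. Attributes
#'   `alpha` and `correction` record the call.
#' @export
genic_region_enrichment <- function(de_genes, te_loci, alpha = 0.05,
                                    flank = 0, correction = c("none", "bh"),
                                    chrom_sizes = NULL, quiet = FALSE) {
  correction <- match.arg(correction)
  if (!all(c("chrom", "start", "end") %in% names(de_genes))) {
    stop_contract(paste(
      "DE genes carry no coordinates; attach them from a gene annotation",
      "with attach_gene_coords()"
    ))
  }
  if (!"is_de" %in% names(te_loci)) {
    stop_contract("TE loci lack 'is_de'; run expand_families_to_loci() first")
  }
  if (!is.numeric(flank) || length(flank) != 1 || flank < 0) {
    stop_contract("flank must be a single non-negative number")
  }
  N <- nrow(te_loci)
  K <- sum(te_loci$is_de)
  if (K == 0) {
    warn("no TE locus is differentially expressed (K = 0); all p-values are 1")
  }
  regions <- de_genes
  if ("significant" %in% names(regions)) {
    regions <- regions %>% filter(.data$significant)
  }
  regions <- regions %>%
    mutate(
      start = pmax(0, .data$start - flank),
      end = .data$end + flank,
      name = .data$gene_id
    )
  if (!is.null(chrom_sizes)) {
    regions <- regions %>%
      left_join(chrom_sizes, by = "chrom") %>%
      mutate(end = pmin(.data$end, .data$size)) %>%
      select(-"size")
  }
  loci <- te_loci %>% mutate(name = .data$te_name)
  ov <- find_overlaps(regions, loci, min_bp = 1)
  per_region <- ov %>%
    left_join(
      loci %>% select("te_name", "is_de") %>%
        distinct(.data$te_name, .keep_all = TRUE),
      by = c(subject_name = "te_name")
    ) %>%
    group_by(.data$query_name) %>%
    summarise(n = n(), k = sum(.data$is_de), .groups = "drop")
  out <- regions %>%
    select(region_id = "gene_id", "chrom", "start", "end") %>%
    inner_join(per_region, by = c(region_id = "query_name"))
  out$K <- K
  out$N <- N
  out$p <- if (K == 0) {
    rep(1, nrow(out))
  } else {
    hyper_upper_tail(out$k, out$n, K, N)
  }
  if (correction == "bh") {
    out$p_adj <- bh_adjust(out$p)
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out <- out %>%
    select(
      "region_id", "chrom", "start", "end", "k", "n", "K", "N",
      "p", any_of("p_adj"), "significant"
    ) %>%
    arrange(.data$p, .data$region_id)
  if (!quiet) {
    inform(sprintf(
      "%d of %d tested genic regions significant (%s, alpha = %g)",
      sum(out$significant), nrow(out),
      if (correction == "bh") "BH-adjusted p" else "raw p", alpha
    ))
  }
  structure(out, class = c("te_enrichment", class(out)),
            alpha = alpha, correction = correction)
}

#' @rdname genic_region_enrichment
#' @param x A `te_enrichment` table.
#' @param ... Unused.
#' @export
glance.te_enrichment <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    K = if (nrow(x) > 0) x$K[1] else NA_integer_,
    N = if (nrow(x) > 0) x$N[1] else NA_integer_,
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction")
  )
}

#' Chromosome-wide layout of DE genes and DE TE loci
#'
#' Stage 4: lays every feature on a single cumulative axis (chromosomes in
#' natural order, each offset by the sizes of its predecessors; features at
#' their interval midpoints). Tracks are `DE gene`, `DE TE Class I` and
#' `DE TE Class II` (class labels per `nomenclature`, see
#' [te_class_label()]); gene rows whose region is significant in an
#' enrichment result carry `significant_region = TRUE` (plotted as orange
#' diamonds by [plot_chromosomal_layout()]).
#'
#' @param de_genes Significant DE genes with coordinates.
#' @param te_loci DE TE loci (rows with `is_de = TRUE` are used).
#' @param chrom_sizes chrom.sizes tibble; every feature chromosome must be
#'   present.
#' @param enrichment Optional [genic_region_enrichment()] result supplying
#'   the significant-region flags.
#' @param nomenclature Class labelling mode.
#' @return Tibble `feature_id`, `chrom`, `position`, `cumulative_pos`,
#'   `track`, `significant_region`.
#' @export
chromosomal_layout <- function(de_genes, te_loci, chrom_sizes,
                               enrichment = NULL,
                               nomenclature = c("paper", "standard")) {
  nomenclature <- match.arg(nomenclature)
  genes <- de_genes
  if ("significant" %in% names(genes)) {
    genes <- genes %>% filter(.data$significant)
  }
  loci <- te_loci
  if ("is_de" %in% names(loci)) loci <- loci %>% filter(.data$is_de)
  feats <- bind_rows(
    genes %>%
      mutate(feature_id = .data$gene_id, track = "DE gene") %>%
      select("feature_id", "chrom", "start", "end", "track"),
    loci %>%
      mutate(
        feature_id = .data$te_name,
        track = paste("DE TE", te_class_label(.data$te_class, nomenclature))
      ) %>%
      select("feature_id", "chrom", "start", "end", "track")
  )
  unknown <- setdiff(feats$chrom, chrom_sizes$chrom)
  if (length(unknown) > 0) {
    stop_contract(sprintf(
      "chromosome(s) absent from chrom.sizes: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  sizes <- chrom_sizes %>%
    arrange(match(.data$chrom, natural_chrom_order(.data$chrom))) %>%
    mutate(offset = cumsum(dplyr::lag(.data$size, default = 0)))
  sig_ids <- character(0)
  if (!is.null(enrichment)) {
    sig_ids <- enrichment$region_id[enrichment$significant]
  }
  feats %>%
    left_join(sizes %>% select("chrom", "offset"), by = "chrom") %>%
    mutate(
      position = floor((.data$start + .data$end) / 2),
      cumulative_pos = .data$offset + .data$position,
      significant_region = .data$track == "DE gene" &
        .data$feature_id %in% sig_ids
    ) %>%
    select(
      "feature_id", "chrom", "position", "cumulative_pos", "track",
      "significant_region"
    ) %>%
    arrange(
      match(.data$chrom, natural_chrom_order(.data$chrom)),
      .data$cumulative_pos, .data$track, .data$feature_id
    )
}

#' Plot a chromosomal layout
#'
#' @param layout Output of [chromosomal_layout()].
#' @param chrom_sizes chrom.sizes tibble (draws chromosome boundaries).
#' @return A ggplot object.
#' @export
plot_chromosomal_layout <- function(layout, chrom_sizes = NULL) {
  p <- ggplot(layout, aes(x = .data$cumulative_pos, y = .data$track,
                          colour = .data$track)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_point(
      data = layout %>% filter(.data$significant_region),
      colour = "orange", shape = 18, size = 3
    ) +
    scale_colour_manual(values = c(
      "DE gene" = "darkblue",
      "DE TE Class I" = "red",
      "DE TE Class II" = "lightblue",
      "DE TE Unknown" = "grey60"
    )) +
    labs(
      x = "cumulative genomic position (bp)", y = NULL,
      title = "DE genes and DE TE loci along the genome",
      subtitle = "orange diamonds: genic regions enriched for DE TE loci"
    ) +
    theme_minimal() +
    theme(legend.position = "none")
  if (!is.null(chrom_sizes)) {
    sizes <- chrom_sizes %>%
      arrange(match(.data$chrom, natural_chrom_order(.data$chrom)))
    p <- p + geom_vline(
      xintercept = cumsum(sizes$size), linetype = "dotted",
      colour = "grey70", linewidth = 0.3
    )
  }
  p
}

#' Family- and class-level counts of overlapping DE TE loci
#'
#' Stage 5: counts the DE TE loci that overlap DE genes, grouped by TE
#' family and by class. Totals are conserved between the two tables
#' (distinct loci, counted once each).
#'
#' @param overlap A [overlap_de_genes_tes()] result (or its `overlaps`
#'   tibble).
#' @param nomenclature Class labelling mode.
#' @return List with tibbles `by_family` (`te_family`, `class_label`,
#'   `n_loci`) and `by_class` (`class_label`, `n_loci`), both sorted by
#'   count descending.
#' @export
family_class_counts <- function(overlap,
                                nomenclature = c("paper", "standard")) {
  nomenclature <- match.arg(nomenclature)
  ov <- if (inherits(overlap, "fishtea_overlap")) overlap$overlaps else overlap
  distinct_loci <- ov %>%
    distinct(.data$subject_name, .keep_all = TRUE) %>%
    mutate(class_label = te_class_label(.data$te_class, nomenclature))
  by_family <- distinct_loci %>%
    count(.data$te_family, .data$class_label, name = "n_loci") %>%
    arrange(desc(.data$n_loci), .data$te_family)
  by_class <- distinct_loci %>%
    count(.data$class_label, name = "n_loci") %>%
    arrange(desc(.data$n_loci), .data$class_label)
  list(by_family = by_family, by_class = by_class)
}

#' Run the full gene/TE overlap-and-enrichment pipeline
#'
#' Convenience wrapper chaining the five stages on in-memory tables. See the
#' stage functions for details.
#'
#' @param de_genes DE gene table (with or without coordinates).
#' @param gene_annotation Gene annotation used to attach coordinates when
#'   `de_genes` has none.
#' @param de_families Family-level TE DE table.
#' @param te_annotation TE locus annotation from [read_te_gtf()].
#' @param chrom_sizes chrom.sizes tibble.
#' @param alpha,flank,correction,nomenclature See stage functions.
#' @param quiet Suppress messages.
#' @return Object of class `fishtea_result`: list with `loci`, `overlap`,
#'   `enrichment`, `layout`, `counts`.
#' @export
fishtea <- function(de_genes, gene_annotation, de_families, te_annotation,
                    chrom_sizes, alpha = 0.05, flank = 0,
                    correction = c("none", "bh"),
                    nomenclature = c("paper", "standard"), quiet = FALSE) {
  correction <- match.arg(correction)
  nomenclature <- match.arg(nomenclature)
  if (!all(c("chrom", "start", "end") %in% names(de_genes))) {
    de_genes <- attach_gene_coords(de_genes, gene_annotation, quiet = quiet)
  }
  loci <- expand_families_to_loci(te_annotation, de_families, alpha = alpha,
                                  quiet = quiet)
  overlap <- overlap_de_genes_tes(de_genes, loci)
  enrichment <- genic_region_enrichment(
    de_genes, loci, alpha = alpha, flank = flank, correction = correction,
    chrom_sizes = chrom_sizes, quiet = quiet
  )
  layout <- chromosomal_layout(de_genes, loci, chrom_sizes,
                               enrichment = enrichment,
                               nomenclature = nomenclature)
  counts <- family_class_counts(overlap, nomenclature = nomenclature)
  structure(
    list(
      loci = loci, overlap = overlap, enrichment = enrichment,
      layout = layout, counts = counts
    ),
    class = "fishtea_result"
  )
}

#' @rdname fishtea
#' @param x A `fishtea_result`.
#' @param ... Unused.
#' @export
glance.fishtea_result <- function(x, ...) {
  bind_cols(x$overlap$summary, glance(x$enrichment))
}

#' @export
print.fishtea_result <- function(x, ...) {
  print(x$overlap)
  print(glance(x$enrichment))
  invisible(x)
}
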