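# Seed-based miRNA target identification in 3'UTRs and Fisher-exact linking
# of targets with differentially expressed genes. Canonical seed-site classes
# (8mer, 7mer-m8, 7mer-A1, 6mer) stand in for thermodynamic alignment
# scoring; the linking statistic is the contribution here, not the scanner.

# Site patterns on the UTR (read 5'->3'), for a miRNA numbered 1..n from its
# 5' end with seed nucleotides 2..8:
#   6mer     reverse complement of miRNA 2..7
#   7mer-m8  reverse complement of miRNA 2..8
#   7mer-A1  (6mer site) followed by A
#   8mer     (7mer-m8 site) followed by A
mirna_site_patterns <- function(sequence) {
  seq <- normalize_seq(sequence)
  seed27 <- str_sub(seq, 2, 7)
  seed28 <- str_sub(seq, 2, 8)
  list(
    `6mer` = revcomp(seed27),
    `7mer-m8` = revcomp(seed28),
    `7mer-A1` = paste0(revcomp(seed27), "A"),
    `8mer` = paste0(revcomp(seed28), "A")
  )
}

#' Find canonical miRNA seed sites in 3'UTRs
#'
#' Scans every UTR for the site class selected by `site_rule` (default
#' `7mer-m8`) for every miRNA. Each reported hit is additionally classified
#' to its most specific canonical type (an occurrence of the 7mer-m8 site
#' followed by `A` is an `8mer`, etc.). A gene counts as targeted by a miRNA
#' iff it has at least one site.
#'
#' @param mirnas Tibble of mature miRNAs (`id`, `sequence`), each >= 8 nt.
#' @param utrs Tibble of 3'UTR sequences keyed by gene id (`id`,
#'   `sequence`); duplicate ids are an error.
#' @param site_rule One of `"7mer-m8"`, `"8mer"`, `"7mer-A1"`, `"6mer"`.
#' @return Tibble `mirna_id`, `gene_id`, `site_position` (0-based offset of
#'   the site in the UTR), `site_type`; deterministic ordering.
#' @export
find_targets <- function(mirnas, utrs,
                         site_rule = c("7mer-m8", "8mer", "7mer-A1", "6mer")) {
  site_rule <- match.arg(site_rule)
  if (!all(c("id", "sequence") %in% names(mirnas)) ||
      !all(c("id", "sequence") %in% names(utrs))) {
    stop_contract("miRNA and UTR tables need columns 'id' and 'sequence'")
  }
  if (anyDuplicated(utrs$id)) {
    dup <- utrs$id[duplicated(utrs$id)][1]
    stop_contract(sprintf("duplicate UTR id: %s", dup))
  }
  if (any(str_length(mirnas$sequence) < 8)) {
    stop_contract("every miRNA must be at least 8 nt")
  }
  utr_seq <- normalize_seq(utrs$sequence)

  scan_one <- function(mirna_id, sequence) {
    pats <- mirna_site_patterns(sequence)
    m <- scan_pattern(pats[[site_rule]], utr_seq)
    if (length(m$seq_idx) == 0) return(NULL)
    idx <- m$seq_idx
    pos0 <- m$pos0
    rule_len <- str_length(pats[[site_rule]])
    # Most specific classification: is the site preceded by the m8 match
    # and/or followed by the A1 adenine?
    seq_at <- utr_seq[idx]
    after <- str_sub(seq_at, pos0 + rule_len + 1, pos0 + rule_len + 1)
    before <- str_sub(seq_at, pos0, pos0)
    m8_char <- str_sub(pats[["7mer-m8"]], 1, 1)
    site_type <- switch(
      site_rule,
      "7mer-m8" = if_else(after == "A", "8mer", "7mer-m8"),
      "8mer" = rep("8mer", length(pos0)),
      "7mer-A1" = if_else(before == m8_char, "8mer", "7mer-A1"),
      "6mer" = dplyr::case_when(
        before == m8_char & after == "A" ~ "8mer",
        before == m8_char ~ "7mer-m8",
        after == "A" ~ "7mer-A1",
        TRUE ~ "6mer"
      )
    )
    tibble(
      mirna_id = mirna_id,
      gene_id = utrs$id[idx],
      site_position = pos0,
      site_type = site_type
    )
  }

  out <- map2(mirnas$id, mirnas$sequence, scan_one) %>% list_rbind()
  if (nrow(out) == 0) {
    return(tibble(
      mirna_id = character(0), gene_id = character(0),
      site_position = integer(0), site_type = character(0)
    ))
  }
  out %>% arrange(.data$mirna_id, .data$gene_id, .data$site_position)
}

#' Link miRNA target hits to differentially expressed genes
#'
#' Builds the 2x2 contingency table of targeted-by-any-miRNA against
#' differentially-expressed over a background gene universe and tests
#' enrichment with the two-sided Fisher exact test ([fisher_exact()]). A
#' gene targeted by two or more miRNAs counts once in the table (gene-level
#' union) while `per_mirna` counts it under each miRNA.
#'
#' The default background is every gene of the DE table with a non-missing
#' raw p-value (the genes actually tested); a user-supplied id vector is
#' accepted for external backgrounds. Hits on genes outside the background
#' are dropped with a warning; DE genes outside the background are dropped
#' likewise.
#'
#' @param hits Target hits from [find_targets()].
#' @param de_genes DE gene table (see [read_de_table()]).
#' @param background Character vector of background gene ids, or `NULL` for
#'   the default.
#' @param quiet Suppress messages.
#' @return Object of class `mirna_link`: list with `table` (the
#'   [fisher_exact()] result), `targeted_de_genes`, `de_total`,
#'   `background_size`, and `per_mirna` (DE genes targeted per miRNA).
#'   [tidy()] returns `per_mirna`; [glance()] a one-row summary.
#' @export
link_targets_to_de <- function(hits, de_genes, background = NULL,
                               quiet = FALSE) {
  if (!all(c("mirna_id", "gene_id") %in% names(hits))) {
    stop_contract("hits need columns 'mirna_id' and 'gene_id'")
  }
  if (!all(c("gene_id", "significant") %in% names(de_genes))) {
    stop_contract("DE gene table needs 'gene_id' and 'significant'")
  }
  if (is.null(background)) {
    background <- de_genes$gene_id[!is.na(de_genes$pvalue)]
  }
  background <- unique(as.character(background))
  if (length(background) == 0) stop_contract("background gene set is empty")

  outside <- setdiff(unique(hits$gene_id), background)
  if (length(outside) > 0) {
    if (!quiet) {
      warn(sprintf(
        "%d targeted gene(s) absent from the background were dropped",
        length(outside)
      ))
    }
    hits <- hits %>% filter(.data$gene_id %in% background)
  }
  de_ids <- unique(de_genes$gene_id[de_genes$significant])
  de_outside <- setdiff(de_ids, background)
  if (length(de_outside) > 0) {
    if (!quiet) {
      warn(sprintf(
        "%d DE gene(s) absent from the background were dropped",
        length(de_outside)
      ))
    }
    de_ids <- intersect(de_ids, background)
  }
  targeted <- unique(hits$gene_id)
  a <- length(intersect(targeted, de_ids))
  b <- length(setdiff(targeted, de_ids))
  c_ <- length(setdiff(de_ids, targeted))
  d <- length(background) - a - b - c_
  if (!quiet && length(de_ids) == 0) {
    warn("no significantly DE genes in the background; contingency a = c = 0")
  }
  ft <- fisher_exact(a, b, c_, d)
  per_mirna <- hits %>%
    filter(.data$gene_id %in% de_ids) %>%
    distinct(.data$mirna_id, .data$gene_id) %>%
    count(.data$mirna_id, name = "n_de_genes_targeted") %>%
    arrange(desc(.data$n_de_genes_targeted), .data$mirna_id)
  structure(
    list(
      table = ft,
      targeted_de_genes = a,
      de_total = length(de_ids),
      background_size = length(background),
      per_mirna = per_mirna
    ),
    class = "mirna_link"
  )
}

#' @export
print.mirna_link <- function(x, ...) {
  cat(sprintf(
    "miRNA target / DE gene linking over %d background genes\n",
    x$background_size
  ))
  cat(sprintf(
    "  targeted & DE: %d of %d DE genes\n", x$targeted_de_genes, x$de_total
  ))
  print(x$table)
  invisible(x)
}

#' @rdname link_targets_to_de
#' @param x A `mirna_link` object.
#' @param ... Unused.
#' @export
tidy.mirna_link <- function(x, ...) x$per_mirna

#' @rdname link_targets_to_de
#' @export
glance.mirna_link <- function(x, ...) {
  tidy(x$table) %>%
    mutate(
      targeted_de_genes = x$targeted_de_genes,
      de_total = x$de_total,
      background_size = x$background_size
    )
}
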