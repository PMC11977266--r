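# miRNA seed-site scanning and Fisher-exact linking of targets to DE genes.

test_that("find_targets locates canonical sites and classifies them", {
  # miRNA with seed positions 2-8 = AGGCATC -> 7mer-m8 site GATGCCT
  mir <- tibble::tibble(id = "miR-t", sequence = "UAGGCAUCGGUUGUACUGAA")
  utr <- tibble::tibble(
    id = "gene1",
    sequence = paste0("CCCCCCC", "GATGCCT", "CCCCCC")
  )
  hits <- find_targets(mir, utr)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$site_position, 7)
  expect_identical(hits$site_type, "7mer-m8")

  # followed by A -> most specific class is 8mer
  utr8 <- tibble::tibble(id = "gene1",
                         sequence = paste0("CCCCCCC", "GATGCCTA", "CCCCC"))
  expect_identical(find_targets(mir, utr8)$site_type, "8mer")
  expect_identical(find_targets(mir, utr8, site_rule = "8mer")$site_type,
                   "8mer")
  # 6mer rule finds the core and upgrades by context
  h6 <- find_targets(mir, utr8, site_rule = "6mer")
  expect_identical(h6$site_type, "8mer")

  # site excised -> zero hits
  utr0 <- tibble::tibble(id = "gene1", sequence = "CCCCCCCCCCCCCCCCCCCC")
  expect_identical(nrow(find_targets(mir, utr0)), 0L)

  dup <- tibble::tibble(id = c("g", "g"), sequence = c("ACGTACGT", "ACGTACGT"))
  expect_error(find_targets(mir, dup), regexp = "duplicate",
               class = "srnalink_contract_error")
  expect_error(
    find_targets(tibble::tibble(id = "m", sequence = "ACGTACG"), utr),
    class = "srnalink_contract_error"
  )
})

test_that("find_targets equals a naive reverse-complement scan", {
  withr::with_seed(404, {
    for (i in 1:25) {
      mir <- tibble::tibble(id = "m", sequence = rand_dna_str(22))
      utrs <- tibble::tibble(
        id = sprintf("g%d", 1:20),
        sequence = vapply(rep(300, 20), rand_dna_str, character(1))
      )
      pattern <- str_revcomp(substr(mir$sequence, 2, 8))
      hits <- find_targets(mir, utrs)
      want <- lapply(seq_len(20), function(j) {
        pos <- naive_seed_sites(pattern, utrs$sequence[j])
        # naive scan of the site pattern itself: "antisense" rows are the
        # literal occurrences of the pattern
        pos$position[pos$orientation == "antisense"]
      })
      want_n <- sum(lengths(want))
      expect_identical(nrow(hits), want_n)
      if (want_n > 0) {
        got <- split(hits$site_position, factor(hits$gene_id,
                                                levels = utrs$id))
        for (j in seq_len(20)) {
          expect_equal(unname(got[[j]]), want[[j]])
        }
      }
    }
  })
})

test_that("linking builds the documented contingency table", {
  # background 100, 20 DE, 30 targeted, 15 targeted & DE -> (15,15,5,65)
  bg <- sprintf("g%03d", 1:100)
  de <- tibble::tibble(
    gene_id = bg,
    log2_fold_change = 0,
    pvalue = 0.5,
    padj = c(rep(0.01, 20), rep(0.5, 80)),
    significant = c(rep(TRUE, 20), rep(FALSE, 80))
  )
  hits <- tibble::tibble(
    mirna_id = "m1",
    gene_id = c(bg[1:15], bg[21:35])
  )
  link <- link_targets_to_de(hits, de, background = bg, quiet = TRUE)
  expect_identical(link$table$a, 15L)
  expect_identical(link$table$b, 15L)
  expect_identical(link$table$c, 5L)
  expect_identical(link$table$d, 65L)
  expect_equal(link$table$odds_ratio, 13)
  expect_equal(link$table$p_two_sided, oracle_fisher_p(15, 15, 5, 65),
               tolerance = 1e-12)
  g <- glance(link)
  expect_identical(g$targeted_de_genes, 15L)
  expect_identical(g$de_total, 20L)
})

test_that("targets identical to the DE set give an infinite odds ratio", {
  bg <- sprintf("g%03d", 1:100)
  de <- tibble::tibble(
    gene_id = bg, log2_fold_change = 0, pvalue = 0.5,
    padj = c(rep(0.01, 10), rep(0.5, 90)),
    significant = c(rep(TRUE, 10), rep(FALSE, 90))
  )
  hits <- tibble::tibble(mirna_id = "m1", gene_id = bg[1:10])
  link <- link_targets_to_de(hits, de, background = bg, quiet = TRUE)
  expect_identical(link$table$odds_ratio, Inf)
  expect_equal(link$table$p_two_sided, oracle_fisher_p(10, 0, 0, 90),
               tolerance = 1e-12)
})

test_that("per-miRNA counts use each miRNA while the table uses the union", {
  bg <- sprintf("g%02d", 1:50)
  de <- tibble::tibble(
    gene_id = bg, log2_fold_change = 0, pvalue = 0.5,
    padj = ifelse(seq_along(bg) <= 10, 0.01, 0.5),
    significant = seq_along(bg) <= 10
  )
  hits <- tibble::tibble(
    mirna_id = c("mA", "mB", "mB", "mA"),
    gene_id = c("g01", "g01", "g02", "g30")
  )
  link <- link_targets_to_de(hits, de, background = bg, quiet = TRUE)
  expect_identical(link$table$a, 2L)  # g01 counted once in the union
  per <- tidy(link)
  expect_identical(per$n_de_genes_targeted[per$mirna_id == "mA"], 1L)
  expect_identical(per$n_de_genes_targeted[per$mirna_id == "mB"], 2L)
})

test_that("background additions of untargeted non-DE genes only grow d", {
  bg <- sprintf("g%02d", 1:40)
  de <- tibble::tibble(
    gene_id = bg, log2_fold_change = 0, pvalue = 0.5,
    padj = ifelse(seq_along(bg) <= 8, 0.01, 0.5),
    significant = seq_along(bg) <= 8
  )
  hits <- tibble::tibble(mirna_id = "m", gene_id = c(bg[1:5], bg[9:12]))
  small <- link_targets_to_de(hits, de, background = bg, quiet = TRUE)
  big <- link_targets_to_de(hits, de, background = c(bg, "new1", "new2"),
                            quiet = TRUE)
  expect_identical(big$table$a, small$table$a)
  expect_identical(big$table$b, small$table$b)
  expect_identical(big$table$c, small$table$c)
  expect_identical(big$table$d, small$table$d + 2L)
  expect_gte(big$table$odds_ratio, small$table$odds_ratio)
})

test_that("degenerate and out-of-background inputs behave per contract", {
  bg <- c("g1", "g2", "g3")
  de_empty <- tibble::tibble(
    gene_id = bg, log2_fold_change = 0, pvalue = 0.5, padj = 0.5,
    significant = FALSE
  )
  hits <- tibble::tibble(mirna_id = "m", gene_id = c("g1", "outsider"))
  expect_warning(
    expect_warning(
      link <- link_targets_to_de(hits, de_empty, background = bg),
      regexp = "absent from the background"
    ),
    regexp = "a = c = 0"
  )
  expect_identical(link$table$a, 0L)
  expect_identical(link$table$c, 0L)
  expect_identical(link$table$b, 1L)
  expect_error(
    link_targets_to_de(hits, de_empty, background = character(0)),
    class = "srnalink_contract_error"
  )
})

test_that("the planted odds ratio is recovered through the full scan", {
  cfg <- tiny_cfg(seed = 202, n_genes = 2000, n_de_genes = 100,
                  n_targeted_genes = 150, planted_or = 12, n_mirnas = 2,
                  chrom_length = 2e6)
  sim <- simulate_all(cfg)
  de <- sim$de_genes |>
    dplyr::transmute(
      gene_id = .data$gene_id, log2_fold_change = .data$log2FoldChange,
      pvalue = .data$pvalue, padj = .data$padj,
      significant = !is.na(.data$padj) & .data$padj < 0.05
    )
  hits <- find_targets(sim$mirnas, sim$utrs)
  link <- link_targets_to_de(hits, de, quiet = TRUE)
  truth <- sim$truth$contingency
  expect_identical(link$table$a, as.integer(truth[["a"]]))
  expect_identical(link$table$b, as.integer(truth[["b"]]))
  expect_identical(link$table$c, as.integer(truth[["c"]]))
  expect_identical(link$table$d, as.integer(truth[["d"]]))
})
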