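# Deterministic, seeded generators for every input format the toolkit
# consumes, with planted structure (DE sets, region enrichment, seed sites,
# a planted odds ratio) recorded in a machine-readable truth object.
#
# One integer seed controls every stochastic choice; identical configs give
# byte-identical files. Default dimensions follow the result shape of the
# zebrafish paternal-stress study the toolkit targets: 612 DE genes out of
# 25,000, 116 DE TE families, 12 enriched genic regions, 7 DE miRNAs,
# ~515 of the DE genes targeted at a planted odds ratio of 130.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_all()] and friends. Every
#' dimension is a field, not a constant; the defaults emulate a scaled-down
#' zebrafish genome (25 chromosomes of 8 Mb) with a realistic TE landscape
#' (DNA transposons the most abundant class, as in zebrafish).
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_chroms,chrom_length Chromosome count and common length (bp).
#' @param n_genes,gene_length_range Gene count and uniform length range.
#' @param n_te_loci,te_locus_length_range Baseline TE locus count and length
#'   range.
#' @param n_te_families Size of the TE family catalog.
#' @param class_weights Named sampling weights over raw TE classes
#'   (`DNA`, `LTR`, `LINE`, `SINE`, `RC`).
#' @param n_de_genes,n_de_families Planted significant counts.
#' @param n_enriched_regions Genic regions receiving extra DE-family loci.
#' @param enrichment_multiplier Target ratio of DE-locus density inside
#'   enriched regions over baseline.
#' @param planted_or Odds ratio planted between "targeted by a DE miRNA"
#'   and "differentially expressed".
#' @param n_targeted_genes Expected number of targeted genes overall.
#' @param n_mirnas,mirna_length,n_pirnas,pirna_length Small-RNA counts and
#'   lengths (nt).
#' @param seed_window piRNA seed window, 1-based inclusive (teleost default
#'   1-10).
#' @param n_te_seqs,te_seq_length_range TE reference FASTA size and sequence
#'   length range.
#' @param site_fraction_class1 Fraction of DNA-transposon reference
#'   sequences receiving a complementary site per piRNA.
#' @param site_fraction_class2 Same for retroelement sequences.
#' @param utr_length 3'UTR length (nt).
#' @param de_lfc_mean Mean absolute log2 fold change of DE members.
#' @param na_padj_fraction Fraction of non-DE genes with `padj = NA`
#'   (emulating independent filtering).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1234,
                       n_chroms = 25,
                       chrom_length = 8e6,
                       n_genes = 25000,
                       gene_length_range = c(1000, 5000),
                       n_te_loci = 300000,
                       te_locus_length_range = c(100, 800),
                       n_te_families = 500,
                       class_weights = c(DNA = 0.55, LTR = 0.20, LINE = 0.15,
                                         SINE = 0.05, RC = 0.05),
                       n_de_genes = 612,
                       n_de_families = 116,
                       n_enriched_regions = 12,
                       enrichment_multiplier = 8,
                       planted_or = 130,
                       n_targeted_genes = 1466,
                       n_mirnas = 7,
                       mirna_length = 22,
                       n_pirnas = 3,
                       pirna_length = 28,
                       seed_window = c(1, 10),
                       n_te_seqs = 3000,
                       te_seq_length_range = c(400, 3000),
                       site_fraction_class1 = 0.9,
                       site_fraction_class2 = 0.15,
                       utr_length = 150,
                       de_lfc_mean = 2.5,
                       na_padj_fraction = 0.05) {
  cfg <- as.list(environment())
  if (!is_count(seed) || seed >= 2^31) {
    stop_contract("seed must be a non-negative integer below 2^31")
  }
  stopifnot_feasible <- function(ok, msg) if (!ok) stop_contract(msg)
  stopifnot_feasible(n_de_genes <= n_genes, "n_de_genes exceeds n_genes")
  stopifnot_feasible(n_de_families <= n_te_families,
                     "n_de_families exceeds n_te_families")
  stopifnot_feasible(n_enriched_regions <= n_de_genes || n_enriched_regions == 0,
                     "n_enriched_regions exceeds n_de_genes")
  stopifnot_feasible(n_targeted_genes <= n_genes,
                     "n_targeted_genes exceeds n_genes")
  stopifnot_feasible(seed_window[1] >= 1 && seed_window[2] >= seed_window[1],
                     "invalid seed window")
  stopifnot_feasible(pirna_length >= seed_window[2],
                     "piRNA length shorter than the seed window")
  stopifnot_feasible(mirna_length >= 8, "miRNA length must be >= 8")
  stopifnot_feasible(
    gene_length_range[2] * 1.0 <= chrom_length,
    "gene_length_range exceeds chromosome length"
  )
  stopifnot_feasible(
    all(class_weights >= 0) && sum(class_weights) > 0,
    "class_weights must be non-negative with a positive sum"
  )
  structure(cfg, class = "sim_config")
}

superfamily_pool <- list(
  DNA = c("hAT", "TcMar", "PIF-Harbinger", "CMC-EnSpm", "Kolobok",
          "PiggyBac", "Zator"),
  LTR = c("Gypsy", "BEL-Pao", "ERV1", "Copia"),
  LINE = c("L1", "L2", "Rex-Babar", "RTE-X"),
  SINE = c("tRNA-V", "SINE2-1"),
  RC = c("Helitron")
)

# Replace the window [pos0, pos0 + nchar(pattern)) of s by pattern.
insert_at <- function(s, pos0, pattern) {
  str_sub(s, pos0 + 1, pos0 + str_length(pattern)) <- pattern
  s
}

# Remove chance occurrences of `patterns` from sequences[idx] by resampling
# matched windows (windows overlapping a protected planted site are left
# alone). Iterates until clean or max_iter.
excise_patterns <- function(sequences, idx, patterns, protected = NULL,
                            max_iter = 25) {
  if (length(idx) == 0 || length(patterns) == 0) return(sequences)
  patterns <- unique(patterns[str_length(patterns) > 0])
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (pat in patterns) {
      m <- scan_pattern(pat, sequences[idx])
      if (length(m$seq_idx) == 0) next
      plen <- str_length(pat)
      hit_seq <- m$seq_idx
      hit_pos0 <- m$pos0
      for (h in seq_along(hit_seq)) {
        si <- idx[hit_seq[h]]
        p0 <- hit_pos0[h]
        if (!is.null(protected)) {
          prot <- protected[protected$seq_index == si, , drop = FALSE]
          if (nrow(prot) > 0 &&
              any(p0 < prot$end0 & (p0 + plen) > prot$start0)) {
            next
          }
        }
        sequences[si] <- insert_at(
          sequences[si], p0, random_dna(plen)
        )
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sequences
}

#' Simulate gene and TE annotation with planted enrichment
#'
#' Places non-overlapping genes uniformly along the chromosomes, scatters TE
#' loci with uniform baseline density, then raises the density of DE-family
#' loci inside `n_enriched_regions` randomly chosen DE genes to
#' `enrichment_multiplier` times baseline. The DE gene and DE family sets
#' are drawn here and recorded in the truth object.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes`, `te_loci`, `chrom_sizes` (tibbles) and
#'   `truth`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    sizes <- tibble(
      chrom = paste0("chr", seq_len(cfg$n_chroms)),
      size = rep(cfg$chrom_length, cfg$n_chroms)
    )

    # TE family catalog with log-normal abundance weights.
    classes <- sample(
      names(cfg$class_weights), cfg$n_te_families,
      replace = TRUE, prob = cfg$class_weights
    )
    superfam <- map_chr(classes, function(cl) {
      pool <- superfamily_pool[[cl]] %||% "Unknown"
      sample(pool, 1)
    })
    catalog <- tibble(
      name = sprintf("%s-N%d_DR", superfam, seq_len(cfg$n_te_families)),
      superfamily = superfam,
      class = classes,
      weight = rlnorm(cfg$n_te_families, 0, 1)
    )

    # Genes: non-overlapping placement per chromosome.
    per_chrom <- tabulate(
      sample(cfg$n_chroms, cfg$n_genes, replace = TRUE, prob = sizes$size),
      nbins = cfg$n_chroms
    )
    place_chrom <- function(ci, ng) {
      if (ng == 0) return(NULL)
      size <- sizes$size[ci]
      for (try in 1:5) {
        lens <- round(runif(ng, cfg$gene_length_range[1],
                            cfg$gene_length_range[2]))
        if (sum(lens) < size) break
        if (try == 5) {
          stop_contract(paste(
            "cannot place genes without overlap;",
            "use larger chromosomes or fewer genes"
          ))
        }
      }
      free <- size - sum(lens)
      cuts <- sort(floor(runif(ng, 0, free)))
      starts <- cuts + cumsum(c(0, lens[-ng]))
      tibble(
        chrom = sizes$chrom[ci], start = starts, end = starts + lens,
        strand = sample(c("+", "-"), ng, replace = TRUE)
      )
    }
    genes <- map2(seq_len(cfg$n_chroms), per_chrom, place_chrom) %>%
      list_rbind()
    if (is.null(genes) || nrow(genes) == 0) {
      genes <- tibble(
        chrom = character(0), start = numeric(0), end = numeric(0),
        strand = character(0)
      )
    }
    genes$gene_id <- sprintf("ENSDARG%011d", seq_len(nrow(genes)))
    genes$name <- genes$gene_id

    de_genes <- sort(sample(genes$gene_id, cfg$n_de_genes))
    de_families <- sort(sample(catalog$name, cfg$n_de_families))

    # Baseline TE loci.
    loc_chrom <- sample(cfg$n_chroms, cfg$n_te_loci, replace = TRUE,
                        prob = sizes$size)
    loc_len <- round(runif(cfg$n_te_loci, cfg$te_locus_length_range[1],
                           cfg$te_locus_length_range[2]))
    loc_start <- floor(runif(cfg$n_te_loci, 0, sizes$size[loc_chrom] - loc_len))
    fam_idx <- sample(nrow(catalog), cfg$n_te_loci, replace = TRUE,
                      prob = catalog$weight)
    te_loci <- tibble(
      chrom = sizes$chrom[loc_chrom],
      start = loc_start,
      end = loc_start + loc_len,
      strand = sample(c("+", "-"), cfg$n_te_loci, replace = TRUE),
      te_gene = catalog$name[fam_idx],
      te_family = catalog$superfamily[fam_idx],
      te_class = catalog$class[fam_idx]
    )

    # Planted enrichment: extra DE-family loci inside chosen DE genes.
    enriched <- sort(sample(de_genes, cfg$n_enriched_regions))
    density <- cfg$n_te_loci / sum(sizes$size)
    de_weight_share <- sum(catalog$weight[catalog$name %in% de_families]) /
      sum(catalog$weight)
    de_cat <- catalog %>% filter(.data$name %in% de_families)
    extra_list <- map(enriched, function(gid) {
      g <- genes[genes$gene_id == gid, ]
      glen <- g$end - g$start
      n_extra <- max(
        1L,
        round((cfg$enrichment_multiplier - 1) * de_weight_share *
                density * glen)
      )
      lens <- pmin(
        round(runif(n_extra, cfg$te_locus_length_range[1],
                    cfg$te_locus_length_range[2])),
        glen - 1
      )
      starts <- floor(runif(n_extra, g$start, g$end - lens))
      fi <- sample(nrow(de_cat), n_extra, replace = TRUE,
                   prob = de_cat$weight)
      tibble(
        chrom = g$chrom, start = starts, end = starts + lens,
        strand = sample(c("+", "-"), n_extra, replace = TRUE),
        te_gene = de_cat$name[fi],
        te_family = de_cat$superfamily[fi],
        te_class = de_cat$class[fi],
        region_id = gid
      )
    })
    extra <- list_rbind(extra_list)
    if (is.null(extra) || nrow(extra) == 0) {
      extra <- tibble(
        chrom = character(0), start = numeric(0), end = numeric(0),
        strand = character(0), te_gene = character(0),
        te_family = character(0), te_class = character(0),
        region_id = character(0)
      )
    }
    planted_per_region <- extra %>%
      count(.data$region_id, name = "extra_de_loci")
    te_loci <- bind_rows(te_loci, extra %>% select(-"region_id"))
    te_loci$te_name <- paste0(te_loci$te_gene, "_dup", seq_len(nrow(te_loci)))
    te_loci <- te_loci %>%
      select(
        "chrom", "start", "end", "strand", "te_name", "te_gene",
        "te_family", "te_class"
      )

    truth <- list(
      catalog = catalog,
      genes = genes,
      chrom_sizes = sizes,
      de_genes = de_genes,
      de_families = de_families,
      enriched_regions = planted_per_region,
      de_locus_weight_share = de_weight_share
    )
    list(genes = genes, te_loci = te_loci, chrom_sizes = sizes, truth = truth)
  })
}

#' Simulate DESeq2/TEtranscripts-style DE results tables
#'
#' Adjusted p-values are generated directly (DE members strictly below 0.05,
#' the rest strictly above, a configurable fraction of non-DE genes `NA` as
#' left by independent filtering); differential-expression calling itself is
#' out of scope and only the output dialect matters.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth from [simulate_annotation()].
#' @return List with tibbles `de_genes` and `de_te_families` in the on-disk
#'   column dialect (`log2FoldChange`, `pvalue`, `padj`).
#' @export
simulate_de_tables <- function(cfg, truth) {
  with_seed(cfg$seed + 2L, {
    genes <- truth$genes
    n <- nrow(genes)
    is_de <- genes$gene_id %in% truth$de_genes
    padj <- numeric(n)
    padj[is_de] <- 0.05 * rbeta(sum(is_de), 1, 3)
    padj[!is_de] <- runif(sum(!is_de), 0.05, 1)
    pvalue <- padj * runif(n, 0.2, 1)
    na_idx <- which(!is_de)
    na_idx <- sample(na_idx, round(cfg$na_padj_fraction * length(na_idx)))
    padj[na_idx] <- NA_real_
    lfc <- numeric(n)
    lfc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
      abs(rnorm(sum(is_de), cfg$de_lfc_mean, 0.8))
    lfc[!is_de] <- rnorm(sum(!is_de), 0, 0.3)
    de_gene_tbl <- tibble(
      gene_id = genes$gene_id,
      log2FoldChange = lfc,
      pvalue = pvalue,
      padj = padj
    )

    cat <- truth$catalog
    fam_de <- cat$name %in% truth$de_families
    fpadj <- numeric(nrow(cat))
    fpadj[fam_de] <- 0.05 * rbeta(sum(fam_de), 1, 3)
    fpadj[!fam_de] <- runif(sum(!fam_de), 0.05, 1)
    flfc <- numeric(nrow(cat))
    flfc[fam_de] <- sample(c(-1, 1), sum(fam_de), replace = TRUE) *
      abs(rnorm(sum(fam_de), cfg$de_lfc_mean, 0.8))
    flfc[!fam_de] <- rnorm(sum(!fam_de), 0, 0.3)
    de_te_tbl <- tibble(
      gene_id = paste(cat$name, cat$superfamily, cat$class, sep = ":"),
      log2FoldChange = flfc,
      pvalue = fpadj * runif(nrow(cat), 0.2, 1),
      padj = fpadj
    )
    list(de_genes = de_gene_tbl, de_te_families = de_te_tbl)
  })
}

# Solve per-gene targeting probabilities (t1 for DE genes, t0 otherwise)
# such that the expected targeted count is n_targeted and the odds ratio of
# targeting between DE and non-DE genes equals `or`.
solve_target_rates <- function(n_de, n_bg, n_targeted, or) {
  if (n_targeted == 0 || n_bg == 0) return(c(t1 = 0, t0 = 0))
  n_other <- n_bg - n_de
  f <- function(t0) {
    odds1 <- or * t0 / (1 - t0)
    t1 <- odds1 / (1 + odds1)
    n_de * t1 + n_other * t0 - n_targeted
  }
  hi <- min(1 - 1e-9, n_targeted / n_other)
  t0 <- uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  odds1 <- or * t0 / (1 - t0)
  c(t1 = odds1 / (1 + odds1), t0 = t0)
}

#' Simulate TE reference, small-RNA and 3'UTR FASTA inputs
#'
#' Random background sequences with planted structure: a per-class fraction
#' of TE reference sequences receives the reverse complement of each
#' piRNA's seed at a recorded offset (chance occurrences elsewhere are
#' excised so the matched set equals the planted set); targeted genes'
#' UTRs receive canonical 7mer-m8 sites of their assigned miRNAs, with
#' gene-level targeting drawn per gene so the realised 2x2
#' targeted-by-DE-miRNA vs DE table matches `planted_or` in expectation.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth from [simulate_annotation()].
#' @return List with tibbles `te_seqs`, `pirnas`, `mirnas`, `utrs` and a
#'   `truth` list (planted sites, targeted genes, planted contingency
#'   table).
#' @export
simulate_sequences <- function(cfg, truth) {
  with_seed(cfg$seed + 3L, {
    # --- TE reference FASTA -------------------------------------------------
    cat <- truth$catalog
    fam_idx <- sample(nrow(cat), cfg$n_te_seqs, replace = TRUE,
                      prob = cat$weight)
    te_len <- round(runif(cfg$n_te_seqs, cfg$te_seq_length_range[1],
                          cfg$te_seq_length_range[2]))
    te_ids <- sprintf(
      "%s_v%d#%s/%s",
      cat$name[fam_idx], seq_len(cfg$n_te_seqs),
      cat$class[fam_idx], cat$superfamily[fam_idx]
    )
    te_seq <- random_dna(te_len)
    te_group <- te_class_group(cat$class[fam_idx])

    pirnas <- tibble(
      id = sprintf("piR-sim-%d", seq_len(cfg$n_pirnas)),
      sequence = random_dna(rep(cfg$pirna_length, cfg$n_pirnas))
    )
    seed_len <- cfg$seed_window[2] - cfg$seed_window[1] + 1
    seeds <- str_sub(pirnas$sequence, cfg$seed_window[1], cfg$seed_window[2])

    # Plant one site per (piRNA, selected TE) in disjoint per-piRNA zones so
    # later insertions never destroy earlier ones.
    zone_w <- floor((min(te_len) - seed_len) / max(1, cfg$n_pirnas))
    if (cfg$n_pirnas > 0 && zone_w < 1) {
      stop_contract("TE sequences too short for the planted sites")
    }
    te_sites <- list()
    protected <- list()
    selected <- vector("list", cfg$n_pirnas)
    for (p in seq_len(cfg$n_pirnas)) {
      frac <- if_else(te_group == "DNA", cfg$site_fraction_class1,
                      if_else(te_group == "retro",
                              cfg$site_fraction_class2, 0))
      sel <- which(runif(cfg$n_te_seqs) < frac)
      selected[[p]] <- sel
      if (length(sel) == 0) next
      zone_lo <- (p - 1) * zone_w
      offs <- zone_lo + floor(runif(length(sel), 0, zone_w))
      orient <- sample(c("sense", "antisense"), length(sel), replace = TRUE)
      pat <- if_else(orient == "sense", revcomp(seeds[p]), seeds[p])
      for (j in seq_along(sel)) {
        te_seq[sel[j]] <- insert_at(te_seq[sel[j]], offs[j], pat[j])
      }
      te_sites[[p]] <- tibble(
        srna_id = pirnas$id[p], te_id = te_ids[sel],
        offset = offs, orientation = orient
      )
      protected[[p]] <- tibble(
        seq_index = sel, start0 = offs, end0 = offs + seed_len
      )
    }
    te_sites <- list_rbind(te_sites)
    protected <- list_rbind(protected)
    if (is.null(protected) || nrow(protected) == 0) {
      protected <- tibble(seq_index = integer(0), start0 = integer(0),
                          end0 = integer(0))
    }
    # Excise chance complementarity so matched TEs == planted TEs per piRNA.
    for (p in seq_len(cfg$n_pirnas)) {
      unsel <- setdiff(seq_len(cfg$n_te_seqs), selected[[p]])
      te_seq <- excise_patterns(
        te_seq, unsel, c(seeds[p], revcomp(seeds[p])), protected = protected
      )
    }
    te_seqs <- tibble(id = te_ids, sequence = te_seq)

    # --- miRNAs and UTRs ----------------------------------------------------
    mirnas <- tibble(
      id = sprintf("dre-miR-sim-%d", seq_len(cfg$n_mirnas)),
      sequence = random_dna(rep(cfg$mirna_length, cfg$n_mirnas))
    )
    site_pats <- map_chr(mirnas$sequence,
                         function(s) mirna_site_patterns(s)[["7mer-m8"]])

    genes <- truth$genes
    n_bg <- nrow(genes)
    rates <- solve_target_rates(
      length(truth$de_genes), n_bg, cfg$n_targeted_genes, cfg$planted_or
    )
    is_de <- genes$gene_id %in% truth$de_genes
    t_prob <- if_else(is_de, rates[["t1"]], rates[["t0"]])
    targeted <- runif(n_bg) < t_prob

    # Assign miRNAs to targeted genes with skewed weights (hub miRNAs first).
    mir_w <- 1 / seq_len(cfg$n_mirnas)^1.5
    primary <- sample(cfg$n_mirnas, sum(targeted), replace = TRUE,
                      prob = mir_w)
    second <- sample(cfg$n_mirnas, sum(targeted), replace = TRUE,
                     prob = mir_w)
    has_second <- runif(sum(targeted)) < 0.2 & second != primary
    assignments <- bind_rows(
      tibble(gene_idx = which(targeted), mirna_idx = primary),
      tibble(gene_idx = which(targeted)[has_second],
             mirna_idx = second[has_second])
    ) %>% arrange(.data$gene_idx, .data$mirna_idx)

    utr_seq <- random_dna(rep(cfg$utr_length, n_bg))
    zone_w_utr <- floor((cfg$utr_length - 7) / cfg$n_mirnas)
    if (zone_w_utr < 1) {
      stop_contract("UTRs too short for the planted miRNA sites")
    }
    offs <- (assignments$mirna_idx - 1) * zone_w_utr +
      floor(runif(nrow(assignments), 0, zone_w_utr))
    for (j in seq_len(nrow(assignments))) {
      utr_seq[assignments$gene_idx[j]] <- insert_at(
        utr_seq[assignments$gene_idx[j]], offs[j],
        site_pats[assignments$mirna_idx[j]]
      )
    }
    utr_seq <- excise_patterns(utr_seq, which(!targeted), site_pats)
    utrs <- tibble(id = genes$gene_id, sequence = utr_seq)

    a <- sum(targeted & is_de)
    b <- sum(targeted & !is_de)
    c_ <- sum(!targeted & is_de)
    d <- sum(!targeted & !is_de)
    seq_truth <- list(
      te_sites = te_sites %||%
        tibble(srna_id = character(0), te_id = character(0),
               offset = integer(0), orientation = character(0)),
      targeted_genes = tibble(
        gene_id = genes$gene_id[assignments$gene_idx],
        mirna_id = mirnas$id[assignments$mirna_idx]
      ),
      contingency = c(a = a, b = b, c = c_, d = d),
      planted_or_realized = (a * d) / max(1, b * c_),
      target_rates = rates
    )
    list(
      te_seqs = te_seqs, pirnas = pirnas, mirnas = mirnas, utrs = utrs,
      truth = seq_truth
    )
  })
}

#' Run the full simulator
#'
#' Chains [simulate_annotation()], [simulate_de_tables()] and
#' [simulate_sequences()] under one seed and merges their truth records.
#'
#' @param cfg A [sim_config()] (or arguments forwarded to it).
#' @param ... Overrides forwarded to [sim_config()] when `cfg` is missing.
#' @return Object of class `srnalink_sim`: all generated tables plus
#'   `truth`.
#' @export
simulate_all <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- sim_config(...)
  ann <- simulate_annotation(cfg)
  de <- simulate_de_tables(cfg, ann$truth)
  seqs <- simulate_sequences(cfg, ann$truth)
  truth <- c(ann$truth, seqs$truth)
  structure(
    list(
      config = cfg,
      genes = ann$genes,
      te_loci = ann$te_loci,
      chrom_sizes = ann$chrom_sizes,
      de_genes = de$de_genes,
      de_te_families = de$de_te_families,
      te_seqs = seqs$te_seqs,
      pirnas = seqs$pirnas,
      mirnas = seqs$mirnas,
      utrs = seqs$utrs,
      truth = truth
    ),
    class = "srnalink_sim"
  )
}

#' @export
print.srnalink_sim <- function(x, ...) {
  cat(sprintf(
    "srnalink simulation (seed %d): %d genes (%d DE), %d TE loci, %d TE families (%d DE)\n",
    x$config$seed, nrow(x$genes), length(x$truth$de_genes),
    nrow(x$te_loci), nrow(x$truth$catalog), length(x$truth$de_families)
  ))
  cat(sprintf(
    "  %d piRNAs, %d miRNAs, %d targeted genes (planted OR %.1f)\n",
    nrow(x$pirnas), nrow(x$mirnas),
    length(unique(x$truth$targeted_genes$gene_id)), x$config$planted_or
  ))
  invisible(x)
}

#' Write a simulation to disk in the standard input formats
#'
#' Emits `genes.gtf`, `te_loci.gtf`, `chrom.sizes`, `de_genes.tsv`,
#' `de_te_families.tsv`, `te_reference.fa`, `pirnas.fa`, `mirnas.fa`,
#' `utrs.fa` and `truth.json`. Identical simulations produce byte-identical
#' files.
#'
#' @param sim A [simulate_all()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "srnalink_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genes_gtf = file.path(dir, "genes.gtf"),
    te_gtf = file.path(dir, "te_loci.gtf"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    de_genes = file.path(dir, "de_genes.tsv"),
    de_te_families = file.path(dir, "de_te_families.tsv"),
    te_fasta = file.path(dir, "te_reference.fa"),
    pirna_fasta = file.path(dir, "pirnas.fa"),
    mirna_fasta = file.path(dir, "mirnas.fa"),
    utr_fasta = file.path(dir, "utrs.fa"),
    truth = file.path(dir, "truth.json")
  )
  write_gene_gtf(sim$genes, paths["genes_gtf"])
  write_te_gtf(sim$te_loci, paths["te_gtf"])
  write_chrom_sizes(sim$chrom_sizes, paths["chrom_sizes"])
  write_table(sim$de_genes, paths["de_genes"])
  write_table(sim$de_te_families, paths["de_te_families"])
  write_fasta(sim$te_seqs, paths["te_fasta"])
  write_fasta(sim$pirnas, paths["pirna_fasta"])
  write_fasta(sim$mirnas, paths["mirna_fasta"])
  write_fasta(sim$utrs, paths["utr_fasta"])
  truth_json <- list(
    seed = sim$config$seed,
    de_genes = sim$truth$de_genes,
    de_families = sim$truth$de_families,
    enriched_regions = sim$truth$enriched_regions,
    te_sites = sim$truth$te_sites,
    targeted_genes = sim$truth$targeted_genes,
    contingency = as.list(sim$truth$contingency),
    planted_or = sim$config$planted_or
  )
  write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(paths)
}
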