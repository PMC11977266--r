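# File-level pipeline runners behind the command-line interface. Each runner
# reads standard-format inputs, executes one analysis stage, writes
# deterministic TSV outputs (with #-prefixed provenance headers) plus a run
# manifest, and never leaves partial outputs behind: tables are staged to
# temporary files and renamed on success.

runner_header <- function(command, inputs, params = list()) {
  c(
    sprintf("srnalink %s v%s", command, as.character(packageVersion("srnalink"))),
    sprintf("input %s=%s md5=%s", names(inputs),
            basename(unname(unlist(inputs))),
            unname(md5sum(unlist(inputs)))),
    if (length(params) > 0) {
      sprintf("param %s=%s", names(params),
              vapply(params, function(p) paste(format(p), collapse = ","),
                     character(1)))
    }
  )
}

write_manifest <- function(prefix, command, inputs, params, outputs,
                           seed = NULL) {
  manifest <- list(
    tool = "srnalink",
    version = as.character(packageVersion("srnalink")),
    command = command,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(md5sum(p)))
    }),
    params = params,
    seed = seed,
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(md5sum(p)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- paste0(prefix, ".manifest.json")
  write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

# Write all tables atomically: stage into tempfiles in the target directory,
# rename only after every stage succeeded.
publish_tables <- function(tables, headers) {
  staged <- character(0)
  on.exit(unlink(staged), add = TRUE)
  for (path in names(tables)) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    staged <- c(staged, tmp)
    write_table(tables[[path]], tmp, header = headers)
  }
  for (i in seq_along(tables)) {
    file.rename(staged[i], names(tables)[i])
  }
  staged <- character(0)
  invisible(names(tables))
}

save_plot <- function(plot, path, width = 9, height = 5) {
  tryCatch(
    suppressMessages(ggsave(path, plot, width = width, height = height,
                            dpi = 150)),
    error = function(e) {
      warn(sprintf("could not render %s: %s", path, conditionMessage(e)))
    }
  )
  invisible(path)
}

#' Run the piRNA-TE complementarity stage on files
#'
#' Reads piRNA and TE-reference FASTA files, runs
#' [match_pirnas_to_tes()] and writes `<prefix>.matches.tsv`,
#' `<prefix>.class_summary.tsv`, `<prefix>.class_chart.png` and a run
#' manifest.
#'
#' @param pirnas,te_db Paths to FASTA files.
#' @param out_prefix Output path prefix.
#' @param seed_start,seed_end Seed window (teleost piRNA default 1-10).
#' @param nomenclature TE class labelling (see [te_class_label()]).
#' @param plot Also render the class chart PNG.
#' @param quiet Suppress messages.
#' @return The `fishpi_result`, invisibly.
#' @export
run_fishpi <- function(pirnas, te_db, out_prefix, seed_start = 1,
                       seed_end = 10, nomenclature = "paper", plot = TRUE,
                       quiet = FALSE) {
  inputs <- list(pirnas = pirnas, te_db = te_db)
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop_usage(sprintf("input not found: %s", p))
  }
  pir <- read_fasta(pirnas)
  tes <- read_fasta(te_db)
  res <- match_pirnas_to_tes(
    pir, tes, seed_start = seed_start, seed_end = seed_end,
    nomenclature = nomenclature, quiet = quiet
  )
  params <- list(seed_start = seed_start, seed_end = seed_end,
                 nomenclature = nomenclature)
  hdr <- runner_header("fishpi", inputs, params)
  outputs <- c(
    paste0(out_prefix, ".matches.tsv"),
    paste0(out_prefix, ".class_summary.tsv")
  )
  tables <- setNames(
    list(res$matches, summarize_class_chart(res)), outputs
  )
  publish_tables(tables, hdr)
  if (plot) {
    save_plot(autoplot(res), paste0(out_prefix, ".class_chart.png"))
    outputs <- c(outputs, paste0(out_prefix, ".class_chart.png"))
  }
  write_manifest(out_prefix, "fishpi", inputs, params, as.list(outputs))
  invisible(res)
}

fishtea_paths <- function(out_prefix) {
  c(
    te_loci = paste0(out_prefix, ".te_loci.tsv"),
    overlaps = paste0(out_prefix, ".overlaps.tsv"),
    overlap_summary = paste0(out_prefix, ".overlap_summary.tsv"),
    enrichment = paste0(out_prefix, ".enrichment.tsv"),
    chrom_layout = paste0(out_prefix, ".chrom_layout.tsv"),
    chrom_plot = paste0(out_prefix, ".chrom_plot.png"),
    family_counts = paste0(out_prefix, ".family_counts.tsv"),
    class_counts = paste0(out_prefix, ".class_counts.tsv")
  )
}

require_step_output <- function(path, step) {
  if (!file.exists(path)) {
    stop_usage(sprintf(
      "missing %s (produced by step %d); run that step first", path, step
    ))
  }
  path
}

#' Run the gene/TE overlap-and-enrichment pipeline on files
#'
#' The five stages can run as one call (`step = NULL`) or individually
#' (`step = 1..5`), each step reading the previous step's TSV so a chained
#' per-step run reproduces the full run byte for byte. Stages: 1 attach TE
#' locus coordinates to family-level DE calls; 2 overlap DE genes with DE TE
#' loci; 3 hypergeometric enrichment per genic region; 4 chromosomal layout
#' and plot; 5 family/class counts.
#'
#' @param genes DE gene results table (TSV).
#' @param gene_gtf Gene annotation GTF supplying coordinates.
#' @param te_families Family-level TE DE table (TSV).
#' @param te_gtf TE locus annotation GTF (rmsk dialect).
#' @param chrom_sizes Two-column chrom.sizes file.
#' @param out_prefix Output path prefix.
#' @param alpha,flank,correction,nomenclature See
#'   [genic_region_enrichment()] and [te_class_label()].
#' @param step `NULL` for the full pipeline, or a single step 1-5.
#' @param plot Render the chromosomal plot in step 4.
#' @param quiet Suppress messages.
#' @return Invisibly, the written file paths.
#' @export
run_fishtea <- function(genes, gene_gtf, te_families, te_gtf, chrom_sizes,
                        out_prefix, alpha = 0.05, flank = 0,
                        correction = "none", nomenclature = "paper",
                        step = NULL, plot = TRUE, quiet = FALSE) {
  inputs <- list(
    genes = genes, gene_gtf = gene_gtf, te_families = te_families,
    te_gtf = te_gtf, chrom_sizes = chrom_sizes
  )
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop_usage(sprintf("input not found: %s", p))
  }
  if (!is.null(step) && (!is_count(step) || !step %in% 1:5)) {
    stop_usage("step must be NULL or one of 1..5")
  }
  paths <- fishtea_paths(out_prefix)
  params <- list(alpha = alpha, flank = flank, correction = correction,
                 nomenclature = nomenclature)
  hdr <- runner_header("fishtea", inputs, params)
  steps <- if (is.null(step)) 1:5 else step

  log_step <- function(i, what) {
    if (!quiet) inform(sprintf("FishTEA step %d: %s", i, what))
  }
  read_loci_tsv <- function() {
    read_tsv(require_step_output(paths[["te_loci"]], 1), comment = "#",
             show_col_types = FALSE, progress = FALSE)
  }
  de_genes_with_coords <- function() {
    de <- read_de_table(genes, alpha = alpha, quiet = TRUE)
    attach_gene_coords(de, read_gene_gtf(gene_gtf), quiet = quiet)
  }

  written <- character(0)
  for (s in steps) {
    if (s == 1) {
      log_step(1, "addition of TE loci co-ordinates")
      ann <- read_te_gtf(te_gtf)
      fam <- read_de_table(te_families, alpha = alpha, type = "te_family",
                           quiet = TRUE)
      loci <- expand_families_to_loci(ann, fam, alpha = alpha, quiet = quiet)
      publish_tables(setNames(list(loci), paths[["te_loci"]]), hdr)
      written <- c(written, paths[["te_loci"]])
    } else if (s == 2) {
      log_step(2, "matching overlapping genes and TEs")
      loci <- read_loci_tsv()
      ov <- overlap_de_genes_tes(de_genes_with_coords(), loci)
      publish_tables(
        setNames(
          list(ov$overlaps, ov$summary),
          paths[c("overlaps", "overlap_summary")]
        ),
        hdr
      )
      written <- c(written, paths[c("overlaps", "overlap_summary")])
    } else if (s == 3) {
      log_step(3, "hypergeometric testing of genic regions")
      loci <- read_loci_tsv()
      enr <- genic_region_enrichment(
        de_genes_with_coords(), loci, alpha = alpha, flank = flank,
        correction = correction, chrom_sizes = read_chrom_sizes(chrom_sizes),
        quiet = quiet
      )
      publish_tables(
        setNames(list(as_tibble(enr)), paths[["enrichment"]]), hdr
      )
      written <- c(written, paths[["enrichment"]])
    } else if (s == 4) {
      log_step(4, "generation of a chromosomal plot")
      loci <- read_loci_tsv()
      enr <- read_tsv(require_step_output(paths[["enrichment"]], 3),
                      comment = "#", show_col_types = FALSE, progress = FALSE)
      sizes <- read_chrom_sizes(chrom_sizes)
      layout <- chromosomal_layout(
        de_genes_with_coords(), loci, sizes, enrichment = enr,
        nomenclature = nomenclature
      )
      publish_tables(setNames(list(layout), paths[["chrom_layout"]]), hdr)
      written <- c(written, paths[["chrom_layout"]])
      if (plot) {
        save_plot(plot_chromosomal_layout(layout, sizes),
                  paths[["chrom_plot"]], width = 11, height = 4)
        written <- c(written, paths[["chrom_plot"]])
      }
    } else if (s == 5) {
      log_step(5, "bar charts at TE family / class level")
      ov <- read_tsv(require_step_output(paths[["overlaps"]], 2),
                     comment = "#", show_col_types = FALSE, progress = FALSE)
      counts <- family_class_counts(ov, nomenclature = nomenclature)
      publish_tables(
        setNames(
          list(counts$by_family, counts$by_class),
          paths[c("family_counts", "class_counts")]
        ),
        hdr
      )
      written <- c(written, paths[c("family_counts", "class_counts")])
    }
  }
  write_manifest(out_prefix, "fishtea", inputs, c(params, list(step = step)),
                 as.list(unname(written)))
  invisible(written)
}

#' Run the miRNA-target / DE-gene linking stage on files
#'
#' Reads mature miRNA and 3'UTR FASTA files plus a DE gene table, runs
#' [find_targets()] and [link_targets_to_de()], and writes
#' `<prefix>.hits.tsv`, `<prefix>.link_stats.tsv`,
#' `<prefix>.per_mirna_hits.tsv` and a manifest. An empty DE table is not an
#' error: the contingency table then has `a = c = 0` and a warning is
#' emitted.
#'
#' @param mirnas,utrs Paths to FASTA files.
#' @param de_genes Path to the DE gene table.
#' @param background `"auto"` (genes of the DE table with a non-missing raw
#'   p-value) or a path to a one-id-per-line background file.
#' @param site_rule Seed-site class, see [find_targets()].
#' @param alpha Significance cut-off for the DE flag.
#' @param out_prefix Output path prefix.
#' @param quiet Suppress messages.
#' @return The `mirna_link` result, invisibly.
#' @export
run_mirlink <- function(mirnas, utrs, de_genes, out_prefix,
                        background = "auto", site_rule = "7mer-m8",
                        alpha = 0.05, quiet = FALSE) {
  inputs <- list(mirnas = mirnas, utrs = utrs, de_genes = de_genes)
  if (!identical(background, "auto")) {
    inputs$background <- background
  }
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop_usage(sprintf("input not found: %s", p))
  }
  mir <- read_fasta(mirnas)
  utr <- read_fasta(utrs)
  de <- read_de_table(de_genes, alpha = alpha, quiet = TRUE)
  bg <- if (identical(background, "auto")) {
    NULL
  } else {
    readLines(background, warn = FALSE)
  }
  if (is.null(bg) && !any(!is.na(de$pvalue))) {
    warn(paste(
      "DE table provides no background genes with a p-value;",
      "falling back to the UTR gene universe"
    ))
    bg <- unique(utr$id)
  }
  hits <- find_targets(mir, utr, site_rule = site_rule)
  link <- link_targets_to_de(hits, de, background = bg, quiet = quiet)
  params <- list(background = if (is.null(bg)) "auto" else background,
                 site_rule = site_rule, alpha = alpha)
  hdr <- runner_header("mirlink", inputs, params)
  outputs <- c(
    paste0(out_prefix, ".hits.tsv"),
    paste0(out_prefix, ".link_stats.tsv"),
    paste0(out_prefix, ".per_mirna_hits.tsv")
  )
  publish_tables(
    setNames(list(hits, glance(link), tidy(link)), outputs), hdr
  )
  write_manifest(out_prefix, "mirlink", inputs, params, as.list(outputs))
  invisible(link)
}

#' Generate a simulated input set on disk
#'
#' Thin file-level wrapper over [simulate_all()] / [write_simulation()].
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return The simulation object, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1234, ...) {
  sim <- simulate_all(sim_config(seed = seed, ...))
  paths <- write_simulation(sim, out_dir)
  write_manifest(
    file.path(out_dir, "simulation"), "simulate", list(),
    c(list(seed = seed), list(...)), as.list(unname(paths)), seed = seed
  )
  invisible(sim)
}
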