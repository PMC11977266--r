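# File-level runners: outputs, manifests, determinism, step resumability and
# the command-line entry point.

local_sim_files <- function(seed = 401, env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  sim <- simulate_all(tiny_cfg(seed = seed))
  paths <- write_simulation(sim, d)
  list(sim = sim, paths = paths, dir = d)
}

test_that("run_fishpi writes matches, summary and a manifest", {
  sf <- local_sim_files(402)
  out <- file.path(withr::local_tempdir(), "fp")
  res <- run_fishpi(sf$paths[["pirna_fasta"]], sf$paths[["te_fasta"]], out,
                    plot = FALSE, quiet = TRUE)
  expect_true(file.exists(paste0(out, ".matches.tsv")))
  expect_true(file.exists(paste0(out, ".class_summary.tsv")))
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_identical(manifest$command, "fishpi")
  expect_identical(length(manifest$inputs), 2L)
  # provenance headers are #-prefixed and carry input checksums
  hdr <- readLines(paste0(out, ".matches.tsv"), n = 3)
  expect_true(all(grepl("^#", hdr)))
  expect_match(hdr[2], "md5=")
  expect_error(run_fishpi("/nonexistent.fa", sf$paths[["te_fasta"]], out),
               class = "srnalink_usage_error")
})

test_that("runner reruns on identical inputs give identical TSV checksums", {
  sf <- local_sim_files(403)
  out1 <- file.path(withr::local_tempdir(), "a")
  out2 <- file.path(withr::local_tempdir(), "b")
  run_fishpi(sf$paths[["pirna_fasta"]], sf$paths[["te_fasta"]], out1,
             plot = FALSE, quiet = TRUE)
  run_fishpi(sf$paths[["pirna_fasta"]], sf$paths[["te_fasta"]], out2,
             plot = FALSE, quiet = TRUE)
  for (suffix in c(".matches.tsv", ".class_summary.tsv")) {
    expect_identical(
      unname(tools::md5sum(paste0(out1, suffix))),
      unname(tools::md5sum(paste0(out2, suffix)))
    )
  }
})

test_that("fishtea full run equals chained per-step runs byte for byte", {
  sf <- local_sim_files(404)
  full <- file.path(withr::local_tempdir(), "full")
  stepd <- file.path(withr::local_tempdir(), "step")
  args <- list(
    genes = sf$paths[["de_genes"]], gene_gtf = sf$paths[["genes_gtf"]],
    te_families = sf$paths[["de_te_families"]],
    te_gtf = sf$paths[["te_gtf"]], chrom_sizes = sf$paths[["chrom_sizes"]],
    plot = FALSE, quiet = TRUE
  )
  do.call(run_fishtea, c(args, list(out_prefix = full)))
  for (s in 1:5) {
    do.call(run_fishtea, c(args, list(out_prefix = stepd, step = s)))
  }
  for (suffix in c(".te_loci.tsv", ".overlaps.tsv", ".overlap_summary.tsv",
                   ".enrichment.tsv", ".chrom_layout.tsv",
                   ".family_counts.tsv", ".class_counts.tsv")) {
    expect_identical(
      unname(tools::md5sum(paste0(full, suffix))),
      unname(tools::md5sum(paste0(stepd, suffix))),
      info = suffix
    )
  }
})

test_that("fishtea steps fail usefully when the previous step is missing", {
  sf <- local_sim_files(405)
  out <- file.path(withr::local_tempdir(), "x")
  expect_error(
    run_fishtea(
      sf$paths[["de_genes"]], sf$paths[["genes_gtf"]],
      sf$paths[["de_te_families"]], sf$paths[["te_gtf"]],
      sf$paths[["chrom_sizes"]], out, step = 3, quiet = TRUE
    ),
    regexp = "te_loci", class = "srnalink_usage_error"
  )
})

test_that("run_mirlink writes hits and link statistics", {
  sf <- local_sim_files(406)
  out <- file.path(withr::local_tempdir(), "ml")
  link <- run_mirlink(
    sf$paths[["mirna_fasta"]], sf$paths[["utr_fasta"]],
    sf$paths[["de_genes"]], out, quiet = TRUE
  )
  stats <- readr::read_tsv(paste0(out, ".link_stats.tsv"), comment = "#",
                           show_col_types = FALSE)
  expect_equal(stats$a, as.numeric(link$table$a))
  expect_equal(stats$targeted_de_genes, as.numeric(link$targeted_de_genes))
  hits <- readr::read_tsv(paste0(out, ".hits.tsv"), comment = "#",
                          show_col_types = FALSE)
  expect_true(all(c("mirna_id", "gene_id", "site_position") %in% names(hits)))

  # an empty DE table is handled, not fatal
  empty_de <- file.path(sf$dir, "empty_de.tsv")
  writeLines("gene_id\tlog2FoldChange\tpvalue\tpadj", empty_de)
  expect_warning(
    expect_warning(
      link0 <- run_mirlink(
        sf$paths[["mirna_fasta"]], sf$paths[["utr_fasta"]], empty_de,
        file.path(withr::local_tempdir(), "ml0")
      ),
      regexp = "falling back to the UTR gene universe"
    ),
    regexp = "a = c = 0"
  )
  expect_identical(link0$table$a, 0L)
  expect_identical(link0$table$c, 0L)
})

test_that("the CLI dispatches, reports usage errors and stays deterministic", {
  cli <- system.file("cli", "srnalink", package = "srnalink")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    suppressWarnings(system2(
      rscript, c(cli, ...),
      stdout = TRUE, stderr = TRUE,
      env = paste0("R_LIBS=", libs)
    ))
  }
  out <- run_cli("stats", "hyper", "--k", "3", "--n", "4", "--K", "5",
                 "--N", "10")
  expect_identical(attr(out, "status"), NULL)  # exit 0
  expect_match(paste(out, collapse = "\n"), "0.2619", fixed = TRUE)

  bad <- run_cli("fishpi", "--pirnas", "missing.fa")
  expect_identical(attr(bad, "status"), 2L)

  fish <- run_cli("stats", "fisher", "--a", "15", "--b", "15", "--c", "5",
                  "--d", "65")
  expect_match(paste(fish, collapse = "\n"), "odds_ratio\t13")
})

test_that("plot builders return ggplot objects", {
  sf <- local_sim_files(407)
  fp <- run_fishpi(sf$paths[["pirna_fasta"]], sf$paths[["te_fasta"]],
                   file.path(withr::local_tempdir(), "fp"),
                   plot = FALSE, quiet = TRUE)
  expect_s3_class(ggplot2::autoplot(fp), "ggplot")
  loci <- expand_families_to_loci(
    read_te_gtf(sf$paths[["te_gtf"]]),
    read_de_table(sf$paths[["de_te_families"]], type = "te_family",
                  quiet = TRUE),
    quiet = TRUE
  )
  genes <- attach_gene_coords(
    read_de_table(sf$paths[["de_genes"]], quiet = TRUE),
    read_gene_gtf(sf$paths[["genes_gtf"]]), quiet = TRUE
  )
  sizes <- read_chrom_sizes(sf$paths[["chrom_sizes"]])
  lay <- chromosomal_layout(genes, loci, sizes)
  expect_s3_class(plot_chromosomal_layout(lay, sizes), "ggplot")
})
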