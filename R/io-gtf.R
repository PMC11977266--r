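# GTF input (Ensembl gene and RepeatMasker/TEtranscripts TE dialects) and the
# simple writers the simulator uses. GTF is 1-based inclusive on disk and
# converted to the internal 0-based half-open convention on read.

#' Read a TE locus annotation GTF (TEtranscripts rmsk dialect)
#'
#' Expects per-locus records carrying the attributes `gene_id` (TE name),
#' `transcript_id` (locus identifier), `family_id` and `class_id`. Attribute
#' order within a record is irrelevant. A missing required attribute raises a
#' parse error naming the feature index.
#'
#' @param path Path to the GTF.
#' @return Tibble of TE loci: `chrom`, `start` (0-based), `end`, `strand`,
#'   `te_name` (locus id), `te_gene` (TE name, the family-level DE key),
#'   `te_family`, `te_class`.
#' @export
read_te_gtf <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("TE GTF not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- as.data.frame(mcols(gr))
  required <- c("gene_id", "transcript_id", "family_id", "class_id")
  for (attr in required) {
    if (!attr %in% names(mc)) {
      stop_parse(sprintf("TE GTF %s lacks attribute '%s'", path, attr))
    }
    bad <- which(is.na(mc[[attr]]))
    if (length(bad) > 0) {
      stop_parse(sprintf(
        "TE GTF %s: feature %d is missing attribute '%s'", path, bad[1], attr
      ))
    }
  }
  strand <- as.character(BiocGenerics::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = ifelse(strand == "*", ".", strand),
    te_name = as.character(mc$transcript_id),
    te_gene = as.character(mc$gene_id),
    te_family = as.character(mc$family_id),
    te_class = as.character(mc$class_id)
  )
}

#' Read gene records from an Ensembl-style GTF
#'
#' Keeps features of type `gene` when a type column is present (otherwise
#' all records) and requires the `gene_id` attribute.
#'
#' @param path Path to the GTF.
#' @return Tibble: `gene_id`, `chrom`, `start` (0-based), `end`, `strand`.
#' @export
read_gene_gtf <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("gene GTF not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- as.data.frame(mcols(gr))
  if ("type" %in% names(mc) && any(mc$type == "gene")) {
    keep <- mc$type == "gene"
    gr <- gr[keep]
    mc <- mc[keep, , drop = FALSE]
  }
  if (!"gene_id" %in% names(mc) || anyNA(mc$gene_id)) {
    stop_parse(sprintf("gene GTF %s lacks gene_id attributes", path))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  tibble(
    gene_id = as.character(mc$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = ifelse(strand == "*", ".", strand)
  )
}

# Internal writers used by the simulator: coordinates go from 0-based
# half-open back to 1-based inclusive GTF.

write_gene_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tsrnalink_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"protein_coding\";",
    genes$chrom, as.integer(genes$start + 1), as.integer(genes$end),
    genes$strand, genes$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

write_te_gtf <- function(loci, path) {
  lines <- sprintf(
    paste0(
      "%s\tsrnalink_sim\texon\t%d\t%d\t.\t%s\t.\t",
      "gene_id \"%s\"; transcript_id \"%s\"; family_id \"%s\"; class_id \"%s\";"
    ),
    loci$chrom, as.integer(loci$start + 1), as.integer(loci$end),
    loci$strand, loci$te_gene, loci$te_name, loci$te_family, loci$te_class
  )
  writeLines(lines, path)
  invisible(path)
}

write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", sizes$chrom, as.integer(sizes$size)), path)
  invisible(path)
}
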