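# Differential-expression results tables (DESeq2 / TEtranscripts dialects),
# chrom.sizes, and a deterministic TSV writer.

#' Parse composite TE names into name/family/class
#'
#' Handles the TEtranscripts composite `name:family:class` (e.g.
#' `hAT-N1_DR:hAT:DNA`) and the RepeatMasker FASTA-header convention
#' `name#class/family` (e.g. `Gypsy12_DR#LTR/Gypsy`). A bare name falls back
#' to `family = name`, `class = "Unknown"`.
#'
#' @param x Character vector of TE identifiers.
#' @return Tibble with columns `name`, `family`, `class`.
#' @export
parse_te_names <- function(x) {
  x <- as.character(x)
  parts <- str_split(x, ":")
  hash <- str_match(x, "^([^#]+)#([^/]+)(?:/(.+))?$")
  pmap(list(x, parts, seq_along(x)), function(full, p, i) {
    if (!is.na(hash[i, 1])) {
      tibble(
        name = hash[i, 2],
        family = hash[i, 4] %|na|% hash[i, 2],
        class = hash[i, 3]
      )
    } else if (length(p) == 3) {
      tibble(name = p[1], family = p[2], class = p[3])
    } else {
      tibble(name = full, family = full, class = "Unknown")
    }
  }) %>% list_rbind()
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' Read a differential-expression results table
#'
#' Accepts the DESeq2 results dialect: a TSV (or CSV) with a header naming at
#' least an identifier column (`gene_id`, `id`, `gene`, `name`, or the first
#' column), `log2FoldChange` and `padj`; `pvalue` is optional and `NA` is
#' accepted anywhere. Every row is returned; a row is flagged significant iff
#' `padj < alpha` strictly — missing `padj` is never significant and there is
#' no fallback to the raw p-value.
#'
#' With `type = "te_family"` the identifier is the TEtranscripts composite
#' `name:family:class` and is parsed into taxonomy columns.
#'
#' @param path Path to the table (TSV; `,`-separated files are detected).
#' @param alpha Significance cut-off applied to `padj` (strict `<`).
#' @param type `"gene"` or `"te_family"`.
#' @param quiet Suppress the significant-row count message.
#' @return Tibble with columns `gene_id` (or `name`, `te_family`, `te_class`
#'   for TE families), `log2_fold_change`, `pvalue`, `padj`, `significant`.
#' @export
read_de_table <- function(path, alpha = 0.05, type = c("gene", "te_family"),
                          quiet = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_usage(sprintf("DE table not found: %s", path))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop_contract("alpha must be a single probability")
  }
  first <- readLines(path, n = 20)
  first <- first[!str_starts(first, "#")][1]
  delim <- if (str_detect(first, "\t")) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, na = c("NA", ""), comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  id_col <- intersect(c("gene_id", "id", "gene", "name", "te_id"), names(df))[1]
  if (is.na(id_col)) id_col <- names(df)[1]
  required <- c("log2FoldChange", "padj")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_parse(sprintf(
      "DE table %s lacks column(s) %s; found: %s",
      path, paste(missing_cols, collapse = ", "),
      paste(names(df), collapse = ", ")
    ))
  }
  out <- tibble(
    gene_id = as.character(df[[id_col]]),
    log2_fold_change = as.numeric(df$log2FoldChange),
    pvalue = if ("pvalue" %in% names(df)) as.numeric(df$pvalue) else NA_real_,
    padj = as.numeric(df$padj)
  )
  if (any(out$padj < 0 | out$padj > 1, na.rm = TRUE)) {
    stop_parse(sprintf("padj outside [0, 1] in %s", path))
  }
  out$significant <- !is.na(out$padj) & out$padj < alpha
  if (type == "te_family") {
    tax <- parse_te_names(out$gene_id)
    out <- bind_cols(
      tibble(name = tax$name, te_family = tax$family, te_class = tax$class),
      out[, setdiff(names(out), "gene_id")]
    )
  }
  if (!quiet) {
    inform(sprintf(
      "%s: %d of %d rows significant at padj < %g",
      basename(path), sum(out$significant), nrow(out), alpha
    ))
  }
  out
}

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file with columns chromosome name and length.
#' @return Tibble with columns `chrom`, `size`, in natural chromosome order.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("chrom.sizes not found: %s", path))
  df <- readr::read_tsv(
    path, col_names = c("chrom", "size"),
    col_types = cols(chrom = col_character(), size = col_double()),
    comment = "#", progress = FALSE
  )
  if (nrow(df) == 0 || any(is.na(df$size)) || any(df$size <= 0)) {
    stop_parse(sprintf("invalid chrom.sizes file: %s", path))
  }
  df %>% arrange(match(.data$chrom, natural_chrom_order(.data$chrom)))
}

#' Write a tibble as a deterministic TSV
#'
#' Columns are written in their current order, missing values as `NA`, full
#' floating-point precision so a re-read reproduces the values exactly.
#' Optional `#`-prefixed provenance header lines are written first.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param header Character vector of provenance lines (written prefixed with
#'   `# `), or `NULL`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header) && length(header) > 0) {
    writeLines(paste0("# ", header), con)
  }
  readr::write_tsv(x, con, na = "NA", progress = FALSE)
  invisible(path)
}

#' Attach gene coordinates from an annotation to a DE table
#'
#' DESeq2 output carries identifiers only; this explicit join step attaches
#' intervals from a gene annotation (see [read_gene_gtf()]). Identifiers
#' absent from the annotation are dropped with a message.
#'
#' @param de DE gene table (see [read_de_table()]).
#' @param annotation Gene annotation with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param quiet Suppress the dropped-identifier message.
#' @return `de` with interval columns attached, restricted to annotated genes.
#' @export
attach_gene_coords <- function(de, annotation, quiet = FALSE) {
  if (!"gene_id" %in% names(de)) stop_contract("DE table lacks 'gene_id'")
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(annotation))) {
    stop_contract("annotation needs gene_id, chrom, start, end")
  }
  ann <- annotation %>%
    select(any_of(c("gene_id", "chrom", "start", "end", "strand"))) %>%
    distinct(.data$gene_id, .keep_all = TRUE)
  out <- inner_join(de, ann, by = "gene_id")
  dropped <- nrow(de) - nrow(out)
  if (dropped > 0 && !quiet) {
    inform(sprintf(
      "attach_gene_coords: dropped %d DE record(s) absent from the annotation",
      dropped
    ))
  }
  if (!"strand" %in% names(out)) out$strand <- "."
  out$name <- out$gene_id
  out
}
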