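# FASTA reading/writing. The reader is deliberately strict: it names the
# offending line on malformed input, accepts RNA (U folded to T), upper-cases
# everything and rejects characters outside the IUPAC nucleotide alphabet.

#' Read a FASTA file of nucleotide sequences
#'
#' One record per `>` header; multi-line sequences are joined; sequences are
#' upper-cased and `U` is normalised to `T` so downstream matching runs over
#' a single DNA alphabet. Characters outside the IUPAC nucleotide codes
#' (ACGTN plus ambiguity letters) raise a parse error naming the line.
#'
#' @param path Path to a FASTA file (plain text).
#' @return Tibble with columns `id` (header up to first whitespace),
#'   `description` (remainder of the header, possibly empty) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- str_trim(lines, side = "right")
  keep <- lines != ""
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop_parse(sprintf("empty FASTA file: %s", path))
  is_hdr <- str_starts(lines, ">")
  if (!is_hdr[1]) {
    stop_parse(sprintf(
      "sequence before first header at line %d of %s", line_no[1], path
    ))
  }
  bad <- which(!is_hdr &
                 str_detect(str_to_upper(lines), "[^ACGTUNRYSWKMBDHV]"))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "illegal sequence character at line %d of %s", line_no[bad[1]], path
    ))
  }
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(
    split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(headers))),
    paste0, character(1), collapse = ""
  )
  empty_rec <- which(is.na(seqs) | seqs == "")
  if (length(empty_rec) > 0) {
    stop_parse(sprintf(
      "record '%s' has an empty sequence in %s",
      headers[empty_rec[1]], path
    ))
  }
  m <- str_match(headers, "^(\\S+)\\s*(.*)$")
  tibble(
    id = m[, 2],
    description = m[, 3],
    sequence = normalize_seq(unname(seqs))
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `sequence` (optional
#'   `description` appended to headers after a space).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (!all(c("id", "sequence") %in% names(seqs))) {
    stop_contract("write_fasta needs columns 'id' and 'sequence'")
  }
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- ifelse(is.na(desc) | desc == "", "", paste0(" ", desc))
  headers <- paste0(">", seqs$id, desc)
  chunks <- map2(seqs$sequence, headers, function(s, h) {
    starts <- seq(1, max(1, nchar(s)), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(as.character(unlist(chunks)), path)
  invisible(path)
}
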