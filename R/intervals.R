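# Genomic intervals: 0-based half-open internal convention and the pairwise
# overlap engine. GTF is converted from 1-based inclusive on read (io-gtf.R)
# so every coordinate seen here is already half-open.

#' Validate and normalise a table of genomic intervals
#'
#' Internal coordinates are 0-based half-open: `start` is the first base,
#' `end` is one past the last. Requires columns `chrom`, `start`, `end`;
#' `strand` (one of `+`, `-`, `.`) defaults to `.` and `name` defaults to a
#' row index.
#'
#' @param x Data frame with at least `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`
#'   (any further columns carried through).
#' @export
as_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop_contract(sprintf("%s must be a data frame", what))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop_contract(sprintf(
      "%s lacks required column(s): %s", what,
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  if (!"strand" %in% names(x)) x$strand <- "."
  if (!"name" %in% names(x)) x$name <- paste0(what, "_", seq_len(nrow(x)))
  x$chrom <- as.character(x$chrom)
  x$strand <- as.character(x$strand)
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom)) || any(x$chrom == "")) {
      stop_contract(sprintf("%s: chromosome names must be non-empty", what))
    }
    if (any(is.na(x$start)) || any(is.na(x$end)) ||
        any(x$start < 0) || any(x$start >= x$end)) {
      stop_contract(sprintf(
        "%s: require 0 <= start < end (0-based half-open)", what
      ))
    }
    if (!all(x$strand %in% c("+", "-", "."))) {
      stop_contract(sprintf("%s: strand must be one of +, -, .", what))
    }
  }
  x
}

#' Overlap length of two interval sets, elementwise
#'
#' Vectorised over rows (recycled): 0 when chromosomes differ, otherwise
#' `max(0, min(ends) - max(starts))`. Half-open adjacency does not overlap.
#'
#' @param a,b Interval tables (see [as_intervals()]); recycled rowwise.
#' @return Integer vector of overlap widths in bp.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 5, end = 15)
#' b <- data.frame(chrom = "chr1", start = 10, end = 20)
#' overlap_length(a, b)  # 5
#' @export
overlap_length <- function(a, b) {
  a <- as_intervals(a, "a")
  b <- as_intervals(b, "b")
  len <- max(nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(integer(0))
  ia <- rep_len(seq_len(nrow(a)), len)
  ib <- rep_len(seq_len(nrow(b)), len)
  w <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  as.integer(ifelse(a$chrom[ia] == b$chrom[ib], pmax(0, w), 0L))
}

#' Find all overlapping query/subject interval pairs
#'
#' Reports every (query, subject) pair sharing at least `min_bp` overlapping
#' bases, each pair once, in deterministic order (chromosome in natural
#' order, then query start, then subject start). Strand is carried through
#' but does not restrict overlap unless `same_strand = TRUE` (strand `.`
#' then matches either).
#'
#' The matching is delegated to [GenomicRanges::findOverlaps()]; results are
#' contract-checked against a brute-force all-pairs scan in the test suite.
#'
#' @param queries,subjects Interval tables (see [as_intervals()]).
#' @param min_bp Minimum overlap width in bp (>= 1).
#' @param same_strand Require compatible strands.
#' @return Tibble with columns `query_name`, `subject_name`, `chrom`,
#'   `overlap_bp`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `query_strand`, `subject_strand`.
#' @export
find_overlaps <- function(queries, subjects, min_bp = 1, same_strand = FALSE) {
  queries <- as_intervals(queries, "queries")
  subjects <- as_intervals(subjects, "subjects")
  if (!is_count(min_bp) || length(min_bp) != 1 || min_bp < 1) {
    stop_contract("min_bp must be a single integer >= 1")
  }
  empty <- tibble(
    query_name = character(0), subject_name = character(0),
    chrom = character(0), overlap_bp = integer(0),
    query_start = numeric(0), query_end = numeric(0),
    subject_start = numeric(0), subject_end = numeric(0),
    query_strand = character(0), subject_strand = character(0)
  )
  if (nrow(queries) == 0 || nrow(subjects) == 0) return(empty)

  chroms <- union(queries$chrom, subjects$chrom)
  gq <- GRanges(
    factor(queries$chrom, levels = chroms),
    IRanges(queries$start + 1, queries$end)
  )
  gs <- GRanges(
    factor(subjects$chrom, levels = chroms),
    IRanges(subjects$start + 1, subjects$end)
  )
  hits <- findOverlaps(gq, gs, minoverlap = min_bp, ignore.strand = TRUE)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  if (same_strand) {
    keep <- queries$strand[qi] == "." | subjects$strand[si] == "." |
      queries$strand[qi] == subjects$strand[si]
    qi <- qi[keep]
    si <- si[keep]
  }
  if (length(qi) == 0) return(empty)
  out <- tibble(
    query_name = queries$name[qi],
    subject_name = subjects$name[si],
    chrom = queries$chrom[qi],
    overlap_bp = as.integer(
      pmin(queries$end[qi], subjects$end[si]) -
        pmax(queries$start[qi], subjects$start[si])
    ),
    query_start = queries$start[qi],
    query_end = queries$end[qi],
    subject_start = subjects$start[si],
    subject_end = subjects$end[si],
    query_strand = queries$strand[qi],
    subject_strand = subjects$strand[si]
  )
  out %>%
    arrange(
      match(.data$chrom, natural_chrom_order(.data$chrom)),
      .data$query_start, .data$subject_start,
      .data$query_name, .data$subject_name
    )
}
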