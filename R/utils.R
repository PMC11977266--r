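# Shared internal helpers: error classes, sequence utilities, chromosome order.

stop_contract <- function(msg, ...) {
  abort(msg, class = c("srnalink_contract_error", "srnalink_error"), ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("srnalink_parse_error", "srnalink_error"), ...)
}

stop_usage <- function(msg, ...) {
  abort(msg, class = c("srnalink_usage_error", "srnalink_error"), ...)
}

# Reverse complement of plain character vectors (DNA alphabet).
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# Uppercase and fold RNA to DNA alphabet.
normalize_seq <- function(x) {
  str_replace_all(str_to_upper(x), "U", "T")
}

iupac_letters <- c(
  "A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"
)

# Chromosome names in natural order: chr1, chr2, ..., chr10, then the rest
# lexicographically. Deterministic for any input.
natural_chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(str_match(u, "^(?:chr)?([0-9]+)$")[, 2]))
  num[is.na(num)] <- Inf
  u[order(num, u)]
}

is_count <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
}

# Random DNA sequences of the given lengths, as a character vector.
random_dna <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  alphabet <- c("A", "C", "G", "T")
  if (length(unique(lengths)) == 1) {
    # equal lengths: column-wise paste0 is much faster than split/vapply
    n <- length(lengths)
    L <- lengths[1]
    cols <- lapply(seq_len(L), function(i) sample(alphabet, n, replace = TRUE))
    return(do.call(paste0, cols))
  }
  total <- sum(lengths)
  letters <- sample(alphabet, total, replace = TRUE)
  idx <- factor(rep.int(seq_along(lengths), lengths), levels = seq_along(lengths))
  out <- vapply(split(letters, idx), paste0, character(1), collapse = "")
  unname(out)
}

# All 0-based occurrence offsets of an exact pattern in each of `seqs`.
# The sequences are concatenated with N-runs (which never match an A/C/G/T
# pattern) and scanned once: Biostrings::vmatchPattern carries a large
# per-sequence overhead on many short sequences.
scan_pattern <- function(pattern, seqs) {
  if (length(seqs) == 0) {
    return(list(seq_idx = integer(0), pos0 = integer(0)))
  }
  plen <- nchar(pattern)
  sep <- strrep("N", plen)
  w <- nchar(seqs)
  off <- cumsum(c(1, w[-length(w)] + plen))  # 1-based start of each seq
  big <- DNAString(paste(seqs, collapse = sep))
  gstart <- BiocGenerics::start(matchPattern(pattern, big))
  if (length(gstart) == 0) {
    return(list(seq_idx = integer(0), pos0 = integer(0)))
  }
  seq_idx <- findInterval(gstart, off)
  list(seq_idx = seq_idx, pos0 = gstart - off[seq_idx])
}
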