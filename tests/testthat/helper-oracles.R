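# Independent brute-force oracles. These deliberately share no code with the
# package: plain choose()/substring() arithmetic only.

oracle_hyper_tail <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k <= 0) return(1)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

oracle_fisher_p <- function(a, b, c, d, tol = 1e-7) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  pobs <- probs[a - lo + 1]
  sum(probs[probs <= pobs * (1 + tol)])
}

# All-pairs overlap scan; returns a sorted key per overlapping pair.
oracle_overlap_keys <- function(q, s, min_bp = 1) {
  qi <- rep(seq_len(nrow(q)), times = nrow(s))
  si <- rep(seq_len(nrow(s)), each = nrow(q))
  w <- pmin(q$end[qi], s$end[si]) - pmax(q$start[qi], s$start[si])
  keep <- q$chrom[qi] == s$chrom[si] & w >= min_bp
  sort(paste(q$name[qi[keep]], s$name[si[keep]], sep = "|"))
}

str_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

# Naive both-strand sliding-window scan for complementary seed sites.
naive_seed_sites <- function(seed, target) {
  ls <- nchar(seed)
  L <- nchar(target)
  if (L < ls) {
    return(data.frame(position = integer(0), orientation = character(0)))
  }
  wins <- substring(target, 1:(L - ls + 1), ls:L)
  rc <- str_revcomp(seed)
  sense <- which(wins == rc) - 1
  antis <- which(wins == seed) - 1
  out <- data.frame(
    position = c(sense, antis),
    orientation = c(rep("sense", length(sense)),
                    rep("antisense", length(antis)))
  )
  out[order(out$position, out$orientation), , drop = FALSE]
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_interval_set <- function(n, chroms = c("chr1", "chr2", "chr3"),
                              span = 5000, max_len = 300) {
  start <- sample.int(span, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + len,
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    name = sprintf("iv%05d", seq_len(n))
  )
}
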