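# Exact combinatorial statistics used by every enrichment stage.
#
# All probabilities are computed in log-gamma space (lchoose) so that
# genome-scale margins never overflow; tail sums use a max-shifted
# log-sum-exp.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a population of `N` items of which `K` are
#' successes, i.e. `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' per-region test behind [genic_region_enrichment()], where draws are the TE
#' loci overlapping a genic region and successes are loci of differentially
#' expressed TE families.
#'
#' Computed exactly from log-binomial coefficients; arguments are recycled to
#' a common length.
#'
#' @param k Observed successes in the draw. `k <= 0` gives 1 and
#'   `k > min(n, K)` gives 0 (the degenerate tails).
#' @param n Draw size.
#' @param K Successes in the population.
#' @param N Population size.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @examples
#' hyper_upper_tail(3, 4, 5, 10)  # 55/210
#' @export
hyper_upper_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  if (!is_count(args$n) || !is_count(args$K) || !is_count(args$N) ||
      !is_count(args$k)) {
    stop_contract("hypergeometric parameters must be non-negative integer counts")
  }
  if (any(args$n > args$N) || any(args$K > args$N)) {
    stop_contract("hypergeometric test requires n <= N and K <= N")
  }
  pmap_dbl(args, function(k, n, K, N) {
    hi <- min(n, K)
    if (k <= 0) return(1)
    if (k > hi) return(0)
    i <- seq.int(k, hi)
    lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  })
}

# Minimal recycling helper (base-R semantics: scalars recycle to max length).
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(vapply(xs, length, integer(1)))
  bad <- vapply(xs, function(x) !(length(x) %in% c(1L, len)), logical(1))
  if (any(bad)) stop_contract("arguments must have length 1 or a common length")
  lapply(xs, rep_len, length.out = len)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided test by the point-probability method: the p-value is the
#' sum of probabilities of every table with the observed margins whose point
#' probability is no larger than that of the observed table (a relative
#' tolerance of 1e-7 absorbs floating-point rounding when comparing point
#' probabilities). The odds ratio is the sample (cross-product) estimate
#' `(a*d)/(b*c)`, `Inf` when `b*c == 0` with `a*d > 0`, and `NaN` (flagged)
#' when both products vanish. Computation is in log space, so genome-scale
#' margins do not overflow.
#'
#' Cell layout: rows are targeted yes/no, columns are differentially
#' expressed yes/no, with `a` the in-both cell.
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one must be
#'   positive.
#' @param haldane Also report the Haldane–Anscombe (+0.5 in every cell)
#'   corrected odds ratio under `odds_ratio_haldane`.
#' @return An object of class `srnalink_fisher`: a list with the four cells,
#'   `odds_ratio`, `p_two_sided` and optionally `odds_ratio_haldane`.
#'   [tidy()] turns it into a one-row tibble.
#' @examples
#' fisher_exact(15, 15, 5, 65)  # odds ratio 13
#' @export
fisher_exact <- function(a, b, c, d, haldane = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!is_count(cells) || length(cells) != 4) {
    stop_contract("fisher_exact requires four non-negative integer counts")
  }
  if (sum(cells) == 0) {
    stop_contract("fisher_exact is undefined for an all-zero table")
  }
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  ntot <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- seq.int(lo, hi)
  lp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(ntot, c1)
  lobs <- lp[a - lo + 1L]
  keep <- lp <= lobs + log1p(1e-7)
  m <- max(lp[keep])
  p <- min(1, exp(m + log(sum(exp(lp[keep] - m)))))

  ad <- as.numeric(a) * as.numeric(d)
  bc <- as.numeric(b) * as.numeric(c)
  or <- if (bc > 0) {
    ad / bc
  } else if (ad > 0) {
    Inf
  } else {
    NaN
  }
  out <- list(
    a = a, b = b, c = c, d = d,
    odds_ratio = or,
    odds_ratio_defined = !(ad == 0 && bc == 0),
    p_two_sided = p
  )
  if (haldane) {
    out$odds_ratio_haldane <-
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  }
  structure(out, class = "srnalink_fisher")
}

#' @export
print.srnalink_fisher <- function(x, ...) {
  cat("2x2 Fisher exact test (point-probability method)\n")
  cat(sprintf("  table: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  odds ratio: %s\n", format(x$odds_ratio, digits = 6)))
  if (!is.null(x$odds_ratio_haldane)) {
    cat(sprintf("  odds ratio (Haldane-Anscombe): %s\n",
                format(x$odds_ratio_haldane, digits = 6)))
  }
  cat(sprintf("  two-sided p: %s\n", format(x$p_two_sided, digits = 6)))
  invisible(x)
}

#' @rdname fisher_exact
#' @param x An `srnalink_fisher` object.
#' @param ... Unused.
#' @export
tidy.srnalink_fisher <- function(x, ...) {
  out <- tibble(
    a = x$a, b = x$b, c = x$c, d = x$d,
    odds_ratio = x$odds_ratio,
    odds_ratio_defined = x$odds_ratio_defined,
    p_two_sided = x$p_two_sided
  )
  if (!is.null(x$odds_ratio_haldane)) {
    out$odds_ratio_haldane <- x$odds_ratio_haldane
  }
  out
}

#' Benjamini–Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: the i-th smallest
#' p-value is multiplied by `m/i` and a cumulative minimum is taken from the
#' largest down, capped at 1. Output order matches input order; `NA` values
#' pass through and do not count toward `m`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_contract("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_contract("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
  }
  out
}
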