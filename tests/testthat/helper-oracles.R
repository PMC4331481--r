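# Independent brute-force oracles for the exact tail probabilities.
# These enumerate the pmf directly from binomial coefficients and never
# touch the distribution functions the package calls.

oracle_binom_upper <- function(k, n, p) {
  if (k == 0) {
    return(1)
  }
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

oracle_hyper_upper <- function(k, N, K, n) {
  i <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand step-up BH: q_(i) = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# tiny deterministic gene/DMR fixtures used across module tests
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(10000L, 1000L),
    end = c(20000L, 2000L),
    strand = c("+", "-"),
    exons = list(
      tibble::tibble(start = c(10000L, 15000L), end = c(11000L, 16000L)),
      tibble::tibble(start = 1000L, end = 2000L)
    ),
    tss = c(10000L, 1999L),
    tx_end = c(19999L, 1000L)
  )
}

toy_dmrs <- function(starts, ends, delta_m = rep(0.2, length(starts)),
                     chrom = "chr1") {
  tibble::tibble(
    dmr_id = sprintf("d%02d", seq_along(starts)),
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(ends),
    delta_m = delta_m
  )
}
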