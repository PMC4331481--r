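#' Exact binomial upper-tail probability
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p)` exactly (via the
#' regularized incomplete beta function underlying [stats::pbinom()]),
#' never a normal approximation. This is the test used for k-mer motif
#' enrichment against a background occurrence rate.
#'
#' @param k Observed count (vectorized).
#' @param n Number of trials.
#' @param p Success probability per trial.
#' @return Upper-tail probability `P(X >= k)`, in `(0, 1]` for `k <= n`.
#' @examples
#' binom_upper_tail(0, 10, 0.3) # 1
#' binom_upper_tail(2, 2, 0.5) # 0.25
#' @export
binom_upper_tail <- function(k, n, p) {
  stopifnot(all(k >= 0), all(n >= 0), all(p >= 0), all(p <= 1))
  if (any(k > n)) {
    stop("`k` must not exceed `n`.")
  }
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Exact binomial lower-tail probability
#'
#' `P(X <= k)` for `X ~ Binomial(n, p)`; the depletion-side companion of
#' [binom_upper_tail()].
#'
#' @inheritParams binom_upper_tail
#' @return Lower-tail probability `P(X <= k)`.
#' @export
binom_lower_tail <- function(k, n, p) {
  stopifnot(all(k >= 0), all(k <= n), all(p >= 0), all(p <= 1))
  stats::pbinom(k, size = n, prob = p, lower.tail = TRUE)
}

#' Hypergeometric upper-tail probability
#'
#' Computes `P(X >= k)` where `X` counts marked items in a draw of `n`
#' from an urn of `N` items of which `K` are marked. Used for gene-set
#' (GO term) enrichment and for CpG content of motif sets.
#'
#' @param k Observed marked items in the draw (vectorized).
#' @param N Urn (background) size.
#' @param K Marked items in the urn.
#' @param n Draw (set) size.
#' @return Upper-tail probability `P(X >= k)`.
#' @examples
#' hypergeom_upper_tail(5, N = 20, K = 5, n = 10) # 3003/184756
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(all(N >= 0), all(K >= 0), all(n >= 0))
  if (any(K > N) || any(n > N)) {
    stop("Need K <= N and n <= N.")
  }
  if (any(k > pmin(n, K))) {
    stop("`k` must not exceed min(n, K).")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric lower-tail probability
#'
#' `P(X <= k)` for the same urn model as [hypergeom_upper_tail()]; used to
#' test depletion (e.g. CpG-poor motif classes).
#'
#' @inheritParams hypergeom_upper_tail
#' @return Lower-tail probability `P(X <= k)`.
#' @export
hypergeom_lower_tail <- function(k, N, K, n) {
  stopifnot(all(K <= N), all(n <= N), all(k >= 0))
  stats::phyper(k, m = K, n = N - K, k = n, lower.tail = TRUE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR q-values, returned in the input order. A thin, named
#' wrapper over `p.adjust(method = "BH")` so the correction used across
#' the package is explicit at call sites.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Bonferroni correction with an explicit family size
#'
#' `min(1, p * m)` per element. Unlike `p.adjust`, the family size `m`
#' may exceed the number of p-values supplied (e.g. when only the
#' interesting subset of tested terms is passed in).
#'
#' @param pvalues Numeric vector of p-values.
#' @param m Family size; must be at least `length(pvalues)`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  if (m < length(pvalues)) {
    stop("Family size `m` must be >= length(pvalues).")
  }
  pmin(1, pvalues * m)
}

#' Z-score of an observed count against permutation null counts
#'
#' Summarizes a shuffle null: `z = (observed - mean(S)) / sd(S)` with `S`
#' the null counts and `sd` the sample standard deviation. When the null
#' is degenerate (`sd(S) == 0`) the z-score is reported as `NA` and
#' flagged, never as infinite.
#'
#' @param observed Observed count.
#' @param null_counts Numeric vector of counts from >= 2 null replicates.
#' @return An object of class `shuffle_summary` with fields `n` (observed),
#'   `s_bar`, `s_std`, `z`, `z_defined`, `n_shuffles`. Use [generics::tidy()]
#'   for a one-row tibble.
#' @examples
#' shuffle_zscore(10, c(3, 5, 7))
#' @export
shuffle_zscore <- function(observed, null_counts) {
  if (length(null_counts) < 2) {
    stop("Need at least 2 null replicates.")
  }
  s_bar <- mean(null_counts)
  s_std <- stats::sd(null_counts)
  z_defined <- s_std > 0
  structure(
    list(
      n = observed,
      s_bar = s_bar,
      s_std = s_std,
      z = if (z_defined) (observed - s_bar) / s_std else NA_real_,
      z_defined = z_defined,
      n_shuffles = length(null_counts)
    ),
    class = "shuffle_summary"
  )
}

#' @export
print.shuffle_summary <- function(x, ...) {
  cat(sprintf(
    "Shuffle test: observed %g vs null %.3f +/- %.3f (%d shuffles), Z = %s\n",
    x$n, x$s_bar, x$s_std, x$n_shuffles,
    if (x$z_defined) sprintf("%.3f", x$z) else "undefined (degenerate null)"
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.shuffle_summary <- function(x, ...) {
  tibble::tibble(
    observed = x$n,
    null_mean = x$s_bar,
    null_sd = x$s_std,
    z = x$z,
    z_defined = x$z_defined,
    n_shuffles = x$n_shuffles
  )
}

#' @exportS3Method generics::glance
glance.shuffle_summary <- function(x, ...) tidy(x, ...)

#' One-sided binomial test of one proportion against a reference set
#'
#' Tests `k1` successes in `n1` trials against the point proportion
#' `p0 = k2/n2` of a reference set, using the exact binomial tail: upper
#' tail if `k1/n1 >= p0`, lower otherwise. This is the "binomial model"
#' comparison used to contrast per-category location fractions of
#' positive vs negative T-DMRs.
#'
#' @param k1,n1 Successes and trials for the set under test.
#' @param k2,n2 Successes and trials defining the reference proportion.
#' @return One-sided p-value.
#' @export
two_set_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n2 > 0, n1 > 0)
  p0 <- k2 / n2
  if (k1 / n1 >= p0) {
    binom_upper_tail(k1, n1, p0)
  } else {
    binom_lower_tail(k1, n1, p0)
  }
}
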