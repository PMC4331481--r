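#' Categorize DMRs by genomic feature
#'
#' Assigns every DMR exactly one feature label from its midpoint
#' position, with precedence exon > intron > upstream > downstream >
#' intergenic (gene body wins over a neighbouring gene's flank).
#' Upstream/downstream flanks are strand-aware.
#'
#' @param dmrs Tibble with `chrom, start, end` (and anything else, kept).
#' @param genes Gene tibble with `exons` list-column.
#' @param upstream_bp,downstream_bp Flank extents in bp.
#' @return The `dmrs` tibble with a `category` column.
#' @export
categorize_location <- function(dmrs, genes, upstream_bp = 4000,
                                downstream_bp = 4000) {
  mid <- (dmrs$start + dmrs$end) %/% 2L
  pts <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  exon_tbl <- tibble::tibble(
    chrom = rep(genes$chrom, vapply(genes$exons, nrow, integer(1))),
    start = unlist(lapply(genes$exons, `[[`, "start")),
    end = unlist(lapply(genes$exons, `[[`, "end"))
  )
  body_gr <- as_granges(genes[, c("chrom", "start", "end")])
  up_tbl <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+",
      pmax(genes$start - upstream_bp, 0L), genes$end
    ),
    end = ifelse(genes$strand == "+",
      genes$start, genes$end + upstream_bp
    )
  )
  down_tbl <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+",
      genes$end, pmax(genes$start - downstream_bp, 0L)
    ),
    end = ifelse(genes$strand == "+",
      genes$end + downstream_bp, genes$start
    )
  )
  hit <- function(tbl) {
    tbl <- tbl[tbl$end > tbl$start, , drop = FALSE]
    if (nrow(tbl) == 0) {
      return(rep(FALSE, length(pts)))
    }
    IRanges::overlapsAny(pts, as_granges(tbl))
  }
  in_exon <- hit(exon_tbl)
  in_body <- IRanges::overlapsAny(pts, body_gr)
  in_up <- hit(up_tbl)
  in_down <- hit(down_tbl)
  dmrs$category <- dplyr::case_when(
    in_exon ~ "exon",
    in_body ~ "intron",
    in_up ~ "upstream",
    in_down ~ "downstream",
    TRUE ~ "intergenic"
  )
  dmrs
}

#' Compare feature-category distributions of two DMR classes
#'
#' Per category, the proportion in each class plus a one-sided
#' [two_set_proportion_test()] p-value for the first class against the
#' second class's proportion as reference.
#'
#' @param pos_categories,neg_categories Character vectors of category
#'   labels (e.g. the `category` column of [categorize_location()]
#'   output) for the positive and negative DMR classes.
#' @param levels Category set to report; defaults to the union observed.
#' @return Tibble `category, n_pos, prop_pos, n_neg, prop_neg, p`.
#' @export
location_distribution_compare <- function(pos_categories, neg_categories,
                                          levels = NULL) {
  stopifnot(length(pos_categories) > 0, length(neg_categories) > 0)
  if (is.null(levels)) {
    levels <- sort(unique(c(pos_categories, neg_categories)))
  }
  n1 <- length(pos_categories)
  n2 <- length(neg_categories)
  purrr::map_dfr(levels, function(cat) {
    k1 <- sum(pos_categories == cat)
    k2 <- sum(neg_categories == cat)
    tibble::tibble(
      category = cat,
      n_pos = k1, prop_pos = k1 / n1,
      n_neg = k2, prop_neg = k2 / n2,
      p = if (k1 == 0 && k2 == 0) 1 else two_set_proportion_test(k1, n1, k2, n2)
    )
  })
}

#' Call DHS regions from replicates and classify them by tissue
#'
#' Per tissue, a region is a DHS iff covered by at least `min_reps`
#' replicate peak sets. A tissue's DHS overlapping (>= 1 bp) the other
#' tissue's DHS set is `shared` (shared regions are merged); the rest
#' are tissue-specific.
#'
#' @param peaks_t1,peaks_t2 A peak tibble (`chrom, start, end`) or a
#'   list of such tibbles (one per replicate).
#' @param min_reps_t1,min_reps_t2 Replicate support required per tissue
#'   (e.g. a "3 of 7 replicates" rule); must not exceed the number of
#'   replicates supplied.
#' @return Tibble `chrom, start, end, tissue_class` with class in
#'   `{tissue1_specific, tissue2_specific, shared}`.
#' @export
classify_dhs <- function(peaks_t1, peaks_t2,
                         min_reps_t1 = 1, min_reps_t2 = 1) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  peaks_t1 <- as_list(peaks_t1)
  peaks_t2 <- as_list(peaks_t2)
  all_peaks <- dplyr::bind_rows(c(peaks_t1, peaks_t2))
  seqlens <- tapply(all_peaks$end, all_peaks$chrom, max) + 1L
  call_dhs <- function(reps, k) {
    if (k > length(reps)) {
      stop("min_reps exceeds the number of replicate peak sets.")
    }
    # coverage = number of replicate sets covering a base
    covs <- lapply(reps, function(r) {
      gr <- GenomicRanges::reduce(as_granges(r))
      GenomeInfoDb::seqlevels(gr) <- names(seqlens)
      GenomeInfoDb::seqlengths(gr) <- as.integer(seqlens)
      GenomicRanges::coverage(gr)
    })
    cov <- Reduce(`+`, covs)
    GenomicRanges::GRanges(IRanges::slice(cov, lower = k, rangesOnly = TRUE))
  }
  d1 <- call_dhs(peaks_t1, min_reps_t1)
  d2 <- call_dhs(peaks_t2, min_reps_t2)
  sh1 <- IRanges::overlapsAny(d1, d2)
  sh2 <- IRanges::overlapsAny(d2, d1)
  shared <- GenomicRanges::reduce(c(d1[sh1], d2[sh2]))
  out <- dplyr::bind_rows(
    dplyr::mutate(granges_to_tibble(d1[!sh1]), tissue_class = "tissue1_specific"),
    dplyr::mutate(granges_to_tibble(d2[!sh2]), tissue_class = "tissue2_specific"),
    dplyr::mutate(granges_to_tibble(shared), tissue_class = "shared")
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

# uniform length-preserving placement of interval lengths within the
# probe space; returns a tibble of placements. Exact via rejection on
# the fit constraint.
random_placements <- function(lengths, space) {
  n <- length(lengths)
  w <- space$end - space$start
  if (max(lengths) > max(w)) {
    stop("Probe space has no interval long enough for the longest DMR.")
  }
  probs <- w / sum(w)
  iv <- integer(n)
  off <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    j <- sample.int(nrow(space), length(todo), replace = TRUE, prob = probs)
    u <- floor(runif(length(todo), 0, w[j]))
    ok <- u <= w[j] - lengths[todo]
    iv[todo[ok]] <- j[ok]
    off[todo[ok]] <- u[ok]
    todo <- todo[!ok]
  }
  tibble::tibble(
    chrom = space$chrom[iv],
    start = as.integer(space$start[iv] + off),
    end = as.integer(space$start[iv] + off + lengths)
  )
}

#' DHS overlap enrichment of DMRs against random placement
#'
#' The observed statistic is the fraction of DMRs overlapping (>= 1 bp)
#' any supplied DHS peak. The random expectation is the mean overlap
#' fraction of `n_shuffles` length-preserving uniform placements of the
#' same DMR lengths within the probe space (the array-assayable
#' intervals). The p-value is the exact binomial upper tail of the
#' observed count at the expected per-DMR rate (lower tail when the
#' observed fraction falls below expectation).
#'
#' @param dmrs DMR tibble (`chrom, start, end`).
#' @param dhs Peak tibble (`chrom, start, end`); filter by tissue class
#'   upstream to test a class separately.
#' @param probe_space Tibble of assayable intervals (merged internally).
#' @param n_shuffles Number of random placement rounds (default 1000).
#' @param seed Integer seed.
#' @return Object of class `overlap_enrichment` with fields
#'   `observed_fraction, expected_fraction, expected_sd, p, direction,
#'   n_dmrs, n_shuffles`. `tidy()` gives a one-row tibble.
#' @export
dhs_overlap_enrichment <- function(dmrs, dhs, probe_space,
                                   n_shuffles = 1000, seed = 1L) {
  space <- granges_to_tibble(GenomicRanges::reduce(as_granges(probe_space)))
  lengths <- dmrs$end - dmrs$start
  dhs_gr <- GenomicRanges::reduce(as_granges(dhs))
  n <- nrow(dmrs)
  observed <- if (length(dhs_gr) == 0) {
    0
  } else {
    sum(IRanges::overlapsAny(as_granges(dmrs), dhs_gr)) / n
  }
  withr::with_seed(seed, {
    null_frac <- vapply(seq_len(n_shuffles), function(b) {
      pl <- random_placements(lengths, space)
      if (length(dhs_gr) == 0) {
        return(0)
      }
      sum(IRanges::overlapsAny(as_granges(pl), dhs_gr)) / n
    }, numeric(1))
  })
  expected <- mean(null_frac)
  direction <- if (observed >= expected) "enrichment" else "depletion"
  p <- if (direction == "enrichment") {
    binom_upper_tail(round(observed * n), n, expected)
  } else {
    binom_lower_tail(round(observed * n), n, expected)
  }
  structure(
    list(
      observed_fraction = observed,
      expected_fraction = expected,
      expected_sd = sd(null_frac),
      p = p,
      direction = direction,
      n_dmrs = n,
      n_shuffles = n_shuffles
    ),
    class = "overlap_enrichment"
  )
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf(
    "DHS overlap: observed %.1f%% vs expected %.1f%% (n = %d DMRs), %s p = %.3g\n",
    100 * x$observed_fraction, 100 * x$expected_fraction,
    x$n_dmrs, x$direction, x$p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.overlap_enrichment <- function(x, ...) {
  tibble::tibble(
    observed_fraction = x$observed_fraction,
    expected_fraction = x$expected_fraction,
    expected_sd = x$expected_sd,
    p = x$p,
    direction = x$direction,
    n_dmrs = x$n_dmrs,
    n_shuffles = x$n_shuffles
  )
}

#' @exportS3Method generics::glance
glance.overlap_enrichment <- function(x, ...) tidy(x, ...)

#' Empirical CDFs of conservation scores per class
#'
#' Evaluates each class's ECDF (fraction of CpG sites at or below a
#' score) on a fixed grid over `[0, 1]`, suitable for plotting and for
#' stochastic-dominance checks: a pointwise-lower curve is the more
#' conserved class.
#'
#' @param scores_by_class Named list of numeric score vectors, or a
#'   tibble with `class` and `score` columns.
#' @param grid_points Number of evenly spaced grid points (default 101).
#' @return Tibble `class, score, ecdf`.
#' @export
conservation_ecdf <- function(scores_by_class, grid_points = 101) {
  if (is.data.frame(scores_by_class)) {
    scores_by_class <- split(scores_by_class$score, scores_by_class$class)
  }
  empty <- lengths(scores_by_class) == 0
  if (any(empty)) {
    warning(sprintf(
      "Omitted empty class(es): %s",
      paste(names(scores_by_class)[empty], collapse = ", ")
    ))
    scores_by_class <- scores_by_class[!empty]
  }
  grid <- seq(0, 1, length.out = grid_points)
  purrr::map_dfr(names(scores_by_class), function(cl) {
    s <- scores_by_class[[cl]]
    stopifnot(all(s >= 0 & s <= 1))
    tibble::tibble(
      class = cl, score = grid,
      ecdf = stats::ecdf(s)(grid)
    )
  })
}

#' CpG observed/expected ratio of sequences
#'
#' `ratio = (n_CpG * L) / (n_C * n_G)` with `n_CpG` the overlapping
#' count of `CG` dinucleotides, counted on the given strand, and `L` the
#' number of unambiguous (A/C/G/T) positions. Non-ACGT positions are
#' skipped in all counts, with a warning. When `n_C * n_G = 0` the ratio
#' is undefined and `NA` is returned.
#'
#' @param sequences Character vector, `DNAString` or `DNAStringSet`.
#' @return Numeric vector of ratios (NA where undefined).
#' @export
cpg_ratio <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  if (any(Biostrings::width(x) < 2)) {
    stop("Sequences must be at least 2 bases long.")
  }
  freq <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  n_valid <- rowSums(freq)
  if (any(n_valid < Biostrings::width(x))) {
    warning("Non-ACGT positions skipped in all counts.")
  }
  n_cg <- Biostrings::vcountPattern("CG", x, fixed = TRUE)
  denom <- freq[, "C"] * freq[, "G"]
  out <- ifelse(denom > 0, n_cg * n_valid / denom, NA_real_)
  unname(out)
}
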