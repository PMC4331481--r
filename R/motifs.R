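#' Enumerate all DNA k-mers
#'
#' @param k Word length, 1 to 12.
#' @return Character vector of all `4^k` k-mers in lexicographic order.
#' @export
enumerate_kmers <- function(k) {
  stopifnot(k >= 1, k <= 12)
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
}

#' Sample a length-matched random sequence background
#'
#' Draws `multiplier * length(target_lengths)` segments from the gene
#' windows (`upstream_bp` upstream of the TSS to the transcription end):
#' each target length is used exactly `multiplier` times, and for each
#' draw a gene whose window can hold the segment is chosen uniformly,
#' then the start uniformly within the window. The background therefore
#' reproduces the target length distribution exactly, at `multiplier`
#' times the depth.
#'
#' @param genes Gene tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @param target_lengths Integer vector of target (DMR) lengths in bp.
#' @param multiplier Background depth relative to the targets
#'   (default 10, i.e. 25,000 segments for 2,500 DMRs).
#' @param upstream_bp Upstream window extent.
#' @param seed Integer seed.
#' @param return_coords If `TRUE`, also return the segment coordinates.
#' @return A `DNAStringSet` (or, with `return_coords`, a list with
#'   `seqs` and `coords`).
#' @export
sample_background <- function(genes, genome, target_lengths,
                              multiplier = 10, upstream_bp = 4000,
                              seed = 1L, return_coords = FALSE) {
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  wins <- gene_windows(genes, upstream_bp, chrom_lengths)
  w <- wins$end - wins$start
  lengths <- rep(as.integer(target_lengths), each = multiplier)
  ord <- order(w)
  w_sorted <- w[ord]
  withr::with_seed(seed, {
    # genes able to hold length L are a suffix of the sorted widths
    n_feasible <- length(w) - findInterval(lengths - 1L, w_sorted)
    drop <- n_feasible == 0
    if (any(drop)) {
      warning(sprintf(
        "Skipped %d draw(s): no gene window long enough.", sum(drop)
      ))
      lengths <- lengths[!drop]
      n_feasible <- n_feasible[!drop]
    }
    pick <- length(w) - floor(runif(length(lengths)) * n_feasible)
    gene_idx <- ord[pick]
    offs <- floor(runif(length(lengths)) * (w[gene_idx] - lengths + 1L))
  })
  coords <- tibble::tibble(
    chrom = wins$chrom[gene_idx],
    start = as.integer(wins$start[gene_idx] + offs),
    end = as.integer(wins$start[gene_idx] + offs + lengths)
  )
  seqs <- dmr_sequences(
    dplyr::mutate(coords, dmr_id = sprintf("bg%06d", dplyr::row_number())),
    genome
  )
  if (return_coords) list(seqs = seqs, coords = coords) else seqs
}

# collapsed overlapping k-mer counts over a sequence set; windows with
# ambiguous bases count nowhere, so sum(counts) == number of valid
# windows (the "possible positions" denominator).
count_kmers <- function(seqs, k) {
  combined <- paste(as.character(seqs), collapse = strrep("N", k - 1))
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(combined),
    width = k
  )
}

#' k-mer enrichment of target sequences against a background
#'
#' Counts overlapping occurrences of every k-mer on the given strand in
#' the target and background sets, tests each k-mer's target count with
#' the exact binomial upper tail at the background's pooled per-position
#' rate, and corrects over all `4^k` k-mers by Benjamini-Hochberg FDR.
#' The enrichment score is the log2 ratio of pseudocounted (+0.5)
#' per-position frequencies; the pseudocount never enters the test.
#'
#' @param target_seqs,bg_seqs Sequence sets (`DNAStringSet` or character).
#' @param k Word length (default 6).
#' @param fdr_threshold Significance threshold on the q-value
#'   (default 0.01 for an all-DMR analysis; 0.05 is used for
#'   DHS-restricted sets).
#' @return Tibble of `4^k` rows: `kmer, count_target, positions_target,
#'   count_bg, positions_bg, p, q, enrichment_score, significant,
#'   has_cpg, boundary` (boundary flags a zero-background rate met with
#'   a nonzero target count).
#' @export
kmer_enrichment <- function(target_seqs, bg_seqs, k = 6,
                            fdr_threshold = 0.01) {
  stopifnot(length(target_seqs) > 0, length(bg_seqs) > 0)
  ct <- count_kmers(target_seqs, k)
  cb <- count_kmers(bg_seqs, k)
  pos_t <- sum(ct)
  pos_b <- sum(cb)
  p0 <- cb / pos_b
  p <- binom_upper_tail(ct, pos_t, p0)
  boundary <- p0 == 0 & ct > 0
  q <- bh_fdr(p)
  tibble::tibble(
    kmer = names(ct),
    count_target = unname(as.integer(ct)),
    positions_target = pos_t,
    count_bg = unname(as.integer(cb)),
    positions_bg = pos_b,
    p = unname(p),
    q = unname(q),
    enrichment_score = unname(
      log2(((ct + 0.5) / pos_t) / ((cb + 0.5) / pos_b))
    ),
    significant = unname(q < fdr_threshold),
    has_cpg = grepl("CG", names(ct), fixed = TRUE),
    boundary = unname(boundary)
  )
}

#' Classify motifs by the analyses they are significant in
#'
#' @param results_negative,results_positive [kmer_enrichment()] results
#'   for the negative- and positive-class target sets, over the same
#'   k-mer universe.
#' @return Tibble `kmer, role` with role in `{negative, positive, dual,
#'   none}`; dual means significant in both analyses.
#' @export
classify_motifs <- function(results_negative, results_positive) {
  if (!identical(results_negative$kmer, results_positive$kmer)) {
    stop("Result sets cover different k-mer universes.")
  }
  sn <- results_negative$significant
  sp <- results_positive$significant
  tibble::tibble(
    kmer = results_negative$kmer,
    role = dplyr::case_when(
      sn & sp ~ "dual",
      sn ~ "negative",
      sp ~ "positive",
      TRUE ~ "none"
    )
  )
}

#' CpG content of a motif set against the k-mer universe
#'
#' Fraction of motifs containing at least one `CG`, with a
#' hypergeometric p-value for enrichment (or depletion, chosen by the
#' observed direction) relative to drawing the same number of k-mers
#' uniformly from the `4^k` universe.
#'
#' @param motifs Character vector of k-mers, all of length `universe_k`.
#' @param universe_k Word length of the universe (default 6).
#' @return One-row tibble: `n, n_cpg, fraction, universe_size,
#'   universe_cpg, universe_fraction, direction, p`.
#' @export
cpg_motif_fraction <- function(motifs, universe_k = 6) {
  if (length(motifs) == 0) stop("Empty motif list.")
  if (!all(nchar(motifs) == universe_k)) {
    stop("All motifs must have length universe_k.")
  }
  universe <- enumerate_kmers(universe_k)
  K <- sum(grepl("CG", universe, fixed = TRUE))
  N <- length(universe)
  n <- length(motifs)
  k <- sum(grepl("CG", motifs, fixed = TRUE))
  enriched <- k / n >= K / N
  tibble::tibble(
    n = n, n_cpg = k, fraction = k / n,
    universe_size = N, universe_cpg = K, universe_fraction = K / N,
    direction = if (enriched) "enrichment" else "depletion",
    p = if (enriched) {
      hypergeom_upper_tail(k, N = N, K = K, n = n)
    } else {
      hypergeom_lower_tail(k, N = N, K = K, n = n)
    }
  )
}

#' Consistency of two motif analyses against an independent-draw null
#'
#' Compares the significant motif sets of two analyses (e.g. all DMRs
#' vs DHS-restricted DMRs): the observed intersection size and, within
#' the intersection, the number of motifs assigned the same regulation
#' role, each scored by [shuffle_zscore()] against a null where both
#' sets are drawn uniformly without replacement from the k-mer universe
#' with their role proportions preserved.
#'
#' @param set_a,set_b Character vectors of significant k-mers.
#' @param roles_a,roles_b Character vectors of roles aligned with
#'   `set_a` / `set_b`.
#' @param universe Universe size (default 4096 for 6-mers).
#' @param n_shuffles Number of null draws (default 10000).
#' @param seed Integer seed.
#' @return Object of class `consistency_test`: `overlap` and
#'   `agreement` [shuffle_zscore()] summaries plus the observed values.
#'   `tidy()` gives one row per statistic.
#' @export
cross_analysis_consistency <- function(set_a, set_b, roles_a, roles_b,
                                       universe = 4096, n_shuffles = 10000,
                                       seed = 1L) {
  stopifnot(
    length(set_a) == length(roles_a),
    length(set_b) == length(roles_b)
  )
  if (length(set_a) > universe || length(set_b) > universe) {
    stop("Set larger than the k-mer universe.")
  }
  common <- intersect(set_a, set_b)
  obs_overlap <- length(common)
  ra <- setNames(roles_a, set_a)
  rb <- setNames(roles_b, set_b)
  obs_agree <- sum(ra[common] == rb[common])
  na <- length(set_a)
  nb <- length(set_b)
  withr::with_seed(seed, {
    null_overlap <- integer(n_shuffles)
    null_agree <- integer(n_shuffles)
    for (i in seq_len(n_shuffles)) {
      ia <- sample.int(universe, na)
      ib <- sample.int(universe, nb)
      in_a <- logical(universe)
      in_a[ia] <- TRUE
      hit_b <- in_a[ib]
      null_overlap[i] <- sum(hit_b)
      if (null_overlap[i] > 0) {
        role_a_of <- character(universe)
        role_a_of[ia] <- sample(roles_a)
        rb_perm <- sample(roles_b)
        null_agree[i] <- sum(role_a_of[ib[hit_b]] == rb_perm[hit_b])
      }
    }
  })
  structure(
    list(
      overlap = shuffle_zscore(obs_overlap, null_overlap),
      agreement = shuffle_zscore(obs_agree, null_agree),
      n_a = na, n_b = nb, universe = universe,
      n_shuffles = n_shuffles
    ),
    class = "consistency_test"
  )
}

#' @export
print.consistency_test <- function(x, ...) {
  cat(sprintf(
    "Motif-set consistency (|A| = %d, |B| = %d, universe %d):\n",
    x$n_a, x$n_b, x$universe
  ))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.consistency_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$overlap), statistic = "overlap", .before = 1),
    dplyr::mutate(tidy(x$agreement), statistic = "role_agreement", .before = 1)
  )
}

#' @exportS3Method generics::glance
glance.consistency_test <- function(x, ...) {
  tibble::tibble(
    overlap = x$overlap$n,
    expected_overlap = x$overlap$s_bar,
    z_overlap = x$overlap$z,
    agreement = x$agreement$n,
    expected_agreement = x$agreement$s_bar,
    z_agreement = x$agreement$z
  )
}
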