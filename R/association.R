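#' Assign DMRs to genes by proximity
#'
#' Emits one pair for every (DMR, gene) combination where the DMR
#' overlaps (by at least 1 bp) the gene's strand-aware window from
#' `upstream_bp` upstream of the TSS to the transcription end. A DMR
#' overlapping several gene windows yields several pairs.
#'
#' @param dmrs Tibble with `dmr_id, chrom, start, end, delta_m`.
#' @param genes Gene tibble (strand-annotated, see [read_gene_models()]).
#' @param upstream_bp Upstream window extent (default 4000).
#' @return Tibble `dmr_id, gene_id, proximity = "proximal", delta_m`.
#' @export
assign_proximal <- function(dmrs, genes, upstream_bp = 4000) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  wins <- gene_windows(genes, upstream_bp)
  hits <- GenomicRanges::findOverlaps(
    as_granges(dmrs), as_granges(wins),
    minoverlap = 1
  )
  tibble::tibble(
    dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
    gene_id = wins$gene_id[S4Vectors::subjectHits(hits)],
    proximity = "proximal",
    delta_m = dmrs$delta_m[S4Vectors::queryHits(hits)]
  )
}

#' Assign DMRs to genes through an enhancer-promoter map
#'
#' A pair is emitted for every DMR overlapping an enhancer (>= 1 bp),
#' one per distinct target gene. Pairs duplicating an existing proximal
#' (DMR, gene) pair are not re-emitted; enhancer targets missing from
#' `known_genes` are dropped with a warning.
#'
#' @param dmrs Tibble with `dmr_id, chrom, start, end, delta_m`.
#' @param enhancer_map Tibble `chrom, start, end, target_gene_id` (see
#'   [read_enhancer_map()]).
#' @param proximal_pairs Optional tibble of already-assigned proximal
#'   pairs used for deduplication.
#' @param known_genes Optional character vector of gene ids with
#'   expression data; targets outside it are dropped.
#' @return Tibble `dmr_id, gene_id, proximity = "distal", delta_m`.
#' @export
assign_distal <- function(dmrs, enhancer_map, proximal_pairs = NULL,
                          known_genes = NULL) {
  hits <- GenomicRanges::findOverlaps(
    as_granges(dmrs), as_granges(enhancer_map),
    minoverlap = 1
  )
  pairs <- tibble::tibble(
    dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
    gene_id = enhancer_map$target_gene_id[S4Vectors::subjectHits(hits)],
    proximity = "distal",
    delta_m = dmrs$delta_m[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::distinct(.data$dmr_id, .data$gene_id, .keep_all = TRUE)
  if (!is.null(known_genes)) {
    unknown <- !pairs$gene_id %in% known_genes
    if (any(unknown)) {
      warning(sprintf(
        "Dropped %d distal pair(s) whose target gene has no expression record.",
        sum(unknown)
      ))
      pairs <- pairs[!unknown, ]
    }
  }
  if (!is.null(proximal_pairs)) {
    pairs <- dplyr::anti_join(
      pairs, proximal_pairs,
      by = c("dmr_id", "gene_id")
    )
  }
  pairs
}

#' Classify the sign relation of DMR-gene pairs
#'
#' Joins pair records with expression differences and labels each pair
#' `positive` when `delta_m` and `delta_e` share a sign, `negative` when
#' they oppose, and `excluded` when `|delta_e| <= min_abs_delta_e` (the
#' 25% fold-change filter, log2(1.25) by default) or either difference
#' is exactly zero. Pairs whose gene has no expression record are
#' dropped (counted in a message).
#'
#' @param pairs Tibble from [assign_proximal()] / [assign_distal()].
#' @param expression Expression tibble with `gene_id, delta_e`.
#' @param min_abs_delta_e Exclusion threshold on `|delta_e|`, log2 units.
#' @return The pairs tibble with `delta_e` and `sign_class` added.
#' @seealso [sign_fraction_summary()] for per-proximity counts and
#'   fractions.
#' @export
classify_sign <- function(pairs, expression,
                          min_abs_delta_e = log2(1.25)) {
  out <- dplyr::inner_join(
    pairs, expression[, c("gene_id", "delta_e")],
    by = "gene_id"
  )
  n_lost <- nrow(pairs) - nrow(out)
  if (n_lost > 0) {
    message(sprintf(
      "%d pair(s) dropped: gene absent from the expression table.", n_lost
    ))
  }
  dplyr::mutate(out, sign_class = sign_class_of(
    .data$delta_m, .data$delta_e, min_abs_delta_e
  ))
}

# vectorized sign-relation rule shared with the shuffle null
sign_class_of <- function(delta_m, delta_e, min_abs_delta_e) {
  dplyr::case_when(
    abs(delta_e) <= min_abs_delta_e | delta_m == 0 | delta_e == 0 ~ "excluded",
    sign(delta_m) == sign(delta_e) ~ "positive",
    TRUE ~ "negative"
  )
}

#' Sign-class counts and fractions per proximity class
#'
#' Fractions are reported both over pairs and over unique DMRs; a DMR
#' pairing to several genes is deduplicated by majority sign with ties
#' dropped. Excluded pairs never enter fractions.
#'
#' @param pairs Classified pairs from [classify_sign()].
#' @return Tibble with one row per (proximity, unit, sign_class) giving
#'   `n` and `fraction` (fractions over non-excluded items).
#' @export
sign_fraction_summary <- function(pairs) {
  by_pairs <- pairs |>
    dplyr::count(.data$proximity, .data$sign_class) |>
    dplyr::mutate(unit = "pairs")
  uniq <- pairs |>
    dplyr::filter(.data$sign_class != "excluded") |>
    dplyr::group_by(.data$proximity, .data$dmr_id) |>
    dplyr::summarise(
      n_pos = sum(.data$sign_class == "positive"),
      n_neg = sum(.data$sign_class == "negative"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pos != .data$n_neg) |>
    dplyr::mutate(
      sign_class = ifelse(.data$n_pos > .data$n_neg, "positive", "negative")
    ) |>
    dplyr::count(.data$proximity, .data$sign_class) |>
    dplyr::mutate(unit = "unique_dmrs")
  dplyr::bind_rows(by_pairs, uniq) |>
    dplyr::group_by(.data$proximity, .data$unit) |>
    dplyr::mutate(fraction = ifelse(
      .data$sign_class == "excluded", NA_real_,
      .data$n / sum(.data$n[.data$sign_class != "excluded"])
    )) |>
    dplyr::ungroup()
}

#' Expected sign fractions under a delta_m shuffle null
#'
#' Per shuffle, the observed `delta_m` values are permuted across pairs
#' while every `delta_e` stays put; sign classes are recomputed with the
#' identical exclusion filter and the positive/negative fractions over
#' non-excluded pairs are recorded. Returns their means and standard
#' deviations over shuffles — the "random expectation" against which the
#' observed positive fraction is judged.
#'
#' @param pairs Classified pairs (tibble with `delta_m, delta_e`).
#' @param n_shuffles Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param min_abs_delta_e Exclusion threshold, as in [classify_sign()].
#' @return Tibble with one row per sign class: `expected_fraction, sd,
#'   n_shuffles`.
#' @export
shuffle_expected_sign_fractions <- function(pairs, n_shuffles = 10000,
                                            seed = 1L,
                                            min_abs_delta_e = log2(1.25)) {
  keep <- abs(pairs$delta_e) > min_abs_delta_e & pairs$delta_e != 0
  dm <- pairs$delta_m
  de <- pairs$delta_e
  if (sum(keep & dm != 0) < 2) {
    stop("Fewer than 2 non-excluded pairs; nothing to shuffle.")
  }
  withr::with_seed(seed, {
    fracs <- vapply(seq_len(n_shuffles), function(b) {
      dm_b <- sample(dm)
      inc <- keep & dm_b != 0
      sum(sign(dm_b[inc]) == sign(de[inc])) / sum(inc)
    }, numeric(1))
  })
  tibble::tibble(
    sign_class = c("positive", "negative"),
    expected_fraction = c(mean(fracs), 1 - mean(fracs)),
    sd = c(sd(fracs), sd(fracs)),
    n_shuffles = n_shuffles
  )
}

#' Gene-set (GO term) enrichment by the hypergeometric test
#'
#' For every term annotated to at least `min_term_genes` background
#' genes, draws-without-replacement enrichment of the term in
#' `gene_set` against `background` is scored with the hypergeometric
#' upper tail and Bonferroni-corrected over the number of tested terms.
#'
#' @param gene_set Character vector of gene ids (must be a subset of the
#'   background).
#' @param background Character vector of background gene ids (the
#'   expressed-gene universe).
#' @param gene2terms Tibble `gene_id, term_id[, term_name]`.
#' @param min_term_genes Minimum background genes per tested term.
#' @return Tibble sorted by corrected p: `term_id, term_name, k, n, K,
#'   N, ratio, p, p_corrected`.
#' @export
go_enrichment <- function(gene_set, background, gene2terms,
                          min_term_genes = 5) {
  gene_set <- unique(gene_set)
  background <- unique(background)
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of background.")
  }
  if (length(gene_set) == 0) {
    return(tibble::tibble(
      term_id = character(), term_name = character(),
      k = integer(), n = integer(), K = integer(), N = integer(),
      ratio = numeric(), p = numeric(), p_corrected = numeric()
    ))
  }
  ann <- gene2terms |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  N <- length(background)
  n <- length(gene_set)
  res <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% gene_set),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= min_term_genes)
  if (nrow(res) == 0) {
    return(tibble::tibble(
      term_id = character(), term_name = character(),
      k = integer(), n = integer(), K = integer(), N = integer(),
      ratio = numeric(), p = numeric(), p_corrected = numeric()
    ))
  }
  res |>
    dplyr::mutate(
      n = n, N = N,
      ratio = (.data$k / n) / (.data$K / N),
      p = hypergeom_upper_tail(.data$k, N = N, K = .data$K, n = n),
      p_corrected = bonferroni(.data$p, m = dplyr::n())
    ) |>
    dplyr::arrange(.data$p_corrected, .data$p) |>
    dplyr::select(
      "term_id", "term_name", "k", "n", "K", "N",
      "ratio", "p", "p_corrected"
    )
}
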