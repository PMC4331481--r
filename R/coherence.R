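#' Coherence records for genes with multiple DMRs
#'
#' Drops excluded pairs, then builds one record per gene associated with
#' at least two remaining DMRs. A gene is `coherent_positive` /
#' `coherent_negative` when every pair shares that sign relation, and
#' `incoherent` otherwise.
#'
#' @param pairs Classified pairs from [classify_sign()].
#' @return Tibble `gene_id, n_dmrs, n_positive, n_negative,
#'   coherence_class`.
#' @export
build_coherence_records <- function(pairs) {
  pairs |>
    dplyr::filter(.data$sign_class != "excluded") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_dmrs = dplyr::n(),
      n_positive = sum(.data$sign_class == "positive"),
      n_negative = sum(.data$sign_class == "negative"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_dmrs >= 2) |>
    dplyr::mutate(coherence_class = dplyr::case_when(
      .data$n_positive == .data$n_dmrs ~ "coherent_positive",
      .data$n_negative == .data$n_dmrs ~ "coherent_negative",
      TRUE ~ "incoherent"
    ))
}

count_coherence_classes <- function(n_pos_per_gene, n_per_gene) {
  coh_pos <- sum(n_pos_per_gene == n_per_gene)
  coh_neg <- sum(n_pos_per_gene == 0)
  c(
    incoherent = length(n_per_gene) - coh_pos - coh_neg,
    coherent_negative = coh_neg,
    coherent_positive = coh_pos
  )
}

#' Shuffle-null test of coherence class counts
#'
#' Restricts to genes carrying multiple non-excluded DMRs, then, per
#' shuffle, permutes the multiset of `delta_m` values across the DMR
#' slots of those genes only (each gene's `delta_e` is kept), recomputes
#' every pair's sign relation, and counts genes per coherence class. The
#' observed counts are scored against the null with
#' [shuffle_zscore()].
#'
#' @param pairs Classified pairs from [classify_sign()].
#' @param n_shuffles Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @return An object of class `coherence_test`: list with `observed`
#'   (named counts), `summaries` (a [shuffle_zscore()] summary per
#'   class), `n_genes`, `n_shuffles`, `seed`. `tidy()` gives one row per
#'   class.
#' @export
coherence_null_test <- function(pairs, n_shuffles = 10000, seed = 1L) {
  records <- build_coherence_records(pairs)
  if (nrow(records) == 0) {
    stop("No gene with multiple non-excluded DMRs.")
  }
  multi <- pairs |>
    dplyr::filter(
      .data$sign_class != "excluded",
      .data$gene_id %in% records$gene_id
    )
  gene_f <- factor(multi$gene_id)
  gene_idx <- as.integer(gene_f)
  n_per_gene <- as.integer(table(gene_idx))
  s_e <- sign(multi$delta_e)
  dm <- multi$delta_m
  classes <- c("incoherent", "coherent_negative", "coherent_positive")

  observed <- {
    pos <- sign(dm) == s_e
    npos <- as.integer(rowsum(as.integer(pos), gene_idx))
    count_coherence_classes(npos, n_per_gene)
  }
  if (all(sign(dm) == sign(dm)[1])) {
    warning("Degenerate null: all delta_m share one sign; Z undefined.")
  }
  withr::with_seed(seed, {
    null_counts <- matrix(0L, nrow = n_shuffles, ncol = 3,
      dimnames = list(NULL, classes)
    )
    for (b in seq_len(n_shuffles)) {
      dm_b <- sample(dm)
      pos <- sign(dm_b) == s_e
      npos <- as.integer(rowsum(as.integer(pos), gene_idx))
      null_counts[b, ] <- count_coherence_classes(npos, n_per_gene)
    }
  })
  summaries <- lapply(classes, function(cl) {
    shuffle_zscore(observed[[cl]], null_counts[, cl])
  })
  names(summaries) <- classes
  structure(
    list(
      observed = observed,
      summaries = summaries,
      n_genes = nrow(records),
      n_shuffles = n_shuffles,
      seed = seed
    ),
    class = "coherence_test"
  )
}

#' @export
print.coherence_test <- function(x, ...) {
  cat(sprintf(
    "Coherence shuffle test: %d multi-DMR genes, %d shuffles\n",
    x$n_genes, x$n_shuffles
  ))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coherence_test <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$summaries), function(cl) {
    dplyr::mutate(tidy(x$summaries[[cl]]), coherence_class = cl, .before = 1)
  }))
}

#' @exportS3Method generics::glance
glance.coherence_test <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    n_shuffles = x$n_shuffles,
    z_incoherent = x$summaries$incoherent$z,
    z_coherent_negative = x$summaries$coherent_negative$z,
    z_coherent_positive = x$summaries$coherent_positive$z
  )
}
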