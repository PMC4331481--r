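#' Scatter plot of methylation vs expression differences
#'
#' One point per classified DMR-gene pair, coloured by sign class:
#' positive pairs sit in the concordant quadrants, negative in the
#' discordant ones, excluded pairs inside the fold-change band.
#'
#' @param pairs Classified pairs from [classify_sign()].
#' @return A ggplot object.
#' @export
plot_sign_scatter <- function(pairs) {
  ggplot2::ggplot(
    pairs,
    ggplot2::aes(x = .data$delta_e, y = .data$delta_m, colour = .data$sign_class)
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      positive = "#3366cc", negative = "#cc3333", excluded = "grey70"
    )) +
    ggplot2::labs(
      x = expression(Delta * E ~ "(log2 expression difference)"),
      y = expression(Delta * M ~ "(methylation difference)"),
      colour = "sign class"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed vs expected coherence class counts
#'
#' Bars are observed gene counts per coherence class; points with error
#' bars give the shuffle-null mean and standard deviation.
#'
#' @param object A `coherence_test` from [coherence_null_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_test <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$coherence_class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey35") +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        y = .data$null_mean,
        ymin = .data$null_mean - .data$null_sd,
        ymax = .data$null_mean + .data$null_sd
      ),
      colour = "#cc3333"
    ) +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = "Observed (bars) vs shuffle-null (points) coherence counts"
    ) +
    ggplot2::theme_minimal()
}

#' Conservation ECDF curves per class
#'
#' Curves towards the top-left are less conserved; a pointwise-lower
#' curve indicates a more conserved class.
#'
#' @param ecdf_tbl Tibble from [conservation_ecdf()].
#' @return A ggplot object.
#' @export
plot_conservation_ecdf <- function(ecdf_tbl) {
  ggplot2::ggplot(
    ecdf_tbl,
    ggplot2::aes(x = .data$score, y = .data$ecdf, colour = .data$class)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "conservation score", y = "fraction of CpG sites <= score",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of k-mer enrichment results
#'
#' Enrichment score against -log10 q-value, CpG-containing motifs
#' marked.
#'
#' @param results Tibble from [kmer_enrichment()].
#' @return A ggplot object.
#' @export
plot_motif_volcano <- function(results) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(
      x = .data$enrichment_score,
      y = -log10(pmax(.data$q, 1e-300)),
      colour = .data$significant,
      shape = .data$has_cpg
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#cc3333", `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "log2 enrichment score", y = "-log10 FDR q",
      colour = "significant", shape = "contains CpG"
    ) +
    ggplot2::theme_minimal()
}
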