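#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study design the pipeline targets: ~2,500 array-scale DMRs of
#' 200-2000 bp between two tissues, 34% of informative DMR-gene pairs
#' sign-concordant (positive), expression in triplicate vs duplicate,
#' and an 18% DMR/DHS overlap against a 13% random-placement rate.
#'
#' @param n_genes Number of genes laid on the synthetic genome (enough
#'   windows for mostly-single DMR placement at the default n_dmrs).
#' @param gene_len_range,intergenic_len_range Gene / intergenic length
#'   ranges in bp (uniform draws).
#' @param n_chroms Number of chromosomes the genes are spread over.
#' @param gc_content Background GC fraction of the genome sequence.
#' @param n_dmrs Number of DMRs.
#' @param dmr_len_range DMR length range in bp.
#' @param frac_positive Planted fraction of sign-concordant (positive)
#'   DMR-gene pairs among informative pairs.
#' @param frac_multi_dmr_genes Fraction of DMR-bearing genes that carry
#'   multiple DMRs.
#' @param multi_dmr_range Range of DMR counts for a multi-DMR gene.
#' @param coherence_bias Probability that a DMR of a multi-DMR gene
#'   inherits the gene's base sign relation (1 = fully coherent genes).
#' @param frac_inactive Fraction of DMR-bearing genes given a
#'   below-threshold |delta_e| so the expression filter is exercised.
#' @param frac_distal Fraction of DMRs placed outside gene windows and
#'   linked to their gene through a generated enhancer.
#' @param delta_e_sd Scale (sd of the half-normal excess over the
#'   log2(1.25) floor) of planted |delta_e|, log2 units.
#' @param delta_m_sd Scale of planted |delta_m| over its 0.1 floor.
#' @param rep_noise_sd Replicate noise sd on the log2 expression scale.
#' @param n_reps_t1,n_reps_t2 Replicates per tissue (default 3 and 2).
#' @param upstream_bp Upstream extent of a gene's window.
#' @param dhs_cover_frac Target probability that a random
#'   length-preserving placement in the probe space overlaps a DHS peak
#'   (the null rate; the peak count is calibrated to it).
#' @param dhs_dmr_overlap_frac Planted fraction of DMRs overlapping a
#'   DHS peak.
#' @param dhs_peak_len_range DHS peak length range in bp.
#' @param dhs_shared_frac Fraction of peaks present in both tissues.
#' @param cons_base_mean,cons_sd Background conservation score mean / sd.
#' @param cons_shift_negative,cons_shift_positive Additive mean shifts of
#'   per-CpG conservation scores for negative / positive DMRs.
#' @param planted_motifs_pos,planted_motifs_neg Named numeric vectors:
#'   names are 6-mers, values per-DMR insertion rates, planted into the
#'   positive / negative class sequences.
#' @param seed Integer seed; all generator stages are deterministic
#'   given the full configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2400,
                       gene_len_range = c(6000, 14000),
                       intergenic_len_range = c(2000, 6000),
                       n_chroms = 2,
                       gc_content = 0.42,
                       n_dmrs = 2498,
                       dmr_len_range = c(200, 2000),
                       frac_positive = 0.34,
                       frac_multi_dmr_genes = 0.12,
                       multi_dmr_range = c(2, 4),
                       coherence_bias = 0.9,
                       frac_inactive = 0.15,
                       frac_distal = 0.05,
                       delta_e_sd = 1.5,
                       delta_m_sd = 0.15,
                       rep_noise_sd = 0.2,
                       n_reps_t1 = 3,
                       n_reps_t2 = 2,
                       upstream_bp = 4000,
                       dhs_cover_frac = 0.13,
                       dhs_dmr_overlap_frac = 0.18,
                       dhs_peak_len_range = c(1000, 2000),
                       dhs_shared_frac = 0.35,
                       cons_base_mean = 0.25,
                       cons_sd = 0.2,
                       cons_shift_negative = 0.1,
                       cons_shift_positive = 0.2,
                       planted_motifs_pos = c(TACGCG = 0.6),
                       planted_motifs_neg = c(TAATTA = 0.6),
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(
    "frac_positive", "frac_multi_dmr_genes", "coherence_bias",
    "frac_inactive", "frac_distal", "dhs_cover_frac",
    "dhs_dmr_overlap_frac", "dhs_shared_frac", "gc_content"
  )
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must be in [0,1].", p))
  }
  for (r in c(
    "gene_len_range", "intergenic_len_range", "dmr_len_range",
    "dhs_peak_len_range"
  )) {
    if (length(cfg[[r]]) != 2 || any(cfg[[r]] <= 0) || cfg[[r]][2] < cfg[[r]][1]) {
      stop(sprintf("%s must be a positive non-decreasing pair.", r))
    }
  }
  ok_motif <- function(m) {
    length(m) == 0 ||
      (!is.null(names(m)) && all(grepl("^[ACGT]+$", names(m))) && all(m >= 0))
  }
  if (!ok_motif(planted_motifs_pos) || !ok_motif(planted_motifs_neg)) {
    stop("Planted motifs must be named numeric vectors over {A,C,G,T}.")
  }
  stopifnot(n_reps_t1 >= 1, n_reps_t2 >= 1, n_genes >= 2, n_dmrs >= 1)
  structure(cfg, class = "sim_config")
}

runif_len <- function(n, range) {
  as.integer(round(runif(n, range[1], range[2])))
}

#' Lay out synthetic gene models
#'
#' Places non-overlapping genes sequentially along `n_chroms`
#' chromosomes with alternating strand, uniform gene and intergenic
#' lengths, and 2-4 exons per gene.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble as from [read_gene_models()]) and
#'   `chrom_lengths` (named integer vector).
#' @export
simulate_genes <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_genes
    per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
    chrom <- rep(sprintf("chr%d", seq_len(config$n_chroms)), per_chrom)
    lens <- runif_len(n, config$gene_len_range)
    gaps <- runif_len(n, config$intergenic_len_range)
    start <- integer(n)
    chrom_lengths <- integer(config$n_chroms)
    names(chrom_lengths) <- sprintf("chr%d", seq_len(config$n_chroms))
    offset <- 0L
    for (ci in seq_len(config$n_chroms)) {
      idx <- offset + seq_len(per_chrom[ci])
      # cursor walk: upstream margin, then gene + gap alternating
      start[idx] <- config$upstream_bp +
        cumsum(gaps[idx]) + c(0L, cumsum(lens[idx][-length(idx)]))
      last <- idx[length(idx)]
      chrom_lengths[ci] <- start[last] + lens[last] +
        config$upstream_bp + gaps[1]
      offset <- offset + per_chrom[ci]
    }
    n_ex <- sample(2:4, n, replace = TRUE)
    exons <- lapply(seq_len(n), function(i) {
      bp <- sort(sample(lens[i] - 1L, 2L * n_ex[i] - 2L))
      bounds <- c(0L, bp, lens[i])
      odd <- seq(1, length(bounds) - 1, by = 2)
      tibble::new_tibble(
        list(
          start = start[i] + bounds[odd],
          end = start[i] + bounds[odd + 1]
        ),
        nrow = length(odd)
      )
    })
    genes <- add_tss(tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = chrom,
      start = start,
      end = start + lens,
      strand = rep_len(c("+", "-"), n),
      exons = exons
    ))
    list(genes = genes, chrom_lengths = chrom_lengths)
  })
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at the configured GC content, one sequence per
#' chromosome.
#'
#' @param config A [sim_config()].
#' @param chrom_lengths Named integer vector from [simulate_genes()].
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(config, chrom_lengths) {
  gc <- config$gc_content
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withr::with_seed(config$seed + 1L, {
    seqs <- vapply(chrom_lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = ""
      )
    }, character(1))
  })
  Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
}

#' Generate genome sequence and gene models together
#'
#' @param config A [sim_config()].
#' @param sequences If `FALSE`, skip the (comparatively slow) sequence
#'   generation and return coordinates only.
#' @return List with `genes`, `chrom_lengths` and (optionally) `genome`.
#' @export
simulate_genome_and_genes <- function(config, sequences = TRUE) {
  gg <- simulate_genes(config)
  if (sequences) {
    gg$genome <- simulate_genome(config, gg$chrom_lengths)
  }
  gg
}

# strand-aware gene window [TSS - upstream, tx_end] on the reference
gene_windows <- function(genes, upstream_bp, chrom_lengths = NULL) {
  w <- dplyr::mutate(
    genes,
    win_start = ifelse(.data$strand == "+", .data$start - upstream_bp, .data$start),
    win_end = ifelse(.data$strand == "+", .data$end, .data$end + upstream_bp)
  )
  w$win_start <- pmax(w$win_start, 0L)
  if (!is.null(chrom_lengths)) {
    w$win_end <- pmin(w$win_end, chrom_lengths[w$chrom])
  }
  dplyr::select(
    w, "gene_id", "chrom",
    start = "win_start", end = "win_end", "strand"
  )
}

#' Generate DMRs, expression records and the planted truth table
#'
#' Each DMR is placed (non-overlapping per gene) in its gene's window
#' from `upstream_bp` upstream of the TSS to the transcription end; a
#' `frac_distal` share is instead placed in intergenic space and wired
#' to the gene through a generated enhancer. The methylation difference
#' `delta_m` has magnitude at least 0.1 so its sign is unambiguous, and
#' the gene's true `delta_e` is drawn so that the pair's sign relation
#' matches the planted class. Replicate log2 expression values are the
#' true tissue means plus `Normal(0, rep_noise_sd)` noise; informative
#' genes are guaranteed `|delta_e| >= log2(1.25)`, while a
#' `frac_inactive` share falls below the threshold to exercise the
#' filter.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_genes()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return List with `dmrs`, `expression`, `truth` (one row per planted
#'   pair: `dmr_id, gene_id, planted_class, true_delta_e, delta_m,
#'   proximity`) and `enhancers` (map for the distal pairs).
#' @export
simulate_methylation_expression <- function(config, genes,
                                            chrom_lengths = NULL) {
  withr::with_seed(config$seed + 2L, {
    n_g <- nrow(genes)
    n_multi <- floor(config$frac_multi_dmr_genes * n_g)
    k_multi <- if (n_multi > 0) {
      sample(seq(config$multi_dmr_range[1], config$multi_dmr_range[2]),
        n_multi,
        replace = TRUE
      )
    } else {
      integer(0)
    }
    while (sum(k_multi) > config$n_dmrs && length(k_multi) > 0) {
      k_multi <- k_multi[-length(k_multi)]
    }
    n_single <- config$n_dmrs - sum(k_multi)
    if (n_single > n_g - length(k_multi)) {
      stop("More DMRs requested than placeable gene windows.")
    }
    gene_order <- sample(n_g)
    multi_idx <- gene_order[seq_along(k_multi)]
    single_idx <- gene_order[length(k_multi) + seq_len(n_single)]
    alloc <- tibble::tibble(
      gene_row = c(multi_idx, single_idx),
      n_dmr = c(k_multi, rep(1L, n_single))
    )

    wins <- gene_windows(genes, config$upstream_bp, chrom_lengths)
    # intergenic space for distal DMRs: complement of gene windows
    gaps <- NULL
    if (config$frac_distal > 0) {
      win_gr <- GenomicRanges::reduce(as_granges(wins))
      gap_list <- lapply(split(win_gr, GenomicRanges::seqnames(win_gr)), function(g) {
        IRanges::gaps(IRanges::ranges(g))
      })
      gaps <- dplyr::bind_rows(lapply(names(gap_list), function(ch) {
        ir <- gap_list[[ch]]
        tibble::tibble(
          chrom = ch, start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir)
        )
      }))
      gaps <- gaps[gaps$end - gaps$start >= config$dmr_len_range[2] + 200, ]
    }

    n_d <- config$n_dmrs
    d_chrom <- character(n_d)
    d_start <- integer(n_d)
    d_len <- integer(n_d)
    d_m1 <- numeric(n_d)
    d_m2 <- numeric(n_d)
    d_gene <- character(n_d)
    d_class <- character(n_d)
    d_true_de <- numeric(n_d)
    d_distal <- logical(n_d)
    true_de <- numeric(n_g)
    enh_rows <- list()
    dmr_counter <- 0L

    for (ai in seq_len(nrow(alloc))) {
      gi <- alloc$gene_row[ai]
      nk <- alloc$n_dmr[ai]
      win_start <- wins$start[gi]
      win_end <- wins$end[gi]
      active <- runif(1) > config$frac_inactive
      abs_de <- if (active) {
        log2(1.25) + abs(rnorm(1, 0, config$delta_e_sd))
      } else {
        runif(1, 0, 0.95 * log2(1.25))
      }
      de_sign <- sample(c(-1, 1), 1)
      true_de[gi] <- de_sign * abs_de
      base_pos <- runif(1) < config$frac_positive

      lens_k <- runif_len(nk, config$dmr_len_range)
      distal_k <- !is.null(gaps) && nrow(gaps) > 0 &
        runif(nk) < config$frac_distal
      # non-overlapping layout of the proximal DMRs: spread the window's
      # slack over the inter-DMR gaps (always feasible when they fit)
      prox_idx <- which(!distal_k)
      s_k <- integer(nk)
      if (length(prox_idx) > 0) {
        pl <- lens_k[prox_idx]
        slack <- (win_end - win_start) - sum(pl)
        if (slack < 0) {
          stop("More DMRs requested than placeable gene windows.")
        }
        cuts <- sort(runif(length(pl)))
        gap_sizes <- floor(diff(c(0, cuts, 1)) * slack)
        starts <- win_start + cumsum(gap_sizes[-length(gap_sizes)]) +
          c(0L, cumsum(pl[-length(pl)]))
        s_k[prox_idx] <- as.integer(starts)
      }
      for (d in seq_len(nk)) {
        dmr_counter <- dmr_counter + 1L
        len <- lens_k[d]
        distal <- distal_k[d]
        if (distal) {
          gp <- sample.int(nrow(gaps), 1)
          s <- as.integer(floor(runif(
            1, gaps$start[gp] + 50, gaps$end[gp] - len - 50
          )))
          chrom <- gaps$chrom[gp]
          pad <- runif_len(2, c(50, 300))
          enh_rows[[length(enh_rows) + 1L]] <- list(
            chrom = chrom, start = max(0L, s - pad[1]),
            end = s + len + pad[2],
            target_gene_id = genes$gene_id[gi]
          )
        } else {
          chrom <- wins$chrom[gi]
          s <- s_k[d]
        }
        rel_pos <- if (nk > 1 && runif(1) >= config$coherence_bias) {
          runif(1) < config$frac_positive
        } else {
          base_pos
        }
        dm_sign <- if (rel_pos) de_sign else -de_sign
        dm_abs <- min(0.1 + abs(rnorm(1, 0, config$delta_m_sd)), 0.85)
        lo <- runif(1, 0.05, 0.95 - dm_abs)
        i <- dmr_counter
        d_chrom[i] <- chrom
        d_start[i] <- s
        d_len[i] <- len
        d_m1[i] <- if (dm_sign > 0) lo + dm_abs else lo
        d_m2[i] <- if (dm_sign > 0) lo else lo + dm_abs
        d_gene[i] <- genes$gene_id[gi]
        d_class[i] <- if (!active) {
          "excluded"
        } else if (rel_pos) "positive" else "negative"
        d_true_de[i] <- true_de[gi]
        d_distal[i] <- distal
      }
    }
    dmr_ids <- sprintf("dmr%05d", seq_len(n_d))
    dmr_tbl <- tibble::tibble(
      dmr_id = dmr_ids, chrom = d_chrom,
      start = d_start, end = d_start + d_len,
      m_tissue1 = d_m1, m_tissue2 = d_m2, delta_m = d_m1 - d_m2
    )
    truth_tbl <- tibble::tibble(
      dmr_id = dmr_ids, gene_id = d_gene,
      planted_class = d_class, true_delta_e = d_true_de,
      delta_m = d_m1 - d_m2,
      proximity = ifelse(d_distal, "distal", "proximal")
    )

    # expression for every gene; genes without DMRs get unconstrained
    # effects so the background behaves like a real expressed-gene pool
    no_dmr <- setdiff(seq_len(n_g), alloc$gene_row)
    true_de[no_dmr] <- rnorm(length(no_dmr), 0, config$delta_e_sd)
    baseline <- runif(n_g, 4, 10)
    t1_mean <- baseline + true_de / 2
    t2_mean <- baseline - true_de / 2
    reps1 <- lapply(seq_len(n_g), function(i) {
      rnorm(config$n_reps_t1, t1_mean[i], config$rep_noise_sd)
    })
    reps2 <- lapply(seq_len(n_g), function(i) {
      rnorm(config$n_reps_t2, t2_mean[i], config$rep_noise_sd)
    })
    expression <- expression_records(genes$gene_id, reps1, reps2)

    list(
      dmrs = dmr_tbl,
      expression = expression,
      truth = truth_tbl,
      enhancers = if (length(enh_rows)) {
        dplyr::bind_rows(lapply(enh_rows, tibble::as_tibble))
      } else {
        tibble::tibble(
          chrom = character(), start = integer(),
          end = integer(), target_gene_id = character()
        )
      }
    )
  })
}

# sample non-overlapping intervals of widths w inside free space (tibble
# of intervals), returning a tibble; free space shrinks as peaks land.
place_in_free_space <- function(free, widths) {
  f_chrom <- free$chrom
  f_start <- as.integer(free$start)
  f_end <- as.integer(free$end)
  n <- length(widths)
  o_chrom <- character(n)
  o_start <- integer(n)
  for (i in seq_len(n)) {
    w <- widths[i]
    cap <- pmax(f_end - f_start - w + 1L, 0L)
    if (sum(cap) == 0) stop("No free space left for peak placement.")
    j <- sample.int(length(cap), 1, prob = cap)
    s <- as.integer(f_start[j] + floor(runif(1, 0, cap[j])))
    o_chrom[i] <- f_chrom[j]
    o_start[i] <- s
    # split the used interval in place, append the right-hand piece
    old_end <- f_end[j]
    f_end[j] <- s
    f_chrom <- c(f_chrom, f_chrom[j])
    f_start <- c(f_start, s + w)
    f_end <- c(f_end, old_end)
  }
  tibble::tibble(chrom = o_chrom, start = o_start, end = o_start + widths)
}

#' Generate DHS peak tracks with a planted DMR overlap fraction
#'
#' Peaks are laid out so that exactly a `dhs_dmr_overlap_frac` share of
#' DMRs overlap at least 1 bp of a peak (peaks avoid all other DMRs),
#' and the total peak count is calibrated so that a random
#' length-preserving placement of a DMR within the probe space hits a
#' peak with probability `dhs_cover_frac` (the null rate). Each peak is
#' present in both tissues with probability `dhs_shared_frac`, otherwise
#' in one tissue only.
#'
#' @param config A [sim_config()].
#' @param dmrs DMR tibble from [simulate_methylation_expression()].
#' @param genes Gene tibble.
#' @param chrom_lengths Named integer chromosome lengths.
#' @return List with `peaks_t1`, `peaks_t2`, `peaks` (all peaks with
#'   their planted `tissue_class`), `probe_space` (merged gene windows)
#'   and `truth` (`dmr_id, planted, overlaps_dhs` - the planted flag and
#'   the realized overlap).
#' @export
simulate_dhs <- function(config, dmrs, genes, chrom_lengths = NULL) {
  withr::with_seed(config$seed + 3L, {
    probe_space <- granges_to_tibble(GenomicRanges::reduce(
      as_granges(gene_windows(genes, config$upstream_bp, chrom_lengths))
    ))
    l_bar <- mean(dmrs$end - dmrs$start)
    w_bar <- mean(config$dhs_peak_len_range)
    positions <- sum(pmax(probe_space$end - probe_space$start - l_bar + 1, 0))
    n_peaks <- round(config$dhs_cover_frac * positions / (w_bar + l_bar - 1))
    n_overlap <- round(config$dhs_dmr_overlap_frac * nrow(dmrs))
    if (n_overlap > n_peaks) {
      stop(paste(
        "Planted overlap fraction infeasible: it needs more peaks than",
        "the null coverage rate allows. Lower dhs_dmr_overlap_frac or",
        "raise dhs_cover_frac."
      ))
    }
    chosen <- sort(sample(nrow(dmrs), n_overlap))
    is_chosen <- seq_len(nrow(dmrs)) %in% chosen

    # nearest non-chosen DMR boundaries around each chosen DMR
    srt <- dplyr::arrange(
      dplyr::mutate(dmrs, .row = dplyr::row_number(), .chosen = is_chosen),
      .data$chrom, .data$start
    )
    p_chrom <- character(n_overlap)
    p_start <- integer(n_overlap)
    p_width <- integer(n_overlap)
    pi_ <- 0L
    for (ch in unique(srt$chrom)) {
      sub <- srt[srt$chrom == ch, ]
      nc_start <- sub$start[!sub$.chosen]
      nc_end <- sub$end[!sub$.chosen]
      for (r in which(sub$.chosen)) {
        pi_ <- pi_ + 1L
        s <- sub$start[r]
        e <- sub$end[r]
        w <- runif_len(1, config$dhs_peak_len_range)
        prev_end <- suppressWarnings(max(nc_end[nc_end <= s], 0L))
        next_start <- suppressWarnings(
          min(nc_start[nc_start >= e], Inf)
        )
        lo <- max(s - w + 1L, prev_end, 0L)
        hi <- min(e - 1L, next_start - w)
        if (hi < lo) { # fall back: peak inside the DMR itself
          w <- min(w, e - s)
          lo <- s
          hi <- e - w
        }
        p_chrom[pi_] <- ch
        p_start[pi_] <- as.integer(floor(runif(1, lo, hi + 1)))
        p_width[pi_] <- as.integer(w)
      }
    }
    planted <- tibble::tibble(
      chrom = p_chrom, start = p_start, end = p_start + p_width
    )

    # decoy peaks in DMR-free probe space
    n_decoy <- n_peaks - n_overlap
    decoys <- NULL
    if (n_decoy > 0) {
      occupied <- dplyr::bind_rows(
        dmrs[, c("chrom", "start", "end")],
        planted[, c("chrom", "start", "end")]
      )
      free_gr <- GenomicRanges::setdiff(
        as_granges(probe_space),
        GenomicRanges::reduce(as_granges(occupied))
      )
      free <- granges_to_tibble(free_gr)
      decoys <- place_in_free_space(
        free, runif_len(n_decoy, config$dhs_peak_len_range)
      )
    }
    peaks <- dplyr::bind_rows(planted, decoys)
    shared <- runif(nrow(peaks)) < config$dhs_shared_frac
    t1_only <- !shared & runif(nrow(peaks)) < 0.5
    peaks$tissue_class <- dplyr::case_when(
      shared ~ "shared",
      t1_only ~ "tissue1_specific",
      TRUE ~ "tissue2_specific"
    )
    # honest truth: a planted peak can also graze a neighbouring DMR
    # when gene windows overlap, so record the realized overlap too
    truth <- tibble::tibble(
      dmr_id = dmrs$dmr_id,
      planted = is_chosen,
      overlaps_dhs = IRanges::overlapsAny(
        as_granges(dmrs), as_granges(peaks)
      )
    )
    list(
      peaks_t1 = peaks[peaks$tissue_class != "tissue2_specific",
        c("chrom", "start", "end"),
        drop = FALSE
      ],
      peaks_t2 = peaks[peaks$tissue_class != "tissue1_specific",
        c("chrom", "start", "end"),
        drop = FALSE
      ],
      peaks = peaks,
      probe_space = probe_space,
      truth = truth
    )
  })
}

#' Extract DMR sequences from a genome
#'
#' @param dmrs Tibble with `dmr_id, chrom, start, end`.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @return A `DNAStringSet` named by `dmr_id`.
#' @export
dmr_sequences <- function(dmrs, genome) {
  stopifnot(all(dmrs$chrom %in% names(genome)))
  res <- Biostrings::DNAStringSet(rep("", nrow(dmrs)))
  for (ch in unique(dmrs$chrom)) {
    idx <- which(dmrs$chrom == ch)
    res[idx] <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = dmrs$start[idx] + 1L, end = dmrs$end[idx])
    )
  }
  names(res) <- dmrs$dmr_id
  res
}

#' Plant k-mer motifs into sequences by overwrite
#'
#' Each sequence receives each motif `floor(rate)` times plus one more
#' with probability `rate - floor(rate)`, at uniform positions,
#' overwriting the underlying bases (so sequence lengths are
#' preserved, which the length-matched background sampler depends on).
#' Motifs longer than a target sequence are skipped with a warning.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param motifs Named numeric vector: names are motifs over
#'   `{A,C,G,T}`, values per-sequence insertion rates.
#' @param seed Integer seed.
#' @return List with `seqs` (mutated `DNAStringSet`) and `insertions`
#'   (tibble `seq_name, motif, pos` with 1-based positions).
#' @export
plant_motifs <- function(seqs, motifs, seed = 1L) {
  if (length(motifs) == 0) {
    return(list(
      seqs = Biostrings::DNAStringSet(seqs),
      insertions = tibble::tibble(
        seq_name = character(), motif = character(), pos = integer()
      )
    ))
  }
  stopifnot(!is.null(names(motifs)), all(grepl("^[ACGT]+$", names(motifs))))
  chars <- as.character(seqs)
  nm <- names(chars)
  if (is.null(nm)) nm <- as.character(seq_along(chars))
  ins <- list()
  withr::with_seed(seed, {
    for (mi in seq_along(motifs)) {
      motif <- names(motifs)[mi]
      rate <- motifs[[mi]]
      k <- nchar(motif)
      too_short <- nchar(chars) < k
      n_ins <- floor(rate) + (runif(length(chars)) < (rate %% 1))
      if (any(too_short & n_ins > 0)) {
        warning(sprintf(
          "Skipped motif %s for %d sequence(s) shorter than it.",
          motif, sum(too_short & n_ins > 0)
        ))
      }
      n_ins[too_short] <- 0L
      for (si in which(n_ins > 0)) {
        for (j in seq_len(n_ins[si])) {
          pos <- sample.int(nchar(chars[si]) - k + 1L, 1)
          substr(chars[si], pos, pos + k - 1L) <- motif
          ins[[length(ins) + 1L]] <- tibble::tibble(
            seq_name = nm[si], motif = motif, pos = pos
          )
        }
      }
    }
  })
  insertions <- if (length(ins)) {
    dplyr::bind_rows(ins)
  } else {
    tibble::tibble(
      seq_name = character(), motif = character(), pos = integer()
    )
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- nm
  list(seqs = out, insertions = insertions)
}

#' Generate per-CpG conservation scores with class-dependent shifts
#'
#' Locates CpG dinucleotides in every DMR sequence and assigns each a
#' score drawn from `Normal(mean, cons_sd)` clipped to `[0, 1]`, where
#' the mean is the background level plus the configured shift for the
#' DMR's planted class (positive > negative > background). A
#' length-matched set of random probe-space segments provides the
#' background class.
#'
#' @param config A [sim_config()].
#' @param dmrs DMR tibble.
#' @param truth Truth tibble from [simulate_methylation_expression()].
#' @param genes Gene tibble.
#' @param genome A `DNAStringSet`.
#' @param chrom_lengths Named integer chromosome lengths.
#' @return Tibble `chrom, start, end, score, class` (bedGraph-style, one
#'   row per CpG; DMRs without a CpG contribute no rows).
#' @export
simulate_conservation <- function(config, dmrs, truth, genes, genome,
                                  chrom_lengths = NULL) {
  class_of <- setNames(truth$planted_class, truth$dmr_id)[dmrs$dmr_id]
  shift <- c(
    positive = config$cons_shift_positive,
    negative = config$cons_shift_negative,
    excluded = 0
  )
  withr::with_seed(config$seed + 5L, {
    cpg_rows <- function(tbl, cls) {
      seqs <- dmr_sequences(tbl, genome)
      hits <- Biostrings::vmatchPattern("CG", seqs)
      purrr::map_dfr(seq_along(hits), function(i) {
        st <- IRanges::start(hits[[i]])
        if (length(st) == 0) {
          return(NULL)
        }
        tibble::tibble(
          chrom = tbl$chrom[i],
          start = tbl$start[i] + st - 1L,
          end = tbl$start[i] + st + 1L,
          class = cls[i]
        )
      })
    }
    dmr_cpgs <- cpg_rows(
      dmrs,
      ifelse(class_of %in% c("positive", "negative"), class_of, "background")
    )
    # background: length-matched random probe-space segments
    wins <- gene_windows(genes, config$upstream_bp, chrom_lengths)
    bg <- sample_background(
      genes, genome,
      target_lengths = dmrs$end - dmrs$start,
      multiplier = 1, upstream_bp = config$upstream_bp,
      seed = config$seed + 6L, return_coords = TRUE
    )
    bg_tbl <- tibble::tibble(
      dmr_id = sprintf("bg%05d", seq_len(nrow(bg$coords))),
      chrom = bg$coords$chrom, start = bg$coords$start, end = bg$coords$end
    )
    bg_cpgs <- cpg_rows(bg_tbl, rep("background", nrow(bg_tbl)))
    all_cpgs <- dplyr::bind_rows(dmr_cpgs, bg_cpgs)
    mu <- config$cons_base_mean +
      ifelse(all_cpgs$class %in% names(shift), shift[all_cpgs$class], 0)
    all_cpgs$score <- pmin(pmax(rnorm(nrow(all_cpgs), mu, config$cons_sd), 0), 1)
    all_cpgs[, c("chrom", "start", "end", "score", "class")]
  })
}

#' Generate a random gene-to-term annotation map
#'
#' Random term assignment plus one planted term concentrated in a chosen
#' gene set, for exercising set enrichment end to end.
#'
#' @param genes Gene tibble (the background universe).
#' @param n_terms Number of random terms.
#' @param mean_terms_per_gene Average random annotations per gene.
#' @param planted_term Optional term id planted into `planted_genes`.
#' @param planted_genes Gene ids receiving the planted term.
#' @param planted_bg_frac Fraction of background genes also receiving
#'   the planted term.
#' @param seed Integer seed.
#' @return Tibble `gene_id, term_id, term_name`.
#' @export
simulate_gene2go <- function(genes, n_terms = 30, mean_terms_per_gene = 3,
                             planted_term = NULL, planted_genes = character(),
                             planted_bg_frac = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    n_annot <- stats::rpois(nrow(genes), mean_terms_per_gene)
    rows <- tibble::tibble(
      gene_id = rep(genes$gene_id, n_annot),
      term_id = sprintf("T%04d", sample.int(n_terms, sum(n_annot), replace = TRUE))
    )
    if (!is.null(planted_term)) {
      bg_extra <- genes$gene_id[runif(nrow(genes)) < planted_bg_frac]
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        gene_id = unique(c(planted_genes, bg_extra)),
        term_id = planted_term
      ))
    }
    rows <- dplyr::distinct(rows)
    rows$term_name <- rows$term_id
    rows
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper chaining gene layout, genome sequence, DMR /
#' expression / truth generation, DHS tracks, DMR sequence extraction
#' with motif planting, and conservation scores.
#'
#' @param config A [sim_config()].
#' @param sequences If `FALSE`, skip everything requiring the genome
#'   sequence (faster; `dmr_seqs`, `conservation` and motif planting are
#'   then omitted).
#' @return Named list: `config, genes, chrom_lengths, dmrs, expression,
#'   truth, enhancers, dhs` plus, with sequences, `genome, dmr_seqs,
#'   motif_insertions, conservation`.
#' @export
simulate_tdmr_study <- function(config = sim_config(), sequences = TRUE) {
  gg <- simulate_genome_and_genes(config, sequences = sequences)
  me <- simulate_methylation_expression(config, gg$genes, gg$chrom_lengths)
  dhs <- simulate_dhs(config, me$dmrs, gg$genes, gg$chrom_lengths)
  out <- c(list(config = config), gg, me, list(dhs = dhs))
  if (sequences) {
    seqs <- dmr_sequences(me$dmrs, gg$genome)
    cls <- setNames(me$truth$planted_class, me$truth$dmr_id)[names(seqs)]
    pos <- plant_motifs(
      seqs[cls == "positive"], config$planted_motifs_pos,
      seed = config$seed + 7L
    )
    neg <- plant_motifs(
      seqs[cls == "negative"], config$planted_motifs_neg,
      seed = config$seed + 8L
    )
    seqs[cls == "positive"] <- pos$seqs
    seqs[cls == "negative"] <- neg$seqs
    out$dmr_seqs <- seqs
    out$motif_insertions <- dplyr::bind_rows(pos$insertions, neg$insertions)
    out$conservation <- simulate_conservation(
      config, me$dmrs, me$truth, gg$genes, gg$genome, gg$chrom_lengths
    )
  }
  out
}
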