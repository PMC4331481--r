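cfg_small <- sim_config(
  n_genes = 120, n_dmrs = 100, n_chroms = 1, frac_distal = 0.1, seed = 42
)

test_that("the generator is fully deterministic given the config", {
  a <- simulate_tdmr_study(cfg_small, sequences = TRUE)
  b <- simulate_tdmr_study(cfg_small, sequences = TRUE)
  expect_identical(a$genes, b$genes)
  expect_identical(a$dmrs, b$dmrs)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$dmr_seqs), as.character(b$dmr_seqs))
  expect_identical(a$dhs, b$dhs)
  expect_identical(a$conservation, b$conservation)
})

test_that("gene layout respects length ranges and alternates strand", {
  cfg <- sim_config(
    n_genes = 60, gene_len_range = c(1000, 1000), n_dmrs = 50, seed = 2
  )
  gg <- simulate_genes(cfg)
  expect_true(all(gg$genes$end - gg$genes$start == 1000))
  expect_equal(sum(gg$genes$strand == "-") / 60, 0.5)
  # genes non-overlapping per chromosome
  by_chrom <- split(gg$genes, gg$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # exons sorted, non-overlapping, inside the gene
  for (i in seq_len(nrow(gg$genes))) {
    ex <- gg$genes$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
    expect_gte(min(ex$start), gg$genes$start[i])
    expect_lte(max(ex$end), gg$genes$end[i])
  }
})

test_that("genome sequence matches chromosome lengths and GC target", {
  cfg <- sim_config(n_genes = 40, n_dmrs = 30, gc_content = 0.6, seed = 9)
  gg <- simulate_genes(cfg)
  genome <- simulate_genome(cfg, gg$chrom_lengths)
  expect_equal(unname(Biostrings::width(genome)), unname(gg$chrom_lengths))
  gc <- sum(Biostrings::letterFrequency(genome, "GC")) /
    sum(Biostrings::width(genome))
  expect_equal(gc, 0.6, tolerance = 0.02)
})

test_that("planted sign classes follow frac_positive and the floors hold", {
  cfg <- sim_config(
    n_genes = 2400, n_dmrs = 2500, frac_positive = 0.34,
    frac_inactive = 0, frac_distal = 0, seed = 7
  )
  gg <- simulate_genes(cfg)
  me <- simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths)
  frac_pos <- mean(me$truth$planted_class == "positive")
  # binomial expectation 0.34 * 2500, sd ~ 0.0095
  expect_equal(frac_pos, 0.34, tolerance = 0.1)
  expect_true(all(abs(me$dmrs$delta_m) >= 0.1))
  expect_true(all(me$dmrs$m_tissue1 >= 0 & me$dmrs$m_tissue1 <= 1))
  informative <- me$truth$planted_class != "excluded"
  expect_true(all(abs(me$truth$true_delta_e[informative]) >= log2(1.25)))
  expect_true(all(abs(me$truth$true_delta_e[!informative]) < log2(1.25)))
  # planted sign relation holds in the truth table
  concordant <- sign(me$truth$delta_m) == sign(me$truth$true_delta_e)
  expect_true(all(concordant[me$truth$planted_class == "positive"]))
  expect_true(all(!concordant[me$truth$planted_class == "negative"]))
})

test_that("frac_positive = 1 plants only concordant informative pairs", {
  cfg <- sim_config(
    n_genes = 100, n_dmrs = 80, frac_positive = 1,
    frac_inactive = 0, coherence_bias = 1, seed = 3
  )
  gg <- simulate_genes(cfg)
  me <- simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths)
  expect_true(all(me$truth$planted_class == "positive"))
})

test_that("zero replicate noise reproduces the true delta_e exactly", {
  cfg <- sim_config(n_genes = 100, n_dmrs = 80, rep_noise_sd = 0, seed = 4)
  gg <- simulate_genes(cfg)
  me <- simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths)
  joined <- dplyr::inner_join(
    me$truth, me$expression,
    by = "gene_id"
  )
  expect_equal(joined$delta_e, joined$true_delta_e, tolerance = 1e-12)
})

test_that("replicate counts follow the configuration", {
  cfg <- sim_config(n_genes = 50, n_dmrs = 30, n_reps_t1 = 4, n_reps_t2 = 2, seed = 5)
  gg <- simulate_genes(cfg)
  me <- simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths)
  expect_true(all(lengths(me$expression$log2_reps_tissue1) == 4))
  expect_true(all(lengths(me$expression$log2_reps_tissue2) == 2))
})

test_that("DMRs land in their gene's strand-aware window", {
  cfg <- sim_config(n_genes = 150, n_dmrs = 120, frac_distal = 0, seed = 6)
  gg <- simulate_genes(cfg)
  me <- simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths)
  g <- gg$genes[match(me$truth$gene_id, gg$genes$gene_id), ]
  win_start <- ifelse(g$strand == "+", g$start - 4000, g$start)
  win_end <- ifelse(g$strand == "+", g$end, g$end + 4000)
  expect_true(all(me$dmrs$start >= pmax(win_start, 0)))
  expect_true(all(me$dmrs$end <= win_end))
})

test_that("DHS planting hits the overlap target and respects its truth table", {
  sim <- simulate_tdmr_study(
    sim_config(n_genes = 600, n_dmrs = 500, seed = 8),
    sequences = FALSE
  )
  ov <- IRanges::overlapsAny(
    tdmr:::as_granges(sim$dmrs), tdmr:::as_granges(sim$dhs$peaks)
  )
  expect_equal(ov, sim$dhs$truth$overlaps_dhs)
  expect_equal(mean(sim$dhs$truth$planted), 0.18, tolerance = 0.001)
  expect_equal(mean(ov), 0.18, tolerance = 0.1)
  # zero planted overlap -> no DMR touches a peak
  sim0 <- simulate_tdmr_study(
    sim_config(n_genes = 300, n_dmrs = 200, dhs_dmr_overlap_frac = 0, seed = 9),
    sequences = FALSE
  )
  expect_false(any(IRanges::overlapsAny(
    tdmr:::as_granges(sim0$dmrs), tdmr:::as_granges(sim0$dhs$peaks)
  )))
  # all-shared configuration classifies every peak shared
  sim1 <- simulate_tdmr_study(
    sim_config(n_genes = 300, n_dmrs = 200, dhs_shared_frac = 1, seed = 10),
    sequences = FALSE
  )
  expect_true(all(sim1$dhs$peaks$tissue_class == "shared"))
})

test_that("motif planting follows rates and overwrites in place", {
  seqs <- Biostrings::DNAStringSet(setNames(
    strrep("A", c(100, 100, 100, 3)), c("s1", "s2", "s3", "tiny")
  ))
  none <- plant_motifs(seqs, c(ACGTAC = 0))
  expect_identical(as.character(none$seqs), as.character(seqs))
  expect_equal(nrow(none$insertions), 0)

  expect_warning(
    full <- plant_motifs(seqs, c(ACGTAC = 1)),
    "shorter"
  )
  expect_equal(nrow(full$insertions), 3) # one per long sequence
  expect_identical(Biostrings::width(full$seqs), Biostrings::width(seqs))
  counts <- Biostrings::vcountPattern("ACGTAC", full$seqs)
  expect_equal(sum(counts >= 1), 3)
  expect_equal(as.character(full$seqs[["tiny"]]), "AAA")
})

test_that("conservation scores are clipped and shifted by class", {
  cfg <- sim_config(
    n_genes = 200, n_dmrs = 150, frac_distal = 0,
    cons_shift_positive = 0.3, cons_shift_negative = 0.1, seed = 11
  )
  sim <- simulate_tdmr_study(cfg, sequences = TRUE)
  cons <- sim$conservation
  expect_true(all(cons$score >= 0 & cons$score <= 1))
  expect_setequal(
    unique(cons$class), c("positive", "negative", "background")
  )
  mu <- tapply(cons$score, cons$class, mean)
  expect_gt(mu[["positive"]], mu[["negative"]])
  expect_gt(mu[["negative"]], mu[["background"]])
})

test_that("infeasible configurations fail loudly", {
  expect_error(sim_config(frac_positive = 1.5), "in \\[0,1\\]")
  expect_error(sim_config(dmr_len_range = c(500, 200)), "non-decreasing")
  expect_error(
    sim_config(planted_motifs_pos = c(0.5)), "named"
  )
  cfg <- sim_config(n_genes = 10, n_dmrs = 100, frac_multi_dmr_genes = 0, seed = 1)
  gg <- simulate_genes(cfg)
  expect_error(
    simulate_methylation_expression(cfg, gg$genes, gg$chrom_lengths),
    "More DMRs"
  )
  expect_error(
    {
      cfg2 <- sim_config(
        n_genes = 300, n_dmrs = 250,
        dhs_cover_frac = 0.01, dhs_dmr_overlap_frac = 0.9, seed = 1
      )
      gg2 <- simulate_genes(cfg2)
      me2 <- simulate_methylation_expression(cfg2, gg2$genes, gg2$chrom_lengths)
      simulate_dhs(cfg2, me2$dmrs, gg2$genes, gg2$chrom_lengths)
    },
    "infeasible"
  )
})
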