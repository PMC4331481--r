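test_that("proximal assignment uses the strand-aware upstream window", {
  genes <- toy_genes() # gA: + strand, TSS 10000; gB: - strand, TSS 1999
  # 3 kb upstream of gA's TSS -> paired; >4 kb upstream -> not
  dmrs <- toy_dmrs(
    starts = c(7000, 5000, 2500, 12000),
    ends = c(7200, 5500, 2600, 12100)
  )
  pairs <- assign_proximal(dmrs, genes)
  expect_setequal(
    paste(pairs$dmr_id, pairs$gene_id),
    c("d01 gA", "d02 gB", "d03 gB", "d04 gA")
  )
  # d02 (>4 kb upstream of gA) pairs with nothing via gA, but falls in
  # the minus-strand gB window [1000, 6000) (upstream is rightward)
  expect_false(any(pairs$dmr_id == "d02" & pairs$gene_id == "gA"))
  expect_true(all(pairs$proximity == "proximal"))
  # a DMR overlapping two windows yields two pairs
  wide <- toy_dmrs(starts = 1500, ends = 11000)
  expect_equal(nrow(assign_proximal(wide, genes)), 2)
  # reflection invariance: flip coordinates and strands
  span <- 30000L
  genes_flip <- genes |>
    dplyr::mutate(
      start2 = span - .data$end, end2 = span - .data$start,
      strand = ifelse(.data$strand == "+", "-", "+"),
      exons = purrr::map(.data$exons, function(e) {
        tibble::tibble(start = span - rev(e$end), end = span - rev(e$start))
      })
    ) |>
    dplyr::mutate(start = .data$start2, end = .data$end2) |>
    dplyr::select(-"start2", -"end2")
  genes_flip <- tdmr:::add_tss(genes_flip)
  dmrs_flip <- dmrs |>
    dplyr::mutate(
      start2 = span - .data$end, end2 = span - .data$start,
      start = .data$start2, end = .data$end2
    ) |>
    dplyr::select(-"start2", -"end2")
  pairs_flip <- assign_proximal(dmrs_flip, genes_flip)
  expect_setequal(
    paste(pairs$dmr_id, pairs$gene_id),
    paste(pairs_flip$dmr_id, pairs_flip$gene_id)
  )
})

test_that("distal assignment pairs via enhancers without duplicating proximal", {
  dmrs <- toy_dmrs(starts = c(100, 5000), ends = c(300, 5100))
  enh <- tibble::tibble(
    chrom = "chr1",
    start = c(150, 200, 90),
    end = c(250, 260, 120),
    target_gene_id = c("gX", "gY", "gX")
  )
  pairs <- assign_distal(dmrs, enh)
  # d01 overlaps all three enhancers but only two distinct targets
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$gene_id, c("gX", "gY"))
  expect_true(all(pairs$proximity == "distal"))

  # unknown targets dropped with warning
  expect_warning(
    known <- assign_distal(dmrs, enh, known_genes = "gX"),
    "no expression"
  )
  expect_equal(unique(known$gene_id), "gX")

  # existing proximal pair suppresses the distal duplicate
  prox <- tibble::tibble(
    dmr_id = "d01", gene_id = "gX",
    proximity = "proximal", delta_m = 0.2
  )
  dedup <- assign_distal(dmrs, enh, proximal_pairs = prox)
  expect_setequal(dedup$gene_id, "gY")

  # no overlap, no pairs
  far <- toy_dmrs(starts = 9000, ends = 9100)
  expect_equal(nrow(assign_distal(far, enh)), 0)
})

test_that("sign classification follows the sign rule and the delta_e filter", {
  pairs <- tibble::tibble(
    dmr_id = sprintf("d%d", 1:4),
    gene_id = c("g1", "g2", "g3", "g4"),
    proximity = "proximal",
    delta_m = c(0.2, 0.2, 0.2, 0)
  )
  expr <- expression_records(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2_reps_tissue1 = list(c(2, 2), c(0, 0), log2(1.2), 1),
    log2_reps_tissue2 = list(c(1, 1), c(1, 1), 0, 0)
  )
  cls <- classify_sign(pairs, expr)
  expect_equal(cls$sign_class, c("positive", "negative", "excluded", "excluded"))
  # |delta_e| exactly at the threshold is excluded
  at <- classify_sign(
    pairs[1, ],
    expression_records("g1", list(log2(1.25)), list(0))
  )
  expect_equal(at$sign_class, "excluded")
})

test_that("fractions sum to one over non-excluded pairs and dedup by majority", {
  pairs <- tibble::tibble(
    dmr_id = c("d1", "d1", "d1", "d2", "d2", "d3"),
    gene_id = paste0("g", 1:6),
    proximity = "proximal",
    delta_m = 0.3,
    delta_e = c(1, 1, -1, 1, -1, -2),
    sign_class = c(
      "positive", "positive", "negative",
      "positive", "negative", "negative"
    )
  )
  s <- sign_fraction_summary(pairs)
  pair_rows <- s[s$unit == "pairs" & s$sign_class != "excluded", ]
  expect_equal(sum(pair_rows$fraction), 1)
  uniq <- s[s$unit == "unique_dmrs", ]
  # d1 majority positive, d2 tied (dropped), d3 negative
  expect_equal(uniq$n[uniq$sign_class == "positive"], 1)
  expect_equal(uniq$n[uniq$sign_class == "negative"], 1)
})

test_that("shuffle null converges to the closed-form concordance rate", {
  # balanced independent signs: expected positive fraction p*q+(1-p)(1-q) = 0.5
  set.seed(1)
  n <- 400
  pairs <- tibble::tibble(
    dmr_id = sprintf("d%03d", 1:n),
    gene_id = sprintf("g%03d", 1:n),
    proximity = "proximal",
    delta_m = sample(c(-0.3, 0.3), n, replace = TRUE),
    delta_e = sample(c(-1, 1), n, replace = TRUE)
  )
  pairs$sign_class <- tdmr:::sign_class_of(pairs$delta_m, pairs$delta_e, log2(1.25))
  sf <- shuffle_expected_sign_fractions(pairs, n_shuffles = 3000, seed = 5)
  expect_equal(
    sf$expected_fraction[sf$sign_class == "positive"], 0.5,
    tolerance = 0.01
  )
  # unbalanced marginals: p = 1 (all delta_m positive), q = mean(delta_e > 0)
  pairs2 <- dplyr::mutate(pairs, delta_m = abs(.data$delta_m))
  q <- mean(pairs2$delta_e > 0)
  sf2 <- shuffle_expected_sign_fractions(pairs2, n_shuffles = 500, seed = 5)
  expect_equal(
    sf2$expected_fraction[sf2$sign_class == "positive"], q,
    tolerance = 1e-12
  )
  # determinism
  sf3 <- shuffle_expected_sign_fractions(pairs, n_shuffles = 100, seed = 7)
  sf4 <- shuffle_expected_sign_fractions(pairs, n_shuffles = 100, seed = 7)
  expect_identical(sf3, sf4)
})

test_that("all delta_m and delta_e positive gives expected positive fraction 1", {
  pairs <- tibble::tibble(
    dmr_id = c("d1", "d2"), gene_id = c("g1", "g2"),
    proximity = "proximal", delta_m = c(0.2, 0.4), delta_e = c(1, 2),
    sign_class = "positive"
  )
  sf <- shuffle_expected_sign_fractions(pairs, n_shuffles = 50, seed = 1)
  expect_equal(sf$expected_fraction[sf$sign_class == "positive"], 1)
  expect_error(
    shuffle_expected_sign_fractions(
      dplyr::mutate(pairs, delta_e = 0.1), # all filtered out
      n_shuffles = 10, seed = 1
    ),
    "non-excluded"
  )
})

test_that("GO enrichment reproduces the exact hypergeometric example", {
  background <- sprintf("g%02d", 1:20)
  gene_set <- background[1:10]
  # one term annotated to 5 background genes, all inside the set
  g2t <- tibble::tibble(
    gene_id = c(background[1:5], background),
    term_id = c(rep("T_hit", 5), rep("T_all", 20))
  )
  res <- go_enrichment(gene_set, background, g2t, min_term_genes = 5)
  hit <- res[res$term_id == "T_hit", ]
  expect_equal(hit$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(hit$k, 5)
  expect_equal(hit$ratio, (5 / 10) / (5 / 20))
  # a term in every background gene: ratio 1, p = 1
  all_term <- res[res$term_id == "T_all", ]
  expect_equal(all_term$ratio, 1)
  expect_equal(all_term$p, 1)
  # Bonferroni over the 2 tested terms
  expect_equal(hit$p_corrected, min(1, hit$p * 2))
  # empty set and subset violations
  expect_equal(nrow(go_enrichment(character(0), background, g2t)), 0)
  expect_error(go_enrichment("not_there", background, g2t), "subset")
  # small terms are not tested
  g2t_small <- tibble::tibble(gene_id = background[1:3], term_id = "T_small")
  expect_equal(nrow(go_enrichment(gene_set, background, g2t_small)), 0)
})

test_that("sign recovery is exact on noise-free synthetic data", {
  cfg <- sim_config(
    n_genes = 500, n_dmrs = 400, rep_noise_sd = 0, frac_distal = 0, seed = 20
  )
  sim <- simulate_tdmr_study(cfg, sequences = FALSE)
  pairs <- classify_sign(
    assign_proximal(sim$dmrs, sim$genes), sim$expression
  )
  joined <- dplyr::inner_join(
    pairs, sim$truth,
    by = c("dmr_id", "gene_id"), suffix = c("", ".truth")
  )
  expect_equal(nrow(joined), nrow(sim$truth)) # every planted pair recovered
  expect_equal(joined$sign_class, joined$planted_class)
})
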