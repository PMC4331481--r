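test_that("location categories follow midpoint precedence rules", {
  genes <- toy_genes() # gA + strand [10000,20000), exons [10000,11000) [15000,16000)
  dmrs <- toy_dmrs(
    starts = c(10400, 12000, 7000, 21000, 28000, 2500),
    ends = c(10600, 12200, 7400, 21400, 28400, 2700)
  )
  out <- categorize_location(dmrs, genes)
  expect_equal(
    out$category,
    c("exon", "intron", "upstream", "downstream", "intergenic", "upstream")
  )
  # midpoint in an intron of gA while within 4 kb upstream of another
  # gene: gene body wins
  genes2 <- dplyr::bind_rows(genes, tdmr:::add_tss(tibble::tibble(
    gene_id = "gC", chrom = "chr1", start = 14000L, end = 15000L,
    strand = "+",
    exons = list(tibble::tibble(start = 14000L, end = 15000L))
  )))
  mid_intron <- toy_dmrs(starts = 12500, ends = 12700)
  expect_equal(categorize_location(mid_intron, genes2)$category, "intron")
  # totality: every DMR gets exactly one label
  expect_false(any(is.na(out$category)))
})

test_that("location distribution comparison reports proportions and p-values", {
  identical_set <- rep(c("exon", "intron"), c(30, 70))
  cmp_same <- location_distribution_compare(identical_set, identical_set)
  expect_true(all(cmp_same$p >= 0.5))
  expect_equal(cmp_same$prop_pos, cmp_same$prop_neg)
  # absent category reports zero proportions and p = 1
  cmp_abs <- location_distribution_compare(
    identical_set, identical_set,
    levels = c("exon", "intron", "downstream")
  )
  down <- cmp_abs[cmp_abs$category == "downstream", ]
  expect_equal(down$prop_pos, 0)
  expect_equal(down$p, 1)
  # a planted 15% vs 10% upstream excess is detected with direction
  set.seed(4)
  pos <- c(rep("upstream", 1500), rep("intron", 8500))
  neg <- c(rep("upstream", 1000), rep("intron", 9000))
  cmp <- location_distribution_compare(pos, neg)
  up <- cmp[cmp$category == "upstream", ]
  expect_gt(up$prop_pos, up$prop_neg)
  expect_lt(up$p, 1e-10)
})

test_that("DHS calling enforces the k-of-n replicate rule and tissue classes", {
  peak <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  # region covered by 2 of 7 replicates with k = 3 is not a DHS
  reps_t1 <- c(
    lapply(1:2, function(i) peak(100, 200)),
    lapply(1:5, function(i) peak(5000, 5100))
  )
  reps_t2 <- list(peak(5050, 5150))
  out <- classify_dhs(reps_t1, reps_t2, min_reps_t1 = 3, min_reps_t2 = 1)
  expect_false(any(out$start == 100))
  expect_true(all(c("shared") %in% out$tissue_class))
  # same locus in both tissues -> shared (merged); t1-only -> specific
  out2 <- classify_dhs(
    dplyr::bind_rows(peak(100, 200), peak(1000, 1100)),
    peak(150, 250)
  )
  expect_equal(
    out2$tissue_class[out2$start == 100], "shared"
  )
  expect_equal(out2$end[out2$start == 100], 250) # merged shared region
  expect_equal(
    out2$tissue_class[out2$start == 1000], "tissue1_specific"
  )
  expect_error(classify_dhs(peak(1, 2), peak(1, 2), min_reps_t1 = 2), "min_reps")
})

test_that("DHS overlap enrichment handles saturating and empty peak sets", {
  space <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L)
  dmrs <- toy_dmrs(
    starts = seq(1000, 50000, by = 1000),
    ends = seq(1000, 50000, by = 1000) + 200
  )
  # DHS covering the whole space: observed = expected = 1
  full <- dhs_overlap_enrichment(
    dmrs, space, space,
    n_shuffles = 20, seed = 1
  )
  expect_equal(full$observed_fraction, 1)
  expect_equal(full$expected_fraction, 1)
  # no peaks: observed 0, p = 1 for enrichment
  none <- dhs_overlap_enrichment(
    dmrs, tibble::tibble(chrom = character(), start = integer(), end = integer()),
    space,
    n_shuffles = 20, seed = 1
  )
  expect_equal(none$observed_fraction, 0)
  expect_equal(none$p, 1)
  # probe space shorter than the longest DMR is a config error
  expect_error(
    dhs_overlap_enrichment(
      dmrs, space, tibble::tibble(chrom = "chr1", start = 0L, end = 100L),
      n_shuffles = 5, seed = 1
    ),
    "long enough"
  )
})

test_that("random placement expectation matches the analytic probability", {
  # single peak of width W in a homogeneous space: an interval of
  # length L placed uniformly overlaps with probability (W + L - 1) /
  # (S - L + 1)
  space <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L)
  peak <- tibble::tibble(chrom = "chr1", start = 100000L, end = 102000L)
  L <- 500L
  dmrs <- toy_dmrs(starts = seq(0, 990 * 200, by = 200), ends = seq(0, 990 * 200, by = 200) + L)
  enr <- dhs_overlap_enrichment(dmrs, peak, space, n_shuffles = 400, seed = 2)
  analytic <- (2000 + L - 1) / (200000 - L + 1)
  expect_equal(enr$expected_fraction, analytic, tolerance = 0.08)
})

test_that("conservation ECDFs detect stochastic shifts and normalize", {
  all_half <- conservation_ecdf(list(a = rep(0.5, 10)))
  expect_equal(all_half$ecdf[all_half$score < 0.5], rep(0, sum(all_half$score < 0.5)))
  expect_equal(all_half$ecdf[all_half$score >= 0.5], rep(1, sum(all_half$score >= 0.5)))
  expect_equal(all_half$ecdf[all_half$score == 1], 1)

  set.seed(8)
  a <- runif(2000, 0, 0.7)
  b <- pmin(a + 0.2, 1) # shifted class is more conserved
  ec <- conservation_ecdf(list(a = a, b = b))
  wide <- tidyr::pivot_wider(ec, names_from = "class", values_from = "ecdf")
  expect_true(all(wide$b <= wide$a + 1e-12)) # b pointwise below a
  expect_warning(
    conservation_ecdf(list(a = a, empty = numeric(0))),
    "empty"
  )
})

test_that("CpG observed/expected ratio counts overlapping CG dinucleotides", {
  expect_equal(cpg_ratio("CGCG"), 2) # 2 CGs, nC = nG = 2, L = 4
  expect_equal(cpg_ratio("CATG"), 0)
  expect_true(is.na(cpg_ratio("ATAT"))) # undefined: nC * nG = 0
  expect_warning(r <- cpg_ratio("ACGNN"), "Non-ACGT")
  expect_equal(r, (1 * 3) / (1 * 1))
  expect_error(cpg_ratio("A"), "2 bases")
  # reverse-complement invariance when nC == nG (CG is its own
  # reverse-complement pattern)
  seqs <- c("ACGCGT", "TTCGAA", "CCGGCG")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  expect_equal(cpg_ratio(seqs), cpg_ratio(rc))
  # vectorized input
  expect_equal(length(cpg_ratio(seqs)), 3)
})
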