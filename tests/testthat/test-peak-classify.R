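test_that("overlap pairs respect half-open boundaries and match the oracle", {
  a <- data.frame(chrom = "chr1", start = 10, end = 20)
  b <- data.frame(chrom = "chr1", start = 20, end = 30)
  expect_equal(nrow(find_overlap_pairs(a, b)), 0L)    # touching, no overlap
  b2 <- data.frame(chrom = "chr1", start = 19, end = 30)
  expect_equal(nrow(find_overlap_pairs(a, b2)), 1L)
  # different chromosomes never overlap
  b3 <- data.frame(chrom = "chr2", start = 10, end = 20)
  expect_equal(nrow(find_overlap_pairs(a, b3)), 0L)

  # 500 random intervals per set vs the O(n^2) all-pairs oracle
  ra <- random_intervals(500, seed = 41)
  rb <- random_intervals(500, seed = 42)
  got <- find_overlap_pairs(ra, rb)
  got <- got[order(got$query, got$subject), ]
  oracle <- brute_force_overlaps(ra, rb)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)))

  expect_error(find_overlap_pairs(
    data.frame(chrom = "chr1", start = 30, end = 10), ra), "malformed")
})

test_that("overlap results are invariant to within-chromosome input order", {
  ra <- random_intervals(200, seed = 43)
  rb <- random_intervals(200, seed = 44)
  shuf <- ra[sample(nrow(ra)), ]
  n1 <- nrow(find_overlap_pairs(ra, rb))
  n2 <- nrow(find_overlap_pairs(shuf, rb))
  expect_equal(n1, n2)
})

test_that("F1 peak classification partitions by parental overlap", {
  pa <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600))
  pb <- data.frame(chrom = "chr1", start = c(1000, 550), end = c(1100, 650))
  f1 <- data.frame(chrom = "chr1",
                   start = c(150, 1050, 560, 5000),
                   end = c(160, 1060, 590, 5100))
  res <- classify_f1_peaks(f1, pa, pb)
  expect_equal(res$class, c("alleleA", "alleleB", "shared", "novel"))
  expect_equal(sum(res$counts), 4L)
  expect_equal(sum(res$fractions), 1)
  # folding shared into either allele preserves the total
  expect_equal(sum(res$fractions_shared_to_A) + res$fractions[["novel"]], 1)
  expect_equal(res$fractions_shared_to_A[["alleleA"]], 0.5)
  expect_equal(res$fractions_shared_to_B[["alleleB"]], 0.5)

  # F1 identical to parent A, parent B empty -> all alleleA
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  res2 <- classify_f1_peaks(pa, pa, empty)
  expect_true(all(res2$class == "alleleA"))
  expect_equal(res2$fractions[["alleleA"]], 1)
})

test_that("classification recovers generative ownership on model landscapes", {
  cfg <- landscape_sim_config(400, total_protein = 2,
                              detection_threshold = 0.3, seed = 51)
  f1 <- make_hotspot_landscape(cfg, "het")
  pa <- make_hotspot_landscape(cfg, "hom_A")
  pb <- make_hotspot_landscape(cfg, "hom_B")
  res <- classify_f1_peaks(f1$detected, pa$detected, pb$detected)
  truth_allele <- f1$detected$owning_allele
  # sites are laid out non-overlapping, so no F1 peak can be shared
  expect_true(all(res$class %in% c("alleleA", "alleleB", "novel")))
  mapped <- ifelse(res$class == "alleleA", "A",
                   ifelse(res$class == "alleleB", "B", NA))
  non_novel <- res$class != "novel"
  expect_true(any(non_novel))
  expect_equal(mapped[non_novel], truth_allele[non_novel])
  # F1 (half dose per allele) peaks all persist in the matching parent
  expect_equal(sum(res$class == "novel"), 0L)
})

test_that("unique peaks equal the complement of the overlap pairs", {
  ra <- random_intervals(300, seed = 45)
  rb <- random_intervals(300, seed = 46)
  uq <- unique_peaks(ra, rb)
  oracle_idx <- setdiff(seq_len(nrow(ra)), brute_force_overlaps(ra, rb)$query)
  expect_equal(length(uq), length(oracle_idx))
  # identical sets -> empty; disjoint sets -> whole first set
  expect_equal(length(unique_peaks(ra, ra)), 0L)
  far <- ra; far$start <- far$start + 1e7; far$end <- far$end + 1e7
  expect_equal(length(unique_peaks(ra, far)), nrow(ra))
})

test_that("dose-titration peak sets show containment and level enrichment", {
  cfg <- landscape_sim_config(500, total_protein = 1,
                              detection_threshold = 0.4, seed = 52)
  full <- make_hotspot_landscape(cfg, "hom_A")
  cfg_half <- landscape_sim_config(500, total_protein = 0.5,
                                   detection_threshold = 0.4, seed = 52)
  half <- make_hotspot_landscape(cfg_half, "hom_A")
  rep <- subset_and_level_report(half$detected, full$detected)
  expect_equal(rep$containment_fraction, 1.0)
  expect_lt(rep$n_low, rep$n_full)
  # peaks retained at half dose have higher full-dose signal than lost ones
  expect_gt(rep$score_quantiles_retained[["50%"]],
            rep$score_quantiles_lost[["50%"]])
  expect_error(
    subset_and_level_report(
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0)),
      full$detected),
    "empty")
})
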