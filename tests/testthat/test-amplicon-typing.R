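test_that("demultiplexing matches a literal string-comparison oracle", {
  assay <- fixture_assay(3L)
  bcs <- names(assay$barcode_map)
  mols <- molecule_table(
    barcode = c(rep(bcs[1], 4), rep(bcs[2], 3), rep(bcs[3], 2), "NNNNNNNN"),
    left = rep("A", 10), right = rep("C", 10))
  out <- demultiplex(mols, assay)
  # oracle: exact string equality against the map
  oracle <- vapply(mols$barcode, function(b) {
    hit <- which(bcs == b)
    if (length(hit)) unname(assay$barcode_map[hit]) else "unassigned"
  }, character(1), USE.NAMES = FALSE)
  expect_identical(out$sample, oracle)
  expect_equal(unname(table(out$sample)[c("mouse1", "mouse2", "mouse3", "unassigned")]),
               c(4L, 3L, 2L, 1L), ignore_attr = TRUE)
  # partition conserves molecules
  expect_equal(nrow(out), nrow(mols))

  # all barcodes absent from the map -> all unassigned
  alien <- molecule_table(rep("CCCCCCCC", 5), rep("A", 5), rep("C", 5))
  expect_true(all(demultiplex(alien, assay)$sample == "unassigned"))

  # empty input -> empty partition
  empty <- molecule_table(character(0), character(0), character(0))
  expect_equal(nrow(demultiplex(empty, assay)), 0L)

  expect_error(hotspot_assay("x", c(ACGTACGT = "a", ACGTACGT = "b"),
                             c(A = "A", B = "G"), c(A = "C", B = "T")),
               "duplicate")
})

test_that("molecule classification follows the flank-allele definition table", {
  assay <- fixture_assay(1L)   # left A/G, right C/T
  expect_equal(classify_molecules("A", "C", assay), "parental_A")
  expect_equal(classify_molecules("G", "T", assay), "parental_B")
  expect_equal(classify_molecules("A", "T", assay), "crossover_AB")
  expect_equal(classify_molecules("G", "C", assay), "crossover_BA")
  # base matching neither haplotype -> ambiguous, whatever the other flank
  expect_equal(classify_molecules(c("C", "A", "N"), c("C", "N", "T"), assay),
               rep("ambiguous", 3))
})

test_that("class counts equal the truth table exactly when chimeras are off", {
  assay <- fixture_assay(1L)
  cfg <- sperm_sim_config(5000, true_cM = 4, chimera_prob = 0,
                          barcode = names(assay$barcode_map)[1], seed = 31)
  sim <- make_sperm_molecules(cfg, assay)
  counts <- count_classes(demultiplex(sim$molecules, assay), assay)
  truth <- table(factor(sim$truth$true_class,
                        levels = c("parental_A", "parental_B",
                                   "crossover_AB", "crossover_BA")))
  expect_equal(counts$n_parental_A, unname(truth["parental_A"]), ignore_attr = TRUE)
  expect_equal(counts$n_parental_B, unname(truth["parental_B"]), ignore_attr = TRUE)
  expect_equal(counts$n_crossover_AB, unname(truth["crossover_AB"]), ignore_attr = TRUE)
  expect_equal(counts$n_crossover_BA, unname(truth["crossover_BA"]), ignore_attr = TRUE)
  expect_equal(counts$n_ambiguous, 0L)

  # permuting input order leaves counts unchanged
  perm <- sim$molecules[rev(seq_len(nrow(sim$molecules))), ]
  expect_equal(count_classes(demultiplex(perm, assay), assay), counts)

  # single molecule -> exactly one nonzero class cell
  one <- molecule_table(names(assay$barcode_map)[1], "A", "T")
  c1 <- count_classes(demultiplex(one, assay), assay)
  expect_equal(c1$n_crossover_AB, 1L)
  expect_equal(c1$n_informative, 1L)
  expect_equal(c1$n_parental_A + c1$n_parental_B + c1$n_crossover_BA +
                 c1$n_ambiguous, 0L)
})

test_that("rate arithmetic, background floor and CI behave as defined", {
  mk <- function(co, n) data.frame(sample = "s", n_parental_A = (n - co) %/% 2,
                                   n_parental_B = n - co - (n - co) %/% 2,
                                   n_crossover_AB = co, n_crossover_BA = 0L,
                                   n_ambiguous = 0L, n_informative = n)
  # 0 of 10,000
  r0 <- estimate_rate(mk(0L, 10000L))
  expect_equal(r0$raw_cM, 0)
  expect_equal(r0$corrected_cM, 0)
  # 50 of 10,000 with 0.22 background
  r <- estimate_rate(mk(50L, 10000L), background_cM = 0.22)
  expect_equal(r$raw_cM, 0.50)
  expect_equal(r$corrected_cM, 0.28)
  # CI brackets the raw rate and matches binom.test
  ci <- binom.test(50, 10000)$conf.int * 100
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(ci))
  expect_true(r$ci_low <= r$raw_cM && r$raw_cM <= r$ci_high)
  # over-subtraction floors at zero
  expect_equal(estimate_rate(mk(5L, 10000L), background_cM = 1)$corrected_cM, 0)
  # zero informative molecules -> undefined rate
  bad <- mk(0L, 10000L); bad$n_informative <- 0L
  expect_error(estimate_rate(bad), "zero informative")
})

test_that("fold change reproduces printed ratios and flags suppressed rates", {
  expect_equal(fold_change(2.38, 0.41), 5.8)
  expect_equal(fold_change(1.7, 1.7), 1.0)
  expect_error(fold_change(0.61, 0), "fisher_exact_2x2")
})

test_that("jump-PCR chimeras create an apparent rate linear in chimera_prob", {
  # with true_cM = 0 every apparent crossover is a chimera artifact;
  # expected raw rate = 100 * p * P(partner right flank differs) = 50 p
  rates <- vapply(c(0.02, 0.04, 0.08), function(p) {
    simulate_and_estimate(1e5, true_cM = 0, chimera_prob = p,
                          seed = round(1000 * p))$raw_cM
  }, numeric(1))
  expect_true(all(rates > 0))
  expect_true(all(diff(rates) > 0))
  # doubling chimera_prob roughly doubles the apparent rate
  expect_gt(rates[2] / rates[1], 1.6)
  expect_lt(rates[2] / rates[1], 2.4)
  expect_gt(rates[3] / rates[1], 3.2)
  expect_lt(rates[3] / rates[1], 4.8)
  # and the absolute level matches the 50 p prediction within binomial noise
  expect_lt(abs(rates[1] - 1.0), 4 * 100 * sqrt(0.01 * 0.99 / 1e5))
})

test_that("corrected estimate converges to the true rate as n grows", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    abs(simulate_and_estimate(n, true_cM = 2.38, chimera_prob = 0,
                              seed = 77)$corrected_cM - 2.38)
  }, numeric(1))
  expect_lt(errs[3], 0.2)
  expect_lt(errs[3], errs[1])
})
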