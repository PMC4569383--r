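test_that("sperm generator is deterministic and truth partitions the pool", {
  assay <- fixture_assay(1L)
  cfg <- sperm_sim_config(2000, true_cM = 3, chimera_prob = 0.05,
                          barcode = names(assay$barcode_map)[1], seed = 42)
  a <- make_sperm_molecules(cfg, assay)
  b <- make_sperm_molecules(cfg, assay)
  expect_identical(a, b)

  expect_equal(nrow(a$molecules), 2000L)
  expect_equal(sum(table(a$truth$true_class)), 2000L)
  expect_true(all(a$truth$true_class %in%
                    c("parental_A", "parental_B", "crossover_AB", "crossover_BA")))
  # generator must not disturb caller RNG state
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(make_sperm_molecules(cfg, assay)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero crossover rate and zero chimeras yield zero discordant flanks", {
  assay <- fixture_assay(1L)
  sim <- make_sperm_molecules(
    sperm_sim_config(1000, true_cM = 0, chimera_prob = 0,
                     barcode = names(assay$barcode_map)[1], seed = 1), assay)
  cls <- classify_molecules(sim$molecules$left_base, sim$molecules$right_base,
                            assay)
  expect_true(all(cls %in% c("parental_A", "parental_B")))
})

test_that("discordant-flank fraction sits in the exact binomial 99% band", {
  # 99% acceptance band for Binomial(50000, 0.02) computed from qbinom
  n <- 50000L
  band <- qbinom(c(0.005, 0.995), n, 0.02)
  assay <- fixture_assay(1L)
  sim <- make_sperm_molecules(
    sperm_sim_config(n, true_cM = 2.0, chimera_prob = 0,
                     barcode = names(assay$barcode_map)[1], seed = 2024), assay)
  n_co <- sum(grepl("^crossover", sim$truth$true_class))
  expect_gte(n_co, band[1])
  expect_lte(n_co, band[2])
})

test_that("rejects molecules with an invalid barcode alphabet", {
  expect_error(sperm_sim_config(10, 1, 0, barcode = "ACGTACGN"), "ACGT")
  expect_error(sperm_sim_config(10, 1, 0, barcode = "ACGT"), "8-base")
  expect_error(sperm_sim_config(10, 60, 0), "0, 50")
})

test_that("dilution generator matches the Poisson zero-class closed form", {
  # lambda = 0 impossible (rate > 0 enforced); tiny rate ~ all negative
  expect_error(make_dilution_series(0), "> 0")
  ser <- make_dilution_series(1e-9, n_levels = 3, seed = 1)
  expect_true(all(ser$n_negative == ser$n_wells))
  # lambda >= 20: all wells positive with probability ~ 1
  ser <- make_dilution_series(20, n_levels = 1, seed = 2)
  expect_equal(ser$n_negative, 0L)
  # empirical positive fraction at lambda = 1 over 10,000 wells vs 1 - e^-1
  ser <- make_dilution_series(1, n_levels = 1, wells_per_level = 10000, seed = 3)
  pos_frac <- 1 - ser$n_negative / ser$n_wells
  p <- 1 - exp(-1)
  mc_se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(pos_frac - p), 4 * mc_se)
  # determinism
  expect_identical(make_dilution_series(5, seed = 9), make_dilution_series(5, seed = 9))
})

test_that("cross panels segregate and carry the configured additive effect", {
  # N2: two genotype classes only
  p_n2 <- make_cross_panel(60, "c05_m03", 0.5, 0.3, "N2", seed = 5)
  expect_true(all(p_n2$geno %in% 1:2))
  # F2: three classes somewhere
  p_f2 <- make_cross_panel(200, "c05_m03", 0.5, 0.3, "F2", seed = 6)
  expect_true(all(p_f2$geno %in% 0:2))
  expect_true(any(p_f2$geno == 0) && any(p_f2$geno == 1) && any(p_f2$geno == 2))

  # allele-count means at the QTL differ by the configured effect within SE
  qm <- "c05_m03"
  g <- p_f2$geno[, qm]
  fit <- lm(p_f2$pheno ~ g)
  est <- coef(summary(fit))["g", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])

  # zero effect: slope indistinguishable from zero
  p0 <- make_cross_panel(200, "c05_m03", 0, 0.3, "F2", seed = 7)
  fit0 <- lm(p0$pheno ~ p0$geno[, qm])
  expect_gt(coef(summary(fit0))[2, "Pr(>|t|)"], 0.001)

  expect_error(make_cross_panel(50, "nope", 1, 1, "N2"), "not in map")
})

test_that("adjacent-marker genotype correlation follows the Haldane map", {
  map <- data.frame(marker = c("m1", "m2"), chrom = "chr1",
                    pos_mb = c(0, 40))          # 20 cM at 0.5 cM/Mb
  p <- make_cross_panel(5000, NA, 0, 1, "N2", map = map, seed = 8)
  r_obs <- mean(p$geno[, 1] != p$geno[, 2])
  r_exp <- 0.5 * (1 - exp(-2 * 0.2))
  expect_lt(abs(r_obs - r_exp), 4 * sqrt(r_exp * (1 - r_exp) / 5000))
})

test_that("hotspot landscapes respect protein dose and are reproducible", {
  cfg <- landscape_sim_config(300, total_protein = 1,
                              detection_threshold = 0.4, seed = 11)
  hom <- make_hotspot_landscape(cfg, "hom_A")
  hemi <- make_hotspot_landscape(cfg, "hemizygous_A")
  # same sites, same Kd regardless of genotype
  expect_identical(hom$truth$kd, hemi$truth$kd)
  # hemizygote (half dose) detected set is a subset of the homozygote set
  expect_true(all(hemi$truth$site_id[hemi$truth$detected] %in%
                    hom$truth$site_id[hom$truth$detected]))
  # vanishing protein pool: nothing detected
  cfg0 <- landscape_sim_config(300, total_protein = 1e-9,
                               detection_threshold = 0.4, seed = 11)
  expect_equal(sum(make_hotspot_landscape(cfg0, "het")$truth$detected), 0)
  # identical seed/config -> identical detected intervals
  again <- make_hotspot_landscape(cfg, "hom_A")
  expect_identical(as.data.frame(hom$detected), as.data.frame(again$detected))
  expect_error(landscape_sim_config(100, detection_threshold = 1.2), "0, 1")
})
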