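#' Configuration for the single-sperm molecule simulator
#'
#' Describes one simulated pool of single-sperm-derived amplicon molecules:
#' how many molecules, the true crossover rate of the hotspot, the rate of
#' template-switching (jump-PCR) chimera formation, and the sample barcode
#' carried by every molecule.
#'
#' @param n_molecules number of molecules to simulate.
#' @param true_cM true crossover rate in centimorgans (0-50); each molecule
#'   is a crossover with probability `true_cM / 100`.
#' @param chimera_prob probability that a molecule's two flank alleles are
#'   decoupled by template switching during PCR. A chimeric molecule keeps
#'   its left flank and takes the right flank of a uniformly random other
#'   molecule in the pool, so chimeras create false recombinants in both
#'   orientations.
#' @param barcode 8-base ACGT sample barcode stamped on every molecule.
#' @param allele_freq_bias fraction of parental molecules drawn from
#'   haplotype A (0.5 = balanced input DNA).
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#'
#' @return an object of class `sperm_sim_config`.
#' @export
sperm_sim_config <- function(n_molecules, true_cM, chimera_prob,
                             barcode = "ACGTACGT", allele_freq_bias = 0.5,
                             seed = 1L) {
  n_molecules <- assert_count(n_molecules, "n_molecules", min = 1L)
  if (!is.numeric(true_cM) || length(true_cM) != 1L || is.na(true_cM) ||
      true_cM < 0 || true_cM > 50) {
    abort_data("`true_cM` must be in [0, 50]")
  }
  assert_prob(chimera_prob, "chimera_prob")
  assert_prob(allele_freq_bias, "allele_freq_bias")
  if (!is_dna_string(barcode) || nchar(barcode) != 8L) {
    abort_data("`barcode` must be an 8-base ACGT string")
  }
  structure(
    list(n_molecules = n_molecules, true_cM = true_cM,
         chimera_prob = chimera_prob, barcode = barcode,
         allele_freq_bias = allele_freq_bias, seed = as.integer(seed)),
    class = "sperm_sim_config"
  )
}

#' Simulate single-sperm amplicon molecules with ground truth
#'
#' Each simulated molecule represents one sperm-derived DNA template: a
#' barcode plus the base observed at the left and right flanking SNP of the
#' hotspot. True crossovers are drawn Bernoulli(`true_cM/100`) with the two
#' orientations (A-left/B-right and B-left/A-right) equally likely;
#' remaining molecules are parental, haplotype A with probability
#' `allele_freq_bias`. Template-switching chimeras are then drawn
#' independently: with probability `chimera_prob` a molecule's right flank
#' is replaced by the right flank of a uniformly random other molecule,
#' which is how jump-PCR manufactures false recombinants from parental
#' templates.
#'
#' The truth table records the generative (pre-chimera) class of every
#' molecule together with its chimera flag, so downstream counts can be
#' checked against truth exactly when `chimera_prob = 0`.
#'
#' @param cfg a [sperm_sim_config()].
#' @param assay a [hotspot_assay()] supplying the haplotype bases at each
#'   flank. The config barcode need not be in the assay barcode map.
#' @return list with `molecules` (data.frame: molecule_id, barcode,
#'   left_base, right_base) and `truth` (data.frame: molecule_id,
#'   true_class, chimera_flag).
#' @examples
#' assay <- hotspot_assay("Pbx1", c(ACGTACGT = "m1"),
#'                        c(A = "A", B = "G"), c(A = "C", B = "T"))
#' sim <- make_sperm_molecules(
#'   sperm_sim_config(1000, true_cM = 2.38, chimera_prob = 0, seed = 7),
#'   assay)
#' table(sim$truth$true_class)
#' @export
make_sperm_molecules <- function(cfg, assay) {
  stopifnot(inherits(cfg, "sperm_sim_config"), inherits(assay, "hotspot_assay"))
  n <- cfg$n_molecules
  with_seed(cfg$seed, {
    is_co <- runif(n) < cfg$true_cM / 100
    orient_ab <- runif(n) < 0.5           # crossover orientation
    par_a <- runif(n) < cfg$allele_freq_bias
    true_class <- ifelse(is_co,
                         ifelse(orient_ab, "crossover_AB", "crossover_BA"),
                         ifelse(par_a, "parental_A", "parental_B"))
    left_hap <- ifelse(true_class %in% c("parental_A", "crossover_AB"), "A", "B")
    right_hap <- ifelse(true_class %in% c("parental_A", "crossover_BA"), "A", "B")
    left_base <- unname(assay$left_snp_alleles[left_hap])
    right_base <- unname(assay$right_snp_alleles[right_hap])

    chimera <- runif(n) < cfg$chimera_prob
    if (any(chimera) && n > 1L) {
      # partner drawn uniformly from the other molecules' pre-chimera flanks
      idx <- which(chimera)
      partner <- sapply(idx, function(i) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j + 1L else j
      })
      right_base[idx] <- right_base[partner]
    }
    list(
      molecules = data.frame(
        molecule_id = sprintf("mol%07d", seq_len(n)),
        barcode = cfg$barcode,
        left_base = left_base,
        right_base = right_base,
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        molecule_id = sprintf("mol%07d", seq_len(n)),
        true_class = true_class,
        chimera_flag = chimera,
        stringsAsFactors = FALSE
      )
    )
  })
}
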