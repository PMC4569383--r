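#' Configuration for the hotspot-landscape simulator
#'
#' Describes a synthetic genome of PRDM9-defined hotspots for two alleles.
#' Each allele owns `n_hotspots_per_allele` binding sites whose
#' dissociation constants are drawn log-normal — binding affinities span
#' orders of magnitude and must stay positive — and a site is "detected"
#' (called as a peak) when its model occupancy reaches
#' `detection_threshold`.
#'
#' @param n_hotspots_per_allele sites owned by each allele.
#' @param kd_log_mean,kd_log_sd meanlog/sdlog of the per-allele Kd
#'   distribution (concentration units); scalars or length-2 vectors
#'   (allele A, allele B).
#' @param total_protein total PRDM9 pool, same units as Kd.
#' @param detection_threshold occupancy fraction required to call a peak,
#'   in (0, 1).
#' @param seed integer seed.
#' @return object of class `landscape_sim_config`.
#' @export
landscape_sim_config <- function(n_hotspots_per_allele = 1000L,
                                 kd_log_mean = 0, kd_log_sd = 1,
                                 total_protein = 1,
                                 detection_threshold = 0.4, seed = 1L) {
  n_hotspots_per_allele <- assert_count(n_hotspots_per_allele,
                                        "n_hotspots_per_allele", min = 1L)
  if (total_protein < 0) abort_data("`total_protein` must be >= 0")
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    abort_data("`detection_threshold` must be in (0, 1)")
  }
  rep2 <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  structure(
    list(n_hotspots_per_allele = n_hotspots_per_allele,
         kd_log_mean = rep2(kd_log_mean), kd_log_sd = rep2(kd_log_sd),
         total_protein = total_protein,
         detection_threshold = detection_threshold,
         seed = as.integer(seed)),
    class = "landscape_sim_config"
  )
}

# Fraction of the dimer pool with at least one arm of the owning allele,
# counting each heteromer as half an arm per allele. Site placement and Kd
# draws depend only on (cfg, seed), so the same config generates the same
# sites under every genotype; genotype only rescales the competent pool.
genotype_dose <- function(genotype) {
  switch(genotype,
    hom_A = c(A = 1, B = 0),
    hom_B = c(A = 0, B = 1),
    het = c(A = 0.5, B = 0.5),          # 1:2:1 pool, one arm of two per heteromer
    hemizygous_A = c(A = 0.5, B = 0),   # single functional allele, half the pool
    abort_data(sprintf("unknown genotype label '%s'", genotype))
  )
}

#' Simulate parental and F1 hotspot landscapes from the dimer model
#'
#' Lays out non-overlapping hotspot intervals on a synthetic genome, one
#' set owned by each allele, draws per-site dissociation constants from
#' the configured log-normal, and computes each site's occupancy under the
#' requested genotype: the protein competent to bind an allele's sites is
#' the total pool scaled by that allele's arm share in the multimer pool
#' (hom_A: 1 for A sites; het: 1/2; hemizygous_A: 1/2 — a hemizygote has
#' half the pool, all of it allele A). Sites whose occupancy reaches the
#' detection threshold form the detected peak set.
#'
#' @param cfg a [landscape_sim_config()].
#' @param genotype one of `"hom_A"`, `"hom_B"`, `"het"`,
#'   `"hemizygous_A"`.
#' @return list: `truth` (data.frame site_id, owning_allele, chrom,
#'   start, end, kd, occupancy, detected) and `detected`
#'   (a `GRanges` of the detected peaks, score = occupancy).
#' @examples
#' cfg <- landscape_sim_config(200, total_protein = 1, seed = 3)
#' f1 <- make_hotspot_landscape(cfg, "het")
#' table(f1$truth$owning_allele[f1$truth$detected])
#' @export
make_hotspot_landscape <- function(cfg, genotype = c("het", "hom_A", "hom_B",
                                                     "hemizygous_A")) {
  stopifnot(inherits(cfg, "landscape_sim_config"))
  genotype <- match.arg(genotype)
  dose <- genotype_dose(genotype)
  n <- cfg$n_hotspots_per_allele
  with_seed(cfg$seed, {
    # non-overlapping 1.5 kb sites on 5 kb slots across a synthetic genome
    slots <- sample.int(10L * n, 2L * n)
    start <- (slots - 1L) * 5000L + 1000L
    kd <- c(rlnorm(n, cfg$kd_log_mean[1], cfg$kd_log_sd[1]),
            rlnorm(n, cfg$kd_log_mean[2], cfg$kd_log_sd[2]))
    truth <- data.frame(
      site_id = sprintf("hs%05d", seq_len(2L * n)),
      owning_allele = rep(c("A", "B"), each = n),
      chrom = "chr1",
      start = start,
      end = start + 1500L,
      kd = kd,
      stringsAsFactors = FALSE
    )
    p_eff <- cfg$total_protein * dose[truth$owning_allele]
    truth$occupancy <- ifelse(p_eff > 0, site_occupancy(kd, p_eff), 0)
    truth$detected <- truth$occupancy >= cfg$detection_threshold
    det <- truth[truth$detected, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = det$chrom,
      ranges = IRanges::IRanges(start = det$start + 1L, end = det$end),
      site_id = det$site_id,
      owning_allele = det$owning_allele,
      score = det$occupancy
    )
    list(truth = truth, detected = gr)
  })
}
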