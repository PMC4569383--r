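#' Default genome-wide marker map
#'
#' A mouse-like marker grid: `n_markers` spread over 19 autosomes in
#' proportion to a 150 Mb chromosome, evenly spaced. Used by the cross
#' simulator when no map is supplied; matches the density of a typical
#' low-resolution QTL genotyping panel.
#'
#' @param n_markers total markers (default 165).
#' @param n_chrom number of chromosomes (default 19).
#' @param chrom_length_mb chromosome length in Mb (default 150).
#' @return data.frame: `marker`, `chrom`, `pos_mb`.
#' @export
default_marker_map <- function(n_markers = 165L, n_chrom = 19L,
                               chrom_length_mb = 150) {
  n_markers <- assert_count(n_markers, "n_markers", min = n_chrom)
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    pos <- seq(5, chrom_length_mb - 5, length.out = per[ch])
    data.frame(marker = sprintf("c%02d_m%02d", ch, seq_len(per[ch])),
               chrom = paste0("chr", ch),
               pos_mb = pos,
               stringsAsFactors = FALSE)
  }))
}

# Haldane map function: recombination fraction between adjacent markers
# separated by d centimorgans (no crossover interference).
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# Simulate one F1 gamete per mouse across the map: B6 allele indicator at
# each marker, Markov along each chromosome with Haldane recombination.
sim_gametes <- function(n_mice, map, cm_per_mb) {
  g <- matrix(0L, n_mice, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_mb[idx]
    g[, idx[1]] <- rbinom(n_mice, 1L, 0.5)
    if (length(idx) > 1L) {
      for (j in 2:length(idx)) {
        r <- haldane_r((pos[j] - pos[j - 1]) * cm_per_mb)
        flip <- rbinom(n_mice, 1L, r)
        g[, idx[j]] <- ifelse(flip == 1L, 1L - g[, idx[j - 1]], g[, idx[j - 1]])
      }
    }
  }
  g
}

#' Simulate a QTL mapping cross panel
#'
#' Generates genotypes under backcross (N2) or intercross (F2)
#' segregation with recombination between adjacent markers given by the
#' Haldane map function (default 0.5 cM/Mb, the mouse genome-wide
#' average), and a phenotype carrying one additive QTL:
#' `phenotype = baseline + effect_per_allele * (B6-allele count at
#' qtl_marker) + N(0, resid_sd)`.
#'
#' @param n_mice number of mice.
#' @param qtl_marker marker name or index carrying the QTL (NA for a null
#'   panel with no QTL).
#' @param effect_per_allele phenotype shift per B6 allele (cM units when
#'   the phenotype is a recombination rate).
#' @param resid_sd residual phenotype standard deviation.
#' @param cross_type `"N2"` (backcross, genotypes \{1, 2\}) or `"F2"`
#'   (intercross, \{0, 1, 2\}).
#' @param map marker map (default [default_marker_map()]).
#' @param baseline phenotype at zero B6 alleles.
#' @param cm_per_mb genetic:physical map ratio for inter-marker
#'   recombination.
#' @param seed integer seed.
#' @return a [cross_panel()] with the simulation truth in attribute
#'   `"truth"` (qtl_marker, effect_per_allele, baseline, resid_sd).
#' @export
make_cross_panel <- function(n_mice, qtl_marker, effect_per_allele,
                             resid_sd, cross_type = c("N2", "F2"),
                             map = default_marker_map(),
                             baseline = 0.5, cm_per_mb = 0.5, seed = 1L) {
  cross_type <- match.arg(cross_type)
  n_mice <- assert_count(n_mice, "n_mice", min = 2L)
  if (resid_sd <= 0) abort_data("`resid_sd` must be > 0")
  if (is.character(qtl_marker) && !is.na(qtl_marker)) {
    qm <- match(qtl_marker, map$marker)
    if (is.na(qm)) abort_data("`qtl_marker` not in map")
  } else qm <- qtl_marker
  if (!is.na(qm) && (qm < 1 || qm > nrow(map))) {
    abort_data("`qtl_marker` outside the marker set")
  }
  with_seed(seed, {
    geno <- if (cross_type == "N2") {
      1L + sim_gametes(n_mice, map, cm_per_mb)       # one F1 gamete + B6 gamete
    } else {
      sim_gametes(n_mice, map, cm_per_mb) + sim_gametes(n_mice, map, cm_per_mb)
    }
    dose <- if (is.na(qm)) 0 else geno[, qm]
    pheno <- baseline + effect_per_allele * dose + rnorm(n_mice, 0, resid_sd)
    panel <- cross_panel(geno, map, pheno, cross_type)
    attr(panel, "truth") <- list(qtl_marker = if (is.na(qm)) NA else map$marker[qm],
                                 effect_per_allele = effect_per_allele,
                                 baseline = baseline, resid_sd = resid_sd)
    panel
  })
}

#' Pool two cross panels that share a marker map
#'
#' Stacks mice from panels genotyped on the same map (e.g. an N2 and an F2
#' cross mapped jointly with a cross covariate).
#'
#' @param a,b [cross_panel()] objects with identical maps.
#' @return a pooled [cross_panel()].
#' @export
pool_panels <- function(a, b) {
  stopifnot(inherits(a, "cross_panel"), inherits(b, "cross_panel"))
  if (!identical(a$map$marker, b$map$marker)) {
    abort_data("panels must share a marker map")
  }
  cross_panel(rbind(a$geno, b$geno), a$map,
              c(a$pheno, b$pheno), c(a$cross, b$cross))
}
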