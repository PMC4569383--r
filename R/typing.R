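#' Demultiplex barcoded molecules into per-sample pools
#'
#' Routes each molecule to the sample whose barcode it matches exactly;
#' molecules whose barcode is absent from the assay barcode map are routed
#' to `"unassigned"`. Matching is exact by design: with 8-base codes and
#' small code sets, tolerant matching risks cross-sample collisions, so the
#' mismatch tolerance defaults to 0 (tolerance > 0 accepts barcodes within
#' that Hamming distance of a unique map entry).
#'
#' @param molecules data.frame with columns `molecule_id`, `barcode`,
#'   `left_base`, `right_base` (as produced by [make_sperm_molecules()] or
#'   read by [read_molecules_tsv()]).
#' @param assay a [hotspot_assay()].
#' @param max_mismatch allowed barcode mismatches (default 0 = exact).
#' @return the input data.frame with a `sample` column added; the partition
#'   conserves molecule count.
#' @export
demultiplex <- function(molecules, assay, max_mismatch = 0L) {
  stopifnot(inherits(assay, "hotspot_assay"))
  need <- c("molecule_id", "barcode", "left_base", "right_base")
  if (!all(need %in% names(molecules))) {
    abort_data(paste("molecule table needs columns:", paste(need, collapse = ", ")))
  }
  bc <- names(assay$barcode_map)
  if (max_mismatch == 0L) {
    sample <- unname(assay$barcode_map[molecules$barcode])
  } else {
    sample <- vapply(molecules$barcode, function(b) {
      d <- vapply(bc, function(ref) {
        sum(utf8ToInt(b) != utf8ToInt(ref))
      }, integer(1))
      hit <- which(d <= max_mismatch)
      if (length(hit) == 1L) unname(assay$barcode_map[hit]) else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  molecules$sample <- ifelse(is.na(sample), "unassigned", sample)
  molecules
}

#' Classify molecules as parental or crossover from their flank bases
#'
#' Pure lookup against the assay's haplotype alleles: (A,A) is parental_A,
#' (B,B) parental_B, (A,B) crossover_AB, (B,A) crossover_BA; any flank base
#' matching neither haplotype makes the molecule ambiguous. Total function,
#' vectorised over molecules.
#'
#' @param left_base,right_base character vectors of single bases.
#' @param assay a [hotspot_assay()].
#' @return character vector over
#'   \{parental_A, parental_B, crossover_AB, crossover_BA, ambiguous\}.
#' @export
classify_molecules <- function(left_base, right_base, assay) {
  stopifnot(inherits(assay, "hotspot_assay"))
  l <- ifelse(left_base == assay$left_snp_alleles[["A"]], "A",
              ifelse(left_base == assay$left_snp_alleles[["B"]], "B", "?"))
  r <- ifelse(right_base == assay$right_snp_alleles[["A"]], "A",
              ifelse(right_base == assay$right_snp_alleles[["B"]], "B", "?"))
  out <- rep("ambiguous", length(l))
  out[l == "A" & r == "A"] <- "parental_A"
  out[l == "B" & r == "B"] <- "parental_B"
  out[l == "A" & r == "B"] <- "crossover_AB"
  out[l == "B" & r == "A"] <- "crossover_BA"
  out
}

MOLECULE_CLASSES <- c("parental_A", "parental_B",
                      "crossover_AB", "crossover_BA", "ambiguous")

#' Tally molecule classes per sample
#'
#' Counts parental, crossover and ambiguous molecules for every sample in a
#' demultiplexed pool. `n_informative` excludes ambiguous molecules, which
#' carry no crossover information. Counts are order-invariant and conserve
#' the input: the class counts of each sample sum to the molecules assigned
#' to it.
#'
#' @param molecules demultiplexed data.frame (see [demultiplex()]); a
#'   missing `sample` column is treated as a single unnamed sample.
#' @param assay a [hotspot_assay()].
#' @param drop_unassigned drop the "unassigned" pseudo-sample from the
#'   table (default TRUE).
#' @return data.frame with one row per sample: `sample`, `n_parental_A`,
#'   `n_parental_B`, `n_crossover_AB`, `n_crossover_BA`, `n_ambiguous`,
#'   `n_informative`.
#' @export
count_classes <- function(molecules, assay, drop_unassigned = TRUE) {
  if (is.null(molecules$sample)) molecules$sample <- "sample"
  if (nrow(molecules) == 0L) {
    out <- data.frame(sample = character(0))
    for (cl in MOLECULE_CLASSES) out[[paste0("n_", cl)]] <- integer(0)
    out$n_informative <- integer(0)
    return(out)
  }
  klass <- factor(
    classify_molecules(molecules$left_base, molecules$right_base, assay),
    levels = MOLECULE_CLASSES
  )
  tab <- table(sample = molecules$sample, klass)
  out <- data.frame(sample = rownames(tab), stringsAsFactors = FALSE)
  for (cl in MOLECULE_CLASSES) out[[paste0("n_", cl)]] <- as.integer(tab[, cl])
  out$n_informative <- out$n_parental_A + out$n_parental_B +
    out$n_crossover_AB + out$n_crossover_BA
  if (drop_unassigned) out <- out[out$sample != "unassigned", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate a background-corrected recombination rate in centimorgans
#'
#' The raw rate is `100 * crossovers / n_informative` (both crossover
#' orientations pooled; ambiguous molecules excluded from the denominator).
#' The background is the assay's false-recombination rate measured on
#' control mixes where true crossovers are impossible, entirely due to
#' jump-PCR chimeras; it is subtracted from the raw rate with a floor at
#' zero. The confidence interval is the Clopper-Pearson exact binomial
#' interval on the raw crossover fraction, appropriate for rates near zero.
#'
#' @param counts a per-sample count table from [count_classes()].
#' @param background_cM assay false-recombination rate in cM to subtract
#'   (default 0: report raw rates).
#' @param conf_level confidence level for the exact interval.
#' @return data.frame with one row per sample: `sample`, `n_informative`,
#'   `n_crossover`, `raw_cM`, `background_cM`, `corrected_cM`, `ci_low`,
#'   `ci_high` (interval on the raw rate, in cM).
#' @examples
#' counts <- data.frame(sample = "m1", n_parental_A = 4975,
#'                      n_parental_B = 4975, n_crossover_AB = 25,
#'                      n_crossover_BA = 25, n_ambiguous = 0,
#'                      n_informative = 10000)
#' estimate_rate(counts, background_cM = 0.22)
#' @export
estimate_rate <- function(counts, background_cM = 0, conf_level = 0.95) {
  if (nrow(counts) == 0L) abort_data("empty count table")
  if (any(counts$n_informative == 0L)) {
    abort_data("rate undefined: sample with zero informative molecules")
  }
  if (background_cM < 0) abort_data("`background_cM` must be >= 0")
  n_co <- counts$n_crossover_AB + counts$n_crossover_BA
  n <- counts$n_informative
  raw <- 100 * n_co / n
  ci <- t(mapply(function(x, m) {
    binom.test(x, m, conf.level = conf_level)$conf.int
  }, n_co, n))
  data.frame(
    sample = counts$sample,
    n_informative = n,
    n_crossover = n_co,
    raw_cM = raw,
    background_cM = background_cM,
    corrected_cM = pmax(0, raw - background_cM),
    ci_low = 100 * ci[, 1],
    ci_high = 100 * ci[, 2],
    stringsAsFactors = FALSE
  )
}

#' Fold change between two recombination rates
#'
#' Ratio of two rates (e.g. the same hotspot in two genetic backgrounds),
#' reported to one decimal as rate tables conventionally print it. A zero
#' denominator (a fully suppressed hotspot) leaves the ratio undefined;
#' compare the underlying molecule counts with [fisher_exact_2x2()] instead.
#'
#' @param rate_a,rate_b numeric rates in cM, or single-row results from
#'   [estimate_rate()] (the `corrected_cM` column is used).
#' @param digits decimals to round the ratio to (default 1).
#' @return `rate_a / rate_b`, rounded.
#' @examples
#' fold_change(2.38, 0.41)   # 5.8
#' @export
fold_change <- function(rate_a, rate_b, digits = 1L) {
  pick <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L, "corrected_cM" %in% names(x))
      x$corrected_cM
    } else {
      stopifnot(is.numeric(x), length(x) == 1L)
      x
    }
  }
  a <- pick(rate_a)
  b <- pick(rate_b)
  if (b <= 0) {
    abort_data(paste("fold change undefined for a zero/suppressed denominator;",
                     "use fisher_exact_2x2() on the molecule counts instead"))
  }
  round(a / b, digits = digits)
}
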