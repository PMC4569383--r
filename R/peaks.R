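#' Read and write peak interval sets as BED
#'
#' Peaks travel as BED (0-based, half-open) with 3-6 columns; strand is
#' ignored throughout since H3K4me3/DSB peaks are unstranded.
#'
#' @param path BED file path.
#' @return `read_peaks_bed`: a `GRanges`.
#' @export
read_peaks_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_peaks_bed
#' @param gr a `GRanges` to write.
#' @export
write_peaks_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

as_granges_intervals <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("chrom", "start", "end") %in% names(x))) {
      abort_data("interval data.frame needs chrom/start/end (0-based half-open)")
    }
    if (any(x$start >= x$end) || any(x$start < 0)) {
      abort_data("malformed interval: need 0 <= start < end")
    }
    return(GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end)))
  }
  abort_data("intervals must be a GRanges or a chrom/start/end data.frame")
}

# put two GRanges on a shared seqlevel universe so overlap ops on sets
# with disjoint chromosomes stay silent
harmonize_seqlevels <- function(ga, gb) {
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair of intervals, one from each set, sharing at least
#' 1 bp on the same chromosome: `max(starts) < min(ends)` in half-open
#' coordinates. Strand is ignored.
#'
#' @param a,b `GRanges` or data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with columns `query` (index into `a`) and `subject`
#'   (index into `b`).
#' @export
find_overlap_pairs <- function(a, b) {
  gg <- harmonize_seqlevels(as_granges_intervals(a), as_granges_intervals(b))
  hits <- GenomicRanges::findOverlaps(gg[[1]], gg[[2]], minoverlap = 1L,
                                      ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Assign F1 hotspot peaks to the allele that defines them
#'
#' Each peak of an F1/heterozygote set is classified by overlap against
#' the two parental (homozygote) peak sets: `alleleA` if it overlaps the
#' parent-A set only, `alleleB` if parent-B only, `shared` if both,
#' `novel` if neither. A peak overlapping multiple parental peaks still
#' counts once (peak-level classification). Because convention differs on
#' whether shared peaks belong to either allele, the summary also reports
#' both foldings of the shared class.
#'
#' @param f1 F1/heterozygote peak set (`GRanges` or data.frame).
#' @param parent_a,parent_b parental peak sets.
#' @return object of class `classified_peaks`: list with `class`
#'   (character per F1 peak), `counts`, `fractions`, and
#'   `fractions_shared_to_A` / `fractions_shared_to_B` (two-class
#'   fractions with shared folded into one allele).
#' @export
classify_f1_peaks <- function(f1, parent_a, parent_b) {
  gf <- as_granges_intervals(f1)
  ga <- harmonize_seqlevels(gf, as_granges_intervals(parent_a))
  in_a <- GenomicRanges::countOverlaps(ga[[1]], ga[[2]],
                                       ignore.strand = TRUE) > 0
  gb <- harmonize_seqlevels(gf, as_granges_intervals(parent_b))
  in_b <- GenomicRanges::countOverlaps(gb[[1]], gb[[2]],
                                       ignore.strand = TRUE) > 0
  klass <- ifelse(in_a & in_b, "shared",
                  ifelse(in_a, "alleleA",
                         ifelse(in_b, "alleleB", "novel")))
  lev <- c("alleleA", "alleleB", "shared", "novel")
  counts <- table(factor(klass, levels = lev))
  n <- length(gf)
  fr <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, 4)
  names(fr) <- lev
  fold <- function(to) {
    two <- c(alleleA = fr[["alleleA"]], alleleB = fr[["alleleB"]])
    two[[to]] <- two[[to]] + fr[["shared"]]
    two
  }
  structure(list(class = klass,
                 counts = setNames(as.integer(counts), lev),
                 fractions = fr,
                 fractions_shared_to_A = fold("alleleA"),
                 fractions_shared_to_B = fold("alleleB")),
            class = "classified_peaks")
}

#' @export
print.classified_peaks <- function(x, ...) {
  cat("<classified_peaks>\n")
  print(data.frame(class = names(x$counts), n = x$counts,
                   fraction = round(x$fractions, 4), row.names = NULL))
  invisible(x)
}

#' Peaks unique to one individual
#'
#' Peaks of the first set with no overlap in the second — e.g. peaks found
#' in a heterozygous A/C individual but absent from a homozygous A/A
#' individual are putative C-allele-defined hotspots.
#'
#' @param set_a,set_b peak sets (`GRanges` or data.frame).
#' @return the subset of `set_a` (as `GRanges`) not overlapping `set_b`.
#' @export
unique_peaks <- function(set_a, set_b) {
  gg <- harmonize_seqlevels(as_granges_intervals(set_a),
                            as_granges_intervals(set_b))
  gg[[1]][GenomicRanges::countOverlaps(gg[[1]], gg[[2]],
                                       ignore.strand = TRUE) == 0L]
}

#' Containment and signal-level report for a dose titration
#'
#' Compares the peak set called at a reduced protein dose against the
#' full-dose set: the fraction of low-dose peaks contained in (overlapping)
#' the full-dose set, and — when full-dose peaks carry a score — the
#' score distribution of full-dose peaks that persist at low dose versus
#' those lost, which under the occupancy model shows that low-dose peaks
#' are the highest-signal (smallest-Kd) subset.
#'
#' @param set_low_dose,set_full_dose peak sets; `set_full_dose` may carry
#'   a `score` metadata column.
#' @return list: `containment_fraction`, `n_low`, `n_full`, and (when
#'   scores exist) `score_quantiles_retained` / `score_quantiles_lost`
#'   (full-dose score quartiles of peaks retained vs lost at low dose).
#' @export
subset_and_level_report <- function(set_low_dose, set_full_dose) {
  gg <- harmonize_seqlevels(as_granges_intervals(set_low_dose),
                            as_granges_intervals(set_full_dose))
  glow <- gg[[1]]
  gfull <- gg[[2]]
  if (length(glow) == 0L) {
    abort_data("empty low-dose set: containment undefined")
  }
  contained <- GenomicRanges::countOverlaps(glow, gfull,
                                            ignore.strand = TRUE) > 0
  retained <- GenomicRanges::countOverlaps(gfull, glow,
                                           ignore.strand = TRUE) > 0
  out <- list(containment_fraction = mean(contained),
              n_low = length(glow), n_full = length(gfull))
  score <- if (inherits(set_full_dose, "GRanges") &&
               "score" %in% names(S4Vectors::mcols(set_full_dose))) {
    S4Vectors::mcols(set_full_dose)$score
  } else NULL
  if (!is.null(score)) {
    qs <- function(x) if (length(x)) quantile(x, c(0.25, 0.5, 0.75)) else
      setNames(rep(NA_real_, 3), c("25%", "50%", "75%"))
    out$score_quantiles_retained <- qs(score[retained])
    out$score_quantiles_lost <- qs(score[!retained])
  }
  out
}
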