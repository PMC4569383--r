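#' Define the molecular geometry of a sperm-typing assay
#'
#' A sperm-typing assay measures crossovers at one hotspot by reading, for
#' each single-sperm-derived molecule, one SNP on each flank of the hotspot
#' plus an 8 bp sample barcode at the 5' end. The assay definition holds the
#' barcode-to-sample map, the base expected for each haplotype at each
#' flanking SNP, and the fixed 0-based offsets of the barcode and the two
#' SNP positions within the read layout.
#'
#' @param hotspot_id character label for the hotspot (e.g. `"Pbx1"`).
#' @param barcode_map named character vector mapping 8-base barcodes
#'   (names) to sample labels (values). Barcodes must be unique, length 8,
#'   alphabet ACGT.
#' @param left_snp_alleles,right_snp_alleles named character vectors with
#'   elements `A` and `B`: the single base expected for haplotype A and for
#'   haplotype B at the left / right flanking SNP. The two bases must
#'   differ within each flank.
#' @param barcode_offset,left_offset,right_offset 0-based positions of the
#'   barcode start and the two SNP bases within a fixed-layout read. Only
#'   used for FASTQ input/output; TSV molecule tables carry the fields
#'   directly.
#'
#' @return an object of class `hotspot_assay`.
#' @examples
#' assay <- hotspot_assay(
#'   hotspot_id = "Pbx1",
#'   barcode_map = c(ACGTACGT = "mouse1", TTGCAATG = "mouse2"),
#'   left_snp_alleles = c(A = "A", B = "G"),
#'   right_snp_alleles = c(A = "C", B = "T")
#' )
#' @export
hotspot_assay <- function(hotspot_id, barcode_map,
                          left_snp_alleles, right_snp_alleles,
                          barcode_offset = 0L, left_offset = 8L,
                          right_offset = 9L) {
  stopifnot(is.character(hotspot_id), length(hotspot_id) == 1L)
  if (length(barcode_map) < 1L || is.null(names(barcode_map))) {
    abort_data("`barcode_map` must be a non-empty named vector")
  }
  bc <- names(barcode_map)
  if (anyDuplicated(bc)) {
    abort_data("duplicate barcodes in `barcode_map`")
  }
  if (!all(nchar(bc) == 8L) || !all(grepl("^[ACGT]{8}$", bc))) {
    abort_data("barcodes must be 8 bases over the ACGT alphabet")
  }
  check_alleles <- function(x, side) {
    if (!all(c("A", "B") %in% names(x)) ||
        !all(x[c("A", "B")] %in% c("A", "C", "G", "T"))) {
      abort_data(sprintf("`%s_snp_alleles` needs single ACGT bases named A and B", side))
    }
    if (x[["A"]] == x[["B"]]) {
      abort_data(sprintf("%s flank: haplotype A and B bases must differ", side))
    }
    x[c("A", "B")]
  }
  structure(
    list(
      hotspot_id = hotspot_id,
      barcode_map = barcode_map,
      left_snp_alleles = check_alleles(left_snp_alleles, "left"),
      right_snp_alleles = check_alleles(right_snp_alleles, "right"),
      barcode_offset = assert_count(barcode_offset, "barcode_offset"),
      left_offset = assert_count(left_offset, "left_offset"),
      right_offset = assert_count(right_offset, "right_offset")
    ),
    class = "hotspot_assay"
  )
}

#' @export
print.hotspot_assay <- function(x, ...) {
  cat("<hotspot_assay>", x$hotspot_id, "\n")
  cat("  samples:", length(x$barcode_map), "barcoded\n")
  cat(sprintf("  left SNP  A=%s B=%s   right SNP A=%s B=%s\n",
              x$left_snp_alleles[["A"]], x$left_snp_alleles[["B"]],
              x$right_snp_alleles[["A"]], x$right_snp_alleles[["B"]]))
  invisible(x)
}

#' Read an assay definition from a YAML or JSON config file
#'
#' Expected keys: `hotspot_id`, `barcodes` (map barcode -> sample),
#' `left_snp_alleles` / `right_snp_alleles` (maps with keys A and B), and
#' optionally `barcode_offset`, `left_offset`, `right_offset`.
#'
#' @param path file path; format chosen by extension (`.json` vs yaml).
#' @return a [hotspot_assay()] object.
#' @export
read_assay_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("hotspot_id", "barcodes", "left_snp_alleles", "right_snp_alleles")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort_data(paste("assay config missing keys:", paste(miss, collapse = ", ")))
  }
  hotspot_assay(
    hotspot_id = cfg$hotspot_id,
    barcode_map = unlist(cfg$barcodes),
    left_snp_alleles = unlist(cfg$left_snp_alleles),
    right_snp_alleles = unlist(cfg$right_snp_alleles),
    barcode_offset = cfg$barcode_offset %||% 0L,
    left_offset = cfg$left_offset %||% 8L,
    right_offset = cfg$right_offset %||% 9L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
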