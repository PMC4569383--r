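#' Read and write molecule tables
#'
#' Molecule pools travel either as a 4-column TSV (`molecule_id`,
#' `barcode`, `left_base`, `right_base`) or as FASTQ with the barcode and
#' the two SNP bases embedded at the fixed offsets declared in the assay
#' definition.
#'
#' @param path file path.
#' @return `read_molecules_tsv`: data.frame of molecules.
#' @export
read_molecules_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  need <- c("molecule_id", "barcode", "left_base", "right_base")
  if (!all(need %in% names(df))) {
    abort_data(paste("molecule TSV needs columns:", paste(need, collapse = ", ")))
  }
  df[need]
}

#' @rdname read_molecules_tsv
#' @param molecules molecule data.frame.
#' @param header optional character vector of `#`-prefixed provenance
#'   lines to prepend.
#' @export
write_molecules_tsv <- function(molecules, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(molecules, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixed-layout read string for one molecule: filler 'N' everywhere except
# the barcode and the two SNP positions.
molecule_read_layout <- function(molecules, assay) {
  len <- max(assay$barcode_offset + 8L,
             assay$left_offset + 1L, assay$right_offset + 1L)
  reads <- vapply(seq_len(nrow(molecules)), function(i) {
    s <- rep("N", len)
    s[assay$barcode_offset + 1:8] <- strsplit(molecules$barcode[i], "")[[1]]
    s[assay$left_offset + 1L] <- molecules$left_base[i]
    s[assay$right_offset + 1L] <- molecules$right_base[i]
    paste(s, collapse = "")
  }, character(1))
  reads
}

#' @rdname read_molecules_tsv
#' @param assay a [hotspot_assay()] declaring the read-layout offsets.
#' @export
write_molecules_fastq <- function(molecules, assay, path) {
  reads <- molecule_read_layout(molecules, assay)
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- molecules$molecule_id
  quals <- Biostrings::BStringSet(
    vapply(nchar(reads), function(k) strrep("I", k), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname read_molecules_tsv
#' @export
read_molecules_fastq <- function(path, assay) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- as.character(seqs)
  data.frame(
    molecule_id = names(seqs),
    barcode = substr(reads, assay$barcode_offset + 1L, assay$barcode_offset + 8L),
    left_base = substr(reads, assay$left_offset + 1L, assay$left_offset + 1L),
    right_base = substr(reads, assay$right_offset + 1L, assay$right_offset + 1L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Provenance header lines for output tables: tool version, seed, and a
# short config digest so identical runs are recognizable at a glance.
provenance_header <- function(seed = NULL, config = NULL) {
  h <- c(sprintf("# hotspotkit %s", as.character(packageVersion("hotspotkit"))))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(config)) {
    # destination paths are not part of the run's scientific identity
    if (is.list(config)) {
      config <- config[setdiff(names(config), c("out", "config"))]
    }
    raw <- serialize(config, NULL)
    digest <- sum(as.integer(raw) * (seq_along(raw) %% 97L + 1L)) %% 1e9
    h <- c(h, sprintf("# config-digest: %09.0f", digest))
  }
  h
}

# Atomic table write: write to a temp file in the target directory, then
# rename over the destination.
write_table_atomic <- function(df, path, header = NULL) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "w")
  if (length(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
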