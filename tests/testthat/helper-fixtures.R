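# Shared fixtures, built in code.

fixture_assay <- function(n_samples = 3L) {
  barcodes <- c("ACGTACGT", "TTGCAATG", "GGCCTTAA", "CATGCATG",
                "AATTCCGG", "TGCATGCA")[seq_len(n_samples)]
  hotspot_assay(
    hotspot_id = "Pbx1",
    barcode_map = setNames(sprintf("mouse%d", seq_len(n_samples)), barcodes),
    left_snp_alleles = c(A = "A", B = "G"),
    right_snp_alleles = c(A = "C", B = "T")
  )
}

# quick molecule table from explicit fields
molecule_table <- function(barcode, left, right) {
  data.frame(molecule_id = sprintf("m%03d", seq_along(barcode)),
             barcode = barcode, left_base = left, right_base = right,
             stringsAsFactors = FALSE)
}

# random interval data.frame (0-based half-open), possibly multi-chromosome
random_intervals <- function(n, max_pos = 1e5, width_max = 500,
                             chroms = c("chr1", "chr2"), seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(width_max, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# O(n^2) all-pairs overlap oracle on half-open intervals
brute_force_overlaps <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, pairs)
  out <- data.frame(query = m[, 1], subject = m[, 2])
  out[order(out$query, out$subject), ]
}

# run the full typing pipeline on one simulated pool, return the rate row
simulate_and_estimate <- function(n, true_cM, chimera_prob, seed,
                                  background_cM = 0) {
  assay <- fixture_assay(1L)
  cfg <- sperm_sim_config(n, true_cM, chimera_prob,
                          barcode = names(assay$barcode_map)[1], seed = seed)
  sim <- make_sperm_molecules(cfg, assay)
  counts <- count_classes(demultiplex(sim$molecules, assay), assay)
  estimate_rate(counts, background_cM = background_cM)
}
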