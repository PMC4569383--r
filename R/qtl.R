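#' Assemble a cross panel
#'
#' Bundles the genotype matrix, marker map, phenotype and cross labels of a
#' QTL mapping panel. Genotypes are coded as the count of B6 alleles:
#' backcross (N2) mice take values \{1, 2\}, intercross (F2) mice
#' \{0, 1, 2\}.
#'
#' @param geno integer matrix, mice x markers, B6-allele counts.
#' @param map data.frame with one row per marker: `marker`, `chrom`,
#'   `pos_mb`.
#' @param pheno numeric phenotype per mouse (recombination rate in cM).
#' @param cross character/factor per mouse, e.g. `"N2"` / `"F2"`.
#' @return object of class `cross_panel`.
#' @export
cross_panel <- function(geno, map, pheno, cross) {
  geno <- as.matrix(geno)
  if (nrow(map) != ncol(geno)) abort_data("map rows must match geno columns")
  if (length(pheno) != nrow(geno)) abort_data("phenotype length != mice")
  if (length(cross) == 1L) cross <- rep(cross, nrow(geno))
  if (length(cross) != nrow(geno)) abort_data("cross label length != mice")
  if (!all(geno %in% 0:2)) abort_data("genotypes must be B6-allele counts 0/1/2")
  n2 <- cross == "N2"
  if (any(n2) && !all(geno[n2, ] %in% 1:2)) {
    abort_data("N2 (backcross) genotypes must be coded {1, 2}")
  }
  if (any(is.na(pheno))) abort_data("missing phenotypes are not supported")
  colnames(geno) <- map$marker
  structure(list(geno = geno, map = as.data.frame(map),
                 pheno = as.numeric(pheno),
                 cross = as.character(cross)),
            class = "cross_panel")
}

#' @export
print.cross_panel <- function(x, ...) {
  cat(sprintf("<cross_panel> %d mice x %d markers (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%d %s", table(x$cross), names(table(x$cross))),
                    collapse = " + ")))
  invisible(x)
}

# Residualize y and the columns of X on covariate matrix Z (with intercept).
resid_on <- function(M, Z) {
  qz <- qr(Z)
  M - Z %*% qr.coef(qz, M)
}

# Core engine: per-marker explained sum of squares for phenotype matrix Y
# (n x P, already residualized on covariates) against additive (A) and
# optional dominance (D) predictor matrices (n x M, residualized likewise).
# Returns an M x P matrix of LOD scores. Vectorised closed-form solve of
# the per-marker 1- or 2-predictor regression; degenerate (collinear or
# monomorphic) markers fall back gracefully to the largest well-defined
# submodel.
marker_lod_matrix <- function(Y, A, D = NULL) {
  n <- nrow(Y)
  rss0 <- colSums(Y^2)                      # 1 x P
  Saa <- colSums(A^2)                       # M
  SyA <- crossprod(A, Y)                    # M x P
  eps <- 1e-12
  if (is.null(D)) {
    expl <- sweep(SyA^2, 1, pmax(Saa, eps), "/")
    expl[Saa < eps, ] <- 0
  } else {
    Sdd <- colSums(D^2)
    Sad <- colSums(A * D)
    SyD <- crossprod(D, Y)
    det <- Saa * Sdd - Sad^2
    ok <- det > eps * pmax(Saa * Sdd, eps)
    expl <- matrix(0, nrow(SyA), ncol(SyA))
    if (any(ok)) {
      expl[ok, ] <- (SyA[ok, , drop = FALSE]^2 * Sdd[ok] -
                       2 * SyA[ok, , drop = FALSE] * SyD[ok, , drop = FALSE] * Sad[ok] +
                       SyD[ok, , drop = FALSE]^2 * Saa[ok]) / det[ok]
    }
    # collinear dominance column: single-predictor fallback
    if (any(!ok)) {
      sa <- pmax(Saa[!ok], eps)
      e1 <- SyA[!ok, , drop = FALSE]^2 / sa
      e1[Saa[!ok] < eps, ] <- 0
      expl[!ok, ] <- e1
    }
  }
  rss1 <- sweep(-expl, 2, rss0, "+")        # rss0 - explained
  rss1 <- pmax(rss1, eps)
  lod <- (n / 2) * log10(sweep(rss1, 2, rss0, "/"))
  -lod
}

# Build the design pieces for a panel: covariate matrix (intercept + cross
# indicator when crosses are pooled), residualized phenotype and predictor
# matrices.
panel_design <- function(panel) {
  n <- nrow(panel$geno)
  crosses <- unique(panel$cross)
  Z <- matrix(1, n, 1)
  if (length(crosses) > 1L) {
    Z <- cbind(Z, stats::model.matrix(~ factor(panel$cross))[, -1, drop = FALSE])
  }
  use_dom <- any(panel$cross == "F2")
  A <- resid_on(panel$geno, Z)
  D <- if (use_dom) resid_on(1 * (panel$geno == 1L), Z) else NULL
  y <- drop(resid_on(matrix(panel$pheno, ncol = 1), Z))
  list(Z = Z, A = A, D = D, y = y, use_dom = use_dom)
}

#' Single-QTL genome scan by marker regression
#'
#' At every marker, regresses the phenotype on the additive B6-allele
#' dosage (plus a dominance contrast when the panel contains F2 mice) and
#' reports `LOD = (n/2) log10(RSS0 / RSS1)`. Panels pooling N2 and F2
#' crosses are fitted with a cross-indicator covariate in both the null
#' and the QTL model. A monomorphic panel yields an all-zero LOD curve
#' with a warning. Ties at the peak are broken by the leftmost marker.
#'
#' @param panel a [cross_panel()].
#' @return object of class `qtl_scan`: data.frame `scan` (marker, chrom,
#'   pos_mb, lod), plus `peak_marker`, `peak_lod`, `n`.
#' @export
scan_single_qtl <- function(panel) {
  stopifnot(inherits(panel, "cross_panel"))
  des <- panel_design(panel)
  if (all(apply(panel$geno, 2, function(g) length(unique(g))) == 1L)) {
    warning("monomorphic panel: all LOD scores are zero")
  }
  lod <- drop(marker_lod_matrix(matrix(des$y, ncol = 1), des$A, des$D))
  lod <- pmax(lod, 0)
  scan <- data.frame(marker = panel$map$marker, chrom = panel$map$chrom,
                     pos_mb = panel$map$pos_mb, lod = lod,
                     stringsAsFactors = FALSE)
  peak <- which.max(scan$lod)               # which.max takes the leftmost tie
  structure(list(scan = scan,
                 peak_marker = scan$marker[peak],
                 peak_lod = scan$lod[peak],
                 n = nrow(panel$geno)),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan> %d markers, peak LOD %.2f at %s\n",
              nrow(x$scan), x$peak_lod, x$peak_marker))
  invisible(x)
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the phenotype against the genotypes (within cross strata when
#' crosses are pooled, preserving between-cross phenotype differences),
#' rescans, and returns the `1 - alpha` quantile of the per-permutation
#' genome-wide maximum LOD.
#'
#' @param panel a [cross_panel()].
#' @param n_perm number of permutations (>= 100; 1000 gives adequate
#'   quantile precision at `alpha = 0.05`).
#' @param alpha genome-wide type-I error rate (must satisfy
#'   `alpha >= 1/n_perm`).
#' @param seed integer seed.
#' @return list: `threshold` (LOD), `max_lods` (the permutation null
#'   distribution), `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(panel, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(panel, "cross_panel"))
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  if (alpha < 1 / n_perm || alpha > 1) {
    abort_data("`alpha` must be in [1/n_perm, 1]")
  }
  des <- panel_design(panel)
  n <- length(des$y)
  strata <- split(seq_len(n), panel$cross)
  Y <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- integer(n)
      for (s in strata) idx[s] <- s[sample.int(length(s))]
      des$y[idx]
    }, numeric(n))
  })
  lods <- marker_lod_matrix(Y, des$A, des$D)
  max_lods <- apply(pmax(lods, 0), 2, max)
  list(threshold = unname(quantile(max_lods, probs = 1 - alpha, type = 1)),
       max_lods = max_lods, n_perm = n_perm, alpha = alpha)
}

#' LOD support interval around the scan peak
#'
#' The contiguous run of markers on the peak chromosome whose LOD stays
#' within `drop` units of the peak LOD, reported in map positions (Mb).
#' `drop = 1.5` gives the conventional 1.5-LOD support interval, an
#' approximate confidence region for QTL location. A flat profile yields
#' the whole peak chromosome, with a warning.
#'
#' @param scan a `qtl_scan` from [scan_single_qtl()].
#' @param drop LOD drop defining the interval (default 1.5).
#' @return list: `chrom`, `lo_mb`, `hi_mb`, `peak_marker`, `markers` (the
#'   marker labels inside the interval).
#' @export
support_interval <- function(scan, drop = 1.5) {
  stopifnot(inherits(scan, "qtl_scan"), drop >= 0)
  s <- scan$scan
  peak_i <- which(s$marker == scan$peak_marker)
  chr <- s$chrom[peak_i]
  on_chr <- s[s$chrom == chr, , drop = FALSE]
  on_chr <- on_chr[order(on_chr$pos_mb), , drop = FALSE]
  pi <- which(on_chr$marker == scan$peak_marker)
  if (max(on_chr$lod) - min(on_chr$lod) == 0) {
    warning("flat LOD profile: support interval spans the whole chromosome")
  }
  keep <- on_chr$lod >= scan$peak_lod - drop
  lo <- pi
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- pi
  while (hi < nrow(on_chr) && keep[hi + 1L]) hi <- hi + 1L
  list(chrom = chr,
       lo_mb = on_chr$pos_mb[lo], hi_mb = on_chr$pos_mb[hi],
       peak_marker = scan$peak_marker,
       markers = on_chr$marker[lo:hi])
}

#' Genotype-class effect summary at a marker
#'
#' Mean phenotype and standard error per genotype class at one marker —
#' the effect plot behind a QTL peak — plus an additivity diagnostic: the
#' deviation of the heterozygote mean from the midpoint of the two
#' homozygote means (only defined when both homozygote classes are
#' present).
#'
#' @param panel a [cross_panel()].
#' @param marker marker name or column index.
#' @return list: `effects` data.frame (genotype, n, mean, se) and
#'   `additivity_deviation` (NA unless classes 0, 1, 2 all occupied).
#' @export
genotype_effect <- function(panel, marker) {
  stopifnot(inherits(panel, "cross_panel"))
  if (is.character(marker)) {
    marker <- match(marker, panel$map$marker)
    if (is.na(marker)) abort_data("unknown marker")
  }
  g <- panel$geno[, marker]
  cls <- sort(unique(g))
  eff <- data.frame(
    genotype = cls,
    n = as.integer(table(factor(g, levels = cls))),
    mean = vapply(cls, function(k) mean(panel$pheno[g == k]), numeric(1)),
    se = vapply(cls, function(k) {
      x <- panel$pheno[g == k]
      if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
    }, numeric(1))
  )
  add_dev <- if (all(0:2 %in% cls)) {
    mid <- (eff$mean[eff$genotype == 0] + eff$mean[eff$genotype == 2]) / 2
    eff$mean[eff$genotype == 1] - mid
  } else NA_real_
  list(effects = eff, additivity_deviation = add_dev)
}
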