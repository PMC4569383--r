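#' Multimer composition from allele abundances
#'
#' PRDM9 functions as a multimer (the working case is a dimer). Under
#' random subunit pairing, a heterozygote expressing two alleles at
#' relative monomer abundances `a1`, `a2` assembles multimers of order `n`
#' whose allele-1 subunit count is Binomial(`n`, `a1/(a1+a2)`). Equal
#' abundances and order 2 give the familiar 1:2:1
#' homodimer:heterodimer:homodimer pool.
#'
#' @param abundances numeric length-2 vector of relative monomer
#'   concentrations (non-negative, not both zero); optionally named by
#'   allele.
#' @param order multimer order `n >= 1` (default 2, the dimer case).
#' @return object of class `multimer_pool`: list with `order`,
#'   `p1` (allele-1 subunit fraction) and `composition`, a numeric vector
#'   of probabilities indexed by allele-1 subunit count `0..n`.
#' @examples
#' multimer_composition(c(1, 1))$composition     # 0.25 0.50 0.25
#' @export
multimer_composition <- function(abundances, order = 2L) {
  if (length(abundances) != 2L || any(abundances < 0)) {
    abort_data("`abundances` must be two non-negative numbers")
  }
  if (sum(abundances) == 0) abort_data("abundances must not both be zero")
  order <- assert_count(order, "order", min = 1L)
  p1 <- abundances[[1]] / sum(abundances)
  comp <- dbinom(0:order, size = order, prob = p1)
  names(comp) <- as.character(0:order)
  structure(list(order = order, p1 = p1, composition = comp),
            class = "multimer_pool")
}

#' @export
print.multimer_pool <- function(x, ...) {
  cat(sprintf("<multimer_pool> order %d, allele-1 subunit fraction %.3f\n",
              x$order, x$p1))
  print(round(x$composition, 4))
  invisible(x)
}

#' Predicted fraction of binding events at each allele's hotspots
#'
#' Given a multimer pool, predicts what fraction of hotspot-binding events
#' land on allele 1's versus allele 2's hotspot set. Pure homomultimers
#' bind only their own allele's sites. Mixed multimers are split by rule:
#' \describe{
#'   \item{`complete`}{every mixed multimer binds the stronger allele's
#'     sites (allele 1 by convention) — the infinite-affinity-ratio limit.
#'     A 1:2:1 dimer pool then gives the 3:1 split.}
#'   \item{`kd_weighted`}{each subunit arm competes with affinity `1/Kd` of
#'     its allele, so a mixed multimer with `k` allele-1 subunits of `n`
#'     binds allele 1 with probability `k*R / (k*R + (n-k))` with
#'     `R = kd_ratio` (Kd_weak/Kd_strong; allele 1 strong, i.e. smaller
#'     Kd, when `kd_ratio > 1`).}
#' }
#'
#' @param pool a `multimer_pool` from [multimer_composition()].
#' @param dominance `"complete"` or `"kd_weighted"`.
#' @param kd_ratio ratio `Kd(allele 2) / Kd(allele 1)` (> 0); only used
#'   under `kd_weighted`.
#' @return named numeric: fractions `allele1` and `allele2`, summing to 1.
#' @examples
#' pool <- multimer_composition(c(1, 1), order = 2)
#' predict_class_fractions(pool, "complete")          # 0.75 / 0.25
#' predict_class_fractions(pool, "kd_weighted", 3)
#' @export
predict_class_fractions <- function(pool,
                                    dominance = c("kd_weighted", "complete"),
                                    kd_ratio = 1) {
  stopifnot(inherits(pool, "multimer_pool"))
  dominance <- match.arg(dominance)
  if (kd_ratio <= 0) abort_data("`kd_ratio` must be > 0")
  n <- pool$order
  k <- 0:n
  comp <- pool$composition
  w1 <- switch(dominance,
    complete = ifelse(k == 0, 0, 1),                 # any allele-1 arm wins
    kd_weighted = ifelse(k == 0, 0,
                         ifelse(k == n, 1,
                                k * kd_ratio / (k * kd_ratio + (n - k))))
  )
  f1 <- sum(comp * w1)
  c(allele1 = f1, allele2 = 1 - f1)
}

#' Equilibrium occupancy of a hotspot binding site
#'
#' Single-site equilibrium binding: `occupancy = P / (P + Kd)` with `P` the
#' free protein concentration competent to bind the site and `Kd` its
#' dissociation constant. At `P = Kd` the site is half occupied, by
#' definition of Kd.
#'
#' @param kd dissociation constant(s), > 0 (vectorised).
#' @param free_protein free protein concentration, >= 0.
#' @return occupancy fraction(s) in `[0, 1]`.
#' @export
site_occupancy <- function(kd, free_protein) {
  if (any(kd <= 0)) abort_data("`kd` must be > 0")
  if (any(free_protein < 0)) abort_data("`free_protein` must be >= 0")
  free_protein / (free_protein + kd)
}

#' Dose titration over a hotspot landscape
#'
#' Applies the occupancy model to every site in a landscape at a given
#' total protein dose and flags sites whose occupancy reaches the
#' detection threshold. The per-site H3K4me3 proxy is the occupancy itself
#' (methylation assumed proportional to binding). Because occupancy is
#' monotone in dose for every Kd, halving the dose yields a detected set
#' that is a subset of the full-dose set — enriched for the smallest-Kd
#' (highest-affinity, highest-signal) sites — and the ranking of sites by
#' proxy level is identical at both doses.
#'
#' @param landscape data.frame with at least `site_id` and `kd` columns
#'   (e.g. the truth table of [make_hotspot_landscape()]).
#' @param total_protein protein dose in the same concentration units as Kd.
#' @param detection_threshold minimum occupancy to call a site detected,
#'   in (0, 1).
#' @return the landscape with `occupancy`, `h3k4me3_proxy` and `detected`
#'   columns added.
#' @export
dose_titration <- function(landscape, total_protein, detection_threshold) {
  if (!is.data.frame(landscape) || nrow(landscape) == 0L) {
    abort_data("empty landscape")
  }
  if (!all(c("site_id", "kd") %in% names(landscape))) {
    abort_data("landscape needs `site_id` and `kd` columns")
  }
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    abort_data("`detection_threshold` must be in (0, 1)")
  }
  occ <- site_occupancy(landscape$kd, total_protein)
  landscape$occupancy <- occ
  landscape$h3k4me3_proxy <- occ
  landscape$detected <- occ >= detection_threshold
  landscape
}

#' Fit the affinity ratio that reproduces an observed allele split
#'
#' Inverts [predict_class_fractions()]: given the observed fraction of
#' binding events (or of classified hotspots) assigned to the stronger
#' allele, finds the `kd_ratio` whose predicted fraction matches, by
#' monotone root-finding. The attainable range under a pool with mixed
#' fraction `m` and strong-homomultimer fraction `h` is `(h + m/2, h + m)`
#' for order 2; an observed fraction at or beyond the upper end means
#' complete dominance (ratio unbounded) and is signalled as an error.
#'
#' @param observed_strong_fraction observed fraction in (0, 1).
#' @param pool a `multimer_pool`.
#' @param tol convergence tolerance on the fraction scale.
#' @return estimated `kd_ratio` (`Kd_weak / Kd_strong`).
#' @examples
#' pool <- multimer_composition(c(1, 1))
#' fit_affinity_ratio(0.74, pool)   # the observed 26/74 hotspot split
#' @export
fit_affinity_ratio <- function(observed_strong_fraction, pool, tol = 1e-9) {
  stopifnot(inherits(pool, "multimer_pool"))
  obs <- observed_strong_fraction
  if (obs <= 0 || obs >= 1) abort_data("observed fraction must be in (0, 1)")
  pred <- function(r) predict_class_fractions(pool, "kd_weighted", r)[["allele1"]]
  lo_lim <- sum(pool$composition[pool$order + 1L])          # r -> 0 limit
  hi_lim <- predict_class_fractions(pool, "complete")[["allele1"]]
  if (obs >= hi_lim) {
    abort_data(sprintf(
      paste("observed fraction %.3f is at/above the complete-dominance limit",
            "%.3f for this pool: kd_ratio is unbounded"), obs, hi_lim))
  }
  if (obs <= lo_lim) {
    abort_data(sprintf(
      "observed fraction %.3f is at/below the attainable minimum %.3f",
      obs, lo_lim))
  }
  # monotone in r: bracket on log scale and bisect
  f <- function(logr) pred(exp(logr)) - obs
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  exp(uniroot(f, lower = lo, upper = hi, tol = tol)$root)
}
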