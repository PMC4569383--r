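---
title: "Measuring and modelling recombination hotspot activity with hotspotkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling recombination hotspot activity with hotspotkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotkit)
```

## The measurement problem

Meiotic crossovers cluster in short (1–2 kb) hotspots whose positions are
set by PRDM9, a polymorphic zinc-finger protein that marks its binding
sites with H3K4me3. hotspotkit implements the quantitative machinery
needed to study how hotspot *activity* — not just position — is
controlled: counting crossover molecules in sperm DNA, quantifying
amplifiable molecules by limiting dilution, mapping quantitative trait
loci (QTL) for recombination rate, assigning hotspot peaks to the allele
that defines them, and a dimer-competition model that ties these
observations together. Every input has a seeded synthetic generator, so
the full pipeline runs and is tested without any external data.

This vignette explains the models behind each module, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic data do and do not establish about real experiments.

## Sperm typing: counting crossover molecules

A sperm-typing assay amplifies single sperm-derived DNA molecules
spanning one hotspot. Each molecule carries an 8 bp sample barcode and
one SNP on each flank of the hotspot, so its haplotype phase is read
directly: flanks (A,A) or (B,B) are parental molecules, (A,B) and (B,A)
are crossovers (the two orientations are tallied separately and pooled
for rate estimation), and any flank base matching neither haplotype is
ambiguous and excluded from the denominator. The recombination rate is

$$\hat{c} = 100 \times \frac{n_{CO}}{n_{CO} + n_{par}} \; \text{cM},$$

with a Clopper–Pearson exact binomial interval — the right choice for
rates of a few tenths of a centimorgan, where normal approximations
misbehave.

**False recombinants.** PCR occasionally switches templates mid-cycle
("jump-PCR"): an incompletely extended strand re-primes on a different
molecule, decoupling the two flanks and manufacturing apparent
crossovers in control samples where recombination is impossible. The
generator models this with the simplest mechanism that produces false
recombinants in both orientations: with probability `chimera_prob` a
molecule's right flank is replaced by the right flank of a uniformly
random other molecule in the pool. With balanced parental input, the
expected apparent rate at a true rate of zero is
$100 \times p_{chimera} \times \tfrac12$ — strictly positive and linear
in the chimera rate, which is exactly why assays of this kind must
measure a control-mix background. `estimate_rate()` accepts that
background as a plug-in subtraction floored at zero; the default is 0
(raw rates), since published per-animal phenotypes of this type are
typically raw and the background enters as a reported assay property.
The mechanistic per-cycle chemistry of template switching is not
modelled; `chimera_prob` is the end-to-end probability.

**Barcode matching** is exact by default. With 8-base codes and small
code sets, tolerant matching buys little and risks cross-sample
collisions; a Hamming-distance tolerance is available as an explicit
knob.

## Limiting-dilution (MPN) quantitation

Allele-specific nested PCR can amplify crossover or parental molecules
selectively from pooled sperm DNA. To count molecules, the sample is
serially diluted (two-fold between consecutive levels by default) and
~20 parallel PCR wells are scored positive/negative at each informative
level. Under Poisson seeding a well is negative exactly when zero
amplifiable molecules entered it, so at a single level with dilution
factor $f$,

$$\hat\lambda = -\ln\left(\frac{n_{neg}}{n_{wells}}\right) \times f.$$

Levels are combined by the classical most-probable-number construction:
maximise $\prod_\ell \mathrm{Binom}(n_{neg,\ell};\, n_{wells,\ell},\,
e^{-\lambda/f_\ell})$ over the stock mean $\lambda$. When only one level
is informative this reduces exactly to the closed form above. The 95%
interval is a profile-likelihood interval (χ²₁ cutoff 3.84) rather than
a bootstrap, because 20-well counts are small and discrete. Degenerate
series are handled one-sidedly: all-negative gives $\hat\lambda = 0$
with an upper bound; all-positive gives an unbounded point estimate with
a lower bound. A well is treated as positive if and only if at least one
amplifiable molecule seeded it — PCR failure modes beyond template
absence are out of scope. The recombination rate follows as
$100\,\lambda_{CO}/(\lambda_{CO}+\lambda_{par})$.

Numerically, the likelihood is maximised on $\log\lambda$ (the scale on
which it is well conditioned) with `optimize()` at tolerance 1e-12, and
interval endpoints are found by `uniroot()` with an expanding upper
bracket.

## Single-QTL genome scan

Recombination rate measured per male is a quantitative phenotype and can
be mapped like any other. `scan_single_qtl()` performs marker
regression: at each marker, the phenotype is regressed on the additive
B6-allele dosage (0/1/2), with an added dominance (heterozygote
indicator) column whenever the panel contains F2 mice, and

$$\mathrm{LOD} = \frac{n}{2} \log_{10} \frac{RSS_0}{RSS_1}.$$

With complete observed genotypes — which the synthetic panels provide —
marker regression coincides with imputation-based scanning, so no
imputation engine is included. Panels pooling N2 (backcross) and F2
(intercross) mice are fitted with a cross-indicator covariate in both
the null and the QTL model. The engine residualises the phenotype and
all genotype columns on the covariates once and solves the per-marker
1- or 2-predictor regression in closed form across all markers
simultaneously, which is what makes dense permutation testing cheap.

**Significance** is genome-wide by permutation: the phenotype is
shuffled against the genotypes — within cross strata when crosses are
pooled, so between-cross phenotype differences are preserved under the
null — and the threshold is the $(1-\alpha)$ quantile of the
per-permutation maximum LOD. The default is 1,000 permutations: at
$\alpha = 0.05$ the threshold's Monte-Carlo error is already small
compared to between-panel variation, and larger counts are a flag away.
**Localisation** uses the 1.5-LOD support interval: the contiguous run
of markers on the peak chromosome within 1.5 LOD of the peak, reported
in map positions. Ties at the peak break to the leftmost marker, and the
scan grid is the markers themselves — positions are echoed as given
rather than interpolated onto a genetic map. `genotype_effect()`
summarises class means ± SE at the peak with an additivity diagnostic
(deviation of the heterozygote mean from the homozygote midpoint).

The panel generator segregates chromosomes with recombination between
adjacent markers given by the Haldane map function (no interference) at
0.5 cM/Mb, the mouse genome-wide average; the phenotype is baseline +
effect × (B6-allele count at the QTL) + Gaussian noise. These are the
standard no-frills choices for testing scan machinery; they do not
attempt chromosome-specific map ratios or crossover interference.

## Peak classification by interval overlap

ChIP peak sets (H3K4me3, DSB) travel as BED, and all interval logic is
0-based half-open with any-overlap (≥ 1 bp) as the overlap rule — no
reciprocal-fraction requirement, and strand is ignored. An F1 peak is
assigned `alleleA` if it overlaps the parent-A set only, `alleleB` if
parent-B only, `shared` if both, `novel` if neither; a peak overlapping
several peaks of one parent still counts once. Because conventions
differ on whether shared peaks belong to either allele class, the
summary reports `shared` as its own class *and* both foldings of it into
the two allele classes. `unique_peaks()` supports the
heterozygote-minus-homozygote design for identifying allele-specific
hotspots, and `subset_and_level_report()` checks the dosage prediction
that peaks surviving a reduced protein dose are the highest-signal
subset of the full-dose peaks.

## The dimer-competition model

The model explains allelic dominance at hotspots with three
ingredients:

1. **Random multimer assembly.** Two alleles at monomer abundances
   $a_1, a_2$ form order-$n$ multimers whose allele-1 subunit count is
   Binomial$(n, a_1/(a_1+a_2))$. For a dimer with equal abundances this
   is the 1:2:1 homodimer:heterodimer:homodimer pool. Order defaults to
   2 — the tractable case that the data constrain — but is a parameter,
   so higher-order complexes are explorable; whether in vivo complexes
   are dimers or larger is genuinely unresolved.
2. **Competitive binding under a limiting pool.** Each allele's
   zinc-finger array binds its own hotspot set with dissociation
   constant Kd; occupancy of a site is the single-site equilibrium
   $P/(P + K_d)$. The free protein concentration is treated as the fixed
   total pool: hotspot sites are assumed far from saturating the protein,
   which is the simplest reading of dosage-limited PRDM9 activity. (A
   ligand-depletion fixed point would be the refinement if site counts
   approached pool size; it is deliberately not the default.)
3. **Dominance of mixed multimers.** Homomultimers bind only their own
   allele's sites. A mixed multimer's arms compete: under `kd_weighted`
   a multimer with $k$ allele-1 arms of $n$ binds allele 1's sites with
   probability $k r/(k r + (n-k))$ where $r = K_{d,weak}/K_{d,strong}$;
   `complete` dominance is the $r \to \infty$ limit, under which the
   1:2:1 dimer pool predicts a 3:1 over-representation of the stronger
   allele's hotspots. Each binding event goes to exactly one allele
   class; arms are independent. `fit_affinity_ratio()` inverts the
   prediction by monotone root-finding on $\log r$, so an observed
   hotspot split (say 74% / 26%) maps back to an affinity ratio; the
   predict–fit round trip is accurate to 1e-6, and an observed fraction
   at or beyond the complete-dominance limit for the pool is reported as
   unbounded rather than fitted.

The landscape generator draws per-site Kd log-normally — affinities span
orders of magnitude and must stay positive — and places non-overlapping
1.5 kb sites so that generative ownership is recoverable by overlap
classification without ambiguity. Under a genotype, the pool competent
to bind an allele's sites is the total protein scaled by that allele's
*arm share*: 1 for the matching homozygote, 1/2 in a heterozygote
(counting each heterodimer as one arm of two), and 1/2 in a hemizygote
(half the pool, all of it one allele). This deliberately simple dose
model makes detected sets monotone in dose — a hemizygote's peaks are a
subset of the homozygote's — which is the qualitative behaviour the
dosage experiments show. It does not attempt to predict the quantitative
methylation level of hemizygotes (e.g. whether signal falls to 1/3 or
1/4), because the mapping from occupancy to measured H3K4me3 is not
constrained by anything the package computes: the H3K4me3 proxy is
occupancy times a constant.

## Statistical toolbox

Two printed-summary tests recur in this literature and are provided
directly: Fisher's exact test on 2×2 molecule-count tables (two-sided by
the conventional minimum-likelihood rule, i.e. summing all tables with
point probability at most the observed one), and Welch's
unequal-variance t-test computable from mean ± SD and n alone, with
continuous (unrounded) Welch–Satterthwaite degrees of freedom — the form
needed to check comparisons like "202 ± 29 (n = 16) vs 189 ± 18
(n = 28)" when only summaries are printed.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analyses
assume: Bernoulli crossovers at a set rate, chimeras decoupling flanks,
Poisson well seeding, Mendelian segregation with Haldane recombination,
one additive QTL, and occupancy-thresholded peak landscapes with known
ownership. They omit sequencing error and base quality, PCR duplicate
structure and amplification bias, allele-specific primer misfiring,
crossover interference, genotyping error and missing data, real marker
maps, and signal normalisation across ChIP libraries. Green tests
therefore establish that the estimators and classifiers are correct
*under their own model assumptions* and well calibrated at realistic
sample sizes — not that any particular biological value is reproduced
from raw data. Published headline rates (e.g. 2.38, 0.41 and 0.61 cM)
appear only as simulation set-points in recovery studies.

Problem sizes used by the test suite were chosen to exercise the
study-scale designs directly: typing recovery uses 25,000 molecules per
replicate and 100 replicates per set-point; QTL recovery uses 100 panels
of 49 N2 + 75 F2 mice × 165 markers with a 1-residual-SD additive QTL,
and type-I calibration uses 200 null panels with 1,000 permutations
each; oracle-equivalence checks run at n ≤ 1,000 intervals and 10⁵
molecules. The vectorised scan engine completes a 124 × 165 panel with
1,000 permutations in well under a second, so these studies run
comfortably on a laptop.

## Degenerate inputs and numerical conventions

- Rates with zero informative molecules, fold changes with a zero
  denominator, all-zero contingency tables, empty landscapes and empty
  low-dose peak sets raise typed data errors rather than returning NaN.
- Background subtraction floors at 0; LOD scores floor at 0; explained
  sums of squares guard against near-singular (collinear dominance)
  designs by falling back to the additive-only submodel at that marker.
- All generators take explicit seeds, save and restore the caller's RNG
  state, and are byte-identical across repeated calls with the same
  (config, seed).

## Limitations

Beyond the generator simplifications above: the scan fits single-QTL
additive(+dominance) models only — no multi-QTL or interaction scans
(conditional analyses are expressed by filtering the panel and
rescanning); the MPN module does not model nested-PCR efficiency; the
dimer model treats binding arms as independent and does not model the
protein-protein interfaces themselves; and peak classification performs
no peak calling or cross-library normalisation — it consumes called
peaks as given.
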