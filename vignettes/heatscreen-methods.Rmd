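---
title: "Methods behind heatscreen: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind heatscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatscreen)
```

heatscreen packages the computational steps of a heat-stress DREB
transcription-factor screen: tag-count differential expression between a
control and a heat-treated library, count-matrix normalisation and
screening for transgenic comparisons, pathway over-representation,
sequence-level candidate filtering, distance phylogeny, and the
phenotype/qPCR arithmetic used to verify candidates. This vignette
explains each model, its assumptions, the defaults, and the choices made
where the procedure was genuinely open.

## The two-library exact Poisson test

DGE tag profiling counts clean tags per gene in exactly two libraries,
without replication. Treating a gene's tag count as Poisson — each tag a
rare draw from a very large library — the count `y` in library 2 given
`x` in library 1 has, under equal expression, the distribution

$$p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

with `N1`, `N2` the library totals. `pEqualTerm()` evaluates this in log
space via `lgamma`, so counts in the millions cannot overflow; the terms
sum to 1 over `y` (verified to a tail below 1e-12 in the tests).
`twoSidedP()` implements the two-sided rule literally: twice the
cumulative sum up to `y`, or twice its complement when the sum exceeds
0.5, clipped to [0, 1]. Because the statistic is discrete the test is
conservative: under a pure-Poisson null the empirical size stays at or
below the nominal level, which the suite checks at 0.05 and 0.01 on a
10,000-gene simulation.

Assumptions worth keeping in mind: no biological replication (library
noise only), independence across genes, and totals `N1`, `N2` treated as
fixed. The screen threshold — FDR at or below 0.001 with a normalised
fold change above 2 — is the classical tag-DGE candidate rule and is the
package default (`tagDGE(fdrMax = 0.001, minFold = 2)`).

Open choices resolved here:

* **FDR procedure.** The step-up Benjamini–Hochberg adjustment is the
  default (`bhFdr`), with Benjamini–Yekutieli available by argument; BH
  is the standard choice for expression screens.
* **Fold change on normalised counts.** The fold is
  `((y+c)/N2)/((x+c)/N1)` with pseudocount `c = 0` by default: the test
  itself conditions on `N1`, `N2`, so the fold filter uses the same
  normalisation. A gene observed in only one library has an infinite
  fold and passes the fold filter; both-zero genes are flagged `NA` and
  never become candidates.
* **Direction.** Fold and log2 ratio are library 2 over library 1, so
  "up" means higher in the treated library.

## Count-matrix normalisation and the DE screen

`rpkm()` implements reads per kilobase per million mapped reads; the
identity `sum(RPKM * kb) = 1e6` per sample is enforced as a numerical
test. `scalingFactors()` computes one scaling factor per sample as the
median of that sample's gene-wise ratios to the geometric-mean reference
profile (genes with any zero excluded), normalised to geometric mean 1 —
the standard median-of-ratios construction; the suite cross-checks it
against an independent implementation up to the normalisation
convention.

`deScreen()` applies the package's own exact test to scaling-normalised,
group-summed counts and screens at `p_adj < 0.05` and `|log2 FC| > 1`.
This is deliberately a *screen statistic*, not a replacement for a
negative-binomial GLM: pooling replicates discards biological
variance, so p-values are anti-conservative under real replication.
What the screen shares with the NB tools — and what the bundled
worked-example table exercises — is the fold-change arithmetic and the
thresholds. Printed expression tables round log2 fold changes to two
decimals with ties away from zero (`roundHalfAway`); the bundled
readcount pairs (inst/extdata/hormone_deg_readcounts.tsv) are the rows
whose printed value is reproduced exactly by the plain ratio of the
printed means — for the remaining published rows the printed readcounts
are rounded normalised means, and the ratio lands within 0.03 of the
printed value, so they are not used as exact fixtures.

## Pathway over-representation

`hypergeomP()` is the upper-tail hypergeometric probability (via
`phyper`), tested against exhaustive combinatorial enumeration for
universes up to 30 genes, and by the monotonicity and query/pathway
exchangeability properties. `enrich()` reports one record per pathway
overlapping the query and adjusts those p-values by BH; the "Q-value"
threshold (0.05 by default) is therefore a BH-adjusted p — the upstream
tools' Q-value definition is not pinned down, and BH is the conservative
common denominator. The universe defaults to the union of the collection
and should be set to the assayed genes when known; the tie-break in
ranked output is `(q, p, pathway_id)`, which makes `topKOverlap()`
deterministic.

## Sequence screens

* `translateCds()` validates the reading frame (length divisible by 3,
  ATG start warning, internal stop is an error naming the codon), and
  strips a terminal stop, so a 579-nt CDS encodes 192 residues.
* `scanDre()` finds all, possibly overlapping, matches of IUPAC
  patterns on both strands; minus-strand sites are located by matching
  the reverse-complemented pattern on the forward strand so all
  coordinates stay forward-strand 1-based inclusive (the R/Bioconductor
  convention, used consistently across the package). Overlap
  deduplication is intentionally left to the caller. The default
  pattern set is the DRE/CRT core `[A/G]CCGAC` plus the DRE1/2/3 bait
  9-mers and the mutant control.
* `findDomains()` searches for a domain consensus by iterated
  Smith–Waterman local alignment (BLOSUM62, gap open 11, extend 1):
  report the best hit, mask it with `X`, repeat until the score falls
  below `minScore`. Masking guarantees non-overlapping hits. The
  `minScore` default (60) suits a ~58-residue consensus;
  `calibrateDomainScore()` sets it empirically as the 99th percentile
  of best scores on simulated domain-free proteins, which keeps the
  null hit rate under 1%. `singleDomainFilter()` keeps proteins with
  exactly one hit — the DREB signature. The shipped AP2-like consensus
  (inst/extdata/ap2_consensus_synthetic.fa) is a synthetic sequence
  constructed for demonstrations; tests rely only on simulated
  consensi.
* `extractPromoters()` takes `upstreamBp` (default 2000 bp, a common
  promoter window; configurable) 5' of the gene start, reverse
  complemented for minus-strand genes, truncating with a warning at
  contig edges. The strand-symmetry invariant — reverse-complementing
  the genome and flipping the annotation yields identical promoters —
  is part of the suite.

## Neighbor-joining phylogeny

`pDistance()` computes mismatch proportions with pairwise deletion of
gap columns; a Poisson-type correction was considered and left out
because the downstream consumer (topology + bootstrap) is invariant to
monotone distance transforms on clean data, and p-distance is the
assumption-lightest default. `njTree()` is the standard Saitou–Nei
agglomeration with two determinism guarantees: ties in the Q-criterion
break to the lowest index pair, and negative branch-length estimates
are clamped to zero with the deficit moved to the sibling edge
(preserving the joined pair's path length; the count is recorded in
`attr(tree, "clamped")`). On additive matrices the reconstruction is
exact — leaf-to-leaf path lengths equal the input — which the suite
verifies for random trees up to 8 taxa, alongside topological agreement
with an independent NJ implementation. `njBootstrap()` resamples
alignment columns, rebuilds the tree per replicate, and reports for
each internal edge of the full-data tree the percentage of replicates
containing the same bipartition (canonicalised by the side containing
the first taxon, so supports are invariant to taxon order). 1,000
replicates is the conventional default; tests use 60–100 to stay fast.

## Quantification

`ddct()` averages replicate Ct values before differencing
(target − reference, then sample − calibrator), the usual lab
convention; per-replicate RQ values are available via
`perReplicate = TRUE` for SD propagation. Amplification efficiency is
assumed to be 2 (no Pfaffl correction). The heat injury index
`heatInjuryIndex()` applies the weighted-percentage formula verbatim
over ordinal levels 0..3 by default (0 no curling; 3 whole plant
wilted); it is bounded in [0, 100] and monotone in severity, both
property-tested. `replicateSummary()` uses the equal-variance Student's
t-test (Welch by flag) with `**`/`*` stars at 0.01/0.05.

## The synthetic-data layer

The generators emulate the statistical structure of the study designs:

* `simTagLibraries()` — two libraries of ~1e6 tags (the default
  `librarySizes`), lognormal gene abundances (sdlog 1), a DE fraction
  (default 0.1) with fixed-magnitude log2 effects of random sign
  (default 2), Poisson counts or gamma-Poisson with variance
  `mu + phi mu^2` (`dispersion = 0` recovers the tag-DGE Poisson
  assumption). Library-2 means are not re-normalised after the DE
  shift; the realized totals are the column sums.
* `simCountMatrix()` — replicated two-group NB counts (default 3 per
  group, dispersion 0.05, per-sample depth 5e5) with gene lengths
  uniform on 200–3000 bp.
* `simPromoters()` / `simProteins()` — uniform i.i.d. backgrounds
  (ACGT; 20 amino acids) with elements or mutated domain copies planted
  at recorded positions; uniform background composition is configurable
  but is the default in the absence of a stated genome model.
* `simCtTable()` — target Ct shifted by `-log2(RQ)` against a constant
  reference; Gaussian Ct noise.
* `simInjuryTally()` — multinomial plants over levels.
* `simAlignment()` — Jukes–Cantor evolution along a tree, no indels.

Each generator takes its own `seed` and restores the caller's RNG
state, so adding one simulation to a script never perturbs another.
What the generators do **not** model: tag-to-gene mapping ambiguity and
sequencing error (simulation starts at per-gene counts), compositional
coupling between genes, GC/length biases, promoter base composition,
amplification-efficiency drift, and alignment indels. Passing recovery
tests therefore demonstrate correctness of the algorithms under their
own assumptions, not robustness to every artefact of real libraries.

## Problem sizes and numerics

The suite exercises: the exact-test term against an independent
high-precision evaluation over the full `x, y <= 50` grid at three
library-size ratios (relative error below 1e-10, with spot values frozen
from an exact rational-arithmetic computation); a 10,000-gene null and a
2,000-gene power simulation (sensitivity at least 0.9 at a 4-fold
effect, seeds fixed); hypergeometric enumeration to `N = 30`; NJ
round-trips to 8 taxa; motif scanning against a sliding-window oracle on
1,000 random 200-nt sequences; and ddCt recovery grids (median error
under 10% at 0.1-cycle noise). These sizes keep the whole suite under
two minutes on one core while leaving each statistical check enough
resolution to fail loudly if an implementation drifts.
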