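---
title: "Detecting sex chromosomes and reconstructing their turnover dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex chromosomes and reconstructing their turnover dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexchromevol)
```

`sexchromevol` implements a workflow for finding homomorphic sex
chromosomes in cohorts of closely related species and for quantifying how
fast sex-chromosome systems turn over on a time-calibrated phylogeny. This
vignette explains the models and procedures, the parameters that matter,
the synthetic-data generator that the tests rest on, and the numerical
choices made where the design was genuinely open.

## The detection problem

In a male-heterogametic (XY) system the male carries two different sex
alleles; in a female-heterogametic (ZW) system the female does. At a
sex-linked variant site the heterogametic individual is therefore
heterozygous while the other sex is homozygous, and in expressed data one
allele is seen only in the heterogametic sex. Single such sites are
uninformative — random variation produces the same configuration — so all
three scans look for *accumulations* of sex-patterned sites along a
chromosome, the footprint of suppressed recombination around a
sex-determining locus.

Three complementary scans are implemented:

1. **WGS accumulation scan** (tribe-wise). Each site is classified per
   species from its male/female genome pair as `XY` (male heterozygous,
   female homozygous), `ZW` (mirrored), `nosex` (neither pattern) or
   `noinfo` (a missing genotype). Class counts are summed over all species
   of a tribe in 10-kb windows sliding by 2 kb, and each window's observed
   XY/ZW/nosex counts are compared with expected counts — genome-wide
   class fractions times the window's called sites — by Fisher's exact
   test (Pearson chi-squared for tables whose total exceeds 10,000, where
   exact computation is impractical). Windows are designated XY or ZW only
   when one class is above and the other below expectation; windows with
   both above are ambiguous and dropped. Significance alone is not
   trusted: the class labels are permuted within each species across the
   fixed site positions 100 times, the window pipeline is re-run, and the
   largest per-species-normalised |XY−ZW| difference across permutations
   becomes the tribe's threshold. Retained windows must beat that
   threshold *and* have −log10(p) > 20, a deliberately drastic cutoff.
   Retained windows merge into regions; individual genotypes over each
   region are clustered (Gower mismatch distance, divisive clustering cut
   at two groups), and a species is attributed the call only when its
   male/female pair separates at the cut, its within-region XY−ZW
   difference matches the region direction, and at least one other
   species of the tribe shares the signature.

2. **Association scan** (tribe-wise). A Cochran–Armitage trend test of
   genotype dosage against sex per SNP, followed by clustering of all
   individuals' genotypes at either the top-*k* SNPs (*k* = 100; broad,
   chromosome-scale signals) or all SNPs with −log10(p) > 3 (narrow
   peaks). A species is called when its pair separates by sex at the
   two-cluster cut and the male (female) is heterozygous at more than 80%
   of the selected SNPs while the other sex is homozygous. The 0.8 rule
   makes explicit what is otherwise a visual heatmap inspection. The
   mixed-model structure correction used with real data is intentionally
   omitted: the synthetic cohorts carry no population structure, and the
   decisive step is the downstream clustering, which is reproduced
   faithfully.

3. **Transcriptome scan** (species-level). Replicate allele counts
   (typically 3 males + 3 females) are screened per SNP by a Fisher exact
   test on sex-pooled ref/alt counts with Benjamini–Hochberg adjustment
   (adjusted p ≤ 0.05); this pooled exact test is a transparent stand-in
   for a dedicated differential-allele-use caller, since the decisive
   filters come next: a SNP is XY if its alternative allele has zero reads
   in every female and at least one read in at least two males (ZW
   mirrored). XY−ZW differences per 10-kb non-overlapping window are
   screened for outliers (above Q3 + 1.5·IQR; the mirrored low tail is
   included by default so ZW systems are detectable symmetrically — a
   `one_sided` flag restores the literal high-tail rule). With at least
   three outlier windows, a paired two-sided Wilcoxon signed-rank test on
   (XY, ZW) counts decides the heterogametic system (p < 0.05, side with
   the larger total). Candidate LGs must exceed Q3 + 3·IQR of
   length-normalised per-LG SNP counts *and* mean + 1 SD ("higher than the
   standard deviation" is read as mean + 1·SD, since comparing a count to
   a standard deviation directly is units-inconsistent; a config switch
   restores the literal reading). Quantiles use the linear-interpolation
   convention (type 7).

Calls are merged into a **permissive** set (everything) and a
**stringent** set that drops calls supported only by the WGS accumulation
scan and prunes accumulation-scan-only LGs out of multi-LG (fusion) calls.
Conflicting heterogamety between scans demotes a call to permissive-only,
keeping the transcriptome side where there is one (the transcriptome scan
rests on six individuals rather than two).

## Variant-level filtering

Before any scan: SNPs near indels are masked (2 bp for 1-bp indels, 3 bp
for 2–3 bp, 5 bp for 4–5 bp, 10 bp beyond; 2-bp indels have no stated
width and are interpolated to 3 bp to keep widths monotone), indels are
dropped, genotypes with GQ < 20 or DP < 4 are set missing, sites with more
than two alleles or more than 50% missing genotypes are removed, sites
with no alternative allele left are removed as monomorphic, and sites
where no retained genotype carries the reference allele are recoded with
the first alternative as reference. Coordinates are 1-based inclusive
throughout; the indel mask covers the indel's reference span plus the
width on both sides. The indel mask runs before genotype-level masking
(the order is not prescribed; the two filters commute except at sites
that both lose genotypes and flank indels, where the conservative order
removes slightly more).

## The synthetic-data generator

Every downstream stage is exercised on cohorts with planted truth, so the
generator's assumptions bound what the tests demonstrate.

* **WGS cohorts.** Sites are uniform on each LG at ~5 sites/kb (the real
  resequencing data are denser still, ~20/kb). Background genotypes are
  i.i.d. across individuals with heterozygosity 0.1 and a 10% homozygous-
  alternative share, so random SNPs are mostly low-frequency and ~82% of
  classified sites come out `nosex` — the "most sites show no sex
  difference" regime the window expectations assume. Inside a planted
  region, a fraction *d* (the differentiation) of sites is sex-specific
  (male het / female hom-ref for XY), and species sharing a system share
  the same sex-specific sites, as a shared sex chromosome implies.
* **Transcriptomes.** Background SNPs have sex-balanced Poisson counts;
  25% of them are sex-biased (one sex expresses the alternative allele
  exclusively, direction random) — emulating the autosomal sex-biased
  allelic expression that, in real gonad-containing transcriptomes, fills
  the genome-wide window distribution with scattered classified SNPs.
  Planted sex-specific SNPs concentrate in 20 expressed 10-kb patches
  (genes) of the true region and are forced classifiable (≥ 2 non-zero
  heterogametic replicates).
* **Character histories.** Continuous-time Markov simulation down the
  tree, recording every change, in the same data structure the stochastic
  mapper emits, so turnover detection can be run against the exact truth.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, population structure and shared drift between related
species, reference mapping bias, and read-level noise. Passing tests
therefore demonstrate the logic and calibration of the statistics, not
robustness to those real-data complications — the permutation threshold
and the ≥ 2-species rule address them on real data but are exercised here
only under idealised noise.

## Phylogenetic machinery

Ancestral states are modelled with the Mk family: a continuous-time Markov
chain over recruited-LG identities (run per LG as a binary trait) or
heterogamety states, with equal (ER), symmetric (SYM) or unconstrained
(ARD) rates. The likelihood is computed by Felsenstein pruning with *soft*
tip priors — a species without information contributes a uniform
probability row rather than being dropped — and a uniform root prior,
matching that coding philosophy (a stationary-prior option exists). Rates
are optimised by bounded quasi-Newton (`L-BFGS-B`, two starting values,
rates bounded to [1e−9, 1e4]); models are compared by AIC with ties within
1e−6 going to the simpler model. The pruning likelihood is verified
against exhaustive enumeration on small trees and against an independent
implementation.

Stochastic maps are drawn by sampling node states from their conditional
posteriors and then sampling each branch path conditional on its endpoint
states by uniformization (rate Ω = 1.05·max|Q_ii|, rejection-free), the
standard endpoint-conditioned CTMC sampler. Turnover points are read off
the maps: the per-state posterior is evaluated on a 100-point grid per
branch, and walking rootward from each tip carrying the state, the first
crossing below 0.5 (linearly interpolated between grid points) is the
gain point. Only gains are retained — species without a detectable system
are not counted as losses. Events are deduplicated per branch, and a path
whose posterior never crosses 0.5 yields a single event at the root edge
flagged `root_or_earlier` rather than being dropped, preserving gain
counts.

The turnover **rate** divides the event count by the total branch length
of the tree (events per lineage-My). The alternative denominator (tree
height) is available, but total branch length is the definition under
which a rate *r* implies one expected event between two species that
diverged 1/(2*r*) My ago — two diverging lineages accumulate events at
twice the per-lineage rate — which reproduces the published companion
statement (0.186/My ↔ ~2.7 My).

Heterogamety transitions use the same machinery over XY/ZW (optionally
NonGSD); each gain's source state is the dominant other state just
rootward of the crossing. Transition ages by direction are compared with
a two-sided Mann–Whitney U test (the original analysis states only a
p-value; the test is a design choice here). The recruitment randomization
test draws, per simulation, *n* 10-kb windows uniformly over the genome
(LG with probability proportional to length) and reports how often at
least the observed number of LGs goes unrecruited; with equal-length LGs
its mean matches the closed-form binomial expectation, which the tests
assert. pGLS regressions (turnovers ~ richness, differentiation ~ age)
use generalized least squares with the Brownian covariance C_ij = shared
path length, computed in closed form so that exact relationships (zero
residual variance) are handled; on a star phylogeny the estimates reduce
to ordinary least squares.

## Differentiation and convergence

The sex-differentiated region of a called species is the set of 10-kb
windows on its called LG whose sex-specific SNP count (a count per
window, not a per-bp rate) exceeds twice the genome-wide mean over *all*
windows of all LGs (the threshold base is ambiguous in the source; the
all-genome reading is the default). Cumulative length, coordinate range
and the proportion of the LG follow. For convergence testing, X and Y
haplotypes are extracted at sites XY-classified in at least one focal
species with < 10% missing data: for a focal male, the allele shared with
its homozygous female is the X, the other the Y; non-focal individuals
contribute both alleles in seed-randomised order. A neighbor-joining tree
on Hamming distances (ignoring `N`) stands in for full ML tree inference
— the question answered is topological (do Y haplotypes group by clade or
together?), not branch-length fidelity.

## Numerical choices and problem sizes

* Window grids anchor at position 1 per LG; final partial windows are
  kept when they contain a called site.
* Opposite homozygotes (hom-ref vs hom-alt) are neither heterozygous
  pattern and are classified `nosex`; their count is logged for
  diagnostics.
* Region merging joins windows sharing ≥ 1 bp; region direction comes
  from the minimum-p window, ties broken toward the larger |XY−ZW|.
* In the permutation loop the window test uses the (vectorised) Pearson
  chi-squared branch; the observed data use the exact test where
  feasible. The permutation threshold itself is a max over |XY−ZW|
  differences, so this affects only the recorded minimum permutation p.
* The default reference masks excluded from calls are the protocadherin
  tandem array on LG02 (21.36–21.93 Mb) and all of LG03.
* Test and acceptance runs use desk-scale cohorts — six species, two
  800-kb LGs, 4,000 sites/LG for the WGS scans; 2,000 SNPs over 23 2-Mb
  LGs for the transcriptome scan; 16–20-tip trees with 200–1,000
  stochastic maps — chosen so the full recovery suites run in minutes
  while every statistic stays in its calibrated regime.
* Turnover localisation is exercised on gains planted on the longest stem
  of a 3–5-tip clade below the root: for near-zero stems the crossing
  point legitimately lands on the neighbouring branch, and the direction
  of a change on a root-attached clade is unidentifiable under a
  symmetric model with a uniform root prior.

## Known limitations

* The association scan omits kinship/structure correction; on structured
  real data it must be replaced by a mixed model, and only the
  downstream clustering step carries over unchanged.
* The permissive/stringent conflict policy (transcriptome evidence trumps
  the accumulation scan on LG identity; heterogamety contradictions
  demote to permissive-only) codifies a case-by-case narrative; every
  resolution is logged in the call flags.
* Stochastic-map-based localisation has branch-level resolution at best;
  events on short deep branches inherit that uncertainty.
* The recruitment test treats LG choice as length-proportional sampling
  of a single 10-kb window; it does not model correlated recruitment
  within clades.
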