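---
title: "Quantifying A-to-I RNA editing in single-nucleus RNA-seq: models and design"
author: "scredit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-to-I RNA editing in single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scredit)
```

## The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes is the most
abundant RNA modification in the primate brain. Inosine is read as
guanosine by sequencing, so editing appears in RNA-seq variant calls as
A>G mismatches (or T>C on the antisense strand of unstranded data).
Full-length single-nucleus RNA-seq (SMART-seq style) captures nuclear
pre-mRNA at depth sufficient to call editing per nucleus, but three
obstacles stand between raw variant calls and biology:

1. **Genomic SNPs masquerade as editing.** Without a matched genome,
   an A/G heterozygous SNP is indistinguishable at a single site from a
   ~50%-edited position.
2. **Strand ambiguity.** Unstranded libraries cannot tell an A>G
   variant on the plus strand from a T>C on the minus strand; the
   cognate gene strand must be inferred from annotation, and regions
   where genes overlap on opposite strands are uninterpretable.
3. **Sparsity.** Any given site is transcribed in only a few percent of
   nuclei, so "not transcribed" must be distinguished from
   "transcribed, unedited" and statistics must pool information across
   cells.

`scredit` implements a filter cascade addressing 1–2, an
`editing_matrix` container addressing 3 (paired alt-count and depth
matrices, with depth 0 meaning *not transcribed*), per-cell editing
indices, pseudobulk differential-editing tests, abundance–editing
association models, and a synthetic-data generator that reproduces the
statistical structure these analyses assume, so that every stage is
testable without restricted human data.

## Filter cascade

Cells failing QC are removed first: mitochondrial read fraction
strictly greater than 0.15 (apoptosis proxy), or library complexity
(detected genes) below 1000. The complexity cutoff is a free parameter
of the pipeline — published analyses typically report only that
low-complexity libraries were removed — and is exposed as
`min_complexity`.

Candidate sites are A>G or T>C variants that, in at least `min_cells =
10` QC-passing nuclei, have read depth ≥ 5 with an alternate-allele
count ≥ 2. All thresholds are inclusive ("at least"), and each nucleus
must individually satisfy both the depth and the alt-count condition to
count towards prevalence; requiring mere detection in 10 nuclei would
be the laxer alternative, which we do not use. A replication-style
configuration with `min_cells = 3` suits small data sets. Because
library preparation is independent per nucleus, the prevalence filter
also suppresses PCR artifacts.

Common genomic SNPs are then removed by exact (chrom, pos, ref, alt)
match against a supplied list. Finally the strand rule: a site is kept
iff it is present in a known editing-site catalog (REDIportal-like), or
it lies in exactly one gene footprint with no overlapping gene and its
variant class is cognate with that gene's strand (A>G on +, T>C on −).
Catalog membership rescues only the strand/overlap rule — a cataloged
site must still pass coverage and prevalence, since rescue of
low-evidence sites would reintroduce exactly the artifacts the
prevalence filter removes. Retained sites are reported canonically as
A>G on the inferred strand. Sites in unannotated intergenic space that
are not cataloged cannot satisfy the rule and are dropped.

Context annotation assigns Alu > repetitive non-Alu > nonrepetitive
with Alu precedence when intervals nest; feature annotation uses the
specificity order stop codon > UTR > exon > intron. Novelty is absence
from every supplied catalog, with per-catalog membership flags retained
so that set-intersection censuses (`editing_census()`) can reproduce
upset-style tables exactly.

## Editing indices

The global editing index (GEI) of a nucleus is the unweighted mean of
alt/depth over the candidate sites transcribed in it; the Alu editing
index restricts to Alu-context sites, and the stringent variant to Alu
sites transcribed in ≥ 100 cells. The unweighted mean (rather than
pooled counts) makes the index a per-cell average of per-site editing
levels, insensitive to which highly covered site dominates a cell.
Undefined indices (no eligible transcribed site) propagate as `NA`,
never zero. "Edited in a cell" defaults to alt ≥ 1 at a transcribed
site; the stricter alt ≥ 2 is available via `edited_min_alt`.

Group comparisons of indices use an ordinary linear model of the index
on group indicators plus log10 library size, since library size has a
modest but real effect on editing indices. Phenotype is the default
unit of comparison; subgroup and region-by-phenotype groupings are
options.

## Pseudobulk differential editing

Per-cell counts are too sparse for site-level testing, so counts are
summed within (subgroup × region) pseudoreplicates. Sites whose edited
counts do not vary across pseudoreplicates (variance ≤ 0.2, on counts
by default; on fractions as an option) carry no signal and are removed.

Site-level testing adapts the paired-count design used for bisulfite
differential methylation: for each site, the edited and unedited counts
of every pseudoreplicate enter one negative-binomial GLM with

* a blocking term per sample (absorbing total coverage),
* an editing-status indicator,
* status × adjustment interactions (cortical region by default), and
* the status × contrast interaction — the log odds-ratio of editing
  between phenotypes, the coefficient of interest.

Unlike ratiometric tests, this keeps coverage in the model, so
low-coverage, high-variance sites are not favoured. The NB dispersion
is estimated per site by matching the Pearson statistic to the residual
degrees of freedom (a profile-type estimator that, unlike the naive
moment estimator, accounts for the large number of fitted blocking
parameters), then shrunk towards the median dispersion with 10 prior
degrees of freedom. With dispersion strongly moderated it is treated as
known and Wald statistics are referred to the standard normal; under
exchangeable null simulations (binomial through strongly beta-binomial
pseudoreplicates, 8 samples) the empirical type-I error at α = 0.05
stays within [0.044, 0.060]. Sites with an all-zero arm are refitted
with 0.5 added to both arms and flagged. FDR is Benjamini–Hochberg
throughout.

Two caveats are deliberate. First, the test assumes pseudoreplicates of
broadly comparable size; when one contrast group systematically has
far fewer cells per pseudoreplicate, continuity corrections shrink its
editing log-odds towards zero and both the site and gene tests acquire
bias — aggregate at a coarser grouping in that case. Second, swapping
the contrast labels exactly negates every log fold-change and preserves
p-values, which the test suite asserts.

## Directional gene-level test

No single site may survive site-level correction, yet a gene can show a
consistent shift across its sites. The gene statistic is the mean of
per-site moderated t-statistics for the contrast effect, computed from
weighted linear models of per-sample editing log-odds (weights from the
delta-method variance of the log-odds). Residual variances are squeezed
towards an empirical-Bayes scaled-F prior fitted across all sites, and
the t statistics are mapped to standard-normal equivalents so a few
heavy-tailed sites cannot dominate the mean.

The null is generated by random rotation: each site's data are reduced,
via the QR decomposition of the (weighted) design, to a vector holding
the adjusted contrast effect plus the residual-space coordinates. Under
the null and Gaussian errors this vector's direction is uniform, so
projecting it onto random unit vectors — the same rotation applied to
every site of a gene, preserving inter-site correlation — yields an
exact finite-sample null for the gene statistic. Two one-sided rotation
p-values combine into a direction and a two-sided p; `n_perm` defaults
to 10^4 and values below 100 are refused. Genes with fewer than
`min_sites = 2` sites are excluded.

A power note: with 8 pseudoreplicates the residual space has few
dimensions, so chance alignment between sites' residual vectors costs
sensitivity relative to an (invalid) independence assumption. This is
intrinsic to exact rotation tests at small sample counts. Under our
validation conditions — a 10-site gene with a 0.5 log-odds cell-level
shift, per-cell depth around 20, sites in the dynamic range of editing,
~40 cells per pseudoreplicate — power at FDR < 0.1 exceeds 0.9.
Equivalent planted shifts expressed only at pseudobulk depth ~20 are
below the information bound of any test of this class: a site with 80
reads per arm carries about one standard error of signal at this effect
size, so ten sites top out near 3σ, and we verified that an established
rotation implementation reaches the same ceiling. Differential sites at
saturated editing levels (near 0 or 1) likewise cannot express a
log-odds shift; the power study therefore plants sites at intermediate
baseline editing, which is also where differential editing is
biologically observable.

Disease-overlap questions ("are disease-associated sites concentrated
in genes differentially edited in one direction?") reduce to a 2×2
table tested by Fisher's exact test, with the sample odds ratio
reported and degenerate margins flagged rather than erroring.

## Abundance–editing association

Per gene, GEI is modelled as a linear function of log10 TPM over the
cells expressing the gene (TPM > 0), controlling for gross phenotype
and log10 library size. Fitting only expressing cells matches how such
associations are usually displayed (index versus log abundance among
expressing cells); including zeros with a pseudocount is the exposed
alternative. Genes expressed in fewer than 300 cells are skipped —
the same "expressed in ≥ 300 nuclei" rule used for background gene
sets. Significance requires both FDR < 0.05 and |beta| > 0.01 (index
units per log10 TPM); tiny-but-significant effects in thousands of
cells are biologically negligible. Because significant genes are
preferentially the widely expressed ones, `downsample_check()` refits
each on a seeded subsample of at most 1500 expressing cells and reports
sign concordance and retained significance. Association profiles from
two data sets are compared by Pearson correlation of shared-gene betas,
with a Mann–Whitney separation test for labelled subsets (e.g. genes
with known positive/negative editing associations from bulk tissue).

## The synthetic-data generator

The generator emulates the statistical structure reported for cortical
sNuc-seq editing, not any real genome:

* **Bimodal per-cell edited fractions.** Each site carries a high-mode
  weight `w_s ~ Beta(0.4, 0.6)`; each (site, cell) draws its editing
  probability from a beta distribution around either the low mode
  (0.05) or the high mode (0.9), concentration 30. Cell-level
  log-odds random effects (sd 0.4) and a cell-type log-odds shift (0.5
  on 20% of sites in inhibitory cells) complete the probability. The
  mixture parameters are free: published work reports bimodality but
  not the component parameters, so the defaults were chosen once to
  give clearly separated modes and positively skewed cross-site means
  (skewness ≈ 0.4 under the default seed) and are documented here
  rather than revisited.
* **Sparse negative-binomial coverage.** A site is transcribed in a
  given cell with probability 0.045 (matching the reported ~4.5%
  transcription prevalence per site); transcribed pairs draw depth
  from NB(mean 20, size 2), truncated at 1.
* **Phenotype mix and regions.** Cells are 75% excitatory / 25%
  inhibitory (the ~1:3 ratio reported for cortex), split over eight
  subgroups per phenotype and six Brodmann-area labels.
* **Filter fodder.** 5% of sites are diploid SNPs (alt fraction ~0.5
  or ~1 in every cell — a single donor), 5% are antisense decoys
  (editing-like signal under a non-cognate variant class), ~10% of
  genes overlap an antisense neighbour, 2% of sites are intergenic,
  and 80% of true sites enter the simulated catalog. QC failures are
  planted exactly: ⌈2% · n⌉ high-mitochondrial and ⌈1% · n⌉
  low-complexity cells.
* **Planted associations.** For configured genes, per-cell log10
  abundance is constructed so that regressing the cell's true mean
  editing level on log10 TPM recovers the planted slope; the
  construction pre-compensates the per-cell TPM normalisation shift,
  so the slope refers to the predictor the models actually use.
  Attainable slopes are bounded by `sd(editing) / (2 · abundance sd)`;
  the generator warns and saturates beyond that.

Default scale is 5000 sites × 500 cells × 200 genes — large enough to
exhibit the sparsity census, bimodality and skew, small enough that the
full cascade plus brute-force oracles run in well under a minute. The
association studies use 2000 cells (the scale at which ±0.05 slopes
are comfortably detectable), and the differential-editing calibrations
use 2000 sites × 8 pseudoreplicates and 100-replicate power runs.
Published headline counts (tens of thousands of sites over ~3000
nuclei) derive from restricted data at ~10× this scale and are not
reproduction targets.

What passing tests on these fixtures do **not** show: robustness to
alignment artifacts, hyper-edited reads, base-quality miscalibration,
donor genotype variation (the simulated SNP list is complete by
construction; real SNP removal is only as good as the SNP catalog), or
real Alu sequence context. The generator plants structure at the
variant-call level; everything upstream of variant calls is out of
scope.

## Numerical choices and degenerate inputs

* Coordinates: VCF/GFF3 are 1-based inclusive, BED 0-based half-open;
  conversions happen only in the I/O layer.
* Boundary conventions: coverage/prevalence thresholds inclusive; mito
  QC strictly greater than 0.15; variance filter strictly greater
  than 0.2.
* Percentages round half-up at the stated decimal and carry their
  numerator/denominator as attributes.
* Site models: dispersion capped at 100; NB fits fall back to an
  unstarted fit on failure; all-zero arms get +0.5 on both arms and a
  flag; singular group-comparison designs error with the aliased
  terms named.
* Rotation test: QR sign indeterminacy is normalised so the reported
  direction matches the fitted coefficient's sign; rotation p-values
  use the (1 + exceedances)/(n_perm + 1) convention, so they are never
  zero.
* Ties in feature annotation resolve by the specificity order; ties in
  context by Alu precedence.
* Single-group pseudobulk skips the (undefined) variance filter;
  groups with zero cells are dropped with a warning.

## Known limitations

* The site-level Wald test relies on moderated dispersion; with very
  few sites (no moderation) and few pseudoreplicates it becomes
  anti-conservative. Calibration was verified at 2000 sites.
* Heavily unbalanced pseudoreplicate sizes bias both differential
  tests (see above).
* The rotation test assumes approximate Gaussianity of per-sample
  editing log-odds; at pseudobulk depths below ~10 the logit transform
  is coarse and the null, while still exact under rotation symmetry,
  loses power.
* Association models treat the editing index as an error-free
  response; index measurement noise inflates residual variance (a
  power cost, not a bias) and planted-truth recovery is exact only up
  to that approximation.
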