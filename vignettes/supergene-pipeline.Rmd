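---
title: "Detecting and genotyping a supergene from population genomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and genotyping a supergene from population genomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supergenescan)
```

## The problem

Several ant lineages carry *supergenes*: chromosomal regions of suppressed
recombination whose alternative haplotypes are inherited as units and
control complex polymorphisms such as colony social organization (one
reproducing queen versus many) and queen body size. In a queen-size
dimorphic species, whole-genome sequencing of queens spanning the size
range can reveal such a region as a large, contiguous block of elevated
differentiation between size morphs, with three diploid genotype classes
(here called AA, AB and BB) that are visible as discrete clusters in a
local principal component analysis.

`supergenescan` implements the downstream analysis of such a study as a
reusable, tested pipeline operating on a biallelic SNP genotype matrix
(VCF), a gene annotation (GFF3), a per-sample phenotype/colony table and a
worker microsatellite table:

1. variant filtering (site quality, per-genotype depth, missingness);
2. a windowed Weir–Cockerham FST scan between head-width morphs;
3. detection of the supergene interval as a thresholded run of windows;
4. rolling-window PCA and per-sample AA/AB/BB assignment;
5. extraction of fixed haplotype-diagnostic coding SNPs and gene ranking;
6. genotype–phenotype and genotype–colony association statistics;
7. a parsimony estimate of matriline counts from worker microsatellites.

A seeded synthetic-data generator plants a known supergene so that every
stage can be validated against ground truth at desk scale.

## Statistical machinery

### Weir–Cockerham FST

Per-site differentiation uses the Weir–Cockerham (1984) variance
components a (among populations), b (among individuals within
populations) and c (within individuals), with
θ = a / (a + b + c). Windows report both the "weighted" ratio of sums
Σa / Σ(a+b+c) (the scan statistic, matching what vcftools' weighted
estimate accumulates) and the mean of per-site ratios. θ is reported
unclamped — negative values are informative about sampling noise — and is
undefined (NaN) at sites monomorphic across all populations. The scan
threshold is an empirical percentile of the finite window values with
linear interpolation between order statistics (R's default quantile
definition); we state this because "the Nth percentile" is otherwise
ambiguous.

### Interval detection

A candidate region is a maximal run of windows above the threshold,
tolerating up to `max_gap_windows` (default 2) below-threshold or empty
windows inside the run; the longest candidate at least `min_span` long
(default 10 windows) wins. Two numerical details matter in practice.
First, the percentile must lie below the fraction of windows that are
*not* part of the differentiated region: with the desk-scale simulated
genome (two 10 Mb chromosomes, one 2.7 Mb region ≈ 13% of windows) the
paper-like preset therefore uses the 80th percentile, whereas on a
genome-scale dataset where such a region occupies a few percent of
windows the conventional 95th percentile plays the same role. Second,
because any percentile threshold is exceeded by background windows at the
complementary rate, and background FST values are autocorrelated along
the chromosome (linkage), stray background windows can chain onto the
true run through the gap tolerance. `detect_supergene()` therefore
refines the winning run by trimming edge windows whose FST falls below
half the run's median — a two-stage detect-then-refine rule that leaves
genuine edges (which carry full diagnostic-site density) untouched.

### Rolling PCA and genotype assignment

Within each 50 kb window, genotype dosages are mean-imputed at missing
cells, centred, scaled by √(2p(1−p)), and decomposed by SVD. A PCA sign
is arbitrary per window, so each window is oriented to correlate
positively with the previous informative window (the first window gives
the lexicographically smallest sample a non-negative score); this yields
a continuous per-sample trace along the chromosome. Samples are assigned
by their mean PC1 over the region's windows using one-dimensional
3-means with deterministic seeding at the minimum, median and maximum
score — a reproducible replacement for reading clusters off a figure. The
middle cluster is AB; the outer clusters are polarized by majority call
at the AB-heterozygous sites (mostly homozygous-reference ⇒ AA). Two
degenerate cases are handled explicitly: if the middle seed starves or
one adjacent center gap collapses below a quarter of the other, only two
clusters are reported with a warning rather than forcing a third; fewer
than three distinct scores is an error. The assignment is validated by
requiring AB to have the highest mean observed heterozygosity in the
region.

### Diagnostic coding SNPs

Haplotype-diagnostic sites are those heterozygous in *every* AB sample
(strict: a missing AB call excludes the site) and fixed for opposite
homozygotes between AA and BB among non-missing calls — exactly the set
where two-population θ = 1. Within-CDS filtering uses the longest isoform
per gene (summed CDS length, ties to the lexicographically smallest
transcript id) and 1-based inclusive interval containment, so a SNP at a
CDS boundary counts. Genes are ranked by diagnostic-SNP count with ties
broken by genomic position.

### Associations

Queens are classified macrogyne (> 1.08 mm), microgyne (< 1.04 mm) or
intermediate (the closed interval between) from head width. Head-width
differences across genotype classes use the tie-corrected Kruskal–Wallis
test with Dunn's post hoc z statistics (Holm adjustment by default,
Benjamini–Hochberg selectable; the choice does not affect any
reproducible quantity). Colony-level tables — social type × (AA vs
non-AA) and matriline count (1 vs >1) × (AA vs non-AA) — are tested with
the two-sided Fisher exact test under the point-probability rule with the
conventional 1 + 1e−7 relative tolerance, which reproduces standard
statistical environments exactly.

### Matriline parsimony

Sibship reconstruction from 5-locus microsatellite data is deliberately
replaced by a transparent parsimony criterion: the minimum number of
blocks partitioning a colony's workers such that each block is consistent
with one haplodiploid family. Under monandry a block needs, at every
locus with data, one shared paternal allele and at most two maternal
alleles; under polyandry only the two maternal alleles are required.
Missing data never falsifies a family. Colonies of ≤ 9 workers are solved
exactly by branch-and-bound over set partitions; larger colonies use a
deterministic greedy heuristic (seed with the least-compatible worker,
grow while consistent) whose result is an upper bound and which matches
the exact search on all simulated colonies within the exact range. This
replaces a likelihood model (such as the Colony software) with an
auditable combinatorial criterion; it does not model genotyping error, so
error handling lives in the simulator (dropout and false-allele rates,
default 0).

## The synthetic-data generator

The generator emulates the *downstream* statistical structure of the
study system, not its population history:

* **Background genome.** Each haplotype is a mosaic of 8 founder
  haplotypes with copy switches at 10⁻⁶ per bp, which produces linkage
  disequilibrium that decays over hundreds of kb — required for the LD
  contrast to be non-trivial (independent-site draws would make
  background LD zero everywhere).
* **Supergene.** One 2.7 Mb interval (2.0–4.7 Mb of chromosome 1 of a
  2 × 10 Mb genome; a scaled stand-in for a 9 Mb region of a ~250 Mb
  genome) carries two divergent founder pools A and B. A fraction d = 0.5
  of interval SNPs are fixed 0-vs-1 between pools, planted with A as the
  reference allele so that the AA class is predominantly
  homozygous-reference, matching the polarity convention the class
  labelling relies on. An interval haplotype copies a *single* pool
  founder: the region is modelled as fully non-recombining, which is what
  makes interval LD flat. Remaining interval SNPs are shared ancestral
  polymorphisms planted at the same founder allele count in both pools
  (so their FST is sampling noise, not founder drift), with counts drawn
  from an SFS-like spectrum skewed to low frequencies. This calibrates
  the observed heterozygosity of the region to ≈ 64% in AB and ≈ 15% in
  homozygotes, the study's reported contrast (60–63% vs 13–16%).
* **Cohort.** Class frequencies (default ⅓ each over 60 samples) are
  realized exactly by largest-remainder quota, giving the study's
  20/20/20 design for every seed; head widths are class-conditional
  truncated normals (means 1.20/1.05/0.98 mm, sd 0.03) reported to
  0.01 mm.
* **Colonies.** 20 monogyne colonies headed by one AA queen (with
  probability 0.1 a second, unsampled AA mother also contributes workers
  — serial polygyny) and 11 polygyne colonies with 2–4 AB/BB queens.
  Workers are haplodiploid offspring of one mother and one haploid
  father. Eight workers per colony keeps every colony within the exact
  matriline search.
* **Microsatellites.** Five loci, eight equifrequent alleles per locus;
  each matriline has one diploid mother and one haploid father; workers
  inherit one maternal allele plus the paternal allele, with optional
  dropout and false-allele errors.

What the generator does **not** emulate: coalescent genealogies, mutation
and recombination rate variation, linked selection, inversion breakpoint
structure, genotyping error in the SNP matrix (depth and quality are
drawn so that the study's filters pass essentially everything, keeping
the planted truth recoverable), and polyandrous mothers. Passing tests on
this generator therefore demonstrate the correctness and calibration of
the pipeline's logic, not robustness to every artefact of real data.

## Problem sizes and runtime choices

The default simulation (2 × 10 Mb at 1 SNP / 500 bp, 60 samples) runs the
full pipeline in seconds and is the size used by the validation suite;
unit tests use a 0.5 Mb single-chromosome configuration. LD decay uses a
banded blockwise correlation so only pairs within `max_dist` (default
300 kb, with a MAF ≥ 0.05 filter, PopLDdecay-style defaults) are
computed.

## Known limitations

* One supergene per genome per pass; nested or multiple regions are not
  resolved.
* Genotypes are treated as unphased; r² is the composite dosage
  correlation, not haplotype D′/r².
* The matriline estimator is a minimum — true matriline counts can be
  higher when families collide by chance, and the estimator never splits
  a true family; with five informative loci collisions are rare but not
  impossible.
* The FST percentile threshold is a study-design parameter, not an
  inferred quantity; it must be chosen below the non-region window
  fraction (see above).
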