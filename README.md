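# supergenescan

Detection and genotyping of non-recombining **supergenes** from
population genomic data, with the association statistics used in studies
of social polymorphism in ants.

In queen-size dimorphic ants, colony social organization (one reproducing
queen vs. many) and queen morph can be controlled by a supergene: a
multi-megabase region of suppressed recombination whose alternative
haplotypes (A, B) are inherited as units, giving three diploid genotype
classes AA, AB and BB. Such a region shows up in whole-genome data as

* a long run of windows with elevated Weir–Cockerham
  F<sub>ST</sub> = a / (a + b + c) between size morphs,
* three discrete clusters on PC1 of a local (rolling-window) PCA, with the
  heterozygous AB class in the middle,
* excess observed heterozygosity in AB individuals (most diverged sites
  are heterozygous in every AB sample),
* linkage disequilibrium (dosage r²) that stays flat with distance inside
  the region while decaying outside it.

`supergenescan` implements that whole analysis path — variant filtering
(vcftools-style `--minQ/--minDP/--max-missing` semantics), the windowed
F<sub>ST</sub> scan, interval detection, rolling-window PCA genotype
assignment, extraction of fixed haplotype-diagnostic coding SNPs against a
GFF3 annotation, Kruskal–Wallis/Dunn and Fisher exact association tests,
and a parsimony estimator of matriline counts from haplodiploid worker
microsatellites — plus a seeded synthetic-data generator that plants a
known supergene so the full pipeline can be validated against ground
truth. See the vignette in `vignettes/supergene-pipeline.Rmd` for the
methods in detail.

## Worked example

Simulate the default planted-supergene dataset (two 10 Mb chromosomes,
60 queens 20/20/20 across the three classes, a 2.7 Mb non-recombining
region), then detect, genotype and test:

```r
library(supergenescan)

dat <- simulate_dataset(sim_config(), seed = 42)
gm  <- filter_variants(dat$gm)                 # minQ 20, minDP 3, max-missing 0.6

morph <- classify_morph(dat$samples$head_width_mm)   # >1.08 / <1.04 mm cut-offs
grp   <- setNames(morph, dat$samples$sample_id)
grp   <- grp[grp %in% c("macrogyne", "microgyne")]

fst  <- windowed_fst(gm, grp, window_size = 10000)
call <- detect_supergene(fst, fst_percentile_threshold(fst, 80))
print(call)
#> supergene_call: chr1:2000001-4700000 (2.70 Mb, 270 supporting windows, threshold 0.016)

pca <- rolling_pca(gm, call$chrom, window_size = 50000)
asg <- assign_genotypes(gm, call, pca)
print(asg)
#> genotype_assignment: AA=20, AB=20, BB=20 (validated)

ab    <- ab_het_sites(gm, asg, call$chrom, call$start, call$end)
fixed <- fixed_diff_sites(gm, asg, ab)
length(fixed)
#> [1] 2614     # fixed haplotype-diagnostic SNPs

dat$samples$genotype_class <-
  asg$samples$class[match(dat$samples$sample_id, asg$samples$sample_id)]
colony <- colony_genotype_association(dat$samples)
colony$table
#>                AA non_AA
#> single_queen   20      0
#> multiple_queen  0     11
signif(colony$p, 3)
#> [1] 1.18e-08
```

The detected interval is exactly the planted one (truth in `dat$truth`),
all 60 genotype classes are recovered, and the colony-level association
between the AA genotype and single-queen nesting is highly significant.
`run_pipeline(pipeline_config(seed = 42, out_dir = "out"))` runs the same
stages end-to-end (plus diagnostics, Dunn post hoc tests and matriline
estimation) and writes stage TSVs and a JSON report.

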