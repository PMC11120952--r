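# pavscape

Presence/absence variations (PAVs) — insertions and deletions of at
least 50 bp that some individuals of a resequenced panel carry and
others lack — are a major, under-used source of phenotypic variation in
crop genomes. pavscape is an R package for the post-calling stages of a
PAV study in an inbred panel (e.g. rice cultivars): it merges the
per-sample callsets of two structural-variant callers into a unified
presence/absence genotype matrix, characterizes the PAV landscape, runs
a population-structure-adjusted association scan against quantitative
traits with a permutation-derived genome-wide significance threshold,
and compares single-PAV haplotype groups. A built-in synthetic-data
generator (two imperfect callers over a shared truth set, planted
hotspots, planted causal variants) makes the whole pipeline testable
end to end with no external data.

It is aimed at quantitative/population geneticists who have per-caller
SV VCFs, gene models (GFF3) and a phenotype table (TSV), and want a
transparent, reproducible path from callsets to candidate genes.

## Methods in brief

- **Merging.** Records merge iff same chromosome and SV type and both
  breakpoints within D (default 1000 bp); clusters are connected
  components (position-sorted sweep ≡ all-pairs components, tested);
  consensus coordinates are member medians; genotypes combine
  presence-dominant across callers. Loci are then filtered to
  MAF ≥ 0.01 and missing rate < 40%.
- **Landscape.** Size spectrum on log bins with the short (50–1000 bp)
  fraction; non-exclusive genomic-context classes (±3 kb flank, CDS,
  UTR, intron, intergenic); breakpoint counts in 1000 kb windows at
  500 kb step; hotspot windows are the top 10% genome-wide (ties kept,
  zero counts excluded), merged into maximal regions.
- **Association.** For trait *y* and encoded locus *g* (0/1, mean-imputed),
  fit *y* = β₀ + β·g + PC₁..₃ + ε per locus and test β with a two-sided
  t-test. The genome-wide threshold is the 95th percentile (type-1
  quantile) of per-permutation maxima of −log₁₀ p under Freedman–Lane
  residual permutation with the same engine (1000 permutations by
  default), giving ~5% family-wise error under the null.
- **Haplotypes.** Samples split by presence/absence at one PAV;
  groups compared with a Welch two-sample t-test.

## Worked example

```r
library(pavscape)

cfg <- pav_sim_config(seed = 1)   # 150 inbred samples, 2000 true PAVs,
                                  # 12 x 2.5 Mb chromosomes, 1 planted
                                  # 8x hotspot, 5 traits w/ causal PAVs
report <- run_pav_pipeline(cfg, out_dir = "pav_run", n_permutations = 200)
print(report)
#> PAV pipeline report
#>   3795 input records -> 1858 merged loci -> 1858 after filters
#>   short-PAV fraction 0.745; genic 75.7%; intergenic 36.1%
#>   hotspot regions: 4
#>   significant loci: days_to_heading=0, plant_height=0, flag_leaf_length=1, flag_leaf_width=1, panicle_number=1 (total 3)
```

The two callers reported 3795 PASS records which merge to 1858 loci
(nearby true PAVs can fuse under proximity merging — see the methods
vignette); 74.5% of loci are short (50–1000 bp) by construction of the
size distribution; three of the five planted causal PAVs survive
merging intact and are recovered genome-wide significant. The detected
hotspot regions include the planted 1 Mb region on chromosome 11.

Each trait's scan is a fitted object:

```r
fit <- report$scans$flag_leaf_width
print(fit)
#> pav_gwas scan of 'flag_leaf_width': 1858 loci, 150 samples
#>   threshold -log10(p) = 4.800 (200 permutations, alpha 0.05)
#>   significant loci: 1
plot(fit)       # Manhattan plot with the permutation threshold
```

and the top hit splits the panel into haplotype groups:

```r
ph <- read_phenotype_table("pav_run/phenotypes.tsv")
haplotype_test(report$genotypes, ph, "flag_leaf_width",
               fit$significant$locus[1])
#> haplotype_comparison at L00985 (Welch t-test)
#>   Hap1 (reference): n=54 mean=1.302
#>   Hap2 (PAV):       n=95 mean=1.452
#>   t = -4.274, df = 86.29, p = 4.935e-05 *
```

Here carriers of the PAV have flag leaves ~0.15 cm wider on average —
the planted effect, recovered end to end from noisy caller VCFs.

Real data enter through `read_sv_vcf()` (one per caller),
`read_gff3()` and `read_phenotype_table()`, then the same
`merge_callsets()` → landscape → `pav_gwas()` → `haplotype_test()`
chain. A thin CLI lives at `inst/scripts/pavscape.R`.

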