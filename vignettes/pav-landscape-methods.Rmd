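---
title: "Methods: PAV landscape characterization and association scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAV landscape characterization and association scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

pavscape analyzes presence/absence variations (PAVs) — insertions and
deletions of at least 50 bp that are present in some individuals of a
resequenced panel and absent in others. The package covers the
post-calling part of such a study: it consumes per-caller
structural-variant VCFs (it does not call variants from reads), merges
them into a presence/absence genotype matrix, characterizes the PAV
landscape (size spectrum, genomic context, breakpoint hotspots), scans
the matrix for trait associations with a permutation-calibrated
genome-wide threshold, and compares single-PAV haplotype groups. A
synthetic-data generator emulating the whole study — inbred samples from
two subpopulations, two imperfect callers over a shared truth set,
planted hotspots and planted causal PAVs — makes every stage testable
without external data.

# The synthetic study

`pav_sim_config()` fixes the study conditions; every generator is
deterministic given its seed.

**Population.** Samples are fully inbred lines, so genotypes are binary
presence/absence rather than diploid dosage, and sample frequency equals
allele frequency. The default panel has 150 samples in two
subpopulations at a 109:39-like ratio (roughly the indica/japonica split
of improved Asian rice panels). Each locus draws an independent presence
frequency per subpopulation from Uniform(0.05, 0.95); this is a
deliberately simple stand-in, not a calibrated allele-frequency
spectrum, but it produces the strong population structure (principal
component 1 separates the subpopulations essentially perfectly) that the
association scan's covariate correction is meant to absorb.

**Genome and genes.** Twelve chromosomes of 2.5 Mb give a 30 Mb desk-scale
genome. 3000 non-overlapping gene models (about one per 10 kb, a
rice-like density) are placed with uniformly split inter-gene gaps; each
has 1–5 exons, UTR segments trimmed from the terminal exons when long
enough, CDS on the remainder, and introns defined as inter-exon gaps.

**PAV sizes.** Sizes follow a truncated power law on [50 bp, 100 kb]
with tail index 0.425, i.e. P(S > s) decreases as s^-0.425. The lower
bound is the structural-variant definition; the upper bound reflects
what short-read SV callers actually emit (megabase calls are not
realistic and would not fit the toy chromosomes). The tail index was
chosen from the closed-form truncated CDF so that short PAVs
(50–1000 bp) carry ~75% of the mass, matching the strongly
short-dominated spectra reported for rice panels. About 97% of PAVs are
deletions.

**Hotspots.** Breakpoint positions are uniform outside planted hotspot
regions and `enrichment`-times denser inside (default: one 1 Mb region
on chromosome 11 at 8×). With one region covering fraction c of the
genome at enrichment E, the expected fraction of PAVs inside is
cE/(cE + 1 − c); tests check this closed form and the ±15% density-ratio
recovery at n = 10,000.

**Callers.** Two pseudo-callers share one truth set. Each caller misses a
whole locus with probability `caller_false_negative_rate` (dropout is at
the locus level — a caller that misses an event misses its record), adds
rounded Gaussian jitter to reported breakpoints (clamped to the
chromosome and to the 50 bp size floor), marks a fraction of records
LowQual, and loses a fraction of per-sample genotypes to missingness.
Caller disagreement therefore arises only from jitter and dropout, which
isolates merge-logic testing from caller modeling.

**Phenotypes.** Five rice-like traits (days to heading, plant height,
flag leaf length, flag leaf width, panicle number) with baselines near
the means reported for improved Asian panels (96.8 d, 91.3 cm, 26.9 cm,
1.4 cm, 9.2). Each trait has one planted causal PAV explaining 25% of
phenotypic variance, a subpopulation mean shift of half the residual SD,
and Gaussian noise. The effect size is back-computed from the target
variance fraction v given the locus's realized presence frequency p:
b² p(1−p) = v/(1−v) · V₀, where V₀ is the residual-plus-shift variance.
Causal loci are drawn among loci with realized MAF ≥ 0.05 — an effect
planted on a locus the MAF filter removes would be unobservable by
construction. Causal and shift contributions are centered so the
configured baseline is the population mean. In the degenerate noiseless,
shift-free case V₀ = 0 and no effect size reproduces a variance
fraction; the generator then uses a unit effect so the locus still
splits the phenotype into two values.

# Merging and filtering

Records from all callers are pooled after optional PASS filtering. Two
records are linkable iff they share chromosome and SV type and both
their start and end breakpoints differ by at most D (default 1000 bp,
the common practice for short-read SV merging; the threshold is
configurable). Clusters are connected components of this relation,
computed by a position-sorted sweep with union–find; tests check
equivalence with brute-force all-pairs connected components. Single
linkage means chains longer than D can merge — accepted, and the reason
the default tests at zero caller noise use D = 0: the merge distance
should mirror breakpoint uncertainty, and with exact breakpoints exact
matching recovers the truth set exactly, whereas D = 1000 at the default
density (one PAV per ~15 kb, 8× inside the hotspot) inevitably fuses
some *distinct* true loci that sit within 1 kb on both ends.

Consensus coordinates are the lower-median of member starts/ends
(midpoint for two members, floored at .5 so coordinates stay integral
and deterministic). Per sample, member records combine
presence-dominant: present if any record calls present, else absent if
any calls absent, else missing. This maximizes sensitivity, consistent
with merging callers to obtain more comprehensive PAV data.

Variant filters keep a locus iff MAF ≥ 0.01 (inclusive, computed on
non-missing samples) and missing rate < 0.40 (strict, following the
printed "<" convention). Both bounds are checked against exhaustive
enumeration, including the exact-boundary cases.

A consequence of proximity merging worth knowing: when a causal PAV
happens to sit within the merge distance of another true PAV (most
likely inside a hotspot), the presence-dominant union corrupts its
genotypes and the association signal for that trait can vanish. The
matrix-level power tests (≥90% detection of a 25%-variance locus)
deliberately bypass merging to measure the scan itself; full-pipeline
runs may show fewer significant traits for exactly this reason.

# Landscape characterization

*Size spectrum*: counts in half-open log-spaced bins from 50 bp; the
short-PAV fraction uses the inclusive 50–1000 bp range.

*Genomic context*: a PAV (insertions as 1 bp points at the reported
position) carries every class it overlaps by ≥1 bp: the ±3 kb gene
flanks, CDS, UTR, intron, and intergenic (≥1 bp outside all genes and
flanks). Classes are deliberately non-exclusive — a PAV spanning a gene
boundary carries several, so percentages can sum above 100. "Genic"
means carrying any of flank/CDS/UTR/intron. Five classes are used
(CDS and UTR reported separately). Overlaps go through
GenomicRanges; tests recount by per-base interval arithmetic.

*Hotspots*: breakpoint counts per 1000 kb window at 500 kb step,
windows clipped at chromosome ends. A locus contributes its start
breakpoint once per covering window, so overlapping windows double-count
by design (an option counts deletion end breakpoints too). Windows are
ranked genome-wide (per-chromosome ranking available); hotspot windows
are those reaching the count of the ceiling(0.10·n)-th ranked window —
ties included, determinism without arbitrary dropping — and nonzero
(zero-count windows are never hotspots, avoiding degenerate all-hotspot
output on sparse genomes). Overlapping or touching hotspot windows merge
into maximal regions.

# Association scan

The engine is a transparent fixed-effects least-squares model per locus:
trait ~ intercept + locus + the first three principal components of the
column-centered encoded genotype matrix (present = 1, absent = 0,
missing = per-locus mean imputation; loci monomorphic after imputation
are flagged unusable). Multi-locus iterative engines are intentionally
out of scope; what is preserved is the inferential structure —
PC correction for population structure plus permutation-based
family-wise error control — with a core whose every number has a closed
form (the binary-locus, no-covariate case reduces exactly to the pooled
two-sample t-test, which tests verify to 1e-10). PC score signs are
fixed (largest-magnitude loading positive) for cross-platform
determinism.

The genome-wide threshold is permutation-derived: in each of
`n_permutations` (default 1000; the pipeline default is 200 at desk
scale) the phenotype residuals after regressing out the covariates are
permuted across samples and re-adjusted (Freedman–Lane style residual
permutation — the "conditional" scheme; raw-label permutation is a
flag), all loci are re-scanned under the same engine, and the
genome-wide maximum −log₁₀ p is recorded. The threshold is the
empirical 95th percentile of these maxima, taken as a type-1
(order-statistic, lower interpolation) quantile so it is exactly
reproducible; with 1000 permutations and α = 0.05 it is the 950th order
statistic. An alternative reading — the 95th percentile of the *pooled*
permutation −log₁₀ p distribution — is available via `pooled = TRUE`
but is not the default, because only the max-statistic construction
controls the family-wise error rate; tests confirm null FWER in
[0.02, 0.10] at α = 0.05. Loci at or above the threshold are
significant (inclusive rule).

Significant PAVs map to genes whose span ±3 kb overlaps the locus.

# Haplotype comparison

At a chosen PAV, samples split into the reference group (Hap1, PAV
absent) and the carrier group (Hap2, PAV present); samples with missing
genotype or phenotype are excluded. Groups are compared by a two-sided
Welch t-test (the default unequal-variance behavior of `t.test`);
the pooled-variance variant is a flag. Both groups need at least two
members. The null rejection rate at 0.05 is checked by simulation.

# Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive internally (VCF/GFF3 native);
  conversion to 0-based half-open happens only at BED/window output.
- Consensus ties break to the lower value; quantiles are type 1;
  per-chromosome means round half-down (33220 loci over 12 chromosomes
  report 2768).
- Empty inputs: empty callsets write header-only VCFs and read back
  empty; an empty annotation classifies everything intergenic; a
  genotype vector that is all-missing has no defined MAF and errors.
- Multi-allelic SV rows are rejected (PAV loci here are biallelic by
  construction); records violating the DEL/INS invariants are dropped
  with a warning, never silently kept.
- All stage seeds derive deterministically from the config seed and stay
  within 32-bit integer range.

# Problem sizes used by the test suite

Simulation-based checks run at the sizes their statements require:
10,000 PAVs for distribution and hotspot-recovery properties (100
seeds), 200 replicates of 150 × 1000 with 200 permutations each for the
null FWER check, 50 seeds of 150 × 2000 for power, 100 random callsets
of up to 500 records for the merge oracle, and 2000 replicates for the
t-test calibration. End-to-end pipeline checks use the default
150-sample, 2000-PAV study.

# Known limitations

- No read-level simulation, sequencing-depth modeling, or linkage
  disequilibrium along chromosomes; caller errors are i.i.d.
- The per-subpopulation frequency prior is a stand-in; real panels have
  correlated, skewed frequency spectra.
- Single-linkage merging cannot separate distinct true PAVs closer than
  the merge distance on both breakpoints (see above).
- The scan is single-locus; kinship/mixed-model and multi-locus engines
  are out of scope, as are functional enrichment of hotspot genes and
  centromere annotation.
- Passing tests demonstrate correctness under the generator's
  assumptions, not performance on real resequencing callsets.
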