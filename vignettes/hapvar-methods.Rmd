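---
title: "Haplotype-inheritance QTL mapping and variant prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-inheritance QTL mapping and variant prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapvar)
```

## The inheritance model

In a phased pedigree, each child's genome decomposes into haplotype blocks,
and within a block the child carries exactly one of the father's two
haplotypes and one of the mother's two. `hapvar` encodes these as binary
indicators `p_i` and `m_i` (labels 0/1 are founder-arbitrary: swapping one
parent's labels negates that parent's fitted effect and leaves the joint
test invariant, which the test suite asserts). For a trait `T` anchored in
block `b` the model is ordinary least squares of

`T_i = µ + β_j p_i + β_k m_i (+ covariates) + ε_i`

across the analysis children. Only the block containing the trait's anchor
(TSS, miRNA locus, or summit region midpoint) is tested; traits outside any
block are skipped and counted. The per-trait statistic is the joint F-test
of the retained haplotype terms against the nested covariate-only model.
This choice — rather than, say, the larger of two marginal tests — captures
association with *either* parent's inheritance in one calibrated test;
marginal t-tests (p < 0.05) then attribute the signal to the paternal,
maternal, or both parents among significant traits.

Assumptions worth stating: traits are conditionally Gaussian after
transformation (counts enter as log2 CPM; the F-test's null calibration
under the negative-binomial generative model is verified empirically in the
tests); blocks are transmitted without internal recombination; and the
eleven analysis children are treated as exchangeable — no kinship or
variance-component structure is modeled, since all children are full
siblings measured in one cell system.

### Multiplicity and thresholds

P-values are corrected per scan (genome-wide, not per chromosome) with
Benjamini–Hochberg; the procedure is a config option. Default significance
thresholds follow the study design: FDR < 0.5 for accessibility summits
(caSummits), FDR < 0.4 for eGenes. The e-miRNA threshold is not separately
specified by the study design, so it defaults to 0.4, mirroring eGenes; it
is configurable. These are deliberately lenient screening thresholds —
downstream integration (the cascade) supplies the specificity.

### Covariates

Batch (extraction date, categorical, one-hot minus reference) and quartiled
mean EBV expression (ordinal 1–4 as a single numeric column) enter the gene
and miRNA scans and the mediation regressions; the summit scan runs without
covariates. With n = 11, every degree of freedom matters, which is why EBV
enters as one ordinal column rather than three dummies. A haplotype
indicator constant across usable children carries no information and is
dropped (recorded in `dropped_terms`); fewer than three complete children is
an error; a block with both indicators constant is flagged uninformative
rather than failing.

## Summit atlas

Summit calls (point of maximal pileup within a peak) become 500 bp regions,
summit ± 250 bp, clamped at zero. Overlapping candidate regions are resolved
greedily by descending pileup — the stated pairwise rule (higher pileup
wins) made deterministic by processing order, with ties broken by chromosome
and position. The greedy fixed point is non-overlapping and idempotent, and
the same rule is re-applied when merging across replicates, recording
provenance, since pileups from pooled replicates are treated as comparable.
Regions are kept only when the summit lies inside a master peak, then only
when child-level peak calls from at least three distinct children overlap
the region. IDR filtering of the peak calls themselves is upstream of this
package: inputs are assumed already reproducibility-filtered at the peak
level.

Read counting assigns a (optionally Tn5-shifted, +4/−5 by strand) Read1 5'
position to a region by half-open membership `[start, end)` — a read at
exactly `end` is not counted, the convention used for every interval in the
package (0-based half-open throughout; VCF positions are converted on
ingest). Normalization divides by each child's total reads within summits
(CPM). GC correction, when a per-summit GC fraction is supplied, is a
per-child binned-median detrend of log2(CPM + 1): subtract the median
signal of the region's GC bin and re-center on the child's median. This is
a deliberate simplification of conditional quantile normalization with the
same intent — removing the GC-signal trend — and it is validated by
planting a monotone log-linear GC bias and checking the residual slope is
below 0.05 log2 units per unit GC.

A compositional caveat: dividing by reads-within-summits couples summits.
When one summit's counts are strongly haplotype-dependent and the atlas is
small, that summit's excess reads depress the CPM of all others in the
affected children, which can push null summits over the lenient caSummit
threshold. At the default synthetic scale (25 regions) the effect is
diluted; in the 5-region worked example it is visible, and readers of the
toy output should expect it. Genome-scale atlases (tens of thousands of
regions) make it negligible.

## Methylation filter

CpG records arrive strand-split; plus- and minus-strand cytosines of one CpG
(positions `p` and `p + 1`) are summed per child, orphan minus-strand
records are kept as their own CpGs with a warning. Coverage below 10 reads
masks a child's value; coverage at or above the child's 99.9th percentile is
also masked (an inclusive cut — a PCR-artifact guard, computed per child on
that child's raw coverage distribution so the two rules commute; per-child
rather than pooled percentiles match the artifact rationale, since library
depth differs between children). A CpG is *intermediate* when at least three
unmasked children have methylation fraction in the closed interval
[0.25, 0.75] — the signature of one active and one silenced allele. The
interval bounds are configurable; 0.25/0.75 is the procedural default,
although 0.20/0.80 appears as a descriptive bound in the source study's
narrative. No identity constraint ties the intermediate children to the
children driving a caSummit effect, matching the procedural description.
Degenerate inputs are handled explicitly: an all-equal coverage column makes
the inclusive percentile cut mask every value (documented rather than
special-cased); `low >= high` is a parameter error.

## Variant cascade

Each stage is a pure predicate; the orchestrator's only job is ordering,
short-circuiting and bookkeeping, and the tests assert that the survivor set
equals the independent conjunction of the predicates. In audit mode every
flag is evaluated even after the first failure, so the evidence ledger is
complete per variant. Notable resolutions of underspecified corners:

- **Allele-of-origin** for co-segregation uses the phased child genotype
  when present (written `paternal|maternal` by this package's conventions),
  otherwise Mendelian deduction from the other parent; unresolvable
  children are skipped, and more than half skipped renders the call
  indeterminate (FALSE, flagged).
- **Co-segregation** requires both that children sharing a transmitted
  haplotype share the received allele and that the two haplotype groups
  receive different alleles — a variant identical on both parental
  haplotypes cannot explain a haplotype effect.
- **"Both parents" associations** are treated disjunctively: heterozygosity
  in either implicated parent satisfies the parent filter, and
  co-segregation holds if it holds for at least one heterozygous implicated
  parent.
- **Multi-allelic sites** keep their full allele set; genotype-level
  predicates operate on allele indices directly.
- The **replicated-eGene stage** (membership of the block's eGene in an
  externally replicated list) is a configurable final stage, off by
  default, so both funnel depths — with and without external replication —
  are expressible.
- **Rarity** is an annotation, not a filter: MAF < 0.05 in *every* listed
  population; a variant absent from the MAF table has undefined rarity
  (NA).

Set overlap between two hit lists (e.g. eGene sets from two studies) uses
the one-sided Fisher exact test — the hypergeometric upper tail — plus the
sample odds ratio.

## Allelic imbalance

Reads over a heterozygous site are tallied by allele after a base-quality
filter (default Q20; the source protocol states none, so a conventional
threshold is used). The test is the two-sided exact binomial by the
minimum-likelihood method, appropriate at single-site depths of tens of
reads where normal approximations fail; `(30, 0)` gives exactly
`2 × 0.5^30`. Duplicate-flagged reads are excluded by the BAM reader when
the flag is set upstream; no allele-aware realignment (mapping-bias
correction) is attempted.

## The synthetic study generator

The generator emulates the study conditions end to end: a 17-member,
three-generation pedigree whose 11 third-generation children form the
analysis set; fair Bernoulli transmission of parental block haplotypes
(blocks are the transmission unit — no internal recombination); trait counts
from a negative binomial parameterized by mean and dispersion `k`
(variance = µ + µ²/k) with log-scale planted effects; batch (two levels,
shift 0.2) and EBV-quartile (slope 0.05 per quartile) effects on expression
traits; beta-binomial CpG methylation — Beta(45, 5) highly methylated
background, Beta(5, 45) lowly methylated, Beta(20, 20) intermediate at the
planted monoallelically active summit in children carrying one active and
one inactive haplotype — at Poisson(30) coverage; and binomial allelic reads
(depth 30, active-allele fraction 0.95) at the planted heterozygous site.
Default planted effects are β_p = 2 (natural-log scale) for the caSummit and
1.5 for the eGene/e-miRNA: the emulated study deliberately targeted loci
with very strong effects, and with n = 11 these are the effect sizes that
are reliably detectable. Baseline count means (100 summits / 200 genes /
100 miRNAs, k = 20) are typical of bulk assays at these feature sizes.

Every pipeline input file is written in its external format (pedigree /
transmission / covariate / count / methylation / MAF TSVs, summit BED,
narrowPeak, VCF, per-read base TSV) together with a `truth.json` ledger
resolving every planted element to generated ids. One base seed drives all
draws through named substreams (`substream_seed`), so adding a component
never perturbs earlier streams and identical seeds give byte-identical
files. Stage-specific decoys ensure every filter rejects something: an
overlapping summit pair, a summit outside the master peaks, a summit
reproduced in only two children, sex-chromosome / low-count / outside-block
traits, and — inside the planted caSummit — a haplotype-discordant variant,
a wrong-parent-heterozygous variant, and a monomorphic variant.

What the generator does **not** emulate, and hence what passing tests do not
demonstrate about real data: read-level sequencing error and mapping bias;
linkage disequilibrium beyond block structure; recombination within blocks;
cell-line artifacts such as clonal mosaicism or variable EBV activation
(EBV enters only as a per-sample covariate); peak calling and IDR; and the
genome-scale multiplicity of real scans (thousands of traits rather than
dozens). Calibration and FDR results transfer to the extent that the
Gaussian-after-transformation approximation holds for real normalized
counts.

## Numerical choices

- Intervals: 0-based half-open everywhere; `[start, end)` membership; VCF
  converted on ingest. IRanges does overlap queries after a +1 shift.
- Constant traits: reported with zero haplotype effects and `p_joint = 1`
  (the reduced model already fits perfectly); a perfectly fitting full model
  over a non-fitting reduced one gives `p_joint = 0`.
- Rank-deficient designs after drops are flagged, with `p_joint` undefined.
- Greedy merge ties: descending pileup, then chromosome, then position.
- The percentile coverage cut is inclusive (`>=` the quantile).
- The intermediate-methylation interval is closed on both ends.
- TMM normalization uses edgeR's implementation (reference library, 30%
  M-trim, 5% A-trim) with log2 CPM output; identical libraries give factors
  of exactly 1.

## Problem sizes in the test suite

The suite exercises the method at sizes chosen to make Monte-Carlo bounds
tight while remaining quick to run: 2,000 null traits for F-test
calibration (rejection rate asserted within [0.037, 0.063] at α = 0.05, the
99% binomial interval); 200 replicates per cell of the {β = 0.5, 1, 2} ×
{k = 5, 50} recovery grid (mean estimate within two standard errors of
truth, power monotone); 25 replicates of 1,000-null + 50-alternative scans
for BH FDR control; randomized instances of up to 50 summits, 1,000 reads,
100 CpGs and ~100 variants against brute-force oracles; and two full
pipeline runs for byte-level determinism.

## Known limitations

With eleven children the scans are powered only for large effects, and the
lenient screening FDRs are integral to the design — single-scan hit lists
are not meant to be interpreted alone. The compositional coupling of
within-summit normalization (above) matters for small atlases. The mediation
test is a conditional-prediction regression, not a formal causal mediation
estimand. Haplotype phasing, peak calling, novel-miRNA discovery, motif
analysis and population-genetic annotation beyond the MAF table are out of
scope and consumed, where needed, as inputs.
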