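---
title: "Methods: haplotype-aware SV discovery, validation and integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-aware SV discovery, validation and integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svscribe)
library(dplyr)
```

svscribe implements the computational calculus used to build
haplotype-resolved structural-variant (SV) callsets from complementary
platforms: Strand-seq inversion discovery, cross-platform inversion
unification, multi-caller breakpoint consensus with non-concordance-rate
(NCR) benchmarking, long-read validation (read support, optical-map length
concordance, read depth), haplotype- and assembly-level merging, and
three-way pan-SV integration. All coordinates are 0-based half-open
internally; conversion to 1-based happens only at the VCF boundary.

Because the genuine inputs to such a study (trio-scale multi-platform
sequencing) are far beyond desk scale, the package ships a first-class
synthetic-data module that generates every input with known ground truth,
so each stage — and the pipeline end to end — is testable against planted
answers.

## Strand-seq inversion discovery

A Strand-seq *composite file* pools the oriented reads of many single
cells of one individual. Each read is a point (its 5' position) labelled
`reference` or `non_reference` relative to the assembly, optionally
haplotagged `H1`/`H2` via a phased heterozygous SNV. The *read ratio* of a
locus — non-reference reads over total — is the dosage proxy: ~0 outside
inversions, ~0.5 over a heterozygous inversion, ~1 over a homozygous one,
and intermediate values (≈1/3) over inverted duplications, where extra
segment copies on the carrier haplotype add reference-oriented coverage.

**Segmentation.** A sliding window of 250 reads (step 50) scores the
non-reference fraction; windows above the 15% trigger are merged into
maximal runs. A triggering run necessarily extends up to one window span
past the true orientation switch on each side, and under the 2% background
rate stray non-reference reads sit near the run edges. Trimming the
candidate to the first/last non-reference read of the run alone would
therefore pad candidates by roughly a window span of reference territory,
dilute the read ratio, and systematically drag homozygous events below
about five window spans toward a heterozygous call. Boundaries are instead
refined first by the classic changepoint construction: the maximal-sum
contiguous stretch of per-read scores `is_nonref - c` (default
`c = 0.25`, strictly between the background rate and the lowest genuine
event dosage of 1/3), then trimmed to its first/last non-reference read.
In the noise-free limit this recovers the planted boundaries exactly.

The practical consequence is a resolution floor: an event must push at
least one 250-read window past the trigger, so the smallest discoverable
event is about `0.3 * window_reads / density` bp for heterozygous events.
At the package default of 25 reads/kb that is ≈3 kb; at 5 reads/kb it is
≈13.5 kb. Recovery experiments must be read against this floor.

**Genotyping.** Each candidate's counts are compared against three exact
binomial models of the non-reference proportion — homozygous reference
(`b = 0.02`), heterozygous (0.5), homozygous inverted (`1 - b`) — with the
2% background `b` absorbing residual mis-orientation in the homozygous
states. At least 50 reads are required; the reported genotype is the
maximum-likelihood model, demoted to `untyped` when an exact two-sided
binomial test rejects even the best model at `alpha = 0.01`. The exact
construction (model set, `b`, `alpha`) is config-exposed through
`segmentation_params()`.

The rejection step deliberately does not end the analysis: loci with
ample reads whose best model is rejected are exactly the non-diploid read
ratios that inverted duplications produce, so the discovery wrapper
`call_inversions()` carries the maximum-likelihood model forward into
classification with a `model_rejected` flag. Phase evidence then separates
real complex events from artefacts.

**Classification and phasing.** Haplotype ratios (fraction of H1 among
haplotagged reads) are computed per strand, requiring 10 phased reads per
strand. The signatures:

* `simple_hom` — genotype homozygous, both haplotypes on the
  non-reference strand (ratio in (0.25, 0.75));
* `simple_het` — genotype heterozygous, opposite single haplotypes on the
  two strands (one ratio > 0.75, the other < 0.25); phased `"1/0"` when the
  non-reference strand is H1 (> 0.75), `"0/1"` when H2 (< 0.25);
* `complex` — genotype heterozygous, a single haplotype on the
  non-reference strand but both on the reference strand (the inverted
  duplication signature);
* anything else `unclassified`.

Loci genotyped homozygous-inverted in *every* individual of a cohort are
flagged as likely reference-assembly misorients (`flag_misorients()`,
cross-individual matching by 50% reciprocal overlap).

## Cross-platform inversion unification

Five discovery callsets (short-read, long-insert, long-read, optical map,
Strand-seq) are unified in three support tests: (i) pairs of calls from
*different* platforms with > 50% reciprocal overlap on both sides; (ii)
re-genotyping of every platform call in the composite file (minimum 25
reads; support means a heterozygous or homozygous-inverted genotype);
(iii) Strand-seq calls carrying a phase classification. Supported calls
are chained into non-redundant loci by single-linkage > 50% reciprocal
overlap. Each locus reports outer breakpoints (outermost bounds over
members), inner breakpoints (the region covered by at least half of the
overlapping predictions; equal to the outer bounds for singleton loci), a
majority consensus genotype with one vote per platform (`ambiguous` on
ties), and a `complex` flag when any supporting Strand-seq member is
complex or an external copy-number flag is set. Pericentric loci (outer
interval overlapping the centromere annotation) and loci with > 90%
tandem-repeat fraction are removed.

## Multi-caller breakpoint consensus and NCR

Per-caller breakpoint confidence intervals are estimated empirically: each
caller's calls are matched to a base-pair-resolved gold set by 50%
reciprocal overlap and the 10th/90th percentiles (linear interpolation
between order statistics, `quantile()` type 7) of the signed offsets per
side form the CI; callers with fewer than 30 matches per side receive a
configurable default. Breakpoints are clustered by CI overlap (closed
interval ends): a group whose CIs share a common intersection takes the
minimized CI `[max(lo), min(hi)]`; otherwise the CIs are stacked, the
coverage step function over sorted endpoints is scanned for (plateau-aware)
local maxima, each peak plus its right-neighbour segment becomes a sub-CI,
and breakpoints join their nearest sub-CI. The consensus breakpoint is the
modal proposed coordinate, smallest on ties.

QC labels on the merged consensus set, in order of precedence:
`telomere_centromere`, `oversize` (> 1 Mb), `redundancy` (singleton calls
reciprocally overlapping a multi-algorithm cluster), `PASS`.

`evaluate_combinations()` benchmarks unions of two and three callsets and
the two-of-three majority, merging calls across callers by 50% reciprocal
overlap; NCR = 1 − concordant fraction of merged calls is the FDR proxy.
Reciprocal overlap is only meaningful for calls with extent; insertion
point anchors are merged by breakpoint CIs instead, so combination
benchmarks are run on deletion callsets.

## Long-read validation calculus

* **Read support (PBRC).** A call validates when more than 4 reads
  (alignments ≥ 1.5 kb, counted upstream) support the alternate allele.
* **Optical-map length concordance.** Against an optical-map event of
  length `L_BN`, each overlapping sequence-resolved candidate scores
  `f_BN = |L_BN − L_PB| / L_BN` on length magnitudes after type matching;
  the single minimizing event (never a sum of events) validates when
  `f_BN < 0.1`, regardless of read support.
* **Read depth.** A deletion validates when the minimum over all sliding
  windows of the SV's length of the mean coverage is strictly below 30
  (against a ~40× background); the mean-of-window aggregation is the
  package's reading of "average coverage within a sliding window".
* **Short-read concordance filter.** An Illumina call is concordant when
  any of: (1) best length concordance ≥ 0.5 against assembly-level or
  optical-map targets within 1 kb of its breakpoints; (2) ≥ 3 individual
  long reads at concordance ≥ 0.7; (3) it is a deletion with mean long-read
  depth < 25; (4) a pluggable raw-read predicate fires (default never —
  dot-plot evidence is out of scope and supplied externally).

Boundary values (4 reads, `f = 0.1`, coverage 30) all fall on the strict
side; the test suite pins each one.

## Haplotype and callset merging

Haplotype-resolved callsets are merged into diploid calls with a
tandem-repeat-aware reciprocal-overlap threshold: 0.10 outside tandem
repeats (breakpoints of the same SV assembled from separate haplotypes are
consistent there) and 0.50 inside. The tandem-repeat track is padded by
20 bp and merged first; loci carrying six or more SVs on either haplotype
are set aside entirely (calls removed, locus recorded) since such clusters
reflect representation ambiguity rather than distinct variants. Matched
pairs become homozygous (`1/1`); unmatched calls stay `1/0`/`0/1`.

The two assembly callsets unify in three ordered tiers: (a) optical-map
validated representatives (`f_BN < 0.1`, the callset with the smaller
`f_BN` wins), (b) remaining primary-callset calls with PBRC > 3, (c)
remaining secondary-callset calls at least 10 kb from any primary call.
Cross-tier duplicates are collapsed by 250 bp boundary-window clustering
with tier precedence (a) > (b) > (c).

Local assemblies become contigs via a DAG with an edge between assemblies
separated by ≤ 100 kb with overlap alignments ≥ 10 kb, directed by genomic
order; one contig per weakly connected component, the path maximizing
total genomic span. The maximization is exact: a Pareto dynamic program
over (rightmost end reached, union length) states, so overlapping tiles
are never double-counted.

`build_pan_sv()` integrates the three filtered callsets into one record
per locus (single-linkage 50% reciprocal overlap within SV type), with
provenance the set of contributing platforms and the representative call
preferring PB, then IL (also for IL+BNG loci), then BNG.

## The synthetic-data module

The generator emulates: chromosome-scale genomes with centromere,
tandem-repeat and segmental-duplication tracks; heterozygous SNVs at
exponential spacing (default mean 1360 bp, the typical distance between
phased heterozygous sites); planted simple inversions and heterozygous
inverted duplications with log-uniform sizes; composite files with
per-haplotype Poisson read sampling, orientation noise and haplotags;
per-caller callsets with binomial detection, Gaussian breakpoint jitter
and Poisson false positives with retained truth linkage; and validation
evidence (Poisson read support around separate means for true and false
calls, optical-map lengths with relative Gaussian error, per-bp coverage
profiles with genotype-dependent drops inside deletions).

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `read_density` | 25 reads/kb | composite files pool ~100 single cells; the method's own 50-read genotyping minimum on multi-kb events implies this order of coverage |
| `orientation_error` | 0.02 | matches the 2% background the genotyper allows |
| `haplotag_rate` | 0.3 | fraction of fragments capturing a phased SNV at ~1.3 kb SNV spacing and a few-hundred-bp fragment span |
| `hom_fraction` | 1/3 | applies to simple events; inverted duplications are heterozygous by construction (a homozygous one would show both haplotypes on the non-reference strand and match no signature) |
| `dup_copies` | 1 | one extra direct copy gives the characteristic ≈1/3 read ratio of inverted duplications |
| `support_mean_true` / `false` | 20 / 1 | a ~40× genome split over two haplotypes, against near-zero support for artefacts |
| `min_gap` (planting) | 50 kb | keeps neighbouring events individually resolvable by a 250-read window at default density |

What the generator does **not** emulate: base-level sequences and
alignment, sister-chromatid exchanges and BrdU chemistry, per-cell
composite structure (cells are merged), segmental-duplication-mediated
mis-mapping, and real breakpoint microhomology. Passing tests therefore
demonstrate the correctness of the decision calculus on its stated inputs,
not robustness to upstream artefacts of real data.

## Numerical choices and degenerate inputs

* Exact binomial likelihood ties break in the fixed model order
  (hom-ref, het, hom-inv); a zero-read locus is an error for
  `compute_read_ratio()` and `untyped` for the genotyper.
* RNG: one master seed; every generator derives a labelled 31-bit
  sub-stream, so module outputs are independent of call order and
  bit-identical across reruns.
* CI stacking counts closed interval ends; percentiles interpolate
  linearly (type 7). Both are config-visible choices where the method
  definition is silent.
* Modal-breakpoint ties break to the smallest coordinate; single-linkage
  defines every reciprocal-overlap grouping (the grouping rule for > 2
  calls is otherwise under-determined).
* `merge_local_assemblies()` rejects cyclic inputs (impossible under
  genomic-order edges) rather than silently mis-merging.

## Problem sizes in the shipped tests

The test suite exercises: the full genotyper grid (all count pairs with
total ≤ 100) against an independent enumeration oracle; planted-recovery
experiments on 5 × 10 Mb genomes with 100 inversions (5–500 kb) at
5 reads/kb and on smaller genomes at 25 reads/kb; 500-call three-caller
combination benchmarks against a union-find enumeration oracle; and
random-case oracles (≤ 8 breakpoints, ≤ 10 assemblies, 200–300 bp depth
profiles). The end-to-end pipeline fixture is two 5 Mb chromosomes with 12
inversions and 80 deletions/insertions. These sizes were chosen so each
property is measured on hundreds to thousands of decisions while any
single experiment stays within seconds.

## Known limitations

* Discovery resolution is bounded by the read-count window
  (≈ `0.3 × window_reads / density` bp); events below it are invisible
  regardless of downstream care. At 5 reads/kb this floor (≈13.5 kb for
  heterozygous events) dominates recovery of small inversions.
* The boundary changepoint refinement assumes a single orientation switch
  per run; closely spaced opposite-genotype events inside one run merge
  into one candidate.
* Consensus genotypes weight each platform once; platforms contributing
  several overlapping predictions at one locus are not up-weighted.
* The condition-(4) raw-read predicate defaults to "never fires"; real
  dot-plot evidence must be supplied by the caller.
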