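# svscribe

Haplotype-aware structural-variant (SV) discovery, validation and
multi-platform integration — with a built-in synthetic-truth benchmark.

Comprehensive SV maps of human genomes are built by combining platforms
with complementary blind spots: short-read WGS, long-insert libraries,
long reads, optical maps, and Strand-seq. svscribe implements, as tested
reusable R functions, the decision calculus that turns their raw callsets
into one high-confidence, haplotype-resolved callset:

* **Strand-seq inversion discovery** from composite files of oriented
  reads: sliding-window read-ratio segmentation (250-read windows, >15%
  non-reference trigger), exact three-model binomial genotyping
  (background *b* = 0.02; models *b*, 0.5, 1 − *b*; ≥ 50 reads), and
  strand-aware haplotype-ratio classification into simple homozygous /
  simple heterozygous (with phase `1/0` / `0/1`) / complex
  inverted-duplication events, plus reference-misorient flagging across
  individuals.
* **Cross-platform inversion unification**: >50% reciprocal-overlap
  intersection between independent technologies, Strand-seq re-genotyping
  (≥ 25 reads), phase-supported Strand-seq calls, merged into
  non-redundant loci with outer (InvR) and consensus inner breakpoints,
  majority genotypes, and pericentric / tandem-repeat (>90%) filters.
* **Multi-caller breakpoint consensus**: per-caller empirical breakpoint
  confidence intervals (10th/90th offset percentiles vs a gold set),
  CI-overlap clustering with a coverage-stacking fallback, modal consensus
  breakpoints, QC labels (telomere/centromere, >1 Mb, redundancy, PASS),
  and non-concordance-rate (NCR = 1 − concordance, an FDR proxy)
  benchmarking of caller combinations (union of 2, union of 3,
  two-of-three).
* **Long-read validation & merging**: read-support validation (PBRC > 4),
  optical-map length concordance (*f*<sub>BN</sub> = |L<sub>BN</sub> −
  L<sub>PB</sub>| / L<sub>BN</sub> < 0.1), sliding-window depth validation
  (< 30×), the four-condition short-read concordance filter,
  tandem-repeat-aware haplotype merging (RO 0.10 outside / 0.50 inside
  TRs; ≥ 6-SV TR loci set aside), DAG longest-path contig merging
  (≤ 100 kb gaps, ≥ 10 kb overlaps), tiered unification of two assembly
  callsets, and three-way pan-SV integration with PB > IL > BNG
  representation.
* **A synthetic-data module** that generates every input with known truth
  (genome model with annotation tracks, planted inversions and SVs,
  composite reads, per-caller callsets with jitter and false positives,
  validation evidence) so the whole pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on results, `autoplot()` / `plot_*()` for figures.

## Worked example

Simulate one individual, scan the composite file, classify and phase:

```r
library(svscribe)
library(dplyr)

genome <- generate_genome_model(1, 5e6, tr_density = 0.05,
                                snv_spacing_mean = 1360, seed = 7)
truth  <- plant_inversions(genome, 6, 3e4, 3e5, hom_fraction = 1/3,
                           complex_fraction = 1/3, seed = 7)
reads  <- simulate_strandseq_composite(genome, truth, read_density = 25,
                                       seed = 8)
scan   <- call_inversions(reads)
glance(scan)
#> # A tibble: 1 × 6
#>   n_reads n_candidates n_simple_hom n_simple_het n_complex n_unclassified
#>     <int>        <int>        <int>        <int>     <int>          <int>
#> 1  130598            6            0            3         3              0

tidy(scan) |>
  select(start, end, read_ratio, hap_ratio_ref, hap_ratio_nonref, cls, phase)
#> # A tibble: 6 × 7
#>     start     end read_ratio hap_ratio_ref hap_ratio_nonref cls        phase
#>     <dbl>   <dbl>      <dbl>         <dbl>            <dbl> <chr>      <chr>
#> 1   90180  159278      0.352        0.464           0.00704 complex    <NA>
#> 2  414170  552885      0.518        0.0239          0.979   simple_het 1/0
#> 3  973230 1246213      0.505        0.0217          0.974   simple_het 1/0
#> 4 1550101 1660120      0.502        0.975           0.0256  simple_het 0/1
#> 5 4136262 4226036      0.342        0.517           0.991   complex    <NA>
#> 6 4510101 4747337      0.345        0.510           0.986   complex    <NA>
```

All six planted events are recovered at their planted boundaries. The
three loci with read ratio ≈ 0.5 and a single, opposite haplotype per
strand are simple heterozygous inversions — phase `1/0` marks the
inversion on haplotype H1 (non-reference-strand haplotype ratio > 0.75),
`0/1` on H2 — matching the planted carriers (`het_H1`, `het_H1`,
`het_H2`). The three loci with the depressed read ratio ≈ 1/3 and a
single haplotype on the non-reference strand but both on the reference
strand are the planted inverted duplications (`complex`); the extra
segment copy on the carrier haplotype produces exactly that dosage.

The full pipeline (simulation → discovery → unification → consensus/NCR →
validation/merging → pan-SV) runs from one seeded configuration:

```r
res <- run_pipeline(pipeline_config(seed = 11, outdir = "run1"))
res$manifest$counts$unified_inversions   # 12
pan_sv_summary(res$pan_sv)               # counts and mean lengths per provenance class
```

A thin CLI covers the common entry points:
`exec/svharmonize simulate|strandseq-inv|run --seed N --outdir D`.

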