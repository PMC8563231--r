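---
title: "ROH detection, F_ROH and ROH islands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH detection, F_ROH and ROH islands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

Runs of homozygosity (ROH) are contiguous stretches of a diploid genome in
which all genotyped sites are homozygous. They arise when both parental
haplotypes descend from a common ancestor, so their number, length
distribution and genomic placement carry information about inbreeding
history: long runs point to recent inbreeding, short runs to remote
inbreeding broken up by recombination, and regions where many individuals of
a population share a run ("ROH islands") point to selection or drift.
`rohscan` implements this analysis for dense, resequencing-derived SNP
genotypes — typified by livestock conservation populations genotyped at one
SNP per few hundred base pairs on autosomes — together with a synthetic-data
generator that makes every stage testable against known ground truth.

Three population-genetic quantities are computed:

* **ROH segments** per individual, from a sliding-window homozygosity scan;
* **F_ROH**, the genomic inbreeding coefficient
  $F_{ROH} = L_{ROH} / L_{genome}$, where $L_{ROH}$ is the summed ROH length
  of an individual and $L_{genome}$ the autosomal length covered by SNPs;
* **ROH islands**, maximal runs of SNPs whose *incidence* — the fraction of
  individuals whose ROH cover the SNP — exceeds a threshold.

## The window scan

The caller follows the PLINK-style scanning procedure. For one sample and
one chromosome with $n$ SNPs:

1. every window of `window_snps` (default 50) consecutive SNPs lying fully
   inside the chromosome is flagged *homozygous* when it contains at most
   `window_max_het` (default 1) heterozygous and at most
   `window_max_missing` (default 5) missing calls — the allowances that
   absorb genotyping error; a chromosome shorter than one window is
   evaluated as a single all-SNP window;
2. each SNP receives the fraction of flagged windows among the windows
   containing it, and is *eligible* when that fraction reaches
   `snp_hit_threshold` (default 0.05);
3. maximal runs of consecutive eligible SNPs are split wherever adjacent
   SNPs are more than `max_gap_bp` (default 1 Mb) apart, and a run is
   emitted as a segment iff it has at least `min_snps` SNPs (default 100),
   spans at least `min_length_bp` (default 1 Mb), and averages at most
   `min_density_bp_per_snp` (default 50 kb) per SNP.

Segment endpoints are the first and last SNP positions of the run, not
window edges, so `length_bp = end - start + 1` is well defined from the
data. Missing calls count toward a segment's SNP total but never as
heterozygous — the two allowances are separate. Where the published
criteria for this kind of analysis fix only the window allowances, the
minimum SNP count, the minimum length and the site-quality cutoff, the
remaining knobs (window size, hit threshold, density, gap) take the PLINK
v1.07 `--homozyg` defaults and are all exposed in `roh_params()`.

Two deliberate profiles exist for `min_length_bp`: the 1 Mb default
(the conventional minimum for resequencing data), and 100 kb for
length-class summaries whose lowest class starts at 100 kb. Published
tables of this kind are internally ambiguous about which minimum produced
them, so both are reachable by configuration rather than resolved silently.

Every call path is mirrored by `brute_force_roh()`, a deliberately naive
reimplementation (explicit loops over every window, every SNP, every run)
kept as an in-package oracle; the test suite asserts exact segment-list
equality on randomized instances.

### Site-quality filtering

Input sites with VCF `QUAL` below `min_site_quality` (default 10) are
excluded at read time, as are non-biallelic and indel sites: zygosity is all
the caller consumes, so multi-allelic records are dropped rather than split.
Whether a published "minimum quality of bases" criterion refers to base
qualities during calling or to site quality is generally not recoverable;
`rohscan` implements it as a site-QUAL filter and documents the choice here.

## F_ROH and summaries

`froh_per_sample()` divides each sample's summed segment length by
`genome_span()` — the sum over chromosomes of (last SNP − first SNP + 1),
i.e. the genome *covered by SNPs*, matching the denominator definition of
$F_{ROH}$. The same span (restricted per chromosome) is the denominator of
per-chromosome coverage in `per_chromosome_summary()`, keeping the two
statistics consistent.

`length_class_table()` uses half-open classes in kb — by default
$[100, 500)$, $[500, 1000)$, $[1000, \infty)$ — so a segment of exactly
500 kb belongs to the second class; the published "100–500"/"500–1,000"
labelling is boundary-ambiguous and this tie rule makes it deterministic.
Percentages are reported to 2 decimals with half-up rounding. Segments
shorter than the first class edge are excluded from the table (its total row
is "total above the lowest edge"). Note that a combined share of several
classes computed from counts can differ in the last digit from the sum of
the rounded per-class percentages; the package always computes from counts.

## ROH islands

`snp_incidence()` counts, for every SNP, the samples with at least one
segment whose closed interval contains the SNP. Two threshold conventions
are first-class in `incidence_threshold()` because published practice uses
both and they are not equivalent:

* `fixed` — a stated proportion, e.g. 0.30 for a "30% line" (the default
  profile);
* `quantile` — the top-`value` empirical quantile of all SNP incidences
  (`value = 0.01` for "top 1%"), with a nearest-rank definition (the
  $\lceil p \, n \rceil$-th order statistic) to avoid interpolation
  ambiguity.

`merge_islands()` builds maximal runs of consecutive above-threshold SNPs,
optionally tolerating up to `max_gap_snps` below-threshold SNPs inside a
run (default 0, with the count of tolerated SNPs reported per island), and
discards runs with fewer than `min_snps` above-threshold members (default
2). Islands never span chromosomes. How published island sets were grouped
(gap rule, minimum size) is typically unstated; the defaults here are the
strictest reading, and both knobs are explicit.

## The synthetic-data generator

`simulate_genotypes()` emulates the features of resequencing-derived
genotype data that matter to this analysis, at desk scale:

* a shared SNP panel per chromosome with exponential inter-SNP gaps (mean
  `snp_spacing_bp`, default 500 bp — a scaled-down stand-in for the ~100–150
  bp density of real resequencing SNP sets);
* per-sample autozygous tracts with lengths drawn from an exponential of
  mean `tract_mean_bp` (default 2 Mb) floored at `tract_min_bp` (default
  100 kb), placed uniformly over the remaining free intervals of the
  chromosome until the per-sample target fraction is met, then extended
  into adjacent free space to close the residual deficit — so the realised
  autozygous fraction tracks the target to well within 2% on genomes of
  10 Mb and larger, without a pedigree or recombination model;
* genotypes: inside tracts, homozygous except for a heterozygous-error rate
  (default 0.001); outside, heterozygous at `background_het_rate` (default
  0.25, a typical mean heterozygosity at segregating SNP sites in an
  outbred diploid sample); missingness (default 0.01) applied to any call;
* site QUAL uniform on [20, 60], with an optional fraction of sub-10 QUAL
  sites to exercise the quality filter;
* optional `forced_tracts` implanted at a fixed place in a chosen fraction
  of samples, for island-recovery experiments.

Only zygosity is modelled ({hom, het, missing}; alleles fixed as A/G in
fixture VCFs) because the caller consumes zygosity only. The generator does
*not* model linkage disequilibrium, an allele-frequency spectrum, or
pedigree structure; passing tests therefore demonstrate the correctness of
the scanning, summarising and island logic under controlled autozygosity,
not calibration against any real population's LD or SFS.

Everything is deterministic given `seed`: re-running a configuration
produces byte-identical VCF fixtures, which the pipeline manifest verifies
with MD5 checksums.

## Numerical and convention choices

* Coordinates are 1-based inclusive internally (VCF convention); BED input
  and output convert at the boundary; chromosome names are normalised by
  stripping an optional `chr` prefix, and the autosome allow-list defaults
  to `1..18` (pig autosomes).
* Interval overlap between islands and genes is closed-interval:
  `overlap_bp = min(ends) - max(starts) + 1`, computed via
  `GenomicRanges::findOverlaps`; a hit requires at least 1 bp of overlap
  (the weakest defensible reading of a gene being "harboured"), with
  whole-gene containment available as an option. Strand is ignored.
* The gene report's `size_bp` defaults to the **span** convention
  (`end - start`): published candidate-gene tables of this kind reproduce
  exactly under it (e.g. coordinates 95,854,107–95,918,246 give the
  printed 64,139), while the inclusive length (`end - start + 1`) is one
  larger and available via `size_convention = "inclusive"`.
* Empty inputs are legal where a zero answer is meaningful (an all-zero
  length-class table, an empty island set); they error where the quantity
  is undefined (F_ROH denominator, quantile of an empty track,
  `l_roh > l_genome`).

## Validation strategy and problem sizes

The test suite validates each stage against an independent recomputation:
the vectorised caller against the naive brute-force caller (exact equality
on 100+ randomized instances of up to 300 SNPs), incidence against
interval-stabbing recounts, island merging against an exhaustive run
finder, interval overlap against the all-pairs quadratic check, and the
worked numeric examples above against their printed values. Recovery
experiments use 10–20 samples on a 20 Mb chromosome at 500 bp spacing
(~40,000 SNPs) with 5 replicate seeds — large enough for stable fractions,
small enough to run in seconds — and recover mean F_ROH within a few
thousandths of targets 0.2 and 0.5.

## Known limitations

* **Boundary fuzz.** With 50-SNP windows and a 1-het allowance, windows
  straddling a tract edge that contain only a few background SNPs can still
  pass (one background heterozygote is within the allowance), so segment —
  and hence island — boundaries systematically overshoot true tract edges
  by a few SNP spacings on each side. This is inherent to the window
  criteria, not an implementation artifact (the brute-force oracle agrees);
  the acceptance script measures it as `island_boundary_error_bp`.
  Consumers needing sharp boundaries should post-trim segments to the
  outermost homozygous SNP.
* The caller is zygosity-based; no allele frequencies, LD pruning or
  HMM-based autozygosity inference.
* Ploidy other than 2 and sex chromosomes are out of scope; the quality
  criterion is interpreted at the site level (see above).
* Island significance is not assessed; islands are descriptive summaries of
  incidence, and gene overlap is positional annotation only (no enrichment
  statistics).
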