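---
title: "Methods: mtDNA somatic calling and CRISPR screen fitness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA somatic calling and CRISPR screen fitness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

mitoscreen implements two analysis pipelines used when characterizing
mitochondrial dysfunction in tumors: (1) calling and filtering somatic
mitochondrial DNA (mtDNA) heteroplasmies in a tumor cohort, and (2) scoring
a pooled CRISPR knockout dropout screen for genes that are selectively
essential in a tumor cell line. This vignette describes the models,
parameters and design choices; the README shows worked examples.

## The mtDNA setting

Human mtDNA is a circular 16,569 bp genome (numbered per the revised
Cambridge Reference Sequence, rCRS / NC_012920) encoding 13 OXPHOS protein
subunits, 22 tRNAs and 2 rRNAs. Cells carry hundreds to thousands of mtDNA
copies, so a somatic variant is present in a *fraction* of molecules — its
heteroplasmy — which deep sequencing estimates as the variant allele
fraction (VAF): alternate reads over total depth at the position
(`vaf_from_pileup()`).

### Somatic filters

For a tumor with a matched normal, `filter_matched()` passes a candidate
when all of:

* depth ≥ 15 reads in tumor **and** normal (inclusive),
* tumor VAF > 0.3 (strict),
* normal VAF < 0.05 (strict),
* tumor VAF − normal VAF > 0.4 (strict).

All VAF comparisons are strict and the depth comparison inclusive, exactly
as the thresholds are written; boundary values (VAF 0.3, difference 0.4)
fail, and each failed clause is recorded as a machine-readable reason code
in the `filter_decision`. Without a matched normal there is no germline
subtraction, so `filter_unmatched()` reports only clearly pathogenic
calls: loss-of-function (nonsense/frameshift) variants plus a whitelist of
known pathogenic alleles. The default whitelist contains only the
MELAS-associated tRNA variant m.3244G>A; cohort-specific additions (e.g. a
missense allele already established as pathogenic in a prior cohort for
the same patient) belong in a user-supplied whitelist file rather than in
package code. Calls are validated against RNA-seq by `validate_rna()`:
validated when the RNA heteroplasmy is strictly >10%, with zero RNA depth
reported as `not_assessable` — deliberately distinct from `failed`.

For cell lines, `call_cellline()` keeps variants that are nonsynonymous,
have VAF > 0.1 (strict) and are not haplogroup markers. "Nonsynonymous"
is read broadly — any non-synonymous, non-intergenic effect, including
tRNA/rRNA variants and coding indels — because pathogenic mtDNA lesions
are not limited to missense changes; `protein_only = TRUE` restricts to
protein-altering classes. The haplogroup blacklist defaults to empty: no
haplogroup database is bundled, and which one to use (and its version) is
a study-level decision supplied as a position/ref/alt TSV.

### Effect classification and the reference sequence

`classify_effect()` translates the affected codon under the vertebrate
mitochondrial genetic code (NCBI table 2, via Biostrings), reverse
complementing for light-strand genes and A-completing the incomplete
terminal stop codons that polyadenylation finishes in vivo. Indels in
protein genes are frameshift when the length change is not a multiple of
three. The mitochondrial genome has overlapping genes (MT-ATP8/MT-ATP6,
MT-ND4L/MT-ND4, and tRNA pairs); a variant is classified against **every**
overlapping feature, and the reported class is the most severe under
nonsense = frameshift > missense > inframe_indel > tRNA = rRNA >
synonymous > noncoding. Severity-max is the conservative choice when a
single label is needed downstream, and the per-gene detail is kept.

The packaged gene model uses the standard rCRS coordinate table. The
reference **sequence** bundled with the model is synthetic: a
deterministic stand-in, scrubbed of premature in-frame stop codons in
every protein gene's own frame, with the handful of positions used by the
documented examples pinned to their real rCRS bases. It exercises the
classification machinery fully (tests compare it against an independent
brute-force codon oracle at >1,000 random positions), but classifying
real variant calls requires the real sequence, supplied via
`load_gene_model(fasta = ...)`. Stop-loss SNVs are reported as missense
(there is no dedicated class), which slightly understates their severity;
they are rare at mtDNA stop codons and never reach the disruptive tier
anyway.

### Large-deletion scan

Large heteroplasmic deletions leave a proportional dip in sequencing
coverage. `scan_deletions()`:

1. normalizes per-base depth by the genome-wide median, computed in two
   passes so a multi-kilobase deletion does not drag down its own
   baseline (candidate low windows are excluded from the second-pass
   median);
2. tiles the circular genome into `window_bp` windows (default 300 bp)
   and flags windows whose median normalized depth falls below
   `drop_ratio` (default 0.7);
3. takes maximal circular runs of flagged windows, merging runs separated
   by less than one window;
4. refines each breakpoint to the steepest depth change within ± one
   window of the coarse boundary (difference of flanking means, flank
   min(window, 150) bp);
5. drops calls shorter than `min_len_bp` (default 500 bp) and estimates
   the deleted-molecule fraction as 1 − mean(depth inside)/mean(depth
   outside), clamped to [0, 1].

The defaults are engineering choices, surfaced as arguments/CLI flags: a
300 bp window is small against the kilobase-scale deletions of interest
but large enough that a window median at ≥200× coverage essentially never
fluctuates below 0.7 of baseline (binomial tail over ~300 Poisson draws),
which is what makes the scan specific on deletion-free profiles. The
estimator assumes one deletion species; overlapping deletions emerge
merged. Calls may wrap the origin (`start > end`); BED export splits such
calls into two rows sharing a name, converting to 0-based half-open
coordinates in a single centralized helper.

### Cohort summary

`summarize_cohort()` counts tumors, not variants: tumors with any passing
variant at VAF > 0.20 (strict), tumors with a disruptive variant per
OXPHOS complex (a tumor with hits in two complexes counts once in each),
tumors with tRNA-gene variants (reported separately, since tRNA variants
are never "disruptive" in the nonsense/frameshift sense), and tumor-level
RNA validation tallies. Whether the cohort VAF threshold is applied
before or after somatic filtering is ambiguous in principle; the summary
takes already-filtered calls and applies the threshold on top, keeping the
two decisions independent and inspectable.

## The screen setting

A pooled knockout library — by default 191 genes of interest, 50 control
genes and 10 essential genes at 5 sgRNAs per gene, plus 75 cutting and 75
non-cutting controls (1,405 guides) — is screened in a tumor line and a
non-tumor control line, sequenced at days 5, 8, 11, 16 and 20 post
infection. Scoring (`score_screen()`) follows the printed formulas:

* per sample: `value = log2(reads / total reads × 10^6 + 1)`; the +1
  pseudocount keeps dropouts finite, and per sample
  `Σ(2^value − 1) = 10^6` exactly;
* per guide: log2 fold-change versus the day-5 reference in the same
  cell line;
* per sample: `Z = (lfc − mean) / sd` with the sample standard deviation
  (n−1);
* per gene: mean of its guides' Z (median optional); control guides
  aggregate under their category label;
* per gene and day: `ΔZ = (Z_tumor − Z_control) / 2`, and hits are
  `ΔZ < −2`, strictly.

Two points are genuinely underdetermined and exposed as options. First,
the standardization population: Z over *all* guides in the sample is the
plain reading of the formula and the default; `z_ref = "noncutting"`
standardizes against non-cutting controls instead, the usual choice when
many true dropouts would otherwise inflate the denominator. Second, the
gene aggregation (mean, default, vs median). Zero dispersion or a missing
day-5 reference fails loudly rather than imputing; guide-level QC is off
by default because the scoring definition includes none (a
`--min-day5-reads`-style floor can be applied upstream of
`count_matrix()` by the caller).

## The simulators

`simulate_pileups()` draws alt counts Binomial(depth, fraction) — the
sampling model under which VAF is the maximum-likelihood heteroplasmy
estimate. `simulate_coverage()` draws per-base depth Poisson(baseline),
scaled by 1 − del_fraction inside a planted (possibly origin-wrapping)
deletion. `simulate_screen()` gives each guide a log-normal initial
abundance (sdlog 0.5), grows it exponentially at
`2^((g − f)·(d − 5)/Td)` with neutral growth g = 1 doubling/day and
doubling time Td = 1 day, and sequences each sample multinomially at an
exact total of `n_guides × reads_per_guide_mean` (default 1,000) reads —
multinomial rather than independent Poisson so totals are conserved; a
Dirichlet-multinomial overdispersion option is provided because real
screens are overdispersed. Fitness penalties f are in doublings/day:
essential genes default to f = 1 (growth arrest) in both lines, and
planted selective dropouts default to f = 2 (abundance halves daily in
the affected line). These calibrations are documented choices, not
estimates of any real screen: no effect-size calibration is published for
the screen design this emulates. All simulators are pure functions of
their configs; per-sample seeds derive deterministically from the master
seed, so adding a timepoint leaves other samples' draws untouched.

What the simulators deliberately omit: PCR jackpots, guide-efficiency
heterogeneity, NUMT contamination, strand bias, mapping artifacts, and
copy-number-driven coverage waves. Passing the property suite on
simulated data therefore demonstrates the *scoring and calling logic* is
correct under the assumed sampling models, not that those models capture
every pathology of real libraries.

## Problem sizes and numerical checks

The test suite works at the defaults the methods target: heteroplasmy
recovery at depth 2,000 over 100 replicates (mean absolute error ~0.009,
bound 0.03); deletion recovery of a planted 3,710 bp deletion at
del_fraction 0.6, 1,000× coverage over 100 seeds (interval Jaccard ≥ 0.9
and length error ≤ 150 bp required in ≥95; breakpoint refinement lands
within a few bases in practice) with zero tolerated false calls on 100
deletion-free 200× profiles; and the full 1,405-guide screen over 20
seeds for power (≥9 of 10 planted dropouts hit at day 16 in ≥18 seeds)
and null behaviour (<2% of genes below −2). The end-to-end screen scorer
is required to match an independent straight-line recomputation of the
formulas to 10⁻¹⁰. `scripts/acceptance.R` recomputes all of these from
scratch against the installed package.

## Known limitations

* The bundled reference sequence is synthetic (above); real-variant
  effect classification needs a user-supplied rCRS FASTA.
* The deletion-fraction estimator is biased when multiple deletion
  species overlap, and breakpoint refinement assumes a step-like edge.
* VCF support is a deliberately minimal v4.2 subset (mitochondrial
  contig, AF-else-AD precedence, one or two samples).
* No statistical testing is attached to screen scores (no MAGeCK/BAGEL
  style inference); ΔZ < −2 is a fixed operating point, not a false
  discovery rate.
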