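---
title: "Methods: breed-stratified variant-catalog statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breed-stratified variant-catalog statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`breedvar` analyzes multi-sample diploid variant callsets from multi-breed
cohorts: caller concordance, cohort and per-breed descriptive statistics,
allele-frequency discrepancy screens, special variant classes, a window
variability scan, and cohort-design arithmetic. This vignette records the
models and the design choices behind each stage, and what the synthetic
cohort generator does and does not emulate.

## The callset model

All analyses run on a normalized in-memory callset: biallelic records
keyed by `(contig, pos, ref, alt)`, with two integer allele matrices
(sites × samples; 0 = reference, 1 = alternate, `NA` = missing).
Multiallelic VCF records are decomposed into one record per alternate
allele. In the re-coded genotypes, an allele that matched a *different*
alternate is set missing rather than reference: counting it as reference
would inflate reference allele counts, whereas dropping it restricts each
decomposed record's frequencies to informative chromosomes. Decomposed
records keep a shared multiallelic id so multiallelic-site tallies are
preserved through intersection and union. Alleles are left-normalized
(shared trailing bases trimmed first, then shared leading bases, always
keeping at least one base of each allele).

Two conventions follow from decomposition:

* **Half-missing genotypes** (one allele called, one missing) are a
  legitimate product of the re-coding rule (e.g. genotype `1/2` at a
  two-alternate site) and are also legal VCF, so the reader accepts them.
* **Genotype-level counting.** Every downstream tally — AC/AN, het and
  hom-alt counts, missingness, screens — counts a genotype only when both
  alleles are called; a half-missing genotype is treated as missing
  wholesale. This keeps the intuitive invariants exact, e.g. a site with
  no homozygous-alternate genotype always has alternate-allele frequency
  ≤ 0.5, and per-sample carried sites always split into het + hom-alt.

Variant types: SNP (both alleles one base), INDEL (lengths differ), OTHER
(equal lengths > 1). OTHER records are excluded from TsTv and from the
SNP/indel columns but count toward variant totals. Coordinates are 1-based
in VCF and converted to 0-based half-open for all internal interval
arithmetic; conversions happen only at I/O boundaries. Ploidy is strictly
diploid; haploid or polyploid genotypes are a hard error (autosomal
analysis; sex-chromosome handling is out of scope).

## Concordance

Two callsets are matched on the exact `(contig, pos, ref, alt)` key after
decomposition and normalization — the strictest reproducible choice, since
position-only matching conflates distinct alternates. The intersection
carries the first callset's genotypes by default (`genotype_from = "B"`
swaps the donor); the union carries the donor's genotypes where available
and the second caller's for its private sites. Sample sets must be
identical unless an explicit flag requests the sample intersection. The
descriptive summary reports variant counts by type, multiallelic tallies,
TsTv, and hetNRhom aggregated as total heterozygous over total
homozygous-alternate genotypes across the whole cohort (not a mean of
per-sample ratios); per-sample transition/transversion and het/hom counts
are available from `per_sample_summaries()` for breed-level tables. Zero
denominators yield `NA` with a warning, not an error.

## Cohort metrics

* **MAF** uses called alleles only (AN), folded to `[0, 0.5]`.
* **Estimated marginal means.** Because variant yield depends on depth of
  coverage (DOC), breed means are compared from the least-squares model
  `response ~ breed + doc`, evaluated per breed at the grand-mean DOC
  (via the `emmeans` package), with t-based confidence intervals on the
  residual degrees of freedom. When DOC is constant it is dropped from
  the model, so the marginal means reduce to raw breed means; a design in
  which breed determines DOC exactly is singular and rejected.
* **DOC association.** The non-linear, saturating relation between depth
  and variants detected is summarized by a Spearman rank correlation plus
  a least-squares fit of `count = a(1 − e^{−doc/b})`. The curve is linear
  in `a` given `b`, so `a` is profiled out analytically and `b` found by
  one-dimensional optimization of the profiled sum of squares on a log
  scale — stable even when most samples sit on the plateau, where a
  cold-started two-parameter optimizer can stall on a near-singular
  gradient.

## Breed screens

Thresholds are strict: rare means MAF < 0.03, common means MAF > 0.10,
and values at a threshold are intermediate (the screen definitions are
written with strict inequalities, so equality belongs to neither class).
Both are `screen_config()` parameters. Screens operate on the folded
per-breed MAF; rest-of-population frequencies are recomputed excluding
the focal breed's samples entirely. Breed presence means at least one
alternate allele observed (`AC_b > 0`); a variant is breed-unique when
exactly one breed label carries it, with samples outside the target
breeds contributing under their own labels. Genic proximity (default
5,000 bp) is measured from the variant's anchor position only — for
left-normalized indels the anchor is deterministic, whereas span-based
distances would depend on representation. "Present in all" requires a
called, alternate-carrying genotype in every sample; a single missing
genotype disqualifies, a conservative and reproducible reading.

## Window scan

Each contig is tiled from position 0 into fixed windows (default
10,000 bp); the final window of a contig may be partial and is included,
and empty windows count toward the mean (full tiling). With `m` the mean
variant count per window, high-variability windows have counts strictly
above `2m` and low-variability windows strictly below `m/2`; the label
set is invariant to rescaling all counts. Partial windows can be dropped
(`drop_partial = TRUE`) where length-unnormalized counts would bias small
contigs.

## Power arithmetic

Detection power is `1 − (1 − q)^{n · d}` with `d = 1` draw per individual
by default: treating each individual as a single draw reproduces the
standard printed design values for this kind of survey (e.g. power 0.93
for q = 0.005, n = 534; 0.44 for q = 0.03, n = 19), while `d = 2` is
available to treat individuals as two chromosome draws. The smallest
cohort for a target power is the exact ceiling inverse, verified in tests
by brute-force scan. The one-homozygote cohort size is `⌊1/q²⌋`, the point
at which the Hardy–Weinberg expected homozygote count `q²N` reaches 1
(1,111 individuals at q = 0.03); the floor guards against binary-fraction
round-off. Expected sites per window is `n · w / G` for a catalog of `n`
sites on a genome of `G` bp and window width `w`.

## The synthetic cohort generator

The generator exists so every stage has ground truth. Its defaults emulate
a multi-breed survey at desk scale:

| parameter | default | rationale |
|---|---|---|
| breeds × samples | 10 × 15 | ten target breeds of at least 15 individuals |
| genome | 2 × 2 Mb contigs | keeps runtimes in seconds |
| sites | 50,000 | ≈ 12.5 sites/kb, ≈ 125 per 10 kb window, matching a dense WGS catalog |
| spectrum | density ∝ 1/q on [0.001, 1] | neutral-spectrum shape; truncation at the smallest detectable frequency |
| drift F | 0.05–0.20 across breeds | Balding–Nichols Beta drift spanning weak to strong breed differentiation |
| transition fraction | 0.66 | gives TsTv = 0.66/0.34 ≈ 1.94 |
| indel fraction | 0.07 | indel share of a two-caller intersect catalog |
| DOC | Gamma(shape 1.54, mean 11.5X), floored at 1X | right-skewed depth with median near 9X |
| dropout scale d0 | 2X | missingness `e^{−doc/d0}` ≈ 1% at the median depth, saturating past ~10X |

Sampling `q = q_min (q_max/q_min)^u` with uniform `u` makes `log q`
uniform, the inverse-CDF realization of the 1/q density. Under this
spectrum an HWE cohort's aggregate hetNRhom ratio has closed form
`2(1−a)/(1+a)` at truncation `a` — 1.996 at `a = 0.001`, the classical
expectation of 2 — which the acceptance check verifies by simulation
(200,000 sites × 500 individuals). Balding–Nichols drift draws
`q_b ~ Beta(q(1−F)/F, (1−q)(1−F)/F)`, mean `q`, variance `Fq(1−q)`.
Genotypes are two independent Bernoulli(`q_b`) alleles; dropout is
independent per genotype with probability `e^{−doc/d0}`, giving the
saturating missingness-vs-depth decline whose scale the DOC curve fit
recovers. Window density multipliers reweight site placement per window;
positions are drawn without replacement within windows so site keys are
unique by construction.

Injected truth classes (breed-unique, no-homozygote, present-in-all,
homozygous-in-all) are placed at mutually disjoint sites, exempted from
missingness, and recorded in a truth table. Two subtleties:

* Injected no-homozygote sites are heterozygous in about half the
  samples (never all, so they stay disjoint from present-in-all);
  injected present-in-all sites keep at least one heterozygote so they
  stay disjoint from homozygous-in-all.
* Background HWE sites can legitimately satisfy the same predicates — at
  low `q` a site with a handful of carriers usually has no homozygote.
  The generator deliberately does not "repair" such sites, since that
  would distort the Hardy–Weinberg spectrum the calibration checks rest
  on. Recovery tests therefore assert that (a) every injected site is
  recovered with its exact class and breed, and (b) the complete
  recovered sets equal an independent brute-force recount.

What the generator does **not** emulate: linkage disequilibrium,
recombination, pedigree or within-breed relatedness, mutational context,
genotyping error, or caller-specific biases. Passing tests demonstrate
the correctness of the computations under a known model, not the
statistical behavior of any particular caller on real reads.

## Problem sizes and determinism

The test suite exercises exact-oracle equality on callsets up to 1,000
sites × 20 samples, truth-class recovery on a 50,000-site × 100-sample
no-missingness cohort, calibration checks on 20,000–50,000-site cohorts,
and the HWE expectation on 200,000 sites × 500 individuals — sizes chosen
so the full suite runs in a few minutes while keeping Monte-Carlo
tolerances (3 SD bands, 2% on the HWE ratio) meaningful. All generator
output is reproducible from `cohort_config(seed =)`; the pipeline itself
is deterministic, and every output TSV records the package version, seed
and thresholds applied.

## Known limitations

Autosomal diploid genotypes only; no gVCF or phasing support; functional
impact is passed through from an existing annotation field, never
predicted; concordance is two-way and site-level (no genotype-level
agreement metrics); screens assume the sample sheet's breed labels are
correct and complete.
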