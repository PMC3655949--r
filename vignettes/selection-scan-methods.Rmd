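---
title: "Composite selection-signature scans with selmeta"
author: "selmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection-signature scans with selmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selmeta)
```

## The problem and the model

Recent positive selection drags a favoured allele — and the haplotype it
sits on — to high frequency faster than recombination can break the
haplotype apart. The footprints are (i) unusually long stretches of
haplotype homozygosity around the selected site, (ii) a shifted derived
allele frequency relative to related populations, and (iii) a local
depression of heterozygosity. No single statistic captures all three, and
the individual tests are only weakly correlated; a signal supported by
several of them at once is much stronger evidence than any single extreme
score.

`selmeta` implements four component genome scans on phased, biallelic,
ancestrally polarized SNP panels and combines them per SNP and per focal
population with a weighted Stouffer meta-statistic:

* **iHS** (within population): `ln(iHH_A / iHH_D)`, where iHH_A and iHH_D
  are the areas under the EHH decay curves conditioned on the ancestral and
  derived core allele. Scores are standardized within 20 derived-allele
  frequency (DAF) bins and both tails are of interest, so two-sided
  P-values `1 - 2|Φ(z) - 0.5|` are used.
* **Rsb** (between populations): `ln(iES_focal / iES_other)` per marker,
  where iES integrates the site-EHH (EHHS, normalized to 1 at the core so
  the two populations are on a common scale). Standardization uses the
  genome-wide median and SD, with one-sided upper-tail P-values; positive
  values point at the focal (numerator) population.
* **ΔDAF** (between populations): the difference in derived allele
  frequency, standardized by its genome-wide mean and SD, upper-tail
  P-values.
* **SHp** (within population): the per-site observed heterozygosity
  (fraction of heterozygous individuals), z-scored genome-wide and negated,
  so heterozygosity depressions score high; upper-tail P-values. This is a
  per-SNP adaptation of the windowed ZHp statistic, and it is computed on
  diploid genotypes — haplotype panels are re-paired by sample first.

Each track's P-value is transformed to an upper-tail Z,
`Z_i = Φ⁻¹(1 − p_i)`, and combined as

```
meta-SS:  S = Σ ω_i Z_i / sqrt(Σ ω_i²),    p = 1 − Φ(S)
```

with weights ω = 1 for each within-population test and ω = 1/n for each of
the n between-population comparisons of a given test, so every test
contributes total weight 1. Genome-wide significance uses the Bonferroni
threshold α/n_SNP (for example, `bonferroni_threshold(0.05, 157702)` ≈
3.17×10⁻⁷ on a 157,702-marker scan).

**Sign convention.** Some descriptions of this combination write the
transform as `−Φ⁻¹(1 − p)`, which algebraically makes strongly selected
markers *negative* and is inconsistent with referring S to the upper tail.
`selmeta` uses `Z = Φ⁻¹(1 − p)` throughout: small P ⇒ large positive Z ⇒
large positive S ⇒ small combined P. A `two_sided` flag on `combined_p()`
and `meta_scan()` is available for sensitivity analysis.

**Missing components.** A marker missing one track (e.g. iHS undefined
because one core allele has fewer than two carriers) still combines over
the present tracks: the present weights are used in both the numerator and
the denominator, which keeps S standard normal under the null for any
missingness pattern. Markers with no track at all get a missing S.

## Upstream stages

* **QC** (`apply_qc()`): markers must pass MAF ≥ 0.03, exact-test HWE
  P ≥ 1×10⁻⁶ and call rate ≥ 90% (all inclusive); sample call rates are then
  recomputed on the surviving markers and samples below 90% dropped. The
  HWE test is the exact conditional test (not chi-square), evaluated by a
  numerically stable recurrence and checked in the tests against a direct
  enumeration oracle; it assumes one randomly mating population and is
  never applied to pooled data. QC runs per population; the scans then use
  `intersect_markers()` to keep markers passing QC everywhere.
* **Relatedness** (`estimate_pi_hat()`, `prune_related()`): a
  method-of-moments IBD estimate from IBS counts and panel allele
  frequencies; PI_HAT = P(IBD=2) + P(IBD=1)/2. Pairs above `pi_hat_max`
  (default 0.20, chosen to remove duplicates ≈ 1, parent–offspring ≈ 0.5
  and half-sibs ≈ 0.25 with margin) are pruned greedily and
  deterministically (highest degree first; ties to lower call rate, then
  lexicographic id). Estimates from fewer than 100 overlapping markers are
  flagged unreliable.
* **Ancestral allele calling** (`call_ancestral()`): outgroup panels are
  pooled; a marker is called if and only if every pooled outgroup sample is
  genotyped and exactly one allele is observed, the call being that allele.
  Any second allele — including a single heterozygote — counts as
  polymorphism, the conservative reading when heterozygous outgroup calls
  cannot be distinguished from genotyping error. The summary always
  satisfies `n_called = n_fully_typed − n_polymorphic`. Per-species call
  rates are reported but not used as filters.
* **Polarization** (`polarize()`): columns whose ancestral call is the
  panel's allele2 are bit-flipped so 1 always means derived; allele labels
  are relabelled (allele1 = ancestral) which makes the operation
  idempotent. Markers without an ancestral call are dropped from the scan
  stages and counted.

## EHH kernels and integration policy

Homozygosity uses the unbiased pair-count form `Σ_h C(n_h, 2) / C(n, 2)`
over haplotype identity classes, which is exactly testable against a
pairwise-identity oracle (the test suite and the acceptance script both
compare the C++ kernel with an independent O(n²m) enumeration). Classes
only refine as the span grows, so curves are non-increasing by
construction.

Integration (`integration_policy()`) proceeds from the core outward on each
side, trapezoid rule over bp, truncating at the first marker whose EHH
drops below `ehh_floor` (default 0.05; that marker is included as the final
vertex). Under the default `border_rule = "discard"`, the statistic is
missing when a side reaches the chromosome end before decaying, or when an
inter-marker gap exceeds `max_gap_bp` (default 200 kb) — unintegrable gaps
should not masquerade as long haplotypes. All three knobs are exposed
because published pipelines differ in exactly these choices.

## The synthetic-data generator

`simulate_neutral()` emulates a multi-population SNP-array panel: uniform
marker positions on one chromosome (default 20,000 markers on 100 Mb,
≈ 5 kb spacing); per-marker minor-allele frequencies from a U-shaped
Beta(0.5, 0.5) truncated to [0.03, 0.5]; the derived allele is the minor or
the major allele with equal probability, because outgroup polarization does
not constrain derived alleles to be rare and the 20-bin iHS standardization
presupposes DAF spanning (0, 1). The per-marker derived frequency is shared
across populations (common ancestral polymorphism); haplotypes are drawn
site-independently. Everything is deterministic given the seed (R's
Mersenne–Twister).

The site-independent baseline has, deliberately, **no linkage
disequilibrium**: it gives an analytically known null for calibration
tests. An optional haplotype-copying variant (`ld = list(n_founders,
switch_rate)`) adds background LD for harder tests. Passing tests on this
generator therefore demonstrate correctness of the statistics and their
calibration under a clean null — not performance on demographically
realistic data (bottlenecks, migration, ascertainment are all out of
scope).

`inject_sweep()` adds the textbook hard-sweep signature: a randomly chosen
fraction f (default 0.8) of haplotypes become carriers, receive the derived
allele at the core and one shared template haplotype across ±L bp (default
500 kb), and keep independent draws outside; non-carriers are set ancestral
at the core so the realized DAF is f ± 1/(2N). When a sweep target must be
chosen (power tests, the acceptance script), it is placed at a marker whose
neutral derived frequency is ≤ 0.1 — a hard sweep is, by definition, a
previously rare derived variant driven up — which also maximizes the ΔDAF
contrast at the true core. `simulate_outgroups()` generates the matching
outgroup pool (default 2 + 6 + 2 samples across three species), homozygous
ancestral everywhere, with configurable per-call missingness and
heterozygous contamination.

## Calibration behaviour worth knowing

These are properties the test suite and `scripts/acceptance.R` measure on
the generator's study conditions (2 populations × 50 haplotypes × 20,000
markers, fixed seeds):

* iHS, Rsb and ΔDAF P-values are approximately uniform under the null
  (fraction below 0.05 within 0.05 ± 0.01), and the meta-SS combined
  fraction lands close to nominal.
* SHp's upper tail is conservative (fraction ≈ 0.017 < 0.05): observed
  heterozygosity is bounded below, so its left tail is lighter than a
  normal under this MAF spectrum. The statistic still ranks heterozygosity
  depressions correctly; its tail P-values are simply not uniform on such
  panels.
* The meta-SS null variance sits slightly above 1 (≈ 1.03–1.05): the iHS
  meta-Z inherits the leptokurtosis of `ln(iHH_A/iHH_D)` on 50-haplotype
  no-LD panels. Bonferroni hits under the null are correspondingly rare but
  not impossible (of order one per several genome scans).
* With an injected sweep, the whole ±L span saturates the component tests
  (iHS P-values underflow the 1e-300 clamp; Rsb's denominator is
  independent local noise), so the genome-minimum combined P always falls
  *inside* the swept span but lands on the exact core marker only in a
  minority of replicates. Localization is to the region, not the base pair
  — matching how such scans are read in practice (peaks, then annotation).

## Numerical choices and edge cases

* `p_to_z()` clamps P-values to [1e-300, 1 − eps/2] with a warning; the
  upper clamp is bounded by double precision.
* Degenerate standardizations (zero SD) raise errors for Rsb/ΔDAF/SHp
  (identical populations, constant heterozygosity); iHS bins with fewer
  than two scored markers yield missing scores. "20 equally sized bins" is
  read as equal-*width* 0.05 DAF bins; equal-count binning is available via
  `binning = "count"` since the phrase is ambiguous in the literature.
* Markers with DAF 0 or 1 in a population (no carriers of one allele) get a
  missing iHS and are excluded from binning.
* Gene intervals are stored 0-based half-open; a marker at 1-based position
  p is inside a gene iff `start ≤ p − 1 < end`, so the first base is a hit
  and the base past the end is not — bit-exact with BED-tool conventions.
  Closest-gene ties break to the lower start coordinate, then the smaller
  id; distances are signed (negative = gene upstream of the marker).
* Peak clustering is single-linkage with a 500 kb gap, and LD windows add a
  100 kb flank (floored at position 1); with these defaults the windows come
  out on the few-hundred-kb scale typical of array-based sweep scans. Both
  knobs are arguments and config keys.

## Problem sizes used by the tests

The suite runs the full pipeline at 2 × 50 haplotypes × 20,000 markers (the
generator's defaults) for calibration and sweep-recovery checks — 20 seeded
sweep replicates and 5 neutral replicates — and verifies the EHH and HWE
kernels against brute-force oracles on hundreds of small random panels
(≤ 20 haplotypes × 50 markers; tables with n ≤ 200). These sizes were
chosen so that every stochastic property is measured at a scale where its
sampling error is far below the asserted band.

## Limitations

* Phasing and imputation are out of scope: scan stages require complete
  phased input and fail loudly otherwise.
* The generator is a test harness, not a population-genetics simulator; no
  demographic realism is claimed. A coalescent backend (e.g. msprime
  export → VCF → `read_vcf()`) can be plugged in through the standard
  formats.
* Only Bonferroni thresholding is provided; the composite is a frequentist
  meta-analysis, not a likelihood-based composite (CMS-style methods are a
  different design point).
* Functional-term enrichment and network analyses downstream of the three
  annotation strategies are external-database work and are not reimplemented.
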