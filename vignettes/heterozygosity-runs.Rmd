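---
title: "Detecting runs of heterozygosity, mapping islands, and testing trait associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of heterozygosity, mapping islands, and testing trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Runs of heterozygosity (ROHet) are contiguous genomic segments in which
nearly every SNP genotype of an individual is heterozygous. They are the
mirror image of the much more widely studied runs of homozygosity (ROH):
where ROH mark autozygosity and inbreeding, heterozygosity-rich regions
mark hypervariable segments, possible balancing selection, and loci where
heterozygote genotypes may confer a fitness or production advantage. In
livestock populations genotyped on medium-density arrays (a 50K porcine
chip, of which roughly 39-40k autosomal SNPs survive quality control over
a 2.45 Gb autosomal genome), three questions follow naturally:

1. Where are an individual's ROHet, and how much of the genome do they
   cover (`fROHet`)?
2. Which genomic regions are heterozygosity-rich at the population level
   (ROHet *islands*)?
3. Do shared heterozygous regions associate with quantitative production
   traits?

`rohet` implements this pipeline end to end — quality control, consecutive
run detection, summaries, island mapping, and a fixed-effects
presence/absence association scan — together with a synthetic-data
generator that plants known heterozygosity-rich regions and region-linked
trait effects so every stage can be validated against ground truth.

## Quality control

SNPs are removed, in this order of attribution, when

* call rate < 90% (`call_rate_min = 0.90`),
* minor allele frequency < 5% (`maf_min = 0.05`),
* the exact Hardy-Weinberg test gives p < 1e-6 (`hwe_alpha = 1e-6`),
* the SNP is not autosomal (`autosome_max = 18` for *Sus scrofa*;
  non-numeric chromosome labels such as X, Y, MT and unplaced contigs are
  non-autosomal).

A SNP failing several rules is counted once, under the first rule it
fails; the removal report always sums to the input SNP count. The HWE
test form is the Wigginton-style exact test conditional on allele counts
(PLINK's default for `--hwe`), evaluated in closed form with
log-factorials over all heterozygote counts of the correct parity; a
1-df chi-square alternative is available via `hwe_test = "chisq"`.

Two deliberate choices:

* **Missing genotypes.** Imputation is out of scope. The pipeline runs on
  data with missing calls — a missing call simply interrupts run
  detection under the `max_missing` rule — and an optional per-SNP
  modal-genotype fill (`fill_modal_genotype()`) is provided but off by
  default.
* **HWE on simulated data.** The synthetic analyses disable the HWE rule
  (`hwe_alpha = 0`). The exact test exists to catch genotyping artifacts,
  which the generator does not model; what the generator *does* produce —
  planted segments where a large carrier fraction is near-uniformly
  heterozygous — is true biological structure that a strict HWE screen at
  realistic sample sizes would remove. Real-data defaults keep the filter
  at 1e-6.

## Run detection: the consecutive strategy

Runs are detected by scanning SNPs in map order, per individual and
chromosome, without sliding windows. The default parameters are the
standard ROHet settings for this array density:

| parameter        | default | meaning                                   |
|------------------|---------|-------------------------------------------|
| `min_length_bp`  | 1 Mb    | minimum `end_bp - start_bp`               |
| `min_snp`        | 15      | minimum SNPs spanned (target + opposite)  |
| `max_gap_bp`     | 1 Mb    | largest tolerated inter-SNP gap           |
| `max_opposite`   | 1       | opposite-genotype SNPs allowed inside     |
| `max_missing`    | 0       | missing calls allowed inside              |
| `target_state`   | `"HET"` | `"HOM"` flips the engine to ROH detection |

The engine works with a precise window definition: a window of
map-consecutive SNPs *qualifies* when its two endpoints carry the target
state, it contains at most `max_opposite` opposite and `max_missing`
missing calls, no internal gap exceeds `max_gap_bp`, and it meets the
size minima. Scanning emits, left to right, the qualifying window with
the smallest start and largest end, then resumes after its end.

Consequences of this definition, each enforced by tests:

* runs never begin or end on an opposite or missing SNP (candidates are
  trimmed to target-state endpoints, so reported lengths are not inflated
  by non-heterozygous flanks);
* runs of one individual on one chromosome are non-overlapping and
  sorted. With `max_opposite >= 1`, *maximal* qualifying windows can
  overlap (two windows sharing a stretch but each excluding a different
  opposite SNP); the left-to-right greedy emission resolves these in
  favour of the earliest, longest window. We chose this over emitting all
  maximal windows because overlapping runs would double-count coverage in
  `fROHet` and per-SNP incidence;
* `n_snp` counts every SNP spanned, opposite ones included, and
  `length_bp = end_bp - start_bp` (the convention of the established run
  detection tools, and the length used by the 1-2 Mb class boundary).

The gap rule is stated ambiguously in common usage ("maximum gap between
consecutive heterozygous SNPs"): when an opposite SNP sits between two
heterozygotes, the gap can be measured between all consecutive map
positions or only heterozygote-to-heterozygote. Both are implemented
(`gap_scope = "all"` or `"target"`); the default `"all"` constrains every
consecutive pair inside the run's span, which keeps the rule independent
of the genotype sequence.

Correctness is established against `brute_force_runs()`, an independent
oracle that enumerates every window, checks each constraint directly, and
applies the same greedy selection. The two implementations agree on 1,000
random small chromosomes crossed with random parameter draws (the
acceptance suite) — the scanning algorithm computes candidate windows
from blocker positions (opposite/missing SNPs) with `findInterval`
arithmetic, a completely different route from the oracle's enumeration.

## Summaries

* `fROHet = L_ROHet / L_gen`, an individual's summed run length divided by
  the autosome length. `L_gen` defaults to the sum of per-chromosome map
  spans, and can be overridden with a fixed assembly length (2.45e9 for
  the pig autosomes) for comparability with published values; reports
  state which denominator was used.
* Length classes `[1,2)`, `[2,4)`, `[4,Inf)` Mb. The class bounds are
  half-open so each run lands in exactly one class; labels following the
  usual "1-2 / 2-4 / >4 Mb" presentation do not state the boundary
  assignment, and half-open intervals are the assignment under which
  counts partition the total.
* Per-chromosome counts and coverage, with Pearson correlations (t-test,
  n-2 df) against chromosome length via `stats::cor.test`.

## Islands

The per-SNP *incidence* is the fraction of individuals whose run covers
the SNP's position (closed interval, same chromosome). Because one
individual's runs never overlap, interval stabbing counts individuals
exactly once.

The island threshold is the empirical `1 - top_fraction` quantile
(type 1, inverse CDF — no interpolation, so the threshold is always an
observed incidence) of all per-SNP incidences, default `top_fraction =
0.01`. Membership is `incidence >= threshold`: ties at the threshold are
all included, reading "top 1% of occurrence" as a set rather than an
exact count. A constant track makes every SNP a member; this degenerate
case warns rather than fails. Consecutive member SNPs separated by at
most `max_gap_bp` (default 1 Mb, matching the detection gap) merge into
an island; islands need at least 2 member SNPs, and isolated
above-threshold SNPs are reported separately as singletons rather than
as "regions".

Island sets of two populations are compared by symmetric interval
intersection (GenomicRanges). When islands are compared against planted
truth, the comparison uses the planted region's *SNP footprint* — the
positions of the first and last mapped SNP inside the interval — because
island bounds are SNP positions and the nominal planted interval can
extend beyond the first mapped SNP by up to one inter-SNP spacing on
each side.

## Association

Unique regions are distinct `(chromosome, start, end)` triples among all
runs. Carriership (1/0) has two notions:

* `"exact"` — the animal has a run with exactly those coordinates. This
  is the natural notion on imputed array data, where consecutive
  detection on a shared map snaps many animals' runs to identical
  endpoints; it is the function default.
* `"cover"` — the animal has a run fully containing the region. On data
  with stochastic run boundaries (including this package's simulations,
  which do not impute), exact coordinate identity essentially never
  repeats across animals, and coverage is the usable notion of sharing.
  The synthetic analyses therefore use `mode = "cover"`; outputs are
  labelled with the mode used.

Regions with fewer than 20 carriers are dropped ("effective" regions).
Each effective region is tested per trait with ordinary least squares:

    y = farm + birth_year + sex + region_presence + e

with dummy-coded categorical covariates (first sorted level as
reference), per-trait casewise deletion of missing phenotypes, and a
two-sided Wald t-test on the presence coefficient with `n - rank`
degrees of freedom — equivalent, for a single-fixed-effect linear model,
to the Wald test of standard genome-scan software. Covariates with a
single level in the analysed subset (e.g. one farm) are dropped
automatically; a rank-deficient design after that is a hard error.
Degenerate cases are flagged rather than mis-scored: a constant
presence vector skips the region, a constant response returns
`beta = 0, p = 1`, and an exactly collinear response (zero residual
variance with `se = 0`) is flagged `"zero residual variance"`.

The per-trait significance threshold is

    P = FDR * N / M,   FDR = 0.01

with `N` the number of regions at `p < 0.01` in that trait's scan and `M`
all effective regions. Whether `N` should be counted per trait or pooled
across traits is not settled; we compute it per trait-scan, so each
trait's threshold reflects its own signal density. The implementation
clamps the threshold at `FDR` (reached exactly when `N = M`), avoiding a
one-ulp floating-point overshoot of the `P <= FDR` invariant. Regions
significant for two or more traits are flagged pleiotropic; no
genetic-correlation modelling is attached to that flag.

## The synthetic-data generator

`sim_config()` defines the study conditions:

* **Map**: 18 autosomes, 217 SNPs each (~3.9k total) at mean 62.5 kb
  exponential spacing. This is the density of the post-QC 50K array —
  density, not genome size, is what drives run detection (15 SNPs at
  62.5 kb spacing ~ 0.94 Mb, right at the 1 Mb minimum), so the genome is
  scaled to ~1/10 size while keeping the SNP spacing realistic.
* **Background genotypes**: per-SNP independent draws in Hardy-Weinberg
  proportions at the allele frequency implied by `baseline_het = 0.30`
  (`2q(1-q) = 0.30`, so `q ~ 0.18` and MAF clears the 5% QC floor). At
  this heterozygosity, background stretches of 15 near-consecutive
  heterozygotes are vanishingly rare (~0.3^15 per start), so detected
  runs reflect planted structure.
* **Planted regions**: eight disjoint ~1.2-1.5 Mb segments with carrier
  fractions graded 0.40 down to 0.08 and `within_region_het = 0.95` for
  carriers. A *spectrum* of hotspots is deliberate: with a single planted
  region, 99% of SNPs have incidence ~0 and the top-1% quantile
  degenerates to zero, flagging the whole genome. With ~170 planted SNPs
  out of 3,906, the 99th percentile falls inside the hotspot spectrum and
  the threshold separates strong hotspots from background — mirroring
  real populations, which carry on the order of twenty islands each.
* **Phenotypes**: `y = intercept + farm + year + sex + beta * carrier +
  N(0, sd)` — the same generative form the association stage fits. The
  default trait couples the focal region (carrier fraction 0.40) to an
  ADG-like trait with `beta = 5` against residual SD 1; a second, null
  trait has no region effect and calibrates the false-positive side.
* **Determinism**: `simulate_population()` seeds the RNG once from
  `cfg$seed`; outputs (PED/MAP/phenotypes/truth JSON) are byte-identical
  across runs with the same seed.

What the generator does **not** model, and what that implies: there is no
linkage disequilibrium, no pedigree structure and no genotyping error, so
passing tests demonstrate the correctness of the detection, island and
association machinery on data whose generative process matches the
fitted model — they do not demonstrate robustness to LD-induced
correlation between regions, population stratification, or array
artifacts. Carrier misclassification, however, *is* exercised: with
`within_region_het = 0.95`, a carrier's region contains 1-2 homozygous
calls on average, runs fragment or shrink stochastically, and the
pipeline's association beta is visibly attenuated relative to the
planted effect (detected-carrier contrasts mix misclassified carriers
into the reference group). For this reason the unbiasedness check of the
*estimator* refits over phenotype redraws on the true carrier design,
where the estimate is unbiased by construction, while the end-to-end
pipeline check asserts recovery (island overlap, scan significance) and
reports its attenuated beta as a separate quantity.

## Problem sizes and runtimes

The shipped analyses and checks use populations of 120-500 animals on the
~3.9k-SNP map: large enough that the focal region has >100 carriers and
the island quantile is stable, small enough that the whole test suite
runs in well under a minute and the acceptance script in seconds. The
null-calibration suite uses 2,000 refits at n = 200; the detection
equivalence suite uses 1,000 random chromosomes of up to 40 SNPs (the
enumeration oracle is cubic, so small chromosomes are where exhaustive
checking is feasible).

## Known limitations

* Text PED/MAP only; binary PLINK files and multi-allelic sites are not
  parsed.
* No imputation; missing calls break runs (by default) rather than being
  recovered.
* The association model is fixed-effects OLS; no genomic relationship
  matrix, so relatedness-driven inflation is not controlled.
* Exact-mode region identity is brittle off imputed data (see above);
  cover mode is the supported alternative, not a fix for exact mode.
* `length_bp` and all coordinates are physical (bp); genetic-map (cM)
  lengths are not supported.
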