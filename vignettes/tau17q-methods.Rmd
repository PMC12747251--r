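---
title: "Methods: H1/H2 haplotype analysis at 17q21.31 with tau17q"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: H1/H2 haplotype analysis at 17q21.31 with tau17q}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tau17q)
```

## The scientific problem

The 17q21.31 region containing *MAPT* carries a ~900 kb inversion
polymorphism with two deeply diverged haplotype classes, H1 (direct
orientation, present in all populations) and H2 (inverted, enriched in
European-ancestry populations). H1 is a reproducible risk factor for
Parkinson's disease and other synucleinopathies and tauopathies. Because
the region is one long linkage-disequilibrium block, analyses work at the
level of haplotypes tagged by a handful of SNVs rather than individual
variants. `tau17q` implements that workflow end to end for case/control
cohorts: tag-SNV extraction from VCF, H1/H2 diplotype and subhaplotype
classification, frequency/HWE/association/age-at-onset statistics,
additive-model power, and tree-ensemble ranking of subhaplotypes — plus a
synthetic cohort generator so the whole pipeline is testable without
access-controlled consortium data.

## Tag panel and haplotype calling

The fixed panel (`tag_panel()`) carries nine chr17 SNVs (GRCh38):

* **rs1052553** (A>G): the H2-tagging SNV. A/A is H1/H1, A/G is H1/H2,
  G/G is H2/H2 (`call_diplotype`). Samples missing this genotype are
  excluded by `filter_cohort`, alongside a user-supplied related-sample
  exclusion list (relatedness inference itself is upstream of this
  package).
* **six subhaplotype tags** in panel order rs1467967, rs242557,
  rs3785883, rs2471738, rs8070723, rs7521. Their 0/1 (REF/ALT) patterns
  index a nomenclature table mapping patterns to named subhaplotypes
  (H1b, H1c, ..., H2a).
* **rs199451** and **rs199533**, which together with rs1052553 confirm an
  H2 haplotype: a haplotype is accepted as H2 only when all three carry
  the H2-associated allele (`classify_h2_subtype`). Confirmed H2
  haplotypes are then matched against configurable requirement sets to
  separate the CNV-defined H2 subtypes (H2D vs H2′).

VCF sites are matched by chromosome and position with an orientation
check; swapped REF/ALT records are flipped onto panel orientation, and
records compatible with neither orientation are rejected rather than
silently strand-flipped. rsIDs in the VCF are advisory only, since they
are commonly absent after imputation.

Two subhaplotype assignment modes are provided, and reported separately:

* **phased** (`assign_subhaplotypes_phased`): each haplotype's six-allele
  vector is looked up directly;
* **collapsed** (`collapse_unphased`): genotypes are coded 0/1/2 and
  heterozygous sites collapsed to the alternate allele, giving one
  presence vector — and hence one label — per sample. This reproduces the
  per-sample encoding commonly used to feed haplotype labels into
  machine-learning tooling, at the cost of merging the two haplotypes of
  compound heterozygotes (the union pattern may be unnamed even when both
  haplotypes are named).

Patterns not in the table get cohort-relative labels `US1`, `US2`, ...
("unspecified subhaplotype"), numbered by descending cohort frequency
with lexicographic tie-breaks. The numbering is deterministic for a given
cohort but *not* transferable between cohorts; output consumers should
treat US labels as cohort-local. Haplotypes or samples with missing or
unphased tag sites are dropped from denominators, never imputed.

### The nomenclature table is data, not code

Published SNV-based subhaplotype nomenclatures are defined in primary
literature tables that this package cannot redistribute verbatim; the
default table shipped in `inst/extdata/nomenclature_default.yaml` is a
package-curated approximation, clearly marked as such in the file, and is
intended to be reviewed or replaced for production analyses. The same
holds for the default H2D/H2′ requirement sets, which in the shipped file
key on a panel SNV purely so the classifier surface is exercised; the
published discriminating SNVs live outside the tag panel. Every pipeline
run logs the md5 checksum of the table file it used
(`nomenclature_checksum`), so results are always traceable to an exact
table.

## Statistics

* **Frequencies** (`haplotype_frequencies`): H1/H2 allele, diplotype and
  subhaplotype frequencies per group and status, over non-missing
  denominators, with per-cell denominators reported.
* **HWE** (`hwe_exact_test`): the exact conditional test — the p-value is
  the summed probability of all heterozygote counts no more probable than
  the observed one given the allele counts; no mid-p correction. The
  pipeline computes it in controls only, per group. The test suite checks
  the recurrence implementation against an independent full-enumeration
  oracle to 1e-12 for totals up to 200. Note the p-values are discrete
  and slightly conservative, as exact conditional tests are.
* **Allelic association** (`allelic_association`): 2×2 allele-count odds
  ratio with Wald 95% CI on the log OR and the 1-df chi-square p-value
  (the PLINK `--assoc` convention); a Fisher exact p is available behind
  a flag for small cells. Zero cells get the Haldane–Anscombe +0.5
  correction, flagged in the output.
* **Logistic association** (`logistic_association`): maximum-likelihood
  fit (IRLS via `glm`) of status on the additive H1 allele count with
  covariate sets `none`, `sex + PC1–5`, or `sex + age + PC1–5`, and
  complete-case handling with reported per-arm n. Apparent separation
  (|beta| > 15) or non-convergence yields a flagged row with no estimate
  rather than a silently unstable one.
* **Age at onset** (`aao_analysis`): Mann–Whitney U (midranks,
  tie-corrected variance; exact enumeration when both carrier groups have
  ≤ 8 cases and no ties) comparing H1/H1 homozygotes against H2 carriers,
  plus a linear regression of AAO on H1 allele count adjusted for sex and
  PC1–5. Negative beta means earlier onset per H1 allele.
* **Multiple testing** (`bonferroni_threshold`): alpha/m, with the test
  counts (e.g. 11 group-level tests, 33 subhaplotype tests) taken from
  configuration, not hardcoded.

## Power model

`power_additive` reproduces the standard genetic-association (CaTS-style)
power computation: penetrances f0, f1, f2 are solved from the disease
prevalence under HWE weights, expected genotype frequencies in cases and
controls follow by Bayes' rule, and power is the non-central chi-square
tail of the 1-df trend test. Two risk-scale parameterizations are
exposed: *additive* (f2 = f0(2r − 1), the default) and *multiplicative*
(f2 = f0 r²). `required_n` inverts the calculation by bisection.

Two modelling choices deserve explanation:

* **Which allele is "the" risk allele.** For a protective minor allele
  (here H2) the same locus can be parameterized by the minor allele
  (frequency = MAF, per-allele GRR r) or the major allele (frequency
  1 − MAF, GRR 1/r or r depending on convention). The package defaults to
  modelling the minor-allele frequency directly with the quoted OR as the
  GRR, because that formulation reproduces the published design forecast
  for the low-MAF scenario (prevalence 0.5%, MAF 2.1%, OR 1.32, alpha
  0.05, 1:1 design → 4,358 cases for 80% power, i.e. the printed ~4,360),
  whereas the major-allele formulation gives ≈ 8,850. Both are available
  via an explicit switch.
* **The parameterizations are not symmetric.** Under the additive risk
  scale the minor- and major-allele formulations genuinely diverge at
  extreme frequencies; `power_symmetry_check` computes both powers and
  warns when they differ by more than one percentage point, so the
  discrepancy is surfaced rather than hidden. Under the multiplicative
  scale the two nearly coincide.

The OR→GRR identification (treating 1.32 as the per-allele GRR) is the
usual rare-disease approximation and is accurate at prevalence 0.5%.

## Feature ranking

`one_hot` converts per-sample collapsed labels to exclusive binary
indicators; `rank_gini` fits an ensemble of extremely randomized
classification trees (delegated to `ranger` with
`splitrule = "extratrees"`, one random threshold per candidate feature,
Gini impurity) and reports each subhaplotype's normalized total
Gini-impurity reduction, i.e. Gini importance, ordered and summing to 1.
Defaults — 500 trees, unlimited depth, all features candidate at every
split (the feature count is small), single thread, seeded — are recorded
in the output attributes since rankings are only meaningful given their
settings. Same seed and input give a bit-identical ranking.

Because the collapsed encoding merges haplotypes, a planted H2 effect is
carried by the H2-pattern feature only when most H2 carriers collapse
onto that label, which requires the all-reference H1 background pattern
to be common; in cohorts with highly polymorphic H1 backgrounds the H2
signal spreads across union (US) labels. The ranking recovery test
therefore simulates an EUR-like spectrum with a dominant all-reference H1
background, and sizes the cohort (3,000 cases / 1,500 controls at the
EUR-scale OR 1.35) so the planted feature's expected association signal
clearly dominates chance associations of noise features.

## The synthetic cohort generator

`simulate_cohort` draws control haplotypes i.i.d. from the profile's
subhaplotype spectrum (HWE by construction) and case haplotypes from the
tilted distribution ∝ freq × OR^[H1-class] — the exact case distribution
induced by a multiplicative per-H1-allele odds model under retrospective
sampling, which factorizes over haplotypes and makes expected case
frequencies analytic (e.g. a control H2 frequency of 25% with OR 1.254
gives exactly 21% in cases). Genotypes derive deterministically from the
haplotype labels; genotype missingness, sex, age (with a plantable
per-H1-allele age-at-onset shift and missing-at-random ages) and five
Gaussian PCs are layered on top from fixed-offset RNG sub-streams, so
changing covariate settings never perturbs genotype draws. Cohorts
serialize to plain-text phased VCF v4.2 plus a metadata TSV that the
package's own readers ingest, and same-seed runs are byte-identical.

What the generator deliberately does **not** emulate: LD decay and
recombination within the tag panel (haplotypes are drawn as intact
labels), imputation uncertainty, genotyping batch effects, population
admixture within a group, and any correlation between PCs and genotype.
Passing recovery tests on these cohorts therefore demonstrates the
statistical machinery is correct under its stated model, not that real
cohorts satisfy that model. Preset profiles (`preset_profiles`) emulate
EUR-, AJ-, AFR- and EAS-like groups with approximate published
frequencies (e.g. control H2 at 25% in the AJ-like profile, 2.1% in the
AFR-like one) and the published sample sizes; the frequency vectors are
approximations for calibration, not transcriptions.

## Pipeline

`run_pipeline` executes, per group and strictly independently (no pooled
fits): filtering → diplotype/subhaplotype calling → frequencies → HWE in
controls → allelic + adjusted logistic association → AAO analyses →
Bonferroni flags → optional Gini ranking, then writes TSV tables, a
sample-accounting log in which every input sample appears exactly once
(analyzed or excluded with a reason), and a JSON run log with the package
version, configuration and nomenclature checksum. A failing group is
recorded and does not stop the others. Reruns with identical inputs and
seeds reproduce the bundle byte for byte (the run log intentionally
carries no timestamps). Plot helpers (`plot_frequencies`, `plot_forest`)
are presentation-only.

A thin command-line wrapper (`inst/cli/tau17q.R`) exposes `simulate`,
`power` and `run` subcommands over these functions for shell use.

## Numerical choices and test scales

* Wald CIs everywhere (matching common GWAS tooling); no
  profile-likelihood option.
* Logistic convergence is `glm`'s IRLS default; separation is declared at
  |beta| > 15.
* HWE recurrence is computed in log space and normalized at the end; the
  observed-probability comparison uses a 1e-12 relative guard against
  floating-point ties.
* `required_n` brackets by doubling, then bisects on the integer lattice;
  `power = alpha` exactly at GRR 1.
* Test problem sizes were chosen to make each property decisive yet quick:
  10,000 null replicates for type-I error, 20,000 Monte-Carlo draws for
  power cross-checks, 4,000/4,000 samples for OR recovery, 100 ranking
  seeds on a 4,500-sample cohort, 200-seed exchangeability checks for
  noise importances, and full enumeration up to genotype totals of 200
  for the HWE oracle.

## Known limitations

* Hard GT calls only: no dosage/genotype-probability handling, no
  statistical phasing; unphased data must go through the collapsed mode.
* The default nomenclature and H2-subtype rules are curated
  approximations (see above) and must be reviewed before scientific use.
* US labels are cohort-relative; cross-cohort comparisons must go through
  patterns, not US numbers.
* No meta-analysis, mixed models, CNV-based H1 subtyping, or genome-wide
  scanning; the package is scoped to the tag-SNV haplotype workflow.
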