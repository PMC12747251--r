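# tau17q

Case/control analysis of the chromosome 17q21.31 inversion polymorphism
containing *MAPT*, for statistical geneticists working on Parkinson's
disease and related tauopathies/synucleinopathies.

The locus is one ~1.8 Mb linkage-disequilibrium block with two deeply
diverged haplotype classes — H1 (direct orientation, universal) and H2
(inverted, enriched in European-ancestry populations) — so analyses work
on tag-SNV-defined haplotypes rather than single variants. `tau17q`
covers that workflow end to end:

- **Genotype I/O** — tag-SNV extraction from VCF v4.2 (chrom+pos matching
  with REF/ALT orientation checks and allele flipping), metadata TSV
  reading, and cohort filters (related-sample exclusion list; missing
  rs1052553 genotype).
- **Haplotype calling** — H1/H2 diplotypes from rs1052553 (A/A = H1/H1,
  A/G = H1/H2, G/G = H2/H2); subhaplotypes from the six-SNV pattern
  (rs1467967, rs242557, rs3785883, rs2471738, rs8070723, rs7521) via a
  configurable nomenclature table, in phased and unphased-collapsed
  modes; H2 subtype classification under the three-SNV confirmation rule
  (rs1052553 + rs199451 + rs199533).
- **Statistics** — frequency tables with denominators; exact conditional
  Hardy–Weinberg test; allelic 2×2 odds ratio (Wald CI, 1-df chi-square)
  OR<sub>allelic</sub> = (a₁d₂)/(a₂d₁); covariate-adjusted logistic
  regression on the additive H1 count (complete-case, with sex/age/PC1–5
  sets); Mann–Whitney and adjusted linear regression for age at onset;
  Bonferroni thresholds α/m.
- **Power** — CaTS-style additive-model power of the 1-df trend test from
  penetrances constrained by prevalence (f1 = f0·r, f2 = f0(2r−1),
  Σ gᵢfᵢ = K), and required-N inversion.
- **Feature ranking** — one-hot subhaplotype indicators ranked by Gini
  importance from an extremely-randomized-trees ensemble (deterministic
  given a seed; importances sum to 1).
- **Synthetic cohorts** — a generator planting a per-H1-allele odds ratio
  into group-specific subhaplotype spectra (HWE by construction), with
  genotype missingness, covariates and missing ages, emitted as phased
  VCF + metadata TSV that the package's own readers round-trip.

## Worked example

Simulate an AJ-like cohort (control H2 frequency 25%, planted per-H1
odds ratio 1.254, 1,225 cases / 384 controls) and run the full pipeline:

```r
library(tau17q)
prof   <- preset_profiles(seed = 7)$AJ
paths  <- write_sim_cohort(simulate_cohort(prof), "aj_demo")
res    <- run_pipeline(list(vcf = paths[["vcf"]], metadata = paths[["metadata"]],
                            out_dir = "aj_demo/out", seed = 7))

subset(res$frequencies, metric == "allele" & category == "H2")
#>  group  status metric category count denom      freq
#>     AJ    case allele       H2   516  2438 0.2116489
#>     AJ control allele       H2   210   766 0.2741514
```

The H2 allele is rarer in cases (21.2%) than controls (27.4%), as
expected when H1 carries risk; the denominators are allele counts after
removing samples with missing rs1052553 calls.

```r
subset(res$association, model %in% c("allelic_chisq", "logistic_sex_pc"))[, 1:8]
#>  group           model       or   ci_low  ci_high            p n_cases n_controls
#>     AJ   allelic_chisq 1.406851 1.167913 1.694672 0.0003126426    1219        383
#>     AJ logistic_sex_pc 1.448593 1.193312 1.758485 0.0001790790    1219        383

res$hwe
#>  group      rsid n_homref n_het n_homalt         p
#>     AJ rs1052553      199   158       26 0.5226376
```

The allelic odds ratio on H1 (1.41, 95% CI 1.17–1.69) recovers the
planted effect within sampling error, the sex+PC-adjusted logistic model
agrees with it (as it must when covariates are independent of genotype),
and controls are compatible with Hardy–Weinberg equilibrium (exact
p = 0.52).

Design forecast for a low-frequency-H2 group (prevalence 0.5%, minor
allele frequency 2.1%, odds ratio 1.32, α = 0.05, 80% power, 1:1 design):

```r
required_n(K = 0.005, p = 0.021, grr = 1.32, alpha = 0.05, target_power = 0.8)
#> [1] 4358
```

i.e. roughly 4,360 cases and as many controls.

## Caveats

The default subhaplotype nomenclature
(`inst/extdata/nomenclature_default.yaml`) is a package-curated
approximation of the published SNV-based tables and is meant to be
reviewed or replaced for production use; every pipeline run logs the
checksum of the table it used. `US<k>` labels are cohort-relative.
See the methods vignette (`vignettes/tau17q-methods.Rmd`) for the models,
assumptions and numerical choices.
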