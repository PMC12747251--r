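test_that("subhap_to_alleles inverts the nomenclature lookup for every named label", {
  nom <- read_nomenclature()
  panel <- tag_panel()
  labs <- rownames(nom$patterns)
  n <- length(labs)
  a1 <- t(vapply(labs, subhap_to_alleles, integer(nrow(panel)),
                 nom = nom, panel = panel))
  rownames(a1) <- sprintf("L%02d", seq_len(n))
  g <- structure(list(samples = rownames(a1), panel = panel, a1 = a1,
                      a2 = a1,
                      phased = matrix(TRUE, n, nrow(panel),
                                      dimnames = dimnames(a1))),
                 class = "geno_matrix")
  calls <- assign_subhaplotypes_phased(g, nom)
  got <- calls$label[calls$hap == 1L]
  expect_equal(got[match(rownames(a1), calls$id[calls$hap == 1L])], labs)
  # H2-class labels carry the ALT allele at all three confirming SNVs
  for (lab in labs[nom$class == "H2"]) {
    v <- subhap_to_alleles(lab, nom, panel)
    expect_true(all(v[h2_confirm_rsids()] == 1L))
  }
  for (lab in labs[nom$class == "H1"]) {
    v <- subhap_to_alleles(lab, nom, panel)
    expect_equal(unname(v["rs1052553"]), 0L)
  }
  expect_error(subhap_to_alleles("US3", nom), "not an invertible")
})

test_that("a null planted effect gives equal case/control H1 frequencies", {
  nom <- small_nom()
  pr <- sim_profile("T", c(H1a = 0.5, H1b = 0.3, H2a = 0.2), h1_or = 1,
                    n_cases = 1500, n_controls = 1500,
                    missing_geno_rate = 0, seed = 121)
  co <- simulate_cohort(pr, nom)
  dip <- diplotypes(co$genotypes)
  st <- co$metadata$status == "case"
  h1 <- h1_counts(dip)
  f_case <- sum(h1[st]) / (2 * sum(st))
  f_ctrl <- sum(h1[!st]) / (2 * sum(!st))
  se <- sqrt(0.8 * 0.2 * (1 / (2 * sum(st)) + 1 / (2 * sum(!st))))
  expect_lt(abs(f_case - f_ctrl), 3 * se)
})

test_that("an AJ-like profile reproduces the 21.0%/25.0% case/control H2 frequencies", {
  nom <- read_nomenclature()
  pp <- preset_profiles(seed = 131)$AJ
  # expected case H2 frequency under the tilted haplotype distribution:
  # 0.25 / (0.25 + 0.75 * 1.254) = 0.21
  co <- simulate_cohort(pp, nom)
  dip <- diplotypes(co$genotypes)
  st <- co$metadata$status == "case"
  ok <- dip != "MISSING"
  h2_case <- sum(2 - h1_counts(dip)[ok & st]) / (2 * sum(ok & st))
  h2_ctrl <- sum(2 - h1_counts(dip)[ok & !st]) / (2 * sum(ok & !st))
  se_case <- sqrt(0.21 * 0.79 / (2 * sum(ok & st)))
  se_ctrl <- sqrt(0.25 * 0.75 / (2 * sum(ok & !st)))
  expect_lt(abs(h2_case - 0.210), 3 * se_case)
  expect_lt(abs(h2_ctrl - 0.250), 3 * se_ctrl)
})

test_that("same-seed simulations serialize byte-identically; different seeds differ", {
  nom <- small_nom()
  f <- c(H1a = 0.5, H1b = 0.3, H2a = 0.2)
  pr <- sim_profile("T", f, h1_or = 1.3, n_cases = 120, n_controls = 120,
                    missing_geno_rate = 0.02, seed = 141)
  d1 <- write_sim_cohort(simulate_cohort(pr, nom), tempfile())
  d2 <- write_sim_cohort(simulate_cohort(pr, nom), tempfile())
  expect_identical(readLines(d1["vcf"]), readLines(d2["vcf"]))
  expect_identical(readLines(d1["metadata"]), readLines(d2["metadata"]))
  pr3 <- sim_profile("T", f, h1_or = 1.3, n_cases = 120, n_controls = 120,
                     missing_geno_rate = 0.02, seed = 142)
  d3 <- write_sim_cohort(simulate_cohort(pr3, nom), tempfile())
  expect_false(identical(readLines(d1["vcf"]), readLines(d3["vcf"])))
})

test_that("written cohorts round-trip exactly through the VCF/TSV readers", {
  nom <- read_nomenclature()
  pr <- sim_profile("T", c(H1a = 0.4, H1b = 0.3, H1c = 0.1, H2a = 0.2),
                    h1_or = 1.4, n_cases = 80, n_controls = 80,
                    missing_geno_rate = 0.05, age_missing_rate = 0.3,
                    seed = 151)
  co <- simulate_cohort(pr, nom)
  paths <- write_sim_cohort(co, tempfile())
  g <- load_tag_genotypes(paths["vcf"])
  expect_identical(g$a1, co$genotypes$a1)
  expect_identical(g$a2, co$genotypes$a2)
  expect_identical(g$phased, co$genotypes$phased)
  m <- load_metadata(paths["metadata"])
  expect_equal(m$id, co$metadata$id)
  expect_equal(m$age, co$metadata$age)
  expect_equal(m$status, co$metadata$status)
})

test_that("genotypes derive deterministically from the true haplotypes", {
  nom <- small_nom()
  pr <- sim_profile("T", c(H1a = 0.5, H1b = 0.3, H2a = 0.2), h1_or = 1.2,
                    n_cases = 100, n_controls = 100,
                    missing_geno_rate = 0, seed = 161)
  co <- simulate_cohort(pr, nom)
  panel <- tag_panel()
  for (i in sample(nrow(co$true_haplotypes), 20)) {
    expect_equal(unname(co$genotypes$a1[i, ]),
                 unname(subhap_to_alleles(co$true_haplotypes[i, 1], nom,
                                          panel)))
    expect_equal(unname(co$genotypes$a2[i, ]),
                 unname(subhap_to_alleles(co$true_haplotypes[i, 2], nom,
                                          panel)))
  }
})

test_that("control genotypes at rs1052553 are HWE-distributed across replicate seeds", {
  nom <- small_nom()
  pv <- vapply(1:150, function(s) {
    pr <- sim_profile("T", c(H1a = 0.5, H1b = 0.2, H2a = 0.3), h1_or = 1.5,
                      n_cases = 10, n_controls = 300,
                      missing_geno_rate = 0, seed = 1000 + s)
    co <- simulate_cohort(pr, nom)
    dip <- diplotypes(co$genotypes)[co$metadata$status == "control"]
    hwe_exact_test(sum(dip == "H1/H1"), sum(dip == "H1/H2"),
                   sum(dip == "H2/H2"))
  }, numeric(1))
  # the exact test is conservative/discrete; require no excess of small p
  expect_lt(mean(pv < 0.05), 0.08)
  expect_gt(mean(pv > 0.5), 0.3)
})

test_that("simulator pipeline round-trip recovers the subhaplotype spectrum", {
  nom <- read_nomenclature()
  f <- c(H1a = 0.25, H1b = 0.25, H1c = 0.2, H1e = 0.1, H2a = 0.2)
  pr <- sim_profile("T", f, h1_or = 1, n_cases = 1000, n_controls = 1000,
                    missing_geno_rate = 0, seed = 171)
  co <- simulate_cohort(pr, nom)
  ph <- assign_subhaplotypes_phased(co$genotypes, nom)
  n_hap <- sum(!is.na(ph$label))
  for (lab in names(f)) {
    if (f[lab] * n_hap < 10) next
    est <- mean(ph$label == lab)
    se <- sqrt(f[lab] * (1 - f[lab]) / n_hap)
    expect_lt(abs(est - f[lab]), 3 * se)
  }
})

test_that("profile validation rejects malformed inputs", {
  expect_error(sim_profile("X", c(H1a = 0.6, H2a = 0.5)), "sum to 1")
  expect_error(sim_profile("X", c(0.5, 0.5)), "named")
  expect_error(sim_profile("X", c(H1a = 1), h1_or = -1))
  nom <- small_nom()
  pr <- sim_profile("X", c(H1a = 0.5, H1zz = 0.5), seed = 1)
  expect_error(simulate_cohort(pr, nom), "absent from the nomenclature")
})
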