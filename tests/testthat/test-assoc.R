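test_that("frequency tables reproduce designed cohort frequencies with correct denominators", {
  # AJ-like fixture built to carry H2 at exactly 21.0% in cases, 25.0% in
  # controls: 1000 cases with 420/2000 H2 alleles, 500 controls with 250/1000
  dip_case <- rep(c("H1/H1", "H1/H2", "H2/H2"), c(590, 400, 10))
  dip_ctrl <- rep(c("H1/H1", "H1/H2", "H2/H2"), c(275, 200, 25))
  dip <- factor(c(dip_case, dip_ctrl),
                levels = c("H1/H1", "H1/H2", "H2/H2", "MISSING"))
  names(dip) <- sprintf("S%04d", seq_along(dip))
  meta <- data.frame(id = names(dip),
                     status = rep(c("case", "control"), c(1000, 500)),
                     group = "AJ", stringsAsFactors = FALSE)
  fr <- haplotype_frequencies(dip, meta)
  h2 <- fr[fr$metric == "allele" & fr$category == "H2", ]
  expect_equal(h2$freq[h2$status == "case"], 0.210)
  expect_equal(h2$freq[h2$status == "control"], 0.250)
  expect_equal(h2$denom, c(2000, 1000))
  # H1 + H2 frequencies sum to 1 per stratum
  al <- fr[fr$metric == "allele", ]
  expect_equal(as.numeric(tapply(al$freq, paste(al$group, al$status), sum)),
               c(1, 1))
  # all-H1/H1 cohort has H2 frequency zero
  dip0 <- factor(rep("H1/H1", 10),
                 levels = c("H1/H1", "H1/H2", "H2/H2", "MISSING"))
  names(dip0) <- paste0("T", 1:10)
  fr0 <- suppressWarnings(haplotype_frequencies(
    dip0, data.frame(id = names(dip0), status = "control", group = NA)))
  expect_equal(fr0$freq[fr0$metric == "allele" & fr0$category == "H2"], 0)
})

test_that("simulated cohort frequencies land within 3 binomial SEs of the generative values", {
  nom <- small_nom()
  f <- c(H1a = 0.5, H1b = 0.3, H2a = 0.2)
  pr <- sim_profile("T", f, h1_or = 1, n_cases = 800, n_controls = 800,
                    missing_geno_rate = 0, seed = 31)
  co <- simulate_cohort(pr, nom)
  dip <- diplotypes(co$genotypes)
  fr <- haplotype_frequencies(dip, co$metadata)
  h2 <- fr[fr$metric == "allele" & fr$category == "H2", ]
  se <- sqrt(0.2 * 0.8 / 1600)
  expect_true(all(abs(h2$freq - 0.2) < 3 * se))
})

test_that("frequency-table comparison reports percentage-point differences over the category union", {
  a <- c(A = 0.50, B = 0.50)
  b <- c(A = 0.48, B = 0.52)
  cmp <- compare_frequency_tables(a, b)
  expect_equal(attr(cmp, "max_abs_pp"), 2.0)
  expect_equal(cmp$diff_pp[cmp$category == "A"], 2.0)
  expect_equal(attr(compare_frequency_tables(a, a), "max_abs_pp"), 0)
  # absent categories count as zero
  cmp2 <- compare_frequency_tables(c(A = 1), c(A = 0.9, B = 0.1))
  expect_equal(cmp2$freq_a[cmp2$category == "B"], 0)
  expect_equal(cmp2$abs_diff_pp[cmp2$category == "B"], 10)
})

test_that("HWE exact test matches the enumeration oracle and handles edge cases", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_equal(hwe_exact_test(21, 48, 31), hwe_enum_oracle(21, 48, 31),
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:200, 1)
    cnt <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
})

test_that("HWE p-values are valid and near-uniform under the null", {
  set.seed(7)
  p <- 0.3
  pv <- replicate(1000, {
    gt <- stats::rmultinom(1, 500, c((1 - p)^2, 2 * p * (1 - p), p^2))
    hwe_exact_test(gt[1], gt[2], gt[3])
  })
  # exact conditional p-values are discrete and slightly conservative, so
  # they cannot match continuous uniformity exactly; assert validity
  # (rejection rate never above nominal + MC noise) and rough calibration
  # (never less than half the nominal rate)
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(a * (1 - a) / length(pv))
    expect_lte(mean(pv <= a), a + 3 * se)
    expect_gte(mean(pv <= a), a / 2 - 3 * se)
  }
})

test_that("allelic association has the designed OR algebra", {
  # equal frequencies -> OR 1
  r <- allelic_association(200, 800, 100, 400)
  expect_equal(r$or, 1)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
  # swapping case and control rows inverts the OR, p unchanged
  r1 <- allelic_association(300, 700, 200, 800)
  r2 <- allelic_association(200, 800, 300, 700)
  expect_equal(r1$or, 1 / r2$or)
  expect_equal(r1$p, r2$p)
  # OR invariant to scaling all cells
  r3 <- allelic_association(30, 70, 20, 80)
  expect_equal(r1$or, r3$or)
  # monotone in case_a1
  ors <- vapply(c(250, 300, 350), function(a)
    allelic_association(a, 1000 - a, 200, 800)$or, numeric(1))
  expect_true(all(diff(ors) > 0))
  # zero cell: Haldane correction flagged
  rz <- allelic_association(10, 90, 0, 100)
  expect_equal(rz$flag, "haldane_correction")
  expect_true(is.finite(rz$or))
  # empty stratum flagged undefined
  re <- allelic_association(0, 0, 10, 90)
  expect_equal(re$flag, "undefined_empty_stratum")
})

test_that("allelic test keeps nominal type-I error under the null", {
  set.seed(55)
  reps <- 10000
  na <- 1000
  c1 <- stats::rbinom(reps, na, 0.3)
  t1 <- stats::rbinom(reps, na, 0.3)
  pv <- vapply(seq_len(reps), function(i)
    allelic_association(c1[i], na - c1[i], t1[i], na - t1[i])$p,
    numeric(1))
  err <- mean(pv < 0.05)
  expect_gte(err, 0.04)
  expect_lte(err, 0.06)
})

test_that("logistic association recovers a planted OR and matches the allelic OR under HWE", {
  nom <- small_nom()
  pr <- sim_profile("T", c(H1a = 0.55, H1b = 0.25, H2a = 0.20),
                    h1_or = 1.5, n_cases = 4000, n_controls = 4000,
                    missing_geno_rate = 0, seed = 41)
  co <- simulate_cohort(pr, nom)
  dip <- diplotypes(co$genotypes)
  h1 <- h1_counts(dip)
  fit <- logistic_association(co$metadata, h1, "none")
  se <- (log(fit$ci_high) - log(fit$or)) / 1.96
  expect_lt(abs(log(fit$or) - log(1.5)), 3 * se)
  # unadjusted logistic OR approximates the allelic OR on the same data
  st <- co$metadata$status == "case"
  al <- allelic_association(sum(h1[st]), sum(2 - h1[st]),
                            sum(h1[!st]), sum(2 - h1[!st]))
  expect_lt(abs(log(fit$or) - log(al$or)), 0.05)
})

test_that("logistic Wald CI covers the null at ~95% on null simulations", {
  set.seed(77)
  reps <- 300
  n <- 2000
  cover <- logical(reps)
  meta <- data.frame(status = rep(c("case", "control"), each = n / 2),
                     sex = NA, age = NA, PC1 = NA, PC2 = NA, PC3 = NA,
                     PC4 = NA, PC5 = NA, stringsAsFactors = FALSE)
  for (i in seq_len(reps)) {
    gset <- stats::rbinom(n, 2, 0.8)
    r <- logistic_association(meta, gset, "none")
    cover[i] <- r$ci_low <= 1 && 1 <= r$ci_high
  }
  # 3 binomial SEs around 0.95 at 300 reps
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  expect_lt(mean(cover), 0.95 + 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("complete-case logistic analysis drops samples missing covariates and reports n", {
  set.seed(3)
  n <- 400
  meta <- data.frame(status = rep(c("case", "control"), each = n / 2),
                     sex = sample(c("F", "M"), n, TRUE),
                     age = c(stats::rnorm(n / 2, 60, 8),
                             rep(NA_real_, n / 2)),
                     stringsAsFactors = FALSE)
  for (k in 1:5) meta[[paste0("PC", k)]] <- stats::rnorm(n, 0, 0.02)
  g <- stats::rbinom(n, 2, 0.8)
  r <- logistic_association(meta, g, "sex_age_pc")
  expect_equal(r$n_cases + r$n_controls, sum(!is.na(meta$age)))
  r2 <- logistic_association(meta, g, "sex_pc")
  expect_equal(r2$n_cases + r2$n_controls, n)
})

test_that("separation and degenerate inputs are flagged, not silently estimated", {
  meta <- data.frame(status = rep(c("case", "control"), each = 20),
                     sex = NA, age = NA, PC1 = NA, PC2 = NA, PC3 = NA,
                     PC4 = NA, PC5 = NA, stringsAsFactors = FALSE)
  g_sep <- c(rep(2L, 20), rep(0L, 20))  # perfectly separates the classes
  r <- logistic_association(meta, g_sep, "none")
  expect_true(r$flag %in% c("separation_suspected", "non_convergence"))
  expect_true(is.na(r$or))
  r2 <- logistic_association(meta, rep(1L, 40), "none")
  expect_equal(r2$flag, "undefined_degenerate_input")
})

test_that("age-at-onset analysis recovers a planted per-allele shift", {
  nom <- small_nom()
  pr <- sim_profile("T", c(H1a = 0.5, H1b = 0.3, H2a = 0.2), h1_or = 1,
                    n_cases = 800, n_controls = 100, aao_beta = -3,
                    age_missing_rate = 0, missing_geno_rate = 0, seed = 51)
  co <- simulate_cohort(pr, nom)
  cases <- co$metadata[co$metadata$status == "case", , drop = FALSE]
  h1 <- h1_counts(diplotypes(co$genotypes))[co$metadata$status == "case"]
  r <- aao_analysis(cases, h1)
  expect_lt(abs(r$beta - (-3)), 3 * r$se)
  expect_lt(r$lm_p, 0.05)
  expect_true(r$u_p <= 1 && r$u_p >= 0)
  expect_equal(r$n_h1h1 + r$n_h2carrier, nrow(cases))
})

test_that("age-at-onset analysis is null-calibrated and flags tiny groups", {
  nom <- small_nom()
  pr <- sim_profile("T", c(H1a = 0.5, H1b = 0.3, H2a = 0.2), h1_or = 1,
                    n_cases = 600, n_controls = 100, aao_beta = 0,
                    age_missing_rate = 0, missing_geno_rate = 0, seed = 52)
  co <- simulate_cohort(pr, nom)
  cases <- co$metadata[co$metadata$status == "case", , drop = FALSE]
  h1 <- h1_counts(diplotypes(co$genotypes))[co$metadata$status == "case"]
  r <- aao_analysis(cases, h1)
  expect_lt(abs(r$beta), 3 * r$se)
  # one empty carrier group -> U test skipped with flag
  few <- cases[1:10, , drop = FALSE]
  r2 <- aao_analysis(few, rep(2L, 10))
  expect_true(is.na(r2$u_p))
  expect_equal(r2$flag, "u_test_skipped_small_group")
})

test_that("Bonferroni thresholds follow alpha/m", {
  expect_equal(round(bonferroni_threshold(0.05, 11), 4), 0.0045)
  expect_equal(round(bonferroni_threshold(0.05, 33), 4), 0.0015)
  expect_equal(bonferroni_threshold(0.37, 1), 0.37)
  expect_error(bonferroni_threshold(0.05, 0))
})
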