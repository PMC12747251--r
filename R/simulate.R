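#' Panel alleles carried by a named subhaplotype
#'
#' Inverts the nomenclature lookup: returns the full panel allele vector a
#' haplotype of the given named subhaplotype carries. The six subhap-tag
#' alleles come from the table pattern; the three H2-confirming SNVs
#' (rs1052553, rs199451, rs199533) carry the ALT (H2) allele for H2-class
#' labels and REF otherwise. \code{US} labels and labels absent from the
#' table are not invertible and raise an error.
#'
#' @param label a named subhaplotype label present in the table.
#' @param nom a \code{\link{nomenclature}}.
#' @param panel a \code{\link{tag_panel}}.
#' @return Named integer vector of allele indices over the panel SNVs, in
#'   panel order.
#' @export
#' @examples
#' nom <- read_nomenclature()
#' subhap_to_alleles("H2a", nom)
subhap_to_alleles <- function(label, nom, panel = tag_panel()) {
  if (!label %in% rownames(nom$patterns))
    stop("label '", label, "' is not an invertible named subhaplotype")
  out <- stats::setNames(rep(0L, nrow(panel)), panel$rsid)
  out[colnames(nom$patterns)] <- nom$patterns[label, ]
  if (nom$class[[label]] == "H2")
    out[h2_confirm_rsids()] <- 1L
  out
}

#' Simulation profile for a synthetic case/control cohort
#'
#' Bundles the generative parameters of one ancestry-like group: the
#' control-population subhaplotype frequency spectrum, a planted per-H1-
#' allele odds ratio on case status, sample sizes, genotype missingness,
#' and covariate distributions (sex balance, age with missingness, PC
#' noise). See \code{\link{simulate_cohort}} for the generative model.
#'
#' @param name group label.
#' @param subhap_freqs named numeric vector of control-population
#'   frequencies over named subhaplotypes (must sum to 1).
#' @param h1_or planted per-H1-allele odds ratio on case status (> 0).
#' @param n_cases,n_controls sample counts.
#' @param missing_geno_rate per-site, per-sample genotype missingness
#'   probability.
#' @param sex_balance probability a sample is female.
#' @param age_mean,age_sd age (controls) / age-at-onset (cases) in years.
#' @param aao_beta planted age-at-onset shift in years per H1 allele
#'   (cases only; negative = earlier onset with H1).
#' @param age_missing_rate probability an age is missing.
#' @param pc_sd standard deviation of the five Gaussian PC coordinates.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A list of class \code{sim_profile}.
#' @export
sim_profile <- function(name, subhap_freqs, h1_or = 1, n_cases = 1000L,
                        n_controls = 1000L, missing_geno_rate = 0.005,
                        sex_balance = 0.5, age_mean = 62, age_sd = 10,
                        aao_beta = 0, age_missing_rate = 0.2,
                        pc_sd = 0.02, seed = 1L) {
  stopifnot(h1_or > 0, n_cases >= 1, n_controls >= 1,
            missing_geno_rate >= 0, missing_geno_rate <= 1,
            sex_balance >= 0, sex_balance <= 1,
            age_missing_rate >= 0, age_missing_rate <= 1, pc_sd >= 0)
  if (is.null(names(subhap_freqs)) || any(subhap_freqs < 0))
    stop("subhap_freqs must be a named non-negative vector")
  if (abs(sum(subhap_freqs) - 1) > 1e-8)
    stop("subhap_freqs must sum to 1 (got ", sum(subhap_freqs), ")")
  structure(list(name = name, subhap_freqs = subhap_freqs, h1_or = h1_or,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 missing_geno_rate = missing_geno_rate,
                 sex_balance = sex_balance, age_mean = age_mean,
                 age_sd = age_sd, aao_beta = aao_beta,
                 age_missing_rate = age_missing_rate, pc_sd = pc_sd,
                 seed = as.integer(seed)),
            class = "sim_profile")
}

#' Preset ancestry-like simulation profiles
#'
#' Ready-made profiles loosely emulating the published group-specific
#' subhaplotype spectra (EUR-, AJ-, AFR- and EAS-like): H2 common in the
#' EUR/AJ-like groups (20\%/25\% in controls), rare in the AFR-like group
#' (2.1\%) and nearly absent in the EAS-like group, with group-typical H1
#' spectra (e.g. H1b/H1c dominant in EUR/AJ, H1j enriched in AFR, H1m
#' dominant in EAS). The frequency vectors are approximations for testing
#' and method calibration, not transcriptions of any cohort's exact values.
#'
#' @param seed seed recorded into each profile.
#' @return Named list of \code{\link{sim_profile}} objects.
#' @export
preset_profiles <- function(seed = 1L) {
  f_eur <- c(H2a = 0.200, H1b = 0.180, H1c = 0.130, H1e = 0.080,
             H1h = 0.070, H1d = 0.050, H1i = 0.050, H1l = 0.040,
             H1o = 0.040, H1u = 0.030, H1m = 0.020, H1v = 0.020,
             H1y = 0.020, H1j = 0.011, H1x = 0.010, H1a = 0.049)
  f_aj <- c(H2a = 0.250, H1b = 0.200, H1c = 0.140, H1e = 0.080,
            H1h = 0.060, H1d = 0.040, H1i = 0.040, H1l = 0.030,
            H1o = 0.030, H1u = 0.020, H1m = 0.020, H1j = 0.005,
            H1a = 0.085)
  f_afr <- c(H2a = 0.021, H1j = 0.171, H1m = 0.100, H1e = 0.100,
             H1b = 0.080, H1h = 0.080, H1c = 0.060, H1l = 0.060,
             H1o = 0.050, H1u = 0.050, H1d = 0.040, H1y = 0.040,
             H1i = 0.030, H1x = 0.020, H1a = 0.098)
  f_eas <- c(H2a = 0.004, H1m = 0.300, H1l = 0.150, H1u = 0.100,
             H1i = 0.080, H1e = 0.080, H1h = 0.060, H1o = 0.050,
             H1d = 0.040, H1b = 0.016, H1c = 0.004, H1a = 0.116)
  list(
    EUR = sim_profile("EUR", f_eur, h1_or = 1.35, n_cases = 12992L,
                      n_controls = 5175L, seed = seed),
    AJ = sim_profile("AJ", f_aj, h1_or = 1.254, n_cases = 1225L,
                     n_controls = 384L, seed = seed),
    AFR = sim_profile("AFR", f_afr, h1_or = 1.32, n_cases = 919L,
                      n_controls = 1607L, seed = seed),
    EAS = sim_profile("EAS", f_eas, h1_or = 1.27, n_cases = 2538L,
                      n_controls = 2329L, seed = seed)
  )
}

#' Simulate a phased case/control cohort
#'
#' Generative model: control haplotypes are drawn i.i.d. from the profile's
#' subhaplotype frequencies (Hardy-Weinberg by construction). Case
#' haplotypes are drawn i.i.d. from the case-tilted distribution
#' proportional to \code{freq x h1_or^[label is H1-class]} — the exact
#' haplotype distribution induced in cases by a multiplicative per-H1-allele
#' odds model under retrospective (case/control) sampling, which factorizes
#' over the two haplotypes and makes expected case frequencies analytic.
#' Genotypes derive deterministically from the haplotype labels via
#' \code{\link{subhap_to_alleles}}; missingness is then injected per
#' sample x site, and sex, age (age at onset for cases, optionally shifted
#' by \code{aao_beta} years per H1 allele, missing at random), and five
#' Gaussian PCs are attached. Three fixed-offset RNG sub-streams
#' (haplotypes: seed; missingness: seed + 1; covariates: seed + 2) keep the
#' genotype draws invariant to covariate settings. Fully reproducible from
#' \code{profile$seed}.
#'
#' @param profile a \code{\link{sim_profile}}.
#' @param nom nomenclature table whose named patterns the labels map onto.
#' @param panel tag panel.
#' @return A list of class \code{sim_cohort}: \code{true_haplotypes}
#'   (n x 2 character matrix of labels), \code{genotypes} (a phased
#'   \code{geno_matrix}, after missingness), \code{metadata} (data frame as
#'   from \code{\link{load_metadata}}), \code{profile}.
#' @export
simulate_cohort <- function(profile, nom = read_nomenclature(),
                            panel = tag_panel()) {
  stopifnot(inherits(profile, "sim_profile"))
  labs <- names(profile$subhap_freqs)
  missing_labs <- setdiff(labs, rownames(nom$patterns))
  if (length(missing_labs))
    stop("profile frequencies name labels absent from the nomenclature: ",
         paste(missing_labs, collapse = ", "))
  n_ca <- profile$n_cases
  n_co <- profile$n_controls
  n <- n_ca + n_co
  is_h1 <- nom$class[labs] == "H1"
  w_case <- profile$subhap_freqs * ifelse(is_h1, profile$h1_or, 1)
  w_case <- w_case / sum(w_case)

  set.seed(profile$seed)
  hap_case <- sample(labs, 2L * n_ca, replace = TRUE, prob = w_case)
  hap_ctrl <- sample(labs, 2L * n_co, replace = TRUE,
                     prob = profile$subhap_freqs)
  true_h <- rbind(matrix(hap_case, n_ca, 2L),
                  matrix(hap_ctrl, n_co, 2L))
  ids <- sprintf("%s%05d", profile$name, seq_len(n))
  rownames(true_h) <- ids
  status <- rep(c("case", "control"), c(n_ca, n_co))

  pat <- t(vapply(labs, subhap_to_alleles, integer(nrow(panel)),
                  nom = nom, panel = panel))
  a1 <- pat[match(true_h[, 1], labs), , drop = FALSE]
  a2 <- pat[match(true_h[, 2], labs), , drop = FALSE]
  dimnames(a1) <- dimnames(a2) <- list(ids, panel$rsid)
  phased <- matrix(TRUE, n, nrow(panel), dimnames = dimnames(a1))

  set.seed(profile$seed + 1L)
  if (profile$missing_geno_rate > 0) {
    mask <- matrix(stats::runif(n * nrow(panel)) < profile$missing_geno_rate,
                   n, nrow(panel))
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
    phased[mask] <- FALSE
  }

  set.seed(profile$seed + 2L)
  sex <- ifelse(stats::runif(n) < profile$sex_balance, "F", "M")
  h1_count <- rowSums(matrix(nom$class[true_h] == "H1", n, 2L))
  age <- profile$age_mean + stats::rnorm(n, 0, profile$age_sd)
  age <- age + ifelse(status == "case", profile$aao_beta * h1_count, 0)
  age <- round(age, 1)
  age[stats::runif(n) < profile$age_missing_rate] <- NA_real_
  pcs <- matrix(stats::rnorm(n * 5L, 0, profile$pc_sd), n, 5L)

  meta <- data.frame(id = ids, status = status, sex = sex, age = age,
                     stringsAsFactors = FALSE)
  for (k in 1:5) meta[[paste0("PC", k)]] <- round(pcs[, k], 6)
  meta$group <- profile$name

  g <- structure(list(samples = ids, panel = panel, a1 = a1, a2 = a2,
                      phased = phased),
                 class = "geno_matrix")
  structure(list(true_haplotypes = true_h, genotypes = g, metadata = meta,
                 profile = profile),
            class = "sim_cohort")
}

#' Write a genotype matrix as a phased VCF v4.2
#'
#' Plain-text VCF with one record per panel SNV (sorted by position), GT
#' fields \code{a|b} on panel orientation and \code{./.} for missing calls.
#' Output is byte-deterministic for a given matrix, so same-seed simulated
#' cohorts serialize identically.
#'
#' @param g a \code{geno_matrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(g, path) {
  p <- g$panel
  ord <- order(norm_chrom(p$chrom), p$pos)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tau17q",
           sprintf("##contig=<ID=%s>", unique(p$chrom[ord])),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  body <- vapply(ord, function(j) {
    gt <- ifelse(is.na(g$a1[, j]) | is.na(g$a2[, j]), "./.",
                 paste0(g$a1[, j], "|", g$a2[, j]))
    paste(c(p$chrom[j], p$pos[j], p$rsid[j], p$ref[j], p$alt[j], ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the phased VCF and the metadata TSV in the formats
#' \code{\link{load_tag_genotypes}} and \code{\link{load_metadata}} read
#' back, so a simulated cohort round-trips through the I/O layer.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @return Named character vector with elements \code{vcf} and
#'   \code{metadata}.
#' @export
write_sim_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, paste0(cohort$profile$name, ".vcf"))
  tsv <- file.path(dir, paste0(cohort$profile$name, "_metadata.tsv"))
  write_vcf(cohort$genotypes, vcf)
  meta <- cohort$metadata
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  c(vcf = vcf, metadata = tsv)
}
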