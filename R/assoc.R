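#' Haplotype, diplotype and subhaplotype frequency tables
#'
#' Computes, per group x case/control status, the H1/H2 allele frequencies
#' (from diplotypes), the diplotype frequencies, and (when subhaplotype
#' calls are supplied) the subhaplotype frequencies. All frequencies are
#' over non-missing denominators, and every cell reports its denominator.
#' Empty groups are omitted with a warning.
#'
#' @param diplo factor of diplotypes named by sample id (see
#'   \code{\link{diplotypes}}).
#' @param meta metadata data frame (\code{id}, \code{status}, \code{group}).
#' @param subhap optional subhaplotype calls: a data frame with \code{id}
#'   and \code{label} columns — either per-sample collapsed calls or
#'   per-haplotype phased calls (two rows per sample).
#' @return A long data frame: \code{group}, \code{status}, \code{metric}
#'   (\code{allele} / \code{diplotype} / \code{subhaplotype}),
#'   \code{category}, \code{count}, \code{denom}, \code{freq}.
#' @export
haplotype_frequencies <- function(diplo, meta, subhap = NULL) {
  meta <- meta[match(names(diplo), meta$id), , drop = FALSE]
  grp <- if (all(is.na(meta$group))) rep("all", nrow(meta)) else meta$group
  rows <- list()
  for (gname in unique(grp)) {
    for (st in c("case", "control")) {
      sel <- grp == gname & meta$status == st
      if (!any(sel)) {
        warning("empty stratum: ", gname, "/", st, call. = FALSE)
        next
      }
      d <- diplo[sel]
      dn <- d[d != "MISSING"]
      nh <- length(dn)
      n_h2 <- 2 * sum(dn == "H2/H2") + sum(dn == "H1/H2")
      if (nh > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, status = st, metric = "allele",
          category = c("H1", "H2"),
          count = c(2 * nh - n_h2, n_h2), denom = 2 * nh,
          freq = c(2 * nh - n_h2, n_h2) / (2 * nh),
          stringsAsFactors = FALSE)
      }
      tab <- table(factor(dn, levels = c("H1/H1", "H1/H2", "H2/H2")))
      if (nh > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, status = st, metric = "diplotype",
          category = names(tab), count = as.integer(tab), denom = nh,
          freq = as.integer(tab) / nh, stringsAsFactors = FALSE)
      }
      if (!is.null(subhap)) {
        ids <- meta$id[sel]
        sl <- subhap$label[subhap$id %in% ids]
        sl <- sl[!is.na(sl)]
        if (length(sl)) {
          stab <- sort(table(sl), decreasing = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            group = gname, status = st, metric = "subhaplotype",
            category = names(stab), count = as.integer(stab),
            denom = length(sl), freq = as.integer(stab) / length(sl),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare two frequency tables in percentage points
#'
#' Takes two frequency tables (named numeric vectors of proportions, or
#' data frames with \code{category} and \code{freq} columns), unions their
#' category sets (absent categories count as frequency 0), and reports the
#' signed and absolute per-category differences in percentage points, with
#' the maximum absolute difference as an attribute. This is the concordance
#' check used to compare, e.g., WGS-derived vs imputation-derived
#' subhaplotype spectra.
#'
#' @param table_a,table_b frequency tables (proportions in [0,1]).
#' @return A data frame \code{category}, \code{freq_a}, \code{freq_b},
#'   \code{diff_pp} (signed, a - b), \code{abs_diff_pp}; attribute
#'   \code{max_abs_pp} carries the maximum absolute difference.
#' @export
compare_frequency_tables <- function(table_a, table_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$freq, x$category) else x
  }
  a <- as_vec(table_a)
  b <- as_vec(table_b)
  cats <- sort(union(names(a), names(b)))
  fa <- ifelse(cats %in% names(a), a[cats], 0)
  fb <- ifelse(cats %in% names(b), b[cats], 0)
  out <- data.frame(category = cats, freq_a = unname(fa),
                    freq_b = unname(fb),
                    diff_pp = unname(100 * (fa - fb)),
                    abs_diff_pp = unname(abs(100 * (fa - fb))),
                    stringsAsFactors = FALSE)
  attr(out, "max_abs_pp") <- if (nrow(out)) max(out$abs_diff_pp) else 0
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic SNV: given the observed allele
#' counts, the p-value is the sum of probabilities of all heterozygote
#' counts no more probable than the observed one (no mid-p correction).
#' Probabilities are computed by the stable recurrence over heterozygote
#' counts. Monomorphic input returns p = 1.
#'
#' @param n_homref,n_het,n_homalt genotype counts (hom REF, het, hom ALT).
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' hwe_exact_test(21, 48, 31)
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n == 0) stop("no genotypes")
  rare <- min(2 * n_homref + n_het, 2 * n_homalt + n_het)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities by recurrence from the smallest het count
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k]
    hr <- (rare - h) / 2 + 1          # rare homs at previous h
    hc <- n - (h - 2) - hr            # common homs at previous h
    lp[k] <- lp[k - 1] + log(4 * hr * hc) - log(h * (h - 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (!length(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Allelic (2x2 allele count) association test
#'
#' Case-control odds ratio from the 2x2 table of allele counts with a Wald
#' 95\% CI on the log OR and a 1-df chi-square p-value (the default allelic
#' test of standard GWAS tooling). A Fisher exact p is available for small
#' cells. Tables with a zero cell get the Haldane-Anscombe +0.5 continuity
#' correction for the OR/CI, flagged in the result; an empty case or
#' control stratum yields an undefined-result flag.
#'
#' @param case_a1,case_a2 allele counts in cases (a1 = effect allele, here
#'   conventionally H1).
#' @param ctrl_a1,ctrl_a2 allele counts in controls.
#' @param method \code{"chisq"} (default) or \code{"fisher"} for the p-value.
#' @return One-row data frame: \code{model}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{n_cases}, \code{n_controls} (sample
#'   counts, i.e. allele counts / 2), \code{flag}.
#' @export
allelic_association <- function(case_a1, case_a2, ctrl_a1, ctrl_a2,
                                method = c("chisq", "fisher")) {
  method <- match.arg(method)
  cells <- c(case_a1, case_a2, ctrl_a1, ctrl_a2)
  if (any(cells < 0)) stop("negative allele counts")
  flag <- ""
  if (case_a1 + case_a2 == 0 || ctrl_a1 + ctrl_a2 == 0) {
    return(data.frame(model = paste0("allelic_", method), or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      n_cases = (case_a1 + case_a2) / 2,
                      n_controls = (ctrl_a1 + ctrl_a2) / 2,
                      flag = "undefined_empty_stratum",
                      stringsAsFactors = FALSE))
  }
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  cc <- cells
  if (any(cells == 0)) {
    cc <- cells + 0.5
    flag <- "haldane_correction"
  }
  lor <- log(cc[1]) - log(cc[2]) - log(cc[3]) + log(cc[4])
  se <- sqrt(sum(1 / cc))
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  data.frame(model = paste0("allelic_", method), or = exp(lor),
             ci_low = exp(lor - 1.96 * se), ci_high = exp(lor + 1.96 * se),
             p = p, n_cases = (case_a1 + case_a2) / 2,
             n_controls = (ctrl_a1 + ctrl_a2) / 2, flag = flag,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted logistic association
#'
#' Fits a maximum-likelihood logistic regression of case status on the
#' additive H1 allele count (0/1/2) plus the chosen covariate set, by
#' iteratively reweighted least squares (\code{stats::glm}). Complete-case:
#' samples missing the genotype or any included covariate are dropped and
#' the remaining per-arm counts reported. Non-convergence or apparent
#' separation (|beta| > 15) is flagged and no estimate is reported.
#'
#' @param meta metadata data frame (\code{status}, \code{sex}, \code{age},
#'   \code{PC1}..\code{PC5}), one row per sample.
#' @param h1_count integer vector (0/1/2/NA) of H1 allele counts aligned
#'   with \code{meta} rows.
#' @param covariate_set \code{"none"}, \code{"sex_pc"} (sex + PC1-5) or
#'   \code{"sex_age_pc"} (sex + age + PC1-5).
#' @return One-row data frame as in \code{\link{allelic_association}}, with
#'   \code{model = "logistic_<covariate_set>"}.
#' @export
logistic_association <- function(meta, h1_count,
                                 covariate_set = c("none", "sex_pc",
                                                   "sex_age_pc")) {
  covariate_set <- match.arg(covariate_set)
  covs <- switch(covariate_set,
                 none = character(),
                 sex_pc = c("sex", paste0("PC", 1:5)),
                 sex_age_pc = c("sex", "age", paste0("PC", 1:5)))
  d <- data.frame(y = as.integer(meta$status == "case"), g = h1_count,
                  stringsAsFactors = FALSE)
  for (cv in covs) d[[cv]] <- meta[[cv]]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  model <- paste0("logistic_", covariate_set)
  n_cases <- sum(d$y == 1)
  n_controls <- sum(d$y == 0)
  base <- data.frame(model = model, or = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p = NA_real_, n_cases = n_cases,
                     n_controls = n_controls, flag = "",
                     stringsAsFactors = FALSE)
  if (n_cases == 0 || n_controls == 0 || length(unique(d$g)) < 2) {
    base$flag <- "undefined_degenerate_input"
    return(base)
  }
  fit <- tryCatch(
    stats::glm(y ~ ., data = d, family = stats::binomial()),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    base$flag <- "non_convergence"
    return(base)
  }
  cf <- summary(fit)$coefficients
  if (!"g" %in% rownames(cf) || abs(cf["g", "Estimate"]) > 15) {
    base$flag <- "separation_suspected"
    return(base)
  }
  b <- cf["g", "Estimate"]
  se <- cf["g", "Std. Error"]
  base$or <- exp(b)
  base$ci_low <- exp(b - 1.96 * se)
  base$ci_high <- exp(b + 1.96 * se)
  base$p <- cf["g", "Pr(>|z|)"]
  base
}

#' Age-at-onset contrast between H1 and H2 carriers
#'
#' Two analyses of case age at onset (AAO): (i) a two-sided Mann-Whitney U
#' test of H1/H1 homozygotes vs H2 carriers (normal approximation with
#' midranks and tie-corrected variance; exact enumeration when both groups
#' have at most 8 cases and no ties), and (ii) a linear regression of AAO
#' on the H1 allele count adjusted for sex and PC1-5, reporting beta
#' (years per H1 allele; negative = earlier onset with H1), its SE and p.
#'
#' @param cases data frame of cases with \code{age}, \code{sex},
#'   \code{PC1}..\code{PC5}.
#' @param h1_count integer vector (0/1/2/NA) aligned with \code{cases} rows.
#' @return One-row data frame: \code{u_p}, \code{beta}, \code{se},
#'   \code{lm_p}, \code{n_h1h1}, \code{n_h2carrier}, \code{flag}.
#' @export
aao_analysis <- function(cases, h1_count) {
  d <- data.frame(age = cases$age, g = h1_count, sex = cases$sex,
                  stringsAsFactors = FALSE)
  for (k in 1:5) d[[paste0("PC", k)]] <- cases[[paste0("PC", k)]]
  d <- d[!is.na(d$age) & !is.na(d$g), , drop = FALSE]
  aao_h1 <- d$age[d$g == 2]
  aao_h2 <- d$age[d$g < 2]
  flag <- ""
  u_p <- NA_real_
  if (length(aao_h1) >= 2 && length(aao_h2) >= 2) {
    exact <- length(aao_h1) <= 8 && length(aao_h2) <= 8 &&
      !anyDuplicated(c(aao_h1, aao_h2))
    u_p <- suppressWarnings(
      stats::wilcox.test(aao_h1, aao_h2, exact = exact,
                         correct = FALSE)$p.value)
  } else {
    flag <- "u_test_skipped_small_group"
  }
  beta <- se <- lm_p <- NA_real_
  dc <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(dc) > 8 && length(unique(dc$g)) > 1) {
    fit <- stats::lm(age ~ ., data = dc)
    cf <- summary(fit)$coefficients
    if ("g" %in% rownames(cf)) {
      beta <- cf["g", "Estimate"]
      se <- cf["g", "Std. Error"]
      lm_p <- cf["g", "Pr(>|t|)"]
    }
  }
  data.frame(u_p = u_p, beta = beta, se = se, lm_p = lm_p,
             n_h1h1 = length(aao_h1), n_h2carrier = length(aao_h2),
             flag = flag, stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level, in (0, 1].
#' @param m number of tests, >= 1.
#' @return \code{alpha / m}.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 11)   # 0.004545...
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}
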