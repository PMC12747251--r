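#' H1/H2 diplotype from the rs1052553 genotype
#'
#' rs1052553 (A>G) tags the 17q21.31 inversion: A/A is H1/H1, A/G is H1/H2
#' and G/G is H2/H2. On panel orientation the REF (A) allele is H1 and the
#' ALT (G) allele is H2, so a pair of allele indices maps directly:
#' (0,0) -> H1/H1, (0,1) or (1,0) -> H1/H2, (1,1) -> H2/H2; any missing
#' allele -> MISSING.
#'
#' @param a1,a2 integer vectors of allele indices (0/1/NA) at rs1052553.
#' @return A factor with levels \code{H1/H1}, \code{H1/H2}, \code{H2/H2},
#'   \code{MISSING}.
#' @export
#' @examples
#' call_diplotype(c(0, 0, 1, NA), c(0, 1, 1, 1))
call_diplotype <- function(a1, a2) {
  s <- a1 + a2
  out <- ifelse(is.na(s), "MISSING",
                c("H1/H1", "H1/H2", "H2/H2")[s + 1L])
  factor(out, levels = c("H1/H1", "H1/H2", "H2/H2", "MISSING"))
}

#' @rdname call_diplotype
#' @param g a \code{geno_matrix} containing the H1/H2-tagging SNV.
#' @return \code{diplotypes}: one diplotype per sample, named by sample id.
#' @export
diplotypes <- function(g) {
  tag <- h1h2_rsid(g$panel)
  d <- call_diplotype(g$a1[, tag], g$a2[, tag])
  names(d) <- g$samples
  d
}

# label a set of 6-bit pattern keys: named table entries keep their label,
# unmatched patterns become US1, US2, ... ranked by descending cohort
# frequency, ties broken by lexicographic pattern order
label_patterns <- function(keys, nom) {
  table_keys <- apply(nom$patterns, 1, paste, collapse = "")
  lab <- rownames(nom$patterns)[match(keys, table_keys)]
  un <- keys[is.na(lab) & !is.na(keys)]
  if (length(un)) {
    tab <- table(un)
    ord <- order(-as.integer(tab), names(tab))
    us <- paste0("US", seq_along(ord))
    names(us) <- names(tab)[ord]
    lab[is.na(lab) & !is.na(keys)] <- us[un]
  }
  lab
}

#' Assign subhaplotypes to phased haplotypes
#'
#' Each phased haplotype's six-allele vector over the subhaplotype-tagging
#' SNVs is looked up in the nomenclature table. Exact matches get the named
#' label; unmatched patterns get cohort-relative labels \code{US1},
#' \code{US2}, ... ("unspecified subhaplotype") numbered by descending
#' frequency in the cohort, ties broken by lexicographic pattern order.
#' Haplotypes with any unphased or missing subhap-tag site are labeled
#' \code{NA} and drop out of all frequency denominators.
#'
#' @param g a \code{geno_matrix} with phased calls.
#' @param nom a \code{\link{nomenclature}} table.
#' @return A data frame with one row per haplotype: \code{id}, \code{hap}
#'   (1 or 2), \code{pattern} (6-character 0/1 key or \code{NA}),
#'   \code{label} (named, \code{US<k>}, or \code{NA} when unresolvable).
#' @export
assign_subhaplotypes_phased <- function(g, nom) {
  sh <- subhap_rsids(g$panel)
  ok <- rowSums(is.na(g$a1[, sh, drop = FALSE])) == 0 &
    rowSums(is.na(g$a2[, sh, drop = FALSE])) == 0 &
    rowSums(!g$phased[, sh, drop = FALSE]) == 0
  key1 <- key2 <- rep(NA_character_, length(g$samples))
  key1[ok] <- apply(g$a1[ok, sh, drop = FALSE], 1, paste, collapse = "")
  key2[ok] <- apply(g$a2[ok, sh, drop = FALSE], 1, paste, collapse = "")
  keys <- c(key1, key2)
  out <- data.frame(
    id = rep(g$samples, 2L),
    hap = rep(c(1L, 2L), each = length(g$samples)),
    pattern = keys,
    label = label_patterns(keys, nom),
    stringsAsFactors = FALSE
  )
  out[order(match(out$id, g$samples), out$hap), , drop = FALSE]
}

#' Collapse unphased genotypes to a per-sample subhaplotype label
#'
#' Implements the genotype-collapse coding used for per-sample subhaplotype
#' assignment: each subhap-tag SNV is coded 0 (hom REF), 1 (het), 2 (hom
#' ALT); heterozygous sites are then collapsed to the alternate allele, i.e.
#' the presence vector is \code{min(code, 1)}. The presence vector is looked
#' up in the nomenclature table exactly as a phased pattern would be
#' (including US numbering, here over samples). Samples missing any
#' subhap-tag call are excluded with a recorded reason.
#'
#' @param g a \code{geno_matrix} (phase is irrelevant here).
#' @param nom a \code{\link{nomenclature}} table.
#' @return A list with \code{codes} (samples x 6 matrix in 0/1/2),
#'   \code{presence} (samples x 6 matrix in 0/1), \code{calls} (data frame
#'   \code{id}, \code{pattern}, \code{label}), and \code{excluded} (data
#'   frame \code{id}, \code{reason}).
#' @export
collapse_unphased <- function(g, nom) {
  sh <- subhap_rsids(g$panel)
  codes <- g$a1[, sh, drop = FALSE] + g$a2[, sh, drop = FALSE]
  rownames(codes) <- g$samples
  presence <- pmin(codes, 1L)
  ok <- rowSums(is.na(codes)) == 0
  keys <- rep(NA_character_, length(g$samples))
  keys[ok] <- apply(presence[ok, , drop = FALSE], 1, paste, collapse = "")
  calls <- data.frame(id = g$samples, pattern = keys,
                      label = label_patterns(keys, nom),
                      stringsAsFactors = FALSE)
  excluded <- data.frame(id = g$samples[!ok],
                         reason = rep("missing_subhap_genotype", sum(!ok)),
                         stringsAsFactors = FALSE)
  list(codes = codes, presence = presence, calls = calls,
       excluded = excluded)
}

#' Classify H2 subtypes from confirming SNVs
#'
#' A haplotype is confirmed as H2 only when it carries the H2-associated
#' (ALT) allele at all three confirming SNVs rs1052553, rs199451 and
#' rs199533. Confirmed haplotypes are then matched against the
#' nomenclature's H2 subtype rule sets (every required rsid/allele pair must
#' hold) to yield a subtype label such as \code{H2D} or \code{H2'};
#' confirmed haplotypes matching no rule are \code{H2-unresolved}, as are
#' haplotypes missing any of the three confirming calls (these additionally
#' carry a missing-data flag). Haplotypes failing the three-SNV rule with
#' complete data are \code{not-H2}. With an empty rule list confirmed
#' haplotypes are labeled \code{H2-confirmed}.
#'
#' @param hap_calls integer matrix of allele indices, one row per haplotype,
#'   columns named by rsid; must cover the three confirming SNVs plus any
#'   rsid referenced by the rules.
#' @param nom a \code{\link{nomenclature}} (its \code{h2_rules} are used),
#'   or a bare named list of rules.
#' @return A character vector of labels with a logical attribute
#'   \code{missing} flagging haplotypes unresolved due to missing data.
#' @export
classify_h2_subtype <- function(hap_calls, nom) {
  rules <- if (inherits(nom, "nomenclature")) nom$h2_rules else nom
  trio <- h2_confirm_rsids()
  if (!all(trio %in% colnames(hap_calls)))
    stop("hap_calls must have columns for ", paste(trio, collapse = ", "))
  tc <- hap_calls[, trio, drop = FALSE]
  miss <- rowSums(is.na(tc)) > 0
  confirmed <- !miss & rowSums(tc == 1L) == 3L
  out <- rep("not-H2", nrow(hap_calls))
  out[miss] <- "H2-unresolved"
  if (length(rules) == 0L) {
    out[confirmed] <- "H2-confirmed"
  } else {
    out[confirmed] <- "H2-unresolved"
    for (i in which(confirmed)) {
      for (lab in names(rules)) {
        req <- rules[[lab]]
        vals <- hap_calls[i, names(req)]
        if (!anyNA(vals) && all(vals == req)) {
          out[i] <- lab
          break
        }
      }
    }
  }
  attr(out, "missing") <- miss
  out
}
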