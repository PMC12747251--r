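# shared fixture builders: tiny VCFs written in code, small nomenclatures,
# and a reference enumeration oracle for the HWE exact test

# write a VCF with records built from the panel; `gts` is a list keyed by
# rsid, each a character vector of GT strings (one per sample); `tweak`
# lets a test override REF/ALT or drop sites
mini_vcf <- function(gts, samples, panel = tag_panel(),
                     ref = NULL, alt = NULL, path = tempfile(fileext = ".vcf")) {
  keep <- panel$rsid %in% names(gts)
  p <- panel[keep, , drop = FALSE]
  if (!is.null(ref)) p$ref <- ifelse(is.na(ref[p$rsid]), p$ref, ref[p$rsid])
  if (!is.null(alt)) p$alt <- ifelse(is.na(alt[p$rsid]), p$alt, alt[p$rsid])
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr17>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  ord <- order(p$pos)
  body <- vapply(ord, function(j)
    paste(c(p$chrom[j], p$pos[j], p$rsid[j], p$ref[j], p$alt[j], ".", "PASS",
            ".", "GT", gts[[p$rsid[j]]]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# metadata TSV from a data frame
mini_meta <- function(d, path = tempfile(fileext = ".tsv")) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# three-label nomenclature used by several simulator tests
small_nom <- function() {
  pats <- rbind(H1a = c(0L, 0L, 0L, 0L, 0L, 0L),
                H1b = c(1L, 1L, 0L, 0L, 0L, 0L),
                H2a = c(0L, 0L, 0L, 0L, 1L, 0L))
  nomenclature(pats)
}

# independent HWE oracle: full enumeration with the closed-form conditional
# probability (lchoose), kept apart from the recurrence the package uses
hwe_enum_oracle <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  na <- 2 * n_homalt + n_het
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    nalt <- (na - h) / 2
    nref <- n - h - nalt
    lchoose(n, nref) + lchoose(n - nref, nalt) + h * log(2) -
      lchoose(2 * n, na)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# H1 allele count per sample from a diplotype factor
h1_counts <- function(dip) {
  ifelse(dip == "MISSING", NA_integer_,
         2L - (match(dip, c("H1/H1", "H1/H2", "H2/H2")) - 1L))
}
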