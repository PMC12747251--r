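#' Load tag-SNV genotypes from a VCF
#'
#' Reads a VCF (v4.2, plain or bgzipped) and extracts per-sample allele
#' calls at the panel SNVs. Sites are matched by chromosome + position
#' ("chr17" and "17" compare equal) with a REF/ALT orientation check:
#' records whose REF/ALT are swapped relative to the panel are accepted with
#' allele indices flipped onto panel orientation; records matching neither
#' direct nor swapped orientation raise a site-mismatch error. In
#' multiallelic records, the ALT matching the panel is selected and calls to
#' other ALT alleles become missing. Panel sites absent from the VCF produce
#' a fully missing column with a warning naming the rsid. rsIDs in the VCF
#' ID field are not used for matching (they are often absent after
#' imputation).
#'
#' @param vcf_source path to a VCF file.
#' @param panel a \code{\link{tag_panel}}.
#' @return An object of class \code{geno_matrix}: a list with \code{samples}
#'   (ids), \code{panel}, integer matrices \code{a1} and \code{a2}
#'   (samples x sites, values 0 = panel REF / 1 = panel ALT / NA = missing),
#'   and a logical matrix \code{phased}.
#' @export
load_tag_genotypes <- function(vcf_source, panel = tag_panel()) {
  validate_panel(panel)
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  n <- length(samples)
  m <- nrow(panel)
  a1 <- a2 <- matrix(NA_integer_, n, m,
                     dimnames = list(samples, panel$rsid))
  phased <- matrix(FALSE, n, m, dimnames = list(samples, panel$rsid))

  for (j in seq_len(m)) {
    hits <- which(norm_chrom(fix$CHROM) == norm_chrom(panel$chrom[j]) &
                    as.integer(fix$POS) == panel$pos[j])
    if (!length(hits)) {
      warning("panel site ", panel$rsid[j], " (", panel$chrom[j], ":",
              panel$pos[j], ") absent from VCF; column set to missing",
              call. = FALSE)
      next
    }
    matched <- FALSE
    for (i in hits) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      if (fix$REF[i] == panel$ref[j] && panel$alt[j] %in% alts) {
        code_alt <- match(panel$alt[j], alts)
        flip <- FALSE
      } else if (fix$REF[i] == panel$alt[j] && panel$ref[j] %in% alts) {
        code_alt <- match(panel$ref[j], alts)
        flip <- TRUE
      } else next
      calls <- parse_gt(gt[i, , drop = TRUE])
      map1 <- map_codes(calls$a1, code_alt, flip)
      map2 <- map_codes(calls$a2, code_alt, flip)
      a1[, j] <- map1
      a2[, j] <- map2
      phased[, j] <- calls$phased & !is.na(map1) & !is.na(map2)
      matched <- TRUE
      break
    }
    if (!matched)
      stop("site-mismatch at ", panel$chrom[j], ":", panel$pos[j],
           " (", panel$rsid[j], "): VCF alleles incompatible with panel ",
           panel$ref[j], ">", panel$alt[j], call. = FALSE)
  }
  structure(list(samples = samples, panel = panel,
                 a1 = a1, a2 = a2, phased = phased),
            class = "geno_matrix")
}

# split GT strings into two allele codes plus a phased flag
parse_gt <- function(g) {
  g <- as.character(g)
  phased <- !is.na(g) & grepl("|", g, fixed = TRUE)
  parts <- strsplit(ifelse(is.na(g), "./.", g), "[/|]")
  pick <- function(k) vapply(parts, function(p) {
    if (length(p) < k || p[k] == ".") NA_integer_ else as.integer(p[k])
  }, integer(1))
  list(a1 = pick(1), a2 = pick(2), phased = phased)
}

# VCF allele codes -> panel allele indices (0 ref / 1 alt / NA)
map_codes <- function(code, code_alt, flip) {
  out <- rep(NA_integer_, length(code))
  out[!is.na(code) & code == 0L] <- if (flip) 1L else 0L
  out[!is.na(code) & code == code_alt] <- if (flip) 0L else 1L
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ",
      nrow(x$panel), " panel SNVs; ",
      sum(is.na(x$a1) | is.na(x$a2)), " missing calls\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by sample id
#'
#' @param g a \code{geno_matrix}.
#' @param ids sample ids to keep (order preserved).
#' @return The subsetted \code{geno_matrix}.
#' @export
geno_subset <- function(g, ids) {
  keep <- match(ids, g$samples)
  if (anyNA(keep)) stop("unknown sample ids: ",
                        paste(ids[is.na(keep)], collapse = ", "))
  structure(list(samples = g$samples[keep], panel = g$panel,
                 a1 = g$a1[keep, , drop = FALSE],
                 a2 = g$a2[keep, , drop = FALSE],
                 phased = g$phased[keep, , drop = FALSE]),
            class = "geno_matrix")
}

#' Load a sample metadata table
#'
#' Reads a tab-separated table with header columns \code{id} and
#' \code{status} (required; status tokens \code{case}/\code{control},
#' case-insensitive) and optional \code{sex}, \code{age} (age at onset for
#' cases), \code{PC1}..\code{PC5}, \code{group}. Absent optional columns are
#' created as missing; empty cells become \code{NA}.
#'
#' @param tsv_source path to the TSV file.
#' @return A \code{data.frame} with columns \code{id}, \code{status},
#'   \code{sex}, \code{age}, \code{PC1}..\code{PC5}, \code{group}.
#' @export
load_metadata <- function(tsv_source) {
  d <- utils::read.delim(tsv_source, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), colClasses = NA)
  if (!all(c("id", "status") %in% names(d)))
    stop("metadata must have 'id' and 'status' columns")
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id))
    stop("duplicate sample id in metadata: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  st <- tolower(as.character(d$status))
  bad <- !is.na(st) & !st %in% c("case", "control")
  if (any(bad))
    stop("unknown status token(s): ",
         paste(unique(d$status[bad]), collapse = ", "))
  d$status <- st
  for (col in c("sex", "group"))
    if (is.null(d[[col]])) d[[col]] <- NA_character_
  for (col in c("age", paste0("PC", 1:5))) {
    if (is.null(d[[col]])) d[[col]] <- NA_real_
    d[[col]] <- as.numeric(d[[col]])
  }
  d[, c("id", "status", "sex", "age", paste0("PC", 1:5), "group")]
}

#' Apply cohort inclusion filters
#'
#' Removes (i) samples on the related-sample exclusion list and (ii)
#' samples with a missing call at the H1/H2-tagging SNV (rs1052553) — the
#' two inclusion filters applied before any analysis. Samples present in the
#' genotype matrix but absent from the metadata are also removed, with their
#' own reason code.
#'
#' @param g a \code{geno_matrix}.
#' @param meta metadata data frame from \code{\link{load_metadata}}.
#' @param exclusion_list character vector of sample ids to drop (may be
#'   empty), or a path to a one-id-per-line file.
#' @return A list with \code{genotypes} and \code{metadata} (filtered and
#'   aligned in the same sample order), and \code{removed}, a data frame of
#'   \code{id}, \code{reason} (\code{related_excluded},
#'   \code{missing_h1h2_genotype}, \code{no_metadata}); one row per removed
#'   sample.
#' @export
filter_cohort <- function(g, meta, exclusion_list = character()) {
  if (length(exclusion_list) == 1L && file.exists(exclusion_list))
    exclusion_list <- readLines(exclusion_list)
  exclusion_list <- exclusion_list[nzchar(exclusion_list)]
  tag <- h1h2_rsid(g$panel)
  miss_tag <- is.na(g$a1[, tag]) | is.na(g$a2[, tag])
  reason <- rep(NA_character_, length(g$samples))
  reason[!g$samples %in% meta$id] <- "no_metadata"
  reason[miss_tag & is.na(reason)] <- "missing_h1h2_genotype"
  reason[g$samples %in% exclusion_list] <- "related_excluded"
  keep <- is.na(reason)
  removed <- data.frame(id = g$samples[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep))
    warning("all samples removed by cohort filters", call. = FALSE)
  ids <- g$samples[keep]
  list(genotypes = geno_subset(g, ids),
       metadata = meta[match(ids, meta$id), , drop = FALSE],
       removed = removed)
}
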