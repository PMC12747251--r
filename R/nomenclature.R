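#' Subhaplotype nomenclature tables
#'
#' A nomenclature table maps 6-allele patterns over the subhaplotype-tagging
#' SNVs (panel order: rs1467967, rs242557, rs3785883, rs2471738, rs8070723,
#' rs7521; 0 = REF, 1 = ALT) to named subhaplotype labels, and carries rule
#' sets distinguishing the H2 subtypes (H2D vs H2', the CNV-defined classes)
#' among haplotypes confirmed as H2 by the three-SNV rule.
#'
#' The default table shipped in
#' \code{system.file("extdata", "nomenclature_default.yaml", package = "tau17q")}
#' is a package-curated approximation of the published SNV-based
#' nomenclature; the file is editable and is the object of record — analyses
#' log its checksum (see \code{\link{nomenclature_checksum}}) so that results
#' are tied to the exact table used. Patterns whose haplotype carries the ALT
#' allele at rs8070723 are H2-class; all others are H1-class.
#'
#' @param path path to a YAML nomenclature file; the default reads the
#'   table shipped with the package.
#' @return An object of class \code{nomenclature}: a list with
#'   \describe{
#'     \item{patterns}{integer matrix, one row per named subhaplotype
#'       (rownames = labels), six 0/1 columns named by subhap-tag rsid;}
#'     \item{class}{named character vector, \code{"H1"} or \code{"H2"} per label;}
#'     \item{h2_rules}{named list; each element a named integer vector of
#'       required allele indices (names = rsids) defining one H2 subtype;}
#'     \item{source}{the file path the table was read from.}
#'   }
#' @export
#' @examples
#' nom <- read_nomenclature()
#' rownames(nom$patterns)
read_nomenclature <- function(path = system.file("extdata",
                                                 "nomenclature_default.yaml",
                                                 package = "tau17q")) {
  y <- yaml::read_yaml(path)
  if (is.null(y$subhaplotypes) || !length(y$subhaplotypes))
    stop("nomenclature file has no 'subhaplotypes' block")
  labs <- vapply(y$subhaplotypes, function(e) as.character(e$label), "")
  pats <- t(vapply(y$subhaplotypes, function(e) as.integer(e$pattern),
                   integer(6)))
  if (anyDuplicated(labs)) stop("duplicate subhaplotype labels")
  keys <- apply(pats, 1, paste, collapse = "")
  if (anyDuplicated(keys)) stop("two subhaplotype entries share a pattern")
  if (!all(pats %in% c(0L, 1L))) stop("patterns must be 0/1 allele indices")
  rownames(pats) <- labs
  colnames(pats) <- subhap_rsids()
  cls <- vapply(y$subhaplotypes, function(e) {
    if (!is.null(e$class)) as.character(e$class)
    else if (as.integer(e$pattern[5]) == 1L) "H2" else "H1"
  }, "")
  names(cls) <- labs
  if (!all(cls %in% c("H1", "H2"))) stop("subhaplotype class must be H1 or H2")
  rules <- list()
  for (r in y$h2_subtypes) {
    req <- vapply(r$requirements, function(q) as.integer(q$allele),
                  integer(1))
    names(req) <- vapply(r$requirements, function(q) as.character(q$rsid), "")
    rules[[as.character(r$label)]] <- req
  }
  structure(list(patterns = pats, class = cls, h2_rules = rules,
                 source = path),
            class = "nomenclature")
}

#' Build a nomenclature object in code
#'
#' Mostly useful for tests and simulations that need a small custom table.
#'
#' @param patterns integer matrix of 0/1 allele indices with one row per
#'   label (rownames) and six columns in subhap-tag panel order.
#' @param h2_rules named list of named integer vectors (rsid -> allele index).
#' @param class optional named character vector ("H1"/"H2"); defaults to H2
#'   for patterns with ALT at rs8070723 (column 5), H1 otherwise.
#' @return A \code{nomenclature} object.
#' @export
nomenclature <- function(patterns, h2_rules = list(), class = NULL) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (ncol(patterns) != 6L) stop("patterns must have six columns")
  if (is.null(rownames(patterns))) stop("patterns must have label rownames")
  if (anyDuplicated(rownames(patterns))) stop("duplicate labels")
  if (anyDuplicated(apply(patterns, 1, paste, collapse = "")))
    stop("two entries share a pattern")
  colnames(patterns) <- subhap_rsids()
  if (is.null(class))
    class <- ifelse(patterns[, 5] == 1L, "H2", "H1")
  names(class) <- rownames(patterns)
  structure(list(patterns = patterns, class = class, h2_rules = h2_rules,
                 source = NA_character_),
            class = "nomenclature")
}

#' Checksum of a nomenclature file
#'
#' md5 of the file backing a nomenclature table, recorded in pipeline run
#' logs so a result can always be traced to the exact table used.
#'
#' @param nom a \code{nomenclature} object (with a file source) or a path.
#' @return md5 checksum string, or \code{NA} for in-memory tables.
#' @export
nomenclature_checksum <- function(nom) {
  path <- if (inherits(nom, "nomenclature")) nom$source else nom
  if (is.na(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

#' @export
print.nomenclature <- function(x, ...) {
  cat("<nomenclature> ", nrow(x$patterns), " subhaplotypes (",
      sum(x$class == "H1"), " H1, ", sum(x$class == "H2"), " H2), ",
      length(x$h2_rules), " H2 subtype rule sets\n", sep = "")
  invisible(x)
}
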