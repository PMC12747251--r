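#' Tag-SNV panel for the 17q21.31 locus
#'
#' The default panel carries the nine tag SNVs used throughout the package
#' (GRCh38 coordinates on chr17):
#' \itemize{
#'   \item \code{rs1052553} (chr17:45996523 A>G), the H2-tagging SNV whose
#'     genotype defines the H1/H2 diplotype (role \code{H1H2_TAG});
#'   \item six subhaplotype-tagging SNVs, in panel order \code{rs1467967},
#'     \code{rs242557}, \code{rs3785883}, \code{rs2471738}, \code{rs8070723},
#'     \code{rs7521} (role \code{SUBHAP_TAG});
#'   \item \code{rs199451} (chr17:46724418 G>A) and \code{rs199533}
#'     (chr17:46751565 G>A), which together with \code{rs1052553} confirm an
#'     H2 haplotype (role \code{H2_CONFIRM}).
#' }
#' At each SNV allele index 0 is the panel REF allele and 1 the panel ALT
#' allele; at every H2-confirming SNV the ALT allele is the H2-associated
#' allele.
#'
#' @return A \code{data.frame} of class \code{tag_panel} with columns
#'   \code{rsid}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{role}.
#' @export
#' @examples
#' p <- tag_panel()
#' subhap_rsids(p)
tag_panel <- function() {
  p <- data.frame(
    rsid  = c("rs1467967", "rs242557", "rs3785883", "rs2471738",
              "rs1052553", "rs8070723", "rs7521", "rs199451", "rs199533"),
    chrom = "chr17",
    pos   = c(45908813L, 45942346L, 45977067L, 45998697L,
              45996523L, 46003698L, 46028029L, 46724418L, 46751565L),
    ref   = c("G", "G", "A", "C", "A", "A", "A", "G", "G"),
    alt   = c("A", "A", "G", "T", "G", "G", "G", "A", "A"),
    role  = c("SUBHAP_TAG", "SUBHAP_TAG", "SUBHAP_TAG", "SUBHAP_TAG",
              "H1H2_TAG", "SUBHAP_TAG", "SUBHAP_TAG",
              "H2_CONFIRM", "H2_CONFIRM"),
    stringsAsFactors = FALSE
  )
  class(p) <- c("tag_panel", "data.frame")
  validate_panel(p)
  p
}

#' Validate a tag-SNV panel
#'
#' Checks the structural invariants: positive positions, distinct ref/alt,
#' exactly one H1/H2-tagging SNV (rs1052553), exactly six
#' subhaplotype-tagging SNVs, and that the H2-confirming trio
#' rs1052553/rs199451/rs199533 is present.
#'
#' @param panel a \code{tag_panel} data frame.
#' @return The panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  need <- c("rsid", "chrom", "pos", "ref", "alt", "role")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (any(panel$pos <= 0)) stop("panel positions must be positive")
  if (any(panel$ref == panel$alt)) stop("panel ref and alt alleles must differ")
  if (anyDuplicated(panel$rsid)) stop("duplicated rsid in panel")
  h1h2 <- panel$rsid[panel$role == "H1H2_TAG"]
  if (!identical(h1h2, "rs1052553"))
    stop("panel must have exactly one H1H2_TAG SNV: rs1052553")
  if (sum(panel$role == "SUBHAP_TAG") != 6L)
    stop("panel must have exactly six SUBHAP_TAG SNVs")
  if (!all(h2_confirm_rsids() %in% panel$rsid))
    stop("panel must contain the H2-confirming trio: ",
         paste(h2_confirm_rsids(), collapse = ", "))
  invisible(panel)
}

#' @rdname tag_panel
#' @param panel a \code{tag_panel}.
#' @return \code{subhap_rsids}: the six subhaplotype-tag rsids in panel order.
#' @export
subhap_rsids <- function(panel = tag_panel()) {
  panel$rsid[panel$role == "SUBHAP_TAG"]
}

#' @rdname tag_panel
#' @return \code{h1h2_rsid}: the rsid of the H1/H2-tagging SNV.
#' @export
h1h2_rsid <- function(panel = tag_panel()) {
  panel$rsid[panel$role == "H1H2_TAG"]
}

#' @rdname tag_panel
#' @return \code{h2_confirm_rsids}: the three H2-confirming rsids.
#' @export
h2_confirm_rsids <- function(panel = NULL) {
  c("rs1052553", "rs199451", "rs199533")
}

# strip/add "chr" so "17" and "chr17" compare equal
norm_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))
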