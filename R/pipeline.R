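#' Run the full per-group haplotype analysis pipeline
#'
#' Orchestrates, independently for every group in the metadata (no pooled
#' fits): cohort filtering, H1/H2 diplotype calling, frequency tables, the
#' Hardy-Weinberg exact test in controls at rs1052553, allelic and
#' covariate-adjusted logistic association (one row per group x model),
#' age-at-onset analyses in cases, Bonferroni threshold flags, collapsed
#' subhaplotype assignment, and (optionally) Gini-importance ranking.
#' Failures in one group are recorded and do not stop the others. The
#' report bundle is written as TSV tables plus a JSON run log carrying the
#' package version, the configuration, and the nomenclature checksum; a
#' rerun with identical inputs and seeds reproduces the bundle byte for
#' byte.
#'
#' @param config a named list or a path to a YAML file with fields:
#'   \code{vcf}, \code{metadata} (paths, required); \code{exclusions},
#'   \code{nomenclature} (paths, optional); \code{covariate_sets}
#'   (default all three of \code{none}, \code{sex_pc}, \code{sex_age_pc});
#'   \code{alpha} (default 0.05); \code{n_tests_allele} (default 11) and
#'   \code{n_tests_subhap} (default 33), the Bonferroni test counts;
#'   \code{seed} (default 1); \code{ranking} (default TRUE);
#'   \code{n_trees} (default 500); \code{out_dir} (required).
#' @return Invisibly, a list with the result tables (\code{frequencies},
#'   \code{hwe}, \code{association}, \code{aao}, \code{ranking},
#'   \code{sample_log}) and \code{errors} (per-group failure messages).
#' @export
run_pipeline <- function(config) {
  config_path <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  defaults <- list(covariate_sets = c("none", "sex_pc", "sex_age_pc"),
                   alpha = 0.05, n_tests_allele = 11L, n_tests_subhap = 33L,
                   seed = 1L, ranking = TRUE, n_trees = 500L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("vcf", "metadata", "out_dir"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")

  panel <- tag_panel()
  nom <- if (is.null(config$nomenclature)) read_nomenclature()
         else read_nomenclature(config$nomenclature)
  g <- load_tag_genotypes(config$vcf, panel)
  meta <- load_metadata(config$metadata)
  excl <- if (is.null(config$exclusions)) character() else config$exclusions
  flt <- filter_cohort(g, meta, excl)
  g <- flt$genotypes
  meta <- flt$metadata

  sample_log <- rbind(
    data.frame(id = meta$id, group = ifelse(is.na(meta$group), "all",
                                            meta$group),
               disposition = "analyzed", stringsAsFactors = FALSE),
    data.frame(id = flt$removed$id, group = NA_character_,
               disposition = flt$removed$reason, stringsAsFactors = FALSE))

  grp <- ifelse(is.na(meta$group), "all", meta$group)
  freq_l <- hwe_l <- assoc_l <- aao_l <- rank_l <- list()
  errors <- list()
  for (gname in sort(unique(grp))) {
    res <- tryCatch({
      sel <- grp == gname
      gg <- geno_subset(g, meta$id[sel])
      mm <- meta[sel, , drop = FALSE]
      dip <- diplotypes(gg)
      col <- collapse_unphased(gg, nom)
      fr <- haplotype_frequencies(dip, mm, subhap = col$calls)

      dip_ctrl <- dip[mm$status == "control" & dip != "MISSING"]
      hw <- data.frame(group = gname, rsid = h1h2_rsid(panel),
                       n_homref = sum(dip_ctrl == "H1/H1"),
                       n_het = sum(dip_ctrl == "H1/H2"),
                       n_homalt = sum(dip_ctrl == "H2/H2"),
                       stringsAsFactors = FALSE)
      hw$p <- if (sum(hw[, 3:5]) > 0)
        hwe_exact_test(hw$n_homref, hw$n_het, hw$n_homalt) else NA_real_

      h1_count <- ifelse(dip == "MISSING", NA_integer_,
                         2L - (match(dip, c("H1/H1", "H1/H2", "H2/H2")) - 1L))
      ok <- !is.na(h1_count)
      st_case <- mm$status == "case"
      al <- allelic_association(
        case_a1 = sum(h1_count[ok & st_case]),
        case_a2 = sum(2 - h1_count[ok & st_case]),
        ctrl_a1 = sum(h1_count[ok & !st_case]),
        ctrl_a2 = sum(2 - h1_count[ok & !st_case]))
      lg <- lapply(config$covariate_sets, function(cs)
        logistic_association(mm, h1_count, cs))
      assoc <- cbind(group = gname, rbind(al, do.call(rbind, lg)))
      thr <- bonferroni_threshold(config$alpha, config$n_tests_allele)
      assoc$bonf_threshold <- thr
      assoc$bonf_significant <- !is.na(assoc$p) & assoc$p < thr

      aao <- cbind(group = gname,
                   aao_analysis(mm[st_case, , drop = FALSE],
                                h1_count[st_case]))

      rk <- NULL
      if (isTRUE(config$ranking)) {
        feats <- one_hot(col$calls)
        stat <- mm$status[match(rownames(feats), mm$id)]
        if (ncol(feats) >= 2L && length(unique(stat)) == 2L &&
              min(table(stat)) >= 2L) {
          rk <- cbind(group = gname,
                      rank_gini(feats, stat, seed = config$seed,
                                n_trees = config$n_trees))
        }
      }
      list(freq = cbind(fr), hwe = hw, assoc = assoc, aao = aao, rank = rk)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[gname]] <- conditionMessage(res)
      next
    }
    freq_l[[gname]] <- res$freq
    hwe_l[[gname]] <- res$hwe
    assoc_l[[gname]] <- res$assoc
    aao_l[[gname]] <- res$aao
    if (!is.null(res$rank)) rank_l[[gname]] <- res$rank
  }

  out <- list(frequencies = do.call(rbind, unname(freq_l)),
              hwe = do.call(rbind, unname(hwe_l)),
              association = do.call(rbind, unname(assoc_l)),
              aao = do.call(rbind, unname(aao_l)),
              ranking = if (length(rank_l)) do.call(rbind, unname(rank_l))
                        else NULL,
              sample_log = sample_log, errors = errors)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) if (!is.null(d))
    utils::write.table(d, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  wt(out$frequencies, "frequencies.tsv")
  wt(out$hwe, "hwe.tsv")
  wt(out$association, "association.tsv")
  wt(out$aao, "aao.tsv")
  wt(out$ranking, "ranking.tsv")
  wt(out$sample_log, "sample_log.tsv")
  log <- list(package = "tau17q",
              version = as.character(utils::packageVersion("tau17q")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              config = config[setdiff(names(config), "out_dir")],
              config_file_md5 = if (!is.na(config_path))
                unname(tools::md5sum(config_path)) else NA,
              nomenclature_md5 = nomenclature_checksum(nom),
              errors = errors)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out)
}

#' Presentation plots for pipeline tables
#'
#' \code{plot_frequencies} draws the per-group H1/H2 allele frequency bars
#' in cases vs controls; \code{plot_forest} draws the per-group odds-ratio
#' forest plot with 95\% CIs. Both return ggplot objects (requires
#' \pkg{ggplot2}) and are presentation-only: no analysis depends on them.
#'
#' @param frequencies the \code{frequencies} table from
#'   \code{\link{run_pipeline}}.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(frequencies) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- frequencies[frequencies$metric == "allele" &
                     frequencies$category == "H2", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$freq,
                                  fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "H2 allele frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_frequencies
#' @param association the \code{association} table from
#'   \code{\link{run_pipeline}}.
#' @param model which model tag to plot (default the allelic test).
#' @export
plot_forest <- function(association, model = "allelic_chisq") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- association[association$model == model & !is.na(association$or), ,
                   drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (H1, per allele)", y = NULL) +
    ggplot2::theme_minimal()
}
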