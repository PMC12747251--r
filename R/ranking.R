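#' One-hot encode per-sample subhaplotype labels
#'
#' Converts per-sample subhaplotype assignments (one label per sample, as
#' produced by \code{\link{collapse_unphased}}) to a binary indicator
#' matrix with one column per distinct label. Each row sums to 1.
#'
#' @param calls data frame with \code{id} and \code{label} columns (samples
#'   with \code{NA} labels are dropped).
#' @return Integer indicator matrix, rownames = sample ids, colnames =
#'   labels (in decreasing frequency order).
#' @export
one_hot <- function(calls) {
  calls <- calls[!is.na(calls$label), , drop = FALSE]
  labs <- names(sort(table(calls$label), decreasing = TRUE))
  m <- matrix(0L, nrow(calls), length(labs),
              dimnames = list(calls$id, labs))
  m[cbind(seq_len(nrow(calls)), match(calls$label, labs))] <- 1L
  m
}

#' Rank subhaplotypes by Gini importance
#'
#' Fits an ensemble of extremely randomized classification trees (random
#' split thresholds, Gini impurity splitting; \pkg{ranger} with
#' \code{splitrule = "extratrees"}) of case/control status on the one-hot
#' subhaplotype indicators, and ranks features by Gini importance: each
#' feature's total Gini-impurity reduction accumulated over all splits on
#' it, averaged over trees and normalized to sum to 1. All features are
#' candidates at every split (the feature count is small), trees are grown
#' to purity, and the fit is single-threaded and seeded, so the ranking is
#' deterministic given \code{seed}.
#'
#' @param features binary feature matrix from \code{\link{one_hot}}.
#' @param status character/factor vector aligned with feature rows
#'   (\code{"case"}/\code{"control"}); both classes must be present with at
#'   least 2 samples each.
#' @param seed integer RNG seed.
#' @param n_trees ensemble size (default 500).
#' @return A data frame (class \code{importance_ranking}) with columns
#'   \code{label}, \code{importance}, \code{rank}, sorted by decreasing
#'   importance; attributes \code{seed} and \code{n_trees}.
#' @export
rank_gini <- function(features, status, seed = 1L, n_trees = 500L) {
  status <- as.character(status)
  if (length(status) != nrow(features))
    stop("status length must match feature rows")
  tab <- table(status)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 samples in each of two classes")
  d <- as.data.frame(features)
  names(d) <- colnames(features)
  d$.y <- factor(status)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = n_trees, mtry = ncol(features),
    splitrule = "extratrees", num.random.splits = 1L,
    importance = "impurity", min.node.size = 1L,
    replace = TRUE, num.threads = 1L, seed = seed,
    respect.unordered.factors = "ignore", verbose = FALSE)
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  total <- sum(imp)
  imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  ord <- order(-imp, names(imp))
  out <- data.frame(label = names(imp)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_trees") <- n_trees
  class(out) <- c("importance_ranking", "data.frame")
  out
}
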