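# The FAIME transformation: per-sample exponentially rank-weighted expression
# turned into geneset "mechanism" scores.
#
# For one sample s with measured gene universe G, genes are ranked by
# expression (highest expression -> rank |G|, ties averaged) and weighted
#
#   w_{g,s} = r_{g,s} * exp(-r_{g,s} / |G|),
#
# a weight that increases with rank on [1, |G|], so the highest-expressed
# genes dominate. The raw score of a geneset is the difference between the
# mean weight of its members (the set's normalized centroid) and the mean
# weight of its complement within G. Raw scores are rescaled within each
# sample by subtracting that sample's minimum raw score across the
# mechanisms of one collection, so the per-sample minimum rescaled score is
# exactly 0.

#' Rank one sample's expression values
#'
#' With the default orientation the highest-expressed gene receives rank
#' `|G|` and therefore the maximal weight under [compute_weights()]; tied
#' values receive the average of their would-be ranks. The inverse
#' orientation (`"low-is-max"`) is exposed for sensitivity analysis only.
#'
#' @param x numeric vector of one sample's expression values (length >= 2,
#'   all finite).
#' @param orientation `"high-is-max"` (default) or `"low-is-max"`.
#' @return numeric vector of ranks in `[1, length(x)]`, names preserved.
#' @export
rank_sample <- function(x, orientation = c("high-is-max", "low-is-max")) {
  orientation <- match.arg(orientation)
  if (length(x) < 2L) stop_faime("need at least 2 genes to rank")
  if (!all(is.finite(x))) stop_faime("expression values must be finite")
  r <- rank(x, ties.method = "average")
  if (orientation == "low-is-max") r <- length(x) + 1 - r
  r
}

#' Exponential rank weights
#'
#' Computes `w = r * exp(-r / n_genes)` elementwise. On `[1, n_genes]` this
#' is monotone increasing, so higher ranks (higher expression under the
#' default orientation) receive larger weights.
#'
#' @param ranks ranks from [rank_sample()].
#' @param n_genes the universe size `|G|`.
#' @return numeric weight vector, names preserved.
#' @export
compute_weights <- function(ranks, n_genes = length(ranks)) {
  if (any(ranks < 1 | ranks > n_genes))
    stop_faime("ranks must lie in [1, n_genes]")
  ranks * exp(-ranks / n_genes)
}

#' Raw FAIME score of one geneset in one sample
#'
#' The difference between the mean weight of the member genes and the mean
#' weight of the non-member (complement) genes within the measured universe.
#'
#' @param weights named weight vector for one sample (the full universe).
#' @param member_genes character vector of member gene ids.
#' @return scalar raw score.
#' @export
faime_raw_score <- function(weights, member_genes) {
  idx <- match(member_genes, names(weights))
  if (anyNA(idx))
    stop_faime("member gene(s) absent from the weight vector: ",
               paste(member_genes[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) stop_faime("member set is empty")
  if (length(idx) == length(weights))
    stop_faime("degenerate set equal to the full universe: complement empty")
  mean(weights[idx]) - mean(weights[-idx])
}

#' Transform an expression matrix into mechanism scores
#'
#' Applies the rank-weighting and centroid-difference score to every
#' mechanism and sample, then rescales within each sample by subtracting the
#' per-sample minimum raw score across the mechanisms of this collection
#' (collections are never pooled for the minimum).
#'
#' @param expr gene-by-sample numeric matrix (see [read_expression_tsv()]).
#' @param coll a [geneset_collection()], already filtered against `expr`
#'   (see [filter_collection()]); sets are intersected with the measured
#'   universe here and must remain non-empty and proper subsets.
#' @param orientation rank orientation, see [rank_sample()].
#' @return an object of class `FaimeScores`: list with `raw` and `rescaled`
#'   mechanism-by-sample matrices, `collection` (source label) and
#'   `orientation`.
#' @export
faime_transform <- function(expr, coll,
                            orientation = c("high-is-max", "low-is-max")) {
  orientation <- match.arg(orientation)
  validate_expression(expr)
  stopifnot(inherits(coll, "GeneSetCollection"))
  universe <- rownames(expr)
  n_genes <- length(universe)
  sets <- lapply(coll$sets, function(s) s[s %in% universe])
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    stop_faime("set(s) with no measured genes: ",
               paste(names(sets)[sizes == 0L], collapse = ", "))
  if (any(sizes == n_genes))
    stop_faime("set(s) equal to the measured universe: ",
               paste(names(sets)[sizes == n_genes], collapse = ", "))
  if (length(sets) < 2L)
    warning("collection has a single mechanism: rescaling forces its score to 0",
            call. = FALSE)

  ranks <- apply(expr, 2L, rank, ties.method = "average")
  if (orientation == "low-is-max") ranks <- n_genes + 1 - ranks
  w <- ranks * exp(-ranks / n_genes)

  # 0/1 membership matrix (mechanisms x genes); centroid sums by matmul
  memb <- matrix(0, nrow = length(sets), ncol = n_genes,
                 dimnames = list(names(sets), universe))
  for (i in seq_along(sets)) memb[i, sets[[i]]] <- 1
  set_sums <- memb %*% w
  tot <- matrix(colSums(w), nrow = length(sets), ncol = ncol(expr),
                byrow = TRUE)
  raw <- set_sums / sizes - (tot - set_sums) / (n_genes - sizes)
  colnames(raw) <- colnames(expr)
  rescaled <- sweep(raw, 2L, apply(raw, 2L, min))
  structure(list(raw = raw, rescaled = rescaled,
                 collection = coll$source_label, orientation = orientation),
            class = "FaimeScores")
}

#' @export
print.FaimeScores <- function(x, ...) {
  cat("FaimeScores: ", nrow(x$raw), " mechanisms x ", ncol(x$raw),
      " samples (collection '", x$collection, "', orientation ",
      x$orientation, ")\n", sep = "")
  invisible(x)
}

#' Write FAIME scores as TSV
#'
#' @param scores a [faime_transform()] result.
#' @param path output path.
#' @param which `"rescaled"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, which = c("rescaled", "raw")) {
  which <- match.arg(which)
  stopifnot(inherits(scores, "FaimeScores"))
  write_matrix_tsv(scores[[which]], path, id_col = "mechanism_id")
}

#' Read a mechanism-by-sample score matrix written by [write_scores()]
#'
#' @param path TSV path.
#' @return numeric matrix, mechanisms in rows.
#' @export
read_scores_tsv <- function(path) {
  m <- read_expression_tsv(path)
  m
}
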