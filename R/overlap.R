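# Cross-dataset signature comparison: directional mechanism intersection
# with per-signature percentages, a one-sided Fisher exact (hypergeometric)
# p-value for pairwise overlap, and a fixed-size subset bootstrap giving an
# empirical p-value for gene-level overlap between two signatures drawn
# from their respective measured backgrounds.

#' Directional intersection of two or more signatures
#'
#' A mechanism is in the overlap only if it appears in every signature with
#' the same deregulation direction. Percentages are reported against each
#' signature's own size. When exactly two signatures are given and
#' `universe_size` is supplied, a one-sided Fisher exact p-value for the
#' overlap (ignoring direction concordance in the null model) is attached.
#'
#' @param signatures list of [build_signature()] objects (>= 2) over the
#'   same collection; signatures from different collections are rejected.
#' @param universe_size optional size of the common tested universe
#'   (mechanisms tested in all datasets) for the Fisher test.
#' @return object of class `OverlapResult`: list with `labels`, `n_overlap`,
#'   `sizes`, `pct_of_each`, `mechanisms` (data.frame id, direction) and
#'   `fet_p` (or `NA`).
#' @export
directional_intersect <- function(signatures, universe_size = NULL) {
  stopifnot(is.list(signatures), length(signatures) >= 2L,
            all(vapply(signatures, inherits, TRUE, "DirectionalSignature")))
  colls <- unique(unlist(lapply(signatures, function(s) s$collection)))
  if (length(colls) > 1L)
    stop_faime("signatures come from different collections: ",
               paste(colls, collapse = " vs "))
  ov <- signatures[[1L]]$entries
  for (s in signatures[-1L]) {
    ov <- merge(ov, s$entries, by = c("mechanism_id", "direction"))
  }
  ov <- ov[order(ov$mechanism_id), , drop = FALSE]
  rownames(ov) <- NULL
  sizes <- vapply(signatures, function(s) nrow(s$entries), 0L)
  labels <- vapply(signatures, function(s) s$label, "")
  pct <- ifelse(sizes > 0, 100 * nrow(ov) / sizes, NA_real_)
  fet <- NA_real_
  if (length(signatures) == 2L && !is.null(universe_size)) {
    fet <- fisher_overlap_p(nrow(ov), sizes[1L], sizes[2L], universe_size)
  }
  structure(list(labels = labels, n_overlap = nrow(ov), sizes = sizes,
                 pct_of_each = pct, mechanisms = ov, fet_p = fet),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat("Overlap of ", paste(x$labels, collapse = " & "), ": ", x$n_overlap,
      " mechanisms (", paste0(round(x$pct_of_each), "%", collapse = "; "),
      ")", sep = "")
  if (!is.na(x$fet_p)) cat(", FET p = ", format(x$fet_p, digits = 3), sep = "")
  cat("\n")
  invisible(x)
}

#' One-sided Fisher exact overlap p-value
#'
#' Upper-tail hypergeometric probability `P(X >= n_overlap)` of drawing at
#' least the observed overlap when a set of `size_b` items is sampled from a
#' universe of `universe_size` containing `size_a` marked items.
#'
#' @param n_overlap observed overlap count.
#' @param size_a,size_b the two set sizes.
#' @param universe_size common universe size.
#' @return p-value in (0, 1].
#' @export
fisher_overlap_p <- function(n_overlap, size_a, size_b, universe_size) {
  if (n_overlap < 0 || n_overlap > min(size_a, size_b) ||
      max(size_a, size_b) > universe_size)
    stop_faime("inconsistent overlap counts: need overlap <= min sizes <= universe")
  stats::phyper(n_overlap - 1, size_a, universe_size - size_a, size_b,
                lower.tail = FALSE)
}

#' Constituent genes of a signature
#'
#' Union of member genes over the signature's mechanisms; direction is
#' ignored at gene level.
#'
#' @param signature a `DirectionalSignature`.
#' @param coll the [geneset_collection()] the signature was derived against.
#' @return character vector of gene ids (sorted, unique).
#' @export
signature_genes <- function(signature, coll) {
  stopifnot(inherits(signature, "DirectionalSignature"),
            inherits(coll, "GeneSetCollection"))
  ids <- signature$entries$mechanism_id
  missing <- setdiff(ids, names(coll$sets))
  if (length(missing) > 0L)
    stop_faime("mechanism(s) absent from collection: ",
               paste(missing, collapse = ", "))
  sort(unique(unlist(coll$sets[ids], use.names = FALSE)))
}

#' Bootstrap empirical p-value for gene-level overlap
#'
#' Repeatedly draws `|genes_a|` genes uniformly without replacement from
#' `background_a` and `|genes_b|` from `background_b`, counts the draws
#' whose intersection is at least the observed overlap `|genes_a ∩
#' genes_b|`, and reports the add-one-corrected empirical p-value
#' `(n_at_least + 1) / (n_draws + 1)`. With `background_b` set to a
#' reference gene list's universe the same operation covers comparison of a
#' signature against an external cancer-gene catalogue.
#'
#' @param genes_a,genes_b the two observed gene sets.
#' @param background_a,background_b the measured backgrounds the sets were
#'   drawn from; each set must be a subset of its background.
#' @param n_draws number of bootstrap draws (default 10000).
#' @param seed integer seed; required, recorded in the result.
#' @return object of class `BootstrapOverlapResult`: list with
#'   `observed_overlap`, `n_draws`, `n_at_least`, `empirical_p`, `seed`.
#' @export
bootstrap_overlap_p <- function(genes_a, genes_b, background_a, background_b,
                                n_draws = 10000L, seed) {
  if (missing(seed)) stop_faime("seed is required for bootstrap_overlap_p")
  stopifnot(n_draws >= 1L)
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  background_a <- unique(background_a); background_b <- unique(background_b)
  if (!all(genes_a %in% background_a))
    stop_faime("genes_a is not a subset of background_a")
  if (!all(genes_b %in% background_b))
    stop_faime("genes_b is not a subset of background_b")
  observed <- length(intersect(genes_a, genes_b))
  universe <- union(background_a, background_b)
  ia <- match(background_a, universe)
  ib <- match(background_b, universe)
  na <- length(genes_a); nb <- length(genes_b)
  n_at_least <- with_seed(seed, {
    hits <- 0L
    memb <- logical(length(universe))
    for (d in seq_len(n_draws)) {
      da <- ia[sample.int(length(ia), na)]
      db <- ib[sample.int(length(ib), nb)]
      memb[da] <- TRUE
      ov <- sum(memb[db])
      memb[da] <- FALSE
      if (ov >= observed) hits <- hits + 1L
    }
    hits
  })
  structure(list(observed_overlap = observed, n_draws = as.integer(n_draws),
                 n_at_least = n_at_least,
                 empirical_p = (n_at_least + 1) / (n_draws + 1),
                 seed = as.integer(seed)),
            class = "BootstrapOverlapResult")
}

#' @export
print.BootstrapOverlapResult <- function(x, ...) {
  cat("Bootstrap overlap: observed ", x$observed_overlap, ", ",
      x$n_at_least, "/", x$n_draws, " draws at or above, empirical p = ",
      format(x$empirical_p, digits = 3), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
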