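# Independent oracles, written as direct loop-level transcriptions of the
# definitions, deliberately sharing no code with the implementation.

# Average-tie ranks computed from scratch (no call to rank()).
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    # positions below+1 .. below+ties are shared; average them
    r[i] <- below + (ties + 1) / 2
  }
  r
}

# Loop-level transcription of the rank-weight / centroid-difference /
# per-sample-min-rescale transformation.
oracle_faime <- function(expr, sets) {
  n_genes <- nrow(expr)
  raw <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    r <- oracle_ranks(expr[, s])
    w <- r * exp(-r / n_genes)
    names(w) <- rownames(expr)
    for (i in seq_along(sets)) {
      members <- intersect(sets[[i]], rownames(expr))
      comp <- setdiff(rownames(expr), members)
      nc_in <- sum(w[members]) / length(members)
      nc_out <- sum(w[comp]) / length(comp)
      raw[i, s] <- nc_in - nc_out
    }
  }
  rescaled <- raw
  for (s in seq_len(ncol(raw))) rescaled[, s] <- raw[, s] - min(raw[, s])
  list(raw = raw, rescaled = rescaled)
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# size_b from the universe and count overlaps >= n_overlap with a fixed
# marked set of size_a. Feasible for universes <= 12.
oracle_fisher <- function(n_overlap, size_a, size_b, universe_size) {
  marked <- seq_len(size_a)
  draws <- utils::combn(universe_size, size_b)
  hits <- sum(apply(draws, 2L, function(d) sum(d %in% marked) >= n_overlap))
  hits / ncol(draws)
}

# Step-up BH by literal definition: q_i = min over j with p_j >= p_i of
# m * p_(j) / rank_max(p_(j)), via sorting.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  # literal form: for each i, min_{j>=i} m p_(j) / j
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * p[ord][j] / j)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Random small FAIME instance: expression matrix plus genesets.
random_instance <- function(n_genes, n_samples, n_sets, with_ties = TRUE) {
  genes <- paste0("g", seq_len(n_genes))
  vals <- if (with_ties)
    sample(seq_len(max(3L, n_genes %/% 2L)), n_genes * n_samples, replace = TRUE)
  else stats::rnorm(n_genes * n_samples)
  expr <- matrix(as.numeric(vals), n_genes, n_samples,
                 dimnames = list(genes, paste0("s", seq_len(n_samples))))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(2:(n_genes - 1L), 1L)))
  names(sets) <- paste0("m", seq_len(n_sets))
  list(expr = expr, sets = sets)
}

# Total dissimilarity of a 2-medoid configuration on a distance matrix.
config_cost <- function(d, medoids) sum(pmin(d[, medoids[1L]], d[, medoids[2L]]))
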