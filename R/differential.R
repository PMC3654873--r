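# Directional differential-mechanism signatures: per-mechanism two-sample
# t-test on rescaled FAIME scores, Benjamini-Hochberg adjustment, FDR
# thresholding, and a direction (+1 up in the case group, -1 down) from the
# sign of the group mean difference. A positive mechanism score difference
# indicates that the bulk of the set's member genes sit higher in the
# tumor samples' expression ranking than in the normals'.

#' Per-mechanism two-group t-tests on FAIME scores
#'
#' Runs a two-sided two-sample t-test for every mechanism, Student (pooled
#' variance, the default) or Welch. Mechanisms with zero variance in both
#' groups and no mean difference get `t = 0, p = 1`. Direction is the sign
#' of `mean(case) - mean(control)` on the scores tested.
#'
#' @param scores a [faime_transform()] result, or a mechanism-by-sample
#'   numeric matrix.
#' @param groups named vector mapping sample id to one of exactly two group
#'   labels; every scored sample must be labeled, each group needs >= 2
#'   samples.
#' @param case label of the case (tumor) group; defaults to `"tumor"` when
#'   present, otherwise the alphabetically later label (with a message).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param use which score matrix to test when `scores` is a `FaimeScores`
#'   object: `"rescaled"` (default, the within-sample normalized scores) or
#'   `"raw"`.
#' @return data.frame with one row per mechanism: `mechanism_id`,
#'   `t_statistic`, `p_value`, `q_value`, `direction` (+1/-1, 0 for exact
#'   zero difference), `mean_case`, `mean_control`; attributes `case`,
#'   `control` and `collection` record the contrast.
#' @export
test_mechanisms <- function(scores, groups, case = NULL,
                            variant = c("student", "welch"),
                            use = c("rescaled", "raw")) {
  variant <- match.arg(variant)
  use <- match.arg(use)
  collection <- NULL
  if (inherits(scores, "FaimeScores")) {
    collection <- scores$collection
    scores <- scores[[use]]
  }
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  samples <- colnames(scores)
  if (!all(samples %in% names(groups)))
    stop_faime("unlabeled sample(s): ",
               paste(setdiff(samples, names(groups)), collapse = ", "))
  g <- groups[samples]
  labs <- sort(unique(g))
  if (length(labs) != 2L)
    stop_faime("need exactly 2 group labels, found ", length(labs))
  if (is.null(case)) {
    case <- if ("tumor" %in% labs) "tumor" else labs[2L]
    message("case group not specified; using '", case, "'")
  }
  if (!case %in% labs) stop_faime("case label '", case, "' not among groups")
  control <- setdiff(labs, case)
  i1 <- which(g == case)
  i2 <- which(g == control)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop_faime("each group needs >= 2 samples")

  x1 <- scores[, i1, drop = FALSE]
  x2 <- scores[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  d <- m1 - m2
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- d / se
  degenerate <- se == 0
  if (any(degenerate & d == 0)) {
    tstat[degenerate & d == 0] <- 0
    message(sum(degenerate & d == 0),
            " mechanism(s) with zero variance and zero difference: t = 0, p = 1")
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate & d == 0] <- 1
  p[degenerate & d != 0] <- 0  # infinite t: separation is exact
  out <- data.frame(mechanism_id = rownames(scores),
                    t_statistic = tstat,
                    p_value = p,
                    q_value = bh_adjust(p),
                    direction = sign(d),
                    mean_case = m1,
                    mean_control = m2,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "case") <- case
  attr(out, "control") <- control
  attr(out, "collection") <- collection
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up adjusted values `q_(i) = min_{j >= i} m p_(j) / j`
#' (capped at 1) directly; `q >= p` elementwise and sorted `q` is monotone
#' with sorted `p`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop_faime("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_faime("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(stepped))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Build a directional signature at a stated FDR level
#'
#' Retains mechanisms with `q <= fdr_level`; mechanisms with an exact zero
#' group-mean difference carry no direction and are excluded. The signature
#' records its size as a count and as a percentage of the tested collection.
#'
#' @param records output of [test_mechanisms()].
#' @param fdr_level FDR threshold in (0, 1); conventional choices are 0.05
#'   and 0.01.
#' @param label text label for the signature (e.g. the dataset name).
#' @return object of class `DirectionalSignature`: list with `label`,
#'   `fdr_level`, `entries` (data.frame `mechanism_id`, `direction`),
#'   `n_tested`, `pct` and `collection`.
#' @export
build_signature <- function(records, fdr_level = 0.05, label = "signature") {
  stopifnot(is.data.frame(records),
            all(c("mechanism_id", "q_value", "direction") %in% names(records)))
  if (!(fdr_level > 0 && fdr_level < 1))
    stop_faime("fdr_level must lie in (0, 1)")
  keep <- records$q_value <= fdr_level & records$direction != 0
  entries <- records[keep, c("mechanism_id", "direction"), drop = FALSE]
  rownames(entries) <- NULL
  if (nrow(entries) == 0L)
    warning("signature '", label, "' is empty at FDR ", fdr_level,
            call. = FALSE)
  if (anyDuplicated(entries$mechanism_id))
    stop_faime("duplicate mechanism ids in test records")
  structure(list(label = label, fdr_level = fdr_level, entries = entries,
                 n_tested = nrow(records),
                 pct = 100 * nrow(entries) / nrow(records),
                 collection = attr(records, "collection")),
            class = "DirectionalSignature")
}

#' @export
print.DirectionalSignature <- function(x, ...) {
  cat("DirectionalSignature '", x$label, "' at FDR ", x$fdr_level, ": ",
      round(x$pct), "% (", nrow(x$entries), ") of ", x$n_tested,
      " mechanisms (", sum(x$entries$direction > 0), " up, ",
      sum(x$entries$direction < 0), " down)\n", sep = "")
  invisible(x)
}

#' Write a signature (or full test table) as TSV
#'
#' @param x a `DirectionalSignature` or the [test_mechanisms()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(x, path) {
  df <- if (inherits(x, "DirectionalSignature")) x$entries else x
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path TSV with columns `mechanism_id` and `direction`.
#' @param fdr_level,label metadata to attach (the file does not carry them).
#' @return a `DirectionalSignature`.
#' @export
read_signature <- function(path, fdr_level = 0.05, label = basename(path)) {
  df <- fread_tsv(path, sep = "\t", header = TRUE, data.table = FALSE)
  stopifnot(all(c("mechanism_id", "direction") %in% names(df)))
  structure(list(label = label, fdr_level = fdr_level,
                 entries = df[, c("mechanism_id", "direction")],
                 n_tested = NA_integer_, pct = NA_real_, collection = NULL),
            class = "DirectionalSignature")
}
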