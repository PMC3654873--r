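# Prognostic stratification: restrict the validation cohort's mechanism
# scores to a signature, split samples into two groups with a deterministic
# classic PAM (k-medoids, BUILD then SWAP on Euclidean distances), and test
# recurrence-free survival separation with the Kaplan-Meier product-limit
# estimator and the two-group log-rank test.

#' Restrict a score matrix to a signature's mechanisms
#'
#' @param scores a [faime_transform()] result or mechanism-by-sample matrix.
#' @param signature a `DirectionalSignature` (or character vector of
#'   mechanism ids).
#' @param use which matrix of a `FaimeScores` object to use.
#' @return mechanism-by-sample matrix restricted to the signature's
#'   mechanisms present; warns listing absent mechanisms, errors if none
#'   remain.
#' @export
restrict_scores <- function(scores, signature, use = c("rescaled", "raw")) {
  use <- match.arg(use)
  if (inherits(scores, "FaimeScores")) scores <- scores[[use]]
  stopifnot(is.matrix(scores))
  ids <- if (inherits(signature, "DirectionalSignature"))
    signature$entries$mechanism_id else as.character(signature)
  absent <- setdiff(ids, rownames(scores))
  if (length(absent) == length(ids))
    stop_faime("no signature mechanisms present in the score matrix")
  if (length(absent) > 0L)
    warning("mechanism(s) absent from the validation collection: ",
            paste(absent, collapse = ", "), call. = FALSE)
  scores[intersect(ids, rownames(scores)), , drop = FALSE]
}

#' Two-group k-medoids (PAM) partition of samples
#'
#' Classic deterministic PAM with k = 2: greedy BUILD initialisation
#' followed by SWAP steps (best-improving single medoid swap) to a local
#' optimum, on Euclidean distances between the samples' score vectors.
#' Ties are broken by input sample order, so the result is reproducible
#' without a seed.
#'
#' @param scores a [faime_transform()] result or mechanism-by-sample matrix
#'   (samples in columns); >= 4 samples required.
#' @param standardize if `TRUE`, per-mechanism z-scaling before distances
#'   (default `FALSE`: distances on the scores as given).
#' @param use which matrix of a `FaimeScores` object to use.
#' @return object of class `CohortAssignment`: list with `cluster` (named
#'   1/2 vector), `medoids` (two sample ids), `total_dissimilarity`.
#' @export
pam_partition <- function(scores, standardize = FALSE,
                          use = c("rescaled", "raw")) {
  use <- match.arg(use)
  if (inherits(scores, "FaimeScores")) scores <- scores[[use]]
  stopifnot(is.matrix(scores))
  if (ncol(scores) < 4L) stop_faime("need >= 4 samples to partition")
  x <- t(scores)
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  d <- as.matrix(stats::dist(x))
  fit <- pam_k2(d)
  cl <- fit$cluster
  names(cl) <- colnames(scores)
  structure(list(cluster = cl,
                 medoids = colnames(scores)[fit$medoids],
                 total_dissimilarity = fit$cost),
            class = "CohortAssignment")
}

# Classic PAM for k = 2 on a full distance matrix. Deterministic: BUILD picks
# the first index attaining each minimum; SWAP applies the best-improving
# swap (ties by enumeration order) until no swap strictly improves the total
# dissimilarity (tolerance 1e-12 guards float noise).
pam_k2 <- function(d) {
  n <- nrow(d)
  cost_of <- function(m1, m2) sum(pmin(d[, m1], d[, m2]))
  # BUILD: first medoid minimizes total distance; second minimizes joint cost
  m1 <- which.min(colSums(d))
  costs <- vapply(seq_len(n), function(j)
    if (j == m1) Inf else cost_of(m1, j), 0)
  m2 <- which.min(costs)
  med <- c(m1, m2)
  cost <- cost_of(med[1L], med[2L])
  repeat {
    best <- list(cost = cost, med = med)
    for (mi in 1:2) {
      keep <- med[3L - mi]
      for (h in seq_len(n)) {
        if (h %in% med) next
        cst <- cost_of(keep, h)
        if (cst < best$cost - 1e-12) best <- list(cost = cst, med = sort(c(keep, h)))
      }
    }
    if (best$cost >= cost - 1e-12) break
    med <- best$med
    cost <- best$cost
  }
  assign_ <- ifelse(d[, med[1L]] <= d[, med[2L]], 1L, 2L)
  assign_[med] <- c(1L, 2L)
  list(medoids = med, cluster = assign_, cost = cost)
}

#' @export
print.CohortAssignment <- function(x, ...) {
  cat("CohortAssignment: clusters of size ", sum(x$cluster == 1L), " and ",
      sum(x$cluster == 2L), "; medoids ", paste(x$medoids, collapse = ", "),
      "; total dissimilarity ", format(x$total_dissimilarity, digits = 6),
      "\n", sep = "")
  invisible(x)
}

# Align a survival table with a cohort assignment; errors on missing data.
align_survival <- function(surv, assignment) {
  cl <- if (inherits(assignment, "CohortAssignment")) assignment$cluster
        else assignment
  missing <- setdiff(names(cl), surv$sample_id)
  if (length(missing) > 0L)
    stop_faime("no survival data for sample(s): ",
               paste(missing, collapse = ", "))
  idx <- match(names(cl), surv$sample_id)
  data.frame(sample_id = names(cl), time = surv$time[idx],
             event = surv$event[idx], group = as.integer(cl),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit curves per cluster
#'
#' @param surv data.frame with `sample_id`, `time`, `event` (1 = event
#'   observed, 0 = censored), see [read_survival_tsv()].
#' @param assignment a [pam_partition()] result (or named cluster vector).
#' @return named list of data.frames (one per group), each with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`; the curve starts
#'   at S(0) = 1 and steps down only at event times.
#' @export
km_estimate <- function(surv, assignment) {
  df <- align_survival(surv, assignment)
  out <- lapply(split(df, df$group), function(g) {
    if (nrow(g) == 0L) stop_faime("empty group in KM estimate")
    tms <- sort(unique(g$time))
    n_risk <- n_event <- n_censor <- integer(length(tms))
    s <- numeric(length(tms))
    surv_now <- 1
    for (i in seq_along(tms)) {
      t0 <- tms[i]
      n_risk[i] <- sum(g$time >= t0)
      n_event[i] <- sum(g$time == t0 & g$event == 1)
      n_censor[i] <- sum(g$time == t0 & g$event == 0)
      if (n_event[i] > 0) surv_now <- surv_now * (1 - n_event[i] / n_risk[i])
      s[i] <- surv_now
    }
    data.frame(time = tms, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = s)
  })
  names(out) <- paste0("cluster", names(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom: at each distinct
#' event time the observed minus expected events in group 1 are accumulated
#' with the hypergeometric variance; simultaneous events (ties) are handled
#' by the usual convention of a single risk table per distinct time.
#'
#' @inheritParams km_estimate
#' @return object of class `LogRankResult`: list with `chi_square`,
#'   `p_value`, `n` and `events` per group, and `km` (the [km_estimate()]
#'   curves).
#' @export
logrank_test <- function(surv, assignment) {
  df <- align_survival(surv, assignment)
  if (length(unique(df$group)) != 2L)
    stop_faime("log-rank test requires exactly 2 groups")
  ev_times <- sort(unique(df$time[df$event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t0 in ev_times) {
    at_risk <- df$time >= t0
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & df$group == 1L)
    d_j <- sum(df$time == t0 & df$event == 1)
    d1_j <- sum(df$time == t0 & df$event == 1 & df$group == 1L)
    e1_j <- d_j * n1_j / n_j
    o_minus_e <- o_minus_e + (d1_j - e1_j)
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (length(ev_times) == 0L || v == 0) {
    if (length(ev_times) == 0L)
      warning("no events in either group: statistic 0, p = 1", call. = FALSE)
    chi <- 0
    p <- 1
  } else {
    chi <- o_minus_e^2 / v
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(chi_square = chi, p_value = p,
                 n = table(df$group), events = tapply(df$event, df$group, sum),
                 km = km_estimate(surv, assignment)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat("Log-rank test: chi-square = ", format(x$chi_square, digits = 4),
      " (1 df), p = ", format(x$p_value, digits = 4), "; n = ",
      paste(x$n, collapse = "/"), ", events = ",
      paste(x$events, collapse = "/"), "\n", sep = "")
  invisible(x)
}
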