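mk_sig <- function(ids, dirs = rep(1, length(ids))) {
  structure(list(label = "sig", fdr_level = 0.05,
                 entries = data.frame(mechanism_id = ids, direction = dirs),
                 n_tested = length(ids), pct = 100, collection = "test"),
            class = "DirectionalSignature")
}

test_that("restrict_scores keeps signature rows and reports absences", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("m", 1:10), paste0("s", 1:4)))
  full <- restrict_scores(m, mk_sig(paste0("m", 1:4)))
  expect_identical(rownames(full), paste0("m", 1:4))
  expect_warning(part <- restrict_scores(m, mk_sig(c("m1", "m2", "mX"))),
                 "mX")
  expect_identical(nrow(part), 2L)
  expect_error(restrict_scores(m, mk_sig(c("zz", "yy"))), "no signature")
})

test_that("pam_partition recovers separable clouds and the 1-D toy instance", {
  withr::local_seed(31)
  cloud <- cbind(matrix(rnorm(5 * 10, mean = 0, sd = 0.1), 5),
                 matrix(rnorm(5 * 10, mean = 10, sd = 0.1), 5))
  dimnames(cloud) <- list(paste0("m", 1:5), paste0("s", 1:20))
  asg <- pam_partition(cloud)
  expect_equal(unname(asg$cluster[1:10]), rep(asg$cluster[[1]], 10))
  expect_equal(unname(asg$cluster[11:20]), rep(asg$cluster[[11]], 10))
  expect_false(asg$cluster[[1]] == asg$cluster[[11]])

  line <- matrix(c(0, 1, 10, 11), 1, dimnames = list("m1", paste0("s", 1:4)))
  a2 <- pam_partition(line)
  expect_equal(unname(a2$cluster), c(1L, 1L, 2L, 2L))
  # exhaustive check: chosen medoids attain the minimal total dissimilarity
  d <- as.matrix(dist(t(line)))
  costs <- combn(4, 2, function(p) config_cost(d, p))
  expect_equal(a2$total_dissimilarity, min(costs))
})

test_that("pam partition is invariant to sample order (up to label swap)", {
  withr::local_seed(17)
  x <- cbind(matrix(rnorm(3 * 6, 0, 0.3), 3), matrix(rnorm(3 * 6, 5, 0.3), 3))
  dimnames(x) <- list(paste0("m", 1:3), paste0("s", 1:12))
  base <- pam_partition(x)$cluster
  perm <- sample(12)
  shuffled <- pam_partition(x[, perm])$cluster
  aligned <- shuffled[names(base)]
  agree <- mean(aligned == base)
  expect_true(agree == 1 || agree == 0)  # identical partition, labels may flip
})

test_that("pam reaches a swap-local optimum on random small instances", {
  withr::local_seed(53)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(3 * n), 3, dimnames = list(paste0("m", 1:3),
                                                 paste0("s", 1:n)))
    asg <- pam_partition(x)
    d <- as.matrix(dist(t(x)))
    med <- match(asg$medoids, colnames(x))
    expect_equal(asg$total_dissimilarity, config_cost(d, med),
                 tolerance = 1e-12)
    for (mi in 1:2) for (h in setdiff(seq_len(n), med)) {
      alt <- c(med[3 - mi], h)
      expect_gte(config_cost(d, alt), asg$total_dissimilarity - 1e-9)
    }
  }
})

test_that("km_estimate reproduces product-limit hand calculations", {
  surv <- data.frame(sample_id = paste0("s", 1:3), time = c(1, 2, 3),
                     event = 1L)
  cl <- setNames(rep(1L, 3), surv$sample_id)
  # need two clusters for the assignment contract; put them all in one and
  # test that group's curve via the cluster vector directly
  cl2 <- setNames(c(1L, 1L, 1L, 2L), c(surv$sample_id, "s4"))
  surv2 <- rbind(surv, data.frame(sample_id = "s4", time = 9, event = 0L))
  km <- km_estimate(surv2, cl2)
  expect_equal(km$cluster1$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$cluster2$survival, 1)  # single censored subject
  # all censored: flat at 1
  surv3 <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 0L)
  km3 <- km_estimate(surv3, setNames(c(1L, 1L, 2L, 2L), surv3$sample_id))
  expect_true(all(km3$cluster1$survival == 1))
  # single subject with an event drops 1 -> 0
  surv4 <- data.frame(sample_id = c("a", "b"), time = c(5, 2), event = c(1L, 0L))
  km4 <- km_estimate(surv4, setNames(c(1L, 2L), c("a", "b")))
  expect_equal(km4$cluster1$survival, 0)
})

test_that("km curves match survival::survfit stepwise", {
  skip_if_not_installed("survival")
  withr::local_seed(61)
  n <- 30
  surv <- data.frame(sample_id = paste0("s", 1:n),
                     time = round(rexp(n, 0.1), 2),
                     event = rbinom(n, 1, 0.7))
  cl <- setNames(rep(1:2, each = n / 2), surv$sample_id)
  km <- km_estimate(surv, cl)
  for (g in 1:2) {
    sub <- surv[cl[surv$sample_id] == g, ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    ours <- km[[paste0("cluster", g)]]
    idx <- match(ours$time, fit$time)
    expect_equal(ours$survival, fit$surv[idx], tolerance = 1e-12)
    expect_true(all(diff(ours$survival) <= 1e-15))
  }
})

test_that("logrank_test matches survival::survdiff across random cohorts", {
  skip_if_not_installed("survival")
  withr::local_seed(71)
  for (rep in 1:15) {
    n <- sample(c(20, 40, 79), 1)
    surv <- data.frame(sample_id = paste0("s", 1:n),
                       time = round(rexp(n, 0.05), 1),
                       event = rbinom(n, 1, 0.8))
    cl <- setNames(sample(rep(1:2, length.out = n)), surv$sample_id)
    ours <- logrank_test(surv, cl)
    ref <- survival::survdiff(
      survival::Surv(surv$time, surv$event) ~ cl[surv$sample_id])
    expect_equal(ours$chi_square, unname(ref$chisq), tolerance = 1e-8)
    expect_equal(ours$p_value,
                 pchisq(ref$chisq, 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("logrank handles identical groups and the no-event boundary", {
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time = rep(c(1, 2, 3, 4), 2),
                     event = rep(1L, 8))
  cl <- setNames(rep(1:2, each = 4), surv$sample_id)
  # same survival experience in both groups
  res <- logrank_test(surv, cl)
  expect_lt(res$chi_square, 1e-10)
  expect_gt(res$p_value, 0.999)
  nosurv <- data.frame(sample_id = paste0("s", 1:8), time = rep(5, 8),
                       event = 0L)
  expect_warning(res0 <- logrank_test(nosurv, cl), "no events")
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p_value, 1)
  expect_error(logrank_test(surv[1:6, ], cl), "no survival data")
})
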