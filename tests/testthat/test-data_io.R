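write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_expression_tsv parses well-formed files in both orientations", {
  path <- write_tsv_lines(c("gene_id\ts1\ts2",
                            "TP53\t1.5\t2.5",
                            "EGFR\t0.1\t-0.2",
                            "MYC\t3\t4"))
  m <- read_expression_tsv(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("TP53", "EGFR", "MYC"))
  expect_equal(m["MYC", "s2"], 4)

  tpath <- write_tsv_lines(c("sample_id\tTP53\tEGFR\tMYC",
                             "s1\t1.5\t0.1\t3",
                             "s2\t2.5\t-0.2\t4"))
  expect_equal(read_expression_tsv(tpath, samples_in = "rows"), m)
})

test_that("read_expression_tsv rejects duplicates, NAs and non-numeric cells", {
  dup <- write_tsv_lines(c("gene_id\ts1\ts2", "TP53\t1\t2", "TP53\t3\t4"))
  expect_error(read_expression_tsv(dup), "duplicate gene identifiers.*TP53")

  na <- write_tsv_lines(c("gene_id\ts1\ts2", "TP53\t1\tNA", "MYC\t3\t4"))
  expect_error(read_expression_tsv(na), "row 'TP53', column 's2'")

  txt <- write_tsv_lines(c("gene_id\ts1\ts2", "TP53\t1\t2", "MYC\tx\t4"))
  expect_error(read_expression_tsv(txt), "row 'MYC', column 's1'")
})

test_that("matrix TSV round-trips, including gzip", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_matrix_tsv(m, path)
  expect_equal(read_expression_tsv(path), m, tolerance = 1e-12)
})

test_that("collapse_probes_by_cv keeps the max-CV probe with deterministic ties", {
  vals <- rbind(p1 = c(1, 1, 1),       # CV 0
                p2 = c(1, 2, 3),       # mean 2, sd 1, CV 0.5
                q2 = c(5, 5, 6),       # tie with q1 below
                q1 = c(5, 5, 6),
                r1 = c(2, 2, 2))
  colnames(vals) <- paste0("s", 1:3)
  pm <- probe_matrix(vals, c(p1 = "GX", p2 = "GX", q1 = "GY", q2 = "GY",
                             r1 = "GZ"))
  out <- collapse_probes_by_cv(pm)
  expect_identical(rownames(out), c("GX", "GY", "GZ"))
  expect_equal(out["GX", ], c(s1 = 1, s2 = 2, s3 = 3))   # p2 won on CV
  expect_equal(out["GY", ], c(s1 = 5, s2 = 5, s3 = 6))   # q1 won the tie
  expect_equal(out["GZ", ], c(s1 = 2, s2 = 2, s3 = 2))   # single probe kept
})

test_that("collapse flags zero-mean probes and unmapped probes", {
  vals <- rbind(a1 = c(-1, 0, 1), a2 = c(1, 2, 3), u1 = c(9, 9, 9))
  colnames(vals) <- paste0("s", 1:3)
  expect_message(pm <- probe_matrix(vals, c(a1 = "GA", a2 = "GA", u1 = NA)),
                 "no gene mapping")
  expect_warning(out <- collapse_probes_by_cv(pm), "zero-mean")
  expect_identical(rownames(out), "GA")
  expect_equal(unname(out["GA", ]), c(1, 2, 3))  # zero-mean probe ranked last
})

test_that("collapse is idempotent on its own output", {
  withr::local_seed(7)
  vals <- matrix(abs(rnorm(40, 5)), 10, 4,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  map <- setNames(paste0("G", rep(1:4, c(4, 3, 2, 1))), paste0("p", 1:10))
  once <- collapse_probes_by_cv(probe_matrix(vals, map))
  again <- collapse_probes_by_cv(
    probe_matrix(once, setNames(rownames(once), rownames(once))))
  expect_equal(again, once)
  expect_identical(nrow(once), 4L)
})

test_that("read_gmt parses, dedups, and rejects short lines", {
  path <- write_tsv_lines(c("MODULE_1\tdesc\tA\tB\tA",
                            "MODULE_2\tother\tC\tD"))
  coll <- read_gmt(path)
  expect_length(coll, 2L)
  expect_identical(coll$sets$MODULE_1, c("A", "B"))

  bad <- write_tsv_lines(c("M1\tdesc\tA", "X\tdesc"))
  expect_error(read_gmt(bad), "line 2")
})

test_that("write_gmt / read_gmt round-trips set membership exactly", {
  for (seed in 1:5) {
    cfg <- sim_config(n_genes = 60L, n_sets = 12L, set_size_range = c(3L, 9L),
                      seed = seed)
    coll <- simulate_collection(cfg)
    path <- withr::local_tempfile(fileext = ".gmt")
    write_gmt(coll, path)
    back <- read_gmt(path)
    expect_identical(back$sets, coll$sets)
  }
})

test_that("read_gene2go filters taxon, branch and NOT qualifiers", {
  path <- write_tsv_lines(c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
    "9606\t1\tGO:0001\tIEA\t-\tapoptosis\t-\tProcess",
    "9606\t2\tGO:0001\tIDA\t-\tapoptosis\t123\tProcess",
    "9606\t3\tGO:0002\tIEA\t-\tmitosis\t-\tProcess",
    "9606\t4\tGO:0002\tIEA\tNOT\tmitosis\t-\tProcess",
    "9606\t5\tGO:0003\tIEA\t-\tkinase activity\t-\tFunction",
    "10090\t6\tGO:0001\tIEA\t-\tapoptosis\t-\tProcess"))
  coll <- read_gene2go(path, taxon = 9606)
  expect_length(coll, 2L)
  expect_identical(coll$sets$`GO:0001`, c("1", "2"))
  expect_identical(coll$sets$`GO:0002`, "3")     # NOT row excluded
  expect_error(read_gene2go(path, 9606, category = "Pathway"),
               "valid: Process, Function, Component")
})

test_that("filter_collection intersects, drops, and never invents genes", {
  expr <- matrix(0, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                          c("s1", "s2")))
  coll <- geneset_collection(list(keep = c("A", "B", "Z"),
                                  tiny = c("A", "Q"),
                                  full = c("A", "B", "C", "D")))
  expect_warning(out <- filter_collection(coll, expr, min_size = 2),
                 "full measured universe")
  expect_identical(names(out$sets), "keep")
  expect_identical(out$sets$keep, c("A", "B"))
  for (s in out$sets) {
    expect_true(all(s %in% rownames(expr)))
    expect_lte(length(s), length(coll$sets$keep))
  }
  expect_error(suppressWarnings(filter_collection(coll, expr, min_size = 3)),
               "no genesets remain")
})

test_that("phenotype and survival readers validate their contracts", {
  gp <- write_tsv_lines(c("sample_id\tgroup", "s1\ttumor", "s2\tnormal",
                          "s3\ttumor"))
  g <- read_sample_groups(gp)
  expect_identical(g[["s3"]], "tumor")
  bad <- write_tsv_lines(c("sample_id\tgroup", "s1\ta", "s2\tb", "s3\tc"))
  expect_error(read_sample_groups(bad), "exactly 2 group labels")

  sv <- write_tsv_lines(c("sample_id\ttime\tevent", "s1\t10\t1", "s2\t5\t0"))
  s <- read_survival_tsv(sv)
  expect_identical(s$event, c(1L, 0L))
  badt <- write_tsv_lines(c("sample_id\ttime\tevent", "s1\t-2\t1"))
  expect_error(read_survival_tsv(badt), "non-negative")
})
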