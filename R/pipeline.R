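# End-to-end orchestration: score each training cohort, derive a directional
# signature per cohort, intersect the signatures across cohorts, then
# stratify an independent validation cohort by PAM on the overlap mechanisms
# and test recurrence-free survival separation. Every run writes its
# intermediate tables plus a JSON manifest with input checksums, parameters
# and seeds, sufficient to reproduce the run.

#' Run the full pipeline from a configuration
#'
#' The configuration is a list (or path to a JSON/YAML file) with elements:
#' \describe{
#'   \item{gmt}{path to the geneset collection (GMT).}
#'   \item{cohorts}{list of training cohorts, each a list with `expr`
#'     (expression TSV) and `groups` (phenotype TSV).}
#'   \item{validation}{optional list with `expr` and `surv` (survival TSV)
#'     to run the prognosis stage.}
#'   \item{params}{optional list overriding `fdr` (0.05), `min_size` (5),
#'     `t_variant` ("student"), `rank_orientation` ("high-is-max"),
#'     `draws` (10000), `case` ("tumor"), `seed` (1).}
#' }
#'
#' @param config list or path to a JSON (or YAML, if the yaml package is
#'   available) configuration file.
#' @param outdir results directory, created if needed.
#' @return invisibly, a list with the per-cohort signatures, the
#'   `OverlapResult`, the gene-level `BootstrapOverlapResult` (first two
#'   cohorts), the `LogRankResult` (if a validation cohort was given) and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_config(config)
  p <- config$params %||% list()
  fdr <- p$fdr %||% 0.05
  min_size <- p$min_size %||% 5L
  t_variant <- p$t_variant %||% "student"
  orientation <- p$rank_orientation %||% "high-is-max"
  draws <- p$draws %||% 10000L
  case <- p$case %||% "tumor"
  seed <- p$seed %||% 1L
  if (is.null(config$gmt) || is.null(config$cohorts) ||
      length(config$cohorts) < 1L)
    stop_faime("config must provide 'gmt' and at least one cohort")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_faime("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  coll <- stage("read-collection", read_gmt(config$gmt))

  signatures <- list()
  filtered_ids <- list()
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    label <- co$label %||% sprintf("cohort%d", i)
    expr <- stage(paste0("read-", label), read_expression_tsv(co$expr))
    groups <- stage(paste0("groups-", label), read_sample_groups(co$groups))
    fcoll <- stage(paste0("filter-", label),
                   filter_collection(coll, expr, min_size = min_size))
    scores <- stage(paste0("score-", label),
                    faime_transform(expr, fcoll, orientation = orientation))
    write_scores(scores, file.path(outdir, paste0(label, "_scores.tsv")))
    rec <- stage(paste0("diff-", label),
                 test_mechanisms(scores, groups, case = case,
                                 variant = t_variant))
    data.table::fwrite(rec, file.path(outdir, paste0(label, "_tests.tsv")),
                       sep = "\t")
    sig <- build_signature(rec, fdr_level = fdr, label = label)
    write_signature(sig, file.path(outdir, paste0(label, "_signature.tsv")))
    signatures[[label]] <- sig
    filtered_ids[[label]] <- names(fcoll$sets)
  }

  overlap <- NULL
  boot <- NULL
  sig_final <- signatures[[1L]]
  if (length(signatures) >= 2L) {
    universe <- Reduce(intersect, filtered_ids)
    overlap <- stage("overlap",
                     directional_intersect(signatures,
                                           universe_size = length(universe)))
    ov_tab <- data.frame(comparison = paste(overlap$labels, collapse = " & "),
                         n_overlap = overlap$n_overlap,
                         t(stats::setNames(overlap$pct_of_each,
                                           paste0("pct_", overlap$labels))),
                         fet_p = overlap$fet_p, check.names = FALSE)
    data.table::fwrite(ov_tab, file.path(outdir, "overlap.tsv"), sep = "\t")
    data.table::fwrite(overlap$mechanisms,
                       file.path(outdir, "overlap_mechanisms.tsv"), sep = "\t")
    sig_final <- structure(list(label = "overlap", fdr_level = fdr,
                                entries = overlap$mechanisms,
                                n_tested = length(universe),
                                pct = 100 * overlap$n_overlap /
                                  max(1L, length(universe)),
                                collection = coll$source_label),
                           class = "DirectionalSignature")
    # gene-level overlap significance between the first two signatures
    ga <- signature_genes(signatures[[1L]], coll)
    gb <- signature_genes(signatures[[2L]], coll)
    bg <- sort(unique(unlist(coll$sets, use.names = FALSE)))
    if (length(ga) > 0L && length(gb) > 0L)
      boot <- stage("bootstrap",
                    bootstrap_overlap_p(ga, gb, bg, bg, n_draws = draws,
                                        seed = derive_seed(seed, 11L)))
  }

  logrank <- NULL
  if (!is.null(config$validation)) {
    v <- config$validation
    if (is.null(v$expr) || is.null(v$surv))
      stop_faime("validation stage enabled but 'expr' or 'surv' input missing")
    vexpr <- stage("read-validation", read_expression_tsv(v$expr))
    vsurv <- stage("read-survival", read_survival_tsv(v$surv))
    vcoll <- stage("filter-validation",
                   filter_collection(coll, vexpr, min_size = min_size))
    vscores <- stage("score-validation",
                     faime_transform(vexpr, vcoll, orientation = orientation))
    restricted <- stage("restrict", restrict_scores(vscores, sig_final))
    assignment <- stage("pam", pam_partition(restricted))
    data.table::fwrite(data.frame(sample_id = names(assignment$cluster),
                                  cluster = assignment$cluster),
                       file.path(outdir, "assignment.tsv"), sep = "\t")
    logrank <- stage("logrank", logrank_test(vsurv, assignment))
    for (gname in names(logrank$km))
      data.table::fwrite(logrank$km[[gname]],
                         file.path(outdir, paste0("km_", gname, ".tsv")),
                         sep = "\t")
    data.table::fwrite(data.frame(chi_square = logrank$chi_square,
                                  p_value = logrank$p_value),
                       file.path(outdir, "logrank.tsv"), sep = "\t")
  }

  manifest <- build_manifest(config, outdir,
                             params = list(fdr = fdr, min_size = min_size,
                                           t_variant = t_variant,
                                           rank_orientation = orientation,
                                           draws = draws, case = case,
                                           seed = seed))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(signatures = signatures, overlap = overlap,
                 bootstrap = boot, logrank = logrank, manifest = manifest))
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_faime("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

build_manifest <- function(config, outdir, params) {
  inputs <- c(config$gmt,
              unlist(lapply(config$cohorts, function(co) c(co$expr, co$groups))),
              config$validation$expr, config$validation$surv)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  checksums <- tools::md5sum(unlist(inputs))
  list(subcommand = "run",
       inputs = as.list(checksums),
       params = params,
       version = as.character(utils::packageVersion("faime")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
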