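# Seed-deterministic generators producing the data structures the pipeline
# assumes: overlapping genesets drawn from a gene universe, multi-cohort
# tumor/normal log-expression with planted geneset deregulation (gene-level
# mean shifts inducing mechanism-level signal), and exponential
# recurrence-time tables with group-specific hazards and uniform censoring.

#' Simulation configuration
#'
#' Collects and validates all generator parameters. Defaults emulate a
#' mid-sized two-group microarray cohort: a 1000-gene universe, 200
#' genesets of 10-50 genes, 10 planted deregulated sets at a standardized
#' effect of 1.5 noise SDs, 25 tumor and 25 normal samples, unit Gaussian
#' noise on the log scale, and a recurrence model with hazard 0.01/month in
#' the good-prognosis group versus 0.03/month (hazard ratio 3), 20%
#' censoring over a 120-month follow-up horizon.
#'
#' @param n_genes gene universe size.
#' @param n_sets number of genesets.
#' @param set_size_range integer vector of length 2, inclusive size range.
#' @param n_planted number of deregulated sets (<= n_sets).
#' @param effect_size standardized mean shift (in units of `noise_sd`)
#'   applied to planted sets' member genes in tumor samples.
#' @param n_tumor,n_normal group sizes per dataset.
#' @param noise_sd Gaussian noise SD on the log-expression scale.
#' @param n_datasets number of independent cohorts sharing the planted truth.
#' @param hazard_good,hazard_poor exponential recurrence hazards (per month).
#' @param censor_fraction fraction of subjects with random uniform censoring.
#' @param followup_horizon administrative censoring horizon (months).
#' @param seed master integer seed; all generator randomness derives from it.
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 1000L, n_sets = 200L,
                       set_size_range = c(10L, 50L), n_planted = 10L,
                       effect_size = 1.5, n_tumor = 25L, n_normal = 25L,
                       noise_sd = 1, n_datasets = 1L,
                       hazard_good = 0.01, hazard_poor = 0.03,
                       censor_fraction = 0.2, followup_horizon = 120,
                       seed = 1L) {
  stopifnot(n_genes >= 2L, n_sets >= 1L, length(set_size_range) == 2L,
            set_size_range[1L] >= 1L,
            set_size_range[1L] <= set_size_range[2L],
            n_planted >= 0L, n_planted <= n_sets, effect_size >= 0,
            n_tumor >= 2L, n_normal >= 2L, noise_sd > 0, n_datasets >= 1L,
            hazard_good > 0, hazard_poor > 0,
            censor_fraction >= 0, censor_fraction < 1,
            followup_horizon > 0)
  if (set_size_range[2L] > n_genes)
    stop_faime("set sizes cannot exceed the gene universe")
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a geneset collection
#'
#' Draws `n_sets` sets with sizes uniform in `set_size_range`, members
#' sampled without replacement per set from the gene universe; distinct sets
#' may overlap.
#'
#' @param cfg a [sim_config()].
#' @return a [geneset_collection()] with ids `SET_001`, ...; gene universe
#'   ids `g0001`, ...
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  with_seed(derive_seed(cfg$seed, 1L), {
    sizes <- sample(seq(cfg$set_size_range[1L], cfg$set_size_range[2L]),
                    cfg$n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("SET_%03d", seq_len(cfg$n_sets))
    geneset_collection(sets, source_label = "synthetic")
  })
}

#' Simulate multi-cohort two-group expression with planted deregulation
#'
#' Baseline log-expression is Normal(0, `noise_sd`) per gene and sample,
#' plus a dataset-specific per-gene baseline offset (SD `0.3 * noise_sd`)
#' modelling cross-cohort heterogeneity. `n_planted` sets are chosen and
#' given a random sign; every member gene's mean in tumor samples is
#' shifted by `sign * effect_size * noise_sd` (genes in several planted
#' sets accumulate shifts). All cohorts share the same planted truth but
#' have independent noise and offsets.
#'
#' @param cfg a [sim_config()].
#' @param coll a [simulate_collection()] result (or compatible collection).
#' @return list of class `SimulatedExpression`: `cohorts` (each with
#'   `expr`, `groups`), `truth` (data.frame `mechanism_id`, `direction`),
#'   `planted_genes` (named list).
#' @export
simulate_expression <- function(cfg, coll) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(coll, "GeneSetCollection"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  with_seed(derive_seed(cfg$seed, 2L), {
    planted_idx <- if (cfg$n_planted > 0L)
      sort(sample(length(coll$sets), cfg$n_planted)) else integer(0)
    signs <- if (cfg$n_planted > 0L)
      sample(c(-1L, 1L), cfg$n_planted, replace = TRUE) else integer(0)
    truth <- data.frame(mechanism_id = names(coll$sets)[planted_idx],
                        direction = signs, stringsAsFactors = FALSE)
    # per-gene tumor mean shift induced by the planted sets
    shift <- stats::setNames(numeric(cfg$n_genes), genes)
    for (i in seq_along(planted_idx)) {
      members <- coll$sets[[planted_idx[i]]]
      shift[members] <- shift[members] +
        signs[i] * cfg$effect_size * cfg$noise_sd
    }
    n_s <- cfg$n_tumor + cfg$n_normal
    cohorts <- lapply(seq_len(cfg$n_datasets), function(d) {
      offset <- stats::rnorm(cfg$n_genes, 0, 0.3 * cfg$noise_sd)
      expr <- matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd),
                     nrow = cfg$n_genes) + offset
      tumor_cols <- seq_len(cfg$n_tumor)
      expr[, tumor_cols] <- expr[, tumor_cols] + shift
      rownames(expr) <- genes
      colnames(expr) <- sprintf("d%d_s%02d", d, seq_len(n_s))
      groups <- stats::setNames(
        rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
        colnames(expr))
      list(expr = expr, groups = groups)
    })
    structure(list(cohorts = cohorts, truth = truth,
                   planted_genes = coll$sets[planted_idx]),
              class = "SimulatedExpression")
  })
}

#' Simulate recurrence-time survival data for two latent prognosis groups
#'
#' Recurrence times are exponential with the group's hazard; a fraction
#' `censor_fraction` of subjects additionally receive an independent
#' Uniform(0, `followup_horizon`) censoring time, and everyone is
#' administratively censored at the horizon. `event = 1` iff recurrence
#' precedes both.
#'
#' @param cfg a [sim_config()].
#' @param group_truth named vector of 1 (good prognosis, `hazard_good`) or
#'   2 (poor prognosis, `hazard_poor`) per sample.
#' @return data.frame `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(cfg, group_truth) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            all(group_truth %in% c(1L, 2L)), !is.null(names(group_truth)))
  n <- length(group_truth)
  with_seed(derive_seed(cfg$seed, 3L), {
    hazard <- ifelse(group_truth == 1L, cfg$hazard_good, cfg$hazard_poor)
    recur <- stats::rexp(n, rate = hazard)
    cens <- rep(cfg$followup_horizon, n)
    has_cens <- stats::runif(n) < cfg$censor_fraction
    cens[has_cens] <- pmin(cens[has_cens],
                           stats::runif(sum(has_cens), 0, cfg$followup_horizon))
    data.frame(sample_id = names(group_truth),
               time = pmin(recur, cens),
               event = as.integer(recur <= cens),
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits per-cohort expression and phenotype TSVs, the collection as GMT,
#' a validation-cohort survival TSV (latent prognosis groups follow the
#' first planted mechanism's deregulation direction when available, else
#' an even split), and the planted truth as a JSON sidecar.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  coll <- simulate_collection(cfg)
  sim <- simulate_expression(cfg, coll)
  paths <- list(gmt = file.path(outdir, "sets.gmt"),
                truth = file.path(outdir, "truth.json"))
  write_gmt(coll, paths$gmt)
  for (d in seq_along(sim$cohorts)) {
    pe <- file.path(outdir, sprintf("cohort%d_expr.tsv", d))
    pg <- file.path(outdir, sprintf("cohort%d_groups.tsv", d))
    write_matrix_tsv(sim$cohorts[[d]]$expr, pe)
    data.table::fwrite(data.frame(sample_id = names(sim$cohorts[[d]]$groups),
                                  group = sim$cohorts[[d]]$groups),
                       pg, sep = "\t")
    paths[[sprintf("cohort%d_expr", d)]] <- pe
    paths[[sprintf("cohort%d_groups", d)]] <- pg
  }
  # validation survival: latent prognosis groups from the last cohort's
  # tumor/normal split stand in for the two pathway-profile clusters
  val <- sim$cohorts[[length(sim$cohorts)]]
  grp <- stats::setNames(ifelse(val$groups == "tumor", 2L, 1L),
                         names(val$groups))
  surv <- simulate_survival(cfg, grp)
  paths$survival <- file.path(outdir, "survival.tsv")
  data.table::fwrite(surv, paths$survival, sep = "\t")
  jsonlite::write_json(list(truth = sim$truth,
                            planted_genes = sim$planted_genes,
                            seed = cfg$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
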