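# fread via a connection for gzip input (avoids the R.utils dependency
# data.table would otherwise require for .gz paths)
fread_tsv <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

# Readers and writers for the plain-text formats the pipeline touches, plus
# probe-to-gene collapsing. Expression data are represented as base numeric
# matrices (genes in rows, samples in columns, both named); geneset
# collections as a light S3 list class.

#' Validate an expression matrix
#'
#' Checks the container invariants: named, unique row (gene) and column
#' (sample) identifiers and finite numeric values throughout.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_faime("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_faime("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop_faime("duplicate gene identifiers: ",
               paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_faime("duplicate sample identifiers: ",
               paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_faime("non-finite expression value at gene '", rownames(x)[bad[1L]],
               "', sample '", colnames(x)[bad[2L]], "'")
  }
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must be tab-separated with identifiers in the first column and a
#' header row of sample identifiers (or the transpose, with
#' `samples_in = "rows"`). Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @param samples_in `"columns"` (default) if samples are columns, `"rows"`
#'   if the file is transposed.
#' @return a validated numeric matrix, genes in rows.
#' @export
read_expression_tsv <- function(path, samples_in = c("columns", "rows")) {
  samples_in <- match.arg(samples_in)
  dt <- fread_tsv(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          na.strings = NULL, data.table = FALSE)
  if (ncol(dt) < 2L) stop_faime("expression TSV needs an id column plus data: ", path)
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num))[1L]
      stop_faime("non-numeric cell '", col[bad], "' at row '", ids[bad],
                 "', column '", names(vals)[j], "' in ", path)
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop_faime("missing value at row '", ids[bad], "', column '",
                 names(vals)[j], "' in ", path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (samples_in == "rows") m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop_faime("duplicate gene identifiers in ", path, ": ",
               paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  validate_expression(m)
  m
}

#' Write an expression (or score) matrix as TSV
#'
#' @param x numeric matrix with row and column names.
#' @param path output path; `.gz` suffix writes gzip.
#' @param id_col header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Construct a probe-level matrix with its probe-to-gene map
#'
#' Probes without a gene assignment are allowed (`NA` in the map) and are
#' flagged with a message; they are dropped only at collapse time.
#'
#' @param values numeric matrix, probes in rows.
#' @param probe_to_gene named character vector mapping probe id to gene id
#'   (`NA` for unmapped probes); names must cover the rownames of `values`.
#' @return an object of class `ProbeMatrix`.
#' @export
probe_matrix <- function(values, probe_to_gene) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop_faime("probe values must be a matrix with probe rownames")
  if (anyDuplicated(rownames(values)))
    stop_faime("duplicate probe identifiers")
  if (!all(rownames(values) %in% names(probe_to_gene)))
    stop_faime("probe_to_gene must map every probe row")
  map <- probe_to_gene[rownames(values)]
  n_unmapped <- sum(is.na(map))
  if (n_unmapped > 0L)
    message(n_unmapped, " probe(s) have no gene mapping; they will be dropped at collapse")
  structure(list(values = values, probe_to_gene = map), class = "ProbeMatrix")
}

#' Collapse probe-level rows to one row per gene by coefficient of variation
#'
#' For each gene with multiple probe-sets, the probe with the largest
#' coefficient of variation (sample standard deviation over mean, computed on
#' the values as stored) is retained and the others discarded. Ties are broken
#' by the lexicographically smallest probe id; a probe with zero mean has an
#' undefined CV, is ranked last, and triggers a warning. Unmapped probes are
#' dropped here.
#'
#' @param probes a [probe_matrix()] object.
#' @return a gene-by-sample numeric matrix.
#' @export
collapse_probes_by_cv <- function(probes) {
  stopifnot(inherits(probes, "ProbeMatrix"))
  map <- probes$probe_to_gene
  keep <- !is.na(map)
  vals <- probes$values[keep, , drop = FALSE]
  map <- map[keep]
  if (nrow(vals) == 0L) stop_faime("no mapped probes to collapse")
  mu <- rowMeans(vals)
  sd_ <- apply(vals, 1L, stats::sd)
  cv <- sd_ / mu
  zero_mean <- mu == 0
  if (any(zero_mean)) {
    warning("CV undefined for zero-mean probe(s) ",
            paste(rownames(vals)[zero_mean], collapse = ", "),
            "; ranked last", call. = FALSE)
    cv[zero_mean] <- -Inf
  }
  # stable selection: per gene, max CV, ties by smallest probe id
  ord <- order(map, -cv, rownames(vals), method = "radix")
  first <- ord[!duplicated(map[ord])]
  out <- vals[first, , drop = FALSE]
  rownames(out) <- map[first]
  out <- out[order(rownames(out)), , drop = FALSE]
  validate_expression(out)
  out
}

#' Construct a geneset collection
#'
#' @param sets named list of character vectors of gene ids; each set must be
#'   non-empty and duplicates within a set are removed.
#' @param source_label text label for the collection (e.g. `"GO-BP"`,
#'   `"CancerModule"`).
#' @param set_names optional named character vector of human-readable names.
#' @return an object of class `GeneSetCollection`.
#' @export
geneset_collection <- function(sets, source_label = "user", set_names = NULL) {
  if (length(sets) == 0L) stop_faime("collection must contain at least one set")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_faime("sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    stop_faime("empty geneset(s): ",
               paste(names(sets)[sizes == 0L], collapse = ", "))
  structure(list(source_label = source_label, sets = sets,
                 set_names = set_names),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection '", x$source_label, "': ", length(x$sets),
      " sets, sizes ", min(lengths(x$sets)), "-", max(lengths(x$sets)),
      "\n", sep = "")
  invisible(x)
}

#' Read a GMT geneset file
#'
#' One geneset per line: name, description, then gene symbols, tab-separated.
#' Duplicate symbols within a line are deduplicated.
#'
#' @param path path to a GMT file (optionally gzip-compressed).
#' @param source_label label stored on the collection.
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_faime("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop_faime("GMT line ", which(nf < 3L)[1L],
               " has fewer than 3 fields in ", path)
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  geneset_collection(sets, source_label = source_label,
                     set_names = stats::setNames(descs, ids))
}

#' Write a geneset collection in GMT format
#'
#' @param coll a [geneset_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  desc <- coll$set_names %||%
    stats::setNames(rep("na", length(coll$sets)), names(coll$sets))
  lines <- vapply(names(coll$sets), function(id) {
    paste(c(id, desc[[id]] %||% "na", coll$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read NCBI gene2go annotations into a geneset collection
#'
#' Expects the 8-column tab format (tax_id, GeneID, GO_ID, Evidence,
#' Qualifier, GO_term, PubMed, Category), with or without a leading `#`
#' header line; gzip input is handled. Rows are restricted to the requested
#' taxon and ontology branch, and rows whose qualifier asserts
#' non-membership (`NOT ...`) are excluded.
#'
#' @param path path to a gene2go file.
#' @param taxon NCBI taxonomy id to keep (e.g. `9606`).
#' @param category ontology branch: `"Process"` (default), `"Function"` or
#'   `"Component"`.
#' @return a [geneset_collection()], one set per GO id, members are GeneIDs
#'   as character.
#' @export
read_gene2go <- function(path, taxon, category = "Process") {
  valid <- c("Process", "Function", "Component")
  if (!category %in% valid)
    stop_faime("unknown category '", category, "'; valid: ",
               paste(valid, collapse = ", "))
  cols <- c("tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier",
            "GO_term", "PubMed", "Category")
  dt <- fread_tsv(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  # strip a header line if it survived (first field "#tax_id" or "tax_id")
  if (grepl("tax_id", dt[1L, 1L], fixed = TRUE)) dt <- dt[-1L, , drop = FALSE]
  if (ncol(dt) != 8L)
    stop_faime("gene2go file must have 8 tab-separated columns, found ",
               ncol(dt))
  names(dt) <- cols
  keep <- as.character(dt$tax_id) == as.character(taxon) &
    dt$Category == category &
    !grepl("^NOT", dt$Qualifier)
  dt <- dt[keep, , drop = FALSE]
  if (nrow(dt) == 0L)
    stop_faime("no gene2go rows for taxon ", taxon, ", category ", category)
  sets <- split(as.character(dt$GeneID), dt$GO_ID)
  nm <- vapply(split(as.character(dt$GO_term), dt$GO_ID), `[[`, "", 1L)
  geneset_collection(sets, source_label = paste0("GO-", category),
                     set_names = nm)
}

#' Restrict a collection to measured genes and filter by set size
#'
#' Each set is intersected with the genes of `expr`; sets whose measured size
#' falls outside `[min_size, max_size]` are dropped, as is any set equal to
#' the full measured gene universe (its complement would be empty and the
#' centroid-difference score undefined).
#'
#' @param coll a [geneset_collection()].
#' @param expr expression matrix whose rownames define the measured universe.
#' @param min_size minimum measured set size (default 5).
#' @param max_size maximum measured set size (default unrestricted).
#' @return a filtered [geneset_collection()].
#' @export
filter_collection <- function(coll, expr, min_size = 5L, max_size = Inf) {
  stopifnot(inherits(coll, "GeneSetCollection"), min_size >= 1L)
  universe <- rownames(expr)
  sets <- lapply(coll$sets, function(s) s[s %in% universe])
  full <- lengths(sets) == length(universe)
  if (any(full))
    warning("dropping set(s) equal to the full measured universe: ",
            paste(names(sets)[full], collapse = ", "), call. = FALSE)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size & !full
  if (!any(keep))
    stop_faime("no genesets remain after filtering against measured genes")
  geneset_collection(sets[keep], source_label = coll$source_label,
                     set_names = coll$set_names[names(sets)[keep]])
}

#' Read a two-column sample-group table
#'
#' TSV with header, columns `sample_id` and `group`; exactly two distinct
#' group labels are required.
#'
#' @param path path to the phenotype TSV.
#' @return named character vector, sample id to group label.
#' @export
read_sample_groups <- function(path) {
  dt <- fread_tsv(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop_faime("phenotype TSV needs sample_id and group columns")
  g <- stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
  if (anyDuplicated(names(g))) stop_faime("duplicate sample ids in ", path)
  if (length(unique(g)) != 2L)
    stop_faime("expected exactly 2 group labels, found ",
               length(unique(g)))
  g
}

#' Read a survival table
#'
#' TSV with header, columns `sample_id`, `time` (non-negative, e.g. months to
#' biochemical recurrence or censoring) and `event` (1 = recurrence observed,
#' 0 = censored).
#'
#' @param path path to the survival TSV.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_survival_tsv <- function(path) {
  dt <- fread_tsv(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(dt)))
    stop_faime("survival TSV must have columns ", paste(need, collapse = ", "))
  out <- dt[, need]
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) stop_faime("duplicate sample ids in ", path)
  if (!all(is.finite(out$time)) || any(out$time < 0))
    stop_faime("survival times must be finite and non-negative")
  if (!all(out$event %in% c(0, 1)))
    stop_faime("event indicator must be 0/1")
  out
}
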