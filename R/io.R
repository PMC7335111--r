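#' Read and write delimited feature x sample matrices
#'
#' TSV is the canonical dialect (first column = feature ID, header = sample
#' IDs); comma-separated files via `sep = ","`.  Empty fields and `NA`
#' tokens become missing values.  Writing then reading a matrix returns it
#' unchanged up to float formatting.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return `read_matrix()`: numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2) stopf("'%s': need a feature column plus data columns", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stopf("'%s': duplicate feature ID '%s' (line %d)", path, dup[1],
          which(ids == dup[1])[2] + 1L)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("'%s': non-numeric data values", path)
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m Matrix (or [intensity_matrix()]) to write.
#' @param id_col Header name for the feature-ID column, default
#'   `"feature"`.
#' @export
write_matrix <- function(m, path, sep = "\t", id_col = "feature") {
  v <- as_values(m)
  df <- data.frame(v1 = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.  Duplicate genes within a set are dropped; sets with
#' no members are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stopf("'%s': line %d has fewer than 3 columns", path, bad[1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("dropping empty set(s): %s",
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]; desc <- desc[!empty]
  }
  attr(sets, "description") <- setNames(desc, names(sets))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Run the synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> center -> impute -> consensus subtype ->
#' differential expression on a synthetic cohort and writes every artifact
#' (matrix, labels, PAC table, consensus matrices, differential table, log)
#' into `outdir`.  A single global seed is fanned out to per-stage seeds by
#' fixed offsets (+1 simulate, +2 subtype), so each stage is independently
#' reproducible and the whole run is deterministic: rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config List (or path to a YAML file) with entries `outdir`,
#'   `seed` (default 1), `stages` (default all of `"simulate"`,
#'   `"normalize"`, `"subtype"`, `"diffexp"`), `cohort` (overrides for
#'   [cohort_config()]), `k_range`, `n_iter`.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% stopf("config$outdir is required")
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("simulate", "normalize", "subtype", "diffexp")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0("[%s] ", fmt, "\n"), "proteogpc", ...),
        file = log_path, append = TRUE)
  }
  cat(sprintf("run started; global seed %d\n", seed), file = log_path)
  res <- list()
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if ("simulate" %in% stages) {
    res$bundle <- run_stage("simulate", {
      cc <- do.call(cohort_config,
                    modifyList(list(seed = seed + 1), config$cohort %||% list()))
      logf("simulate: %d proteins x %d samples, seed %d",
           cc$n_proteins, cc$n_samples, cc$seed)
      generate_proteome_bundle(cc)
    })
    write_matrix(res$bundle$matrix, file.path(outdir, "proteome_log2.tsv"))
    write.table(data.frame(sample = names(res$bundle$labels),
                           label = as.character(res$bundle$labels)),
                file.path(outdir, "true_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("normalize" %in% stages) {
    res$normalized <- run_stage("normalize", {
      logf("normalize: median centering + second-smallest imputation")
      impute_second_smallest(median_center(res$bundle$matrix))
    })
    write_matrix(res$normalized, file.path(outdir, "proteome_normalized.tsv"))
  }
  if ("subtype" %in% stages) {
    res$consensus <- run_stage("subtype", {
      k_range <- config$k_range %||% 2:6
      n_iter <- config$n_iter %||% 1000
      logf("subtype: consensus clustering K=%d..%d, %d iterations, seed %d",
           min(k_range), max(k_range), n_iter, seed + 2)
      consensus_cluster(res$normalized, k_range = k_range, n_iter = n_iter,
                        seed = seed + 2)
    })
    cr <- res$consensus
    write.table(data.frame(K = cr$k_range, PAC = cr$pac),
                file.path(outdir, "pac.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # GPC naming convention: the larger cluster is GPC1
    ord <- order(-table(cr$labels))
    gpc <- paste0("GPC", match(cr$labels, names(table(cr$labels))[ord]))
    res$subtype_labels <- setNames(gpc, names(cr$labels))
    write.table(data.frame(sample = names(cr$labels), cluster = cr$labels,
                           subtype = gpc),
                file.path(outdir, "subtype_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in cr$k_range) {
      write_matrix(cr$consensus[[as.character(k)]],
                   file.path(outdir, sprintf("consensus_K%d.tsv", k)),
                   id_col = "sample")
    }
  }
  if ("diffexp" %in% stages) {
    res$diff <- run_stage("diffexp", {
      logf("diffexp: Student t-test between consensus subtypes")
      dep_test(res$normalized, factor(res$subtype_labels))
    })
    write.table(res$diff, file.path(outdir, "diffexp.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logf("run complete: %s", paste(stages, collapse = " -> "))
  invisible(res)
}
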