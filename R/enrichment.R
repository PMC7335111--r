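#' Filter a gene-set collection by size and redundancy
#'
#' Drops exact-duplicate sets (identical membership; first name wins) and
#' sets outside the size bounds used for over-representation analysis
#' (default: at least 5 and at most 150 genes).  Symbols are
#' uppercase-normalized and de-duplicated within each set.
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param min_size,max_size Inclusive size bounds, defaults 5 and 150.
#' @return Filtered named list.
#' @export
filter_gene_sets <- function(sets, min_size = 5, max_size = 150) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  sets[!duplicated(keys)]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set, against a stated background.  Sets overlapping the
#' query in fewer than `min_hits` genes are excluded before testing;
#' Benjamini-Hochberg FDR is computed over the tested sets.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param sets Named list of gene sets (ideally pre-filtered with
#'   [filter_gene_sets()]).
#' @param background Character vector of all measurable genes.
#' @param min_hits Minimum overlap for a set to be tested, default 4.
#' @return `EnrichmentTable` data frame: `set`, `k` (overlap), `set_size`
#'   (within background), `query_size`, `background_size`, `p`, `q`.
#' @export
hypergeom_ora <- function(query, sets, background, min_hits = 4) {
  query <- unique(toupper(query)); background <- unique(toupper(background))
  if (!length(query) || !length(background)) {
    stopf("empty query or background")
  }
  if (!all(query %in% background)) {
    stopf("query genes outside background: %s",
          paste(head(setdiff(query, background), 5), collapse = ", "))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), background)
    k <- length(intersect(s, query))
    if (k < min_hits || !length(s)) return(NULL)
    p <- phyper(k - 1, length(s), N - length(s), n, lower.tail = FALSE)
    data.frame(set = nm, k = k, set_size = length(s), query_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), k = integer(), set_size = integer(),
                      query_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric())
    return(out)
  }
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Overlap (Szymkiewicz-Simpson) coefficient between two gene sets
#'
#' `|A ∩ B| / min(|A|, |B|)`, the similarity used to draw edges between
#' enriched gene sets in an enrichment map.
#'
#' @param a,b Character vectors (non-empty).
#' @return Coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stopf("empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Similarity edges between gene sets
#'
#' Emits every unordered pair of sets whose overlap coefficient reaches the
#' cutoff (default 0.5, the conventional enrichment-map threshold).
#'
#' @param sets Named list of gene sets.
#' @param cutoff Minimum overlap coefficient, default 0.5.
#' @return Data frame `set_a`, `set_b`, `overlap_coefficient`.
#' @export
overlap_edges <- function(sets, cutoff = 0.5) {
  nm <- names(sets)
  rows <- list()
  if (length(sets) >= 2) {
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        oc <- overlap_coefficient(sets[[i]], sets[[j]])
        if (oc >= cutoff) {
          rows[[length(rows) + 1]] <- data.frame(
            set_a = nm[i], set_b = nm[j], overlap_coefficient = oc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(set_a = character(), set_b = character(),
                      overlap_coefficient = numeric()))
  }
  do.call(rbind, rows)
}

# Single-sample enrichment score for one expression vector and one set.
# Genes are walked in decreasing-expression order; in-set steps add the
# rank weight (N - position + 1)^exponent normalized over the set, out-of-set
# steps subtract 1/(N - m); the ES integrates the running sum over the walk.
ssgsea_es_single <- function(expr, in_set, exponent) {
  N <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  inset <- in_set[ord]
  w <- (N - seq_len(N) + 1)^exponent
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / (N - sum(inset))
  sum(p_in - p_out)
}

#' Single-sample GSEA enrichment scores
#'
#' Rank-based per-sample enrichment score for each gene set: within a
#' sample, genes are ordered by expression and a running sum accumulates
#' rank-weighted increments (exponent 0.75) at in-set genes against uniform
#' decrements at out-of-set genes; the ES is the sum of the running-sum
#' difference over the whole walk.  Because only ranks are used, the score
#' is invariant under strictly monotone transforms of a sample's values.
#'
#' @param m Gene x sample matrix (typically z-scored expression).
#' @param sets Named list of gene sets; each must overlap the measured genes
#'   in a proper non-empty subset.
#' @param exponent Rank weight exponent, default 0.75.
#' @param normalize Divide all scores by the range of the raw ES across the
#'   matrix (default `FALSE`, raw ES).
#' @return Set x sample numeric matrix of enrichment scores.
#' @export
ssgsea_scores <- function(m, sets, exponent = 0.75, normalize = FALSE) {
  v <- as_values(m)
  genes <- rownames(v)
  es <- matrix(NA_real_, length(sets), ncol(v),
               dimnames = list(names(sets), colnames(v)))
  for (si in seq_along(sets)) {
    in_set <- genes %in% sets[[si]]
    if (!any(in_set)) stopf("set '%s' shares no genes with the matrix",
                            names(sets)[si])
    if (all(in_set)) stopf("set '%s' covers all measured genes",
                           names(sets)[si])
    for (j in seq_len(ncol(v))) {
      es[si, j] <- ssgsea_es_single(v[, j], in_set, exponent)
    }
  }
  if (normalize) es <- es / (max(es) - min(es))
  es
}

#' Assign the representative RNA subtype per sample
#'
#' Each sample is labeled with the subtype whose signature attains the
#' highest enrichment score; exact ties go to the first subtype in the fixed
#' row order and are flagged.
#'
#' @param es Subtype x sample ES matrix (e.g. from [ssgsea_scores()] over
#'   the four expression-subtype signatures).
#' @param subtypes Expected subtype names; all must be rows of `es`.
#' @return Data frame `sample`, `subtype`, `tie` (logical).
#' @export
assign_rna_subtype <- function(es, subtypes = rownames(es)) {
  if (!all(subtypes %in% rownames(es))) {
    stopf("missing signature(s): %s",
          paste(setdiff(subtypes, rownames(es)), collapse = ", "))
  }
  es <- es[subtypes, , drop = FALSE]
  idx <- apply(es, 2, which.max)
  tie <- apply(es, 2, function(col) sum(col == max(col)) > 1)
  data.frame(sample = colnames(es), subtype = subtypes[idx], tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}
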