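#' Shapiro-Wilk normality screen per feature and group
#'
#' Advisory screen supporting the use of Student's t-test: for each feature
#' and group with at least three non-missing, non-constant values, tests
#' Gaussianity and summarizes the fraction of rejections at 0.05.  Does not
#' gate any downstream test.
#'
#' @param m Feature x sample matrix (or [intensity_matrix()]).
#' @param groups Two-or-more-level factor over samples.
#' @return List: `p` (feature x group matrix of Shapiro-Wilk p-values, `NA`
#'   when skipped), `rejection_fraction` (per group, at alpha 0.05),
#'   `skipped` (feature x group logical).
#' @export
normality_screen <- function(m, groups) {
  v <- as_values(m)
  groups <- as.factor(groups)
  if (length(groups) != ncol(v)) stopf("`groups` length must match samples")
  lev <- levels(groups)
  p <- matrix(NA_real_, nrow(v), length(lev), dimnames = list(rownames(v), lev))
  for (g in lev) {
    sub <- v[, groups == g, drop = FALSE]
    p[, g] <- apply(sub, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 3 || length(r) > 5000 || sd(r) == 0) return(NA_real_)
      shapiro.test(r)$p.value
    })
  }
  list(p = p,
       rejection_fraction = colMeans(p < 0.05, na.rm = TRUE),
       skipped = is.na(p))
}

#' Differential expression by two-sample Student's t-test
#'
#' Classic unpaired equal-variance t-test (Welch via `var_equal = FALSE`)
#' per feature between two groups, with Benjamini-Hochberg FDR over all
#' tested features.  A feature with zero variance in both groups and equal
#' means gets `p = 1` by convention (no evidence of difference); equal
#' constants that differ get `p = 0`.
#'
#' @param m Feature x sample matrix (or [intensity_matrix()]).
#' @param groups Two-level factor over samples; the reported direction is
#'   the sign of `mean(level 1) - mean(level 2)`.
#' @param alpha Significance threshold for the `dep` flag, default 0.05.
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return `DiffTable` data frame: `feature`, `mean1`, `mean2`, `diff`, `t`,
#'   `p`, `q`, `direction` (+1/-1/0), `dep` (logical, `p < alpha`).
#' @export
dep_test <- function(m, groups, alpha = 0.05, var_equal = TRUE) {
  v <- as_values(m)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stopf("`groups` must have exactly two levels")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  if (length(i1) < 2 || length(i2) < 2) stopf("each group needs n >= 2")
  res <- t(apply(v, 1, function(r) {
    x <- r[i1][!is.na(r[i1])]
    y <- r[i2][!is.na(r[i2])]
    if (length(x) < 2 || length(y) < 2) return(c(NA, NA, NA, NA))
    if (sd(x) == 0 && sd(y) == 0) {
      eq <- mean(x) == mean(y)
      return(c(mean(x), mean(y), if (eq) 0 else Inf * sign(mean(x) - mean(y)),
               if (eq) 1 else 0))
    }
    tt <- tryCatch(t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)  # near-constant data
    if (is.null(tt)) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(c(mean(x), mean(y), if (eq) 0 else Inf * sign(mean(x) - mean(y)),
               if (eq) 1 else 0))
    }
    c(mean(x), mean(y), unname(tt$statistic), tt$p.value)
  }))
  out <- data.frame(feature = rownames(v),
                    mean1 = res[, 1], mean2 = res[, 2],
                    diff = res[, 1] - res[, 2],
                    t = res[, 3], p = res[, 4],
                    q = p.adjust(res[, 4], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$direction <- sign(out$diff)
  out$dep <- !is.na(out$p) & out$p < alpha
  attr(out, "groups") <- levels(groups)
  out
}

#' Filter phosphoprotein hits explained by their parent protein
#'
#' A differentially expressed phosphoprotein (DEPP) is removed when its
#' parent protein is itself a DEP changing in the same direction, since the
#' site-level change then carries no information beyond total protein
#' abundance.  Opposite-direction and non-DEP parents are kept; phospho
#' features without a mapped parent are kept and flagged.
#'
#' @param depp `DiffTable` for phospho features (from [dep_test()]).
#' @param dep `DiffTable` for proteins.
#' @param parent Named character vector mapping phospho feature ID to parent
#'   protein ID.
#' @return The filtered `DiffTable` (subset of `depp` rows) with an
#'   `unmapped_parent` flag column.  Idempotent.
#' @export
depp_filter <- function(depp, dep, parent) {
  par <- unname(parent[depp$feature])
  j <- match(par, dep$feature)
  parent_dep <- !is.na(j) & dep$dep[j]
  parent_dir <- ifelse(is.na(j), NA_real_, dep$direction[j])
  drop <- parent_dep & !is.na(parent_dir) & parent_dir == depp$direction
  drop[is.na(drop)] <- FALSE
  out <- depp[!drop, , drop = FALSE]
  out$unmapped_parent <- is.na(parent[out$feature]) |
    is.na(match(unname(parent[out$feature]), dep$feature))
  rownames(out) <- NULL
  out
}

#' Per-gene Spearman correlation between mRNA and protein abundance
#'
#' Correlates matched RNA and protein profiles over their shared samples,
#' gene by gene, and reports the fraction of genes with a significantly
#' positive correlation at a given FDR.
#'
#' @param rna,protein Gene x sample matrices with shared rownames
#'   (symbols) and overlapping sample columns.
#' @param min_samples Minimum shared non-missing samples per gene, default 3.
#' @param fdr FDR threshold for the positive-correlation summary, default
#'   0.05.
#' @return List: `table` (gene, n, rho, p, q) and
#'   `positive_significant_fraction`.
#' @export
rna_protein_correlation <- function(rna, protein, min_samples = 3,
                                    fdr = 0.05) {
  rna <- as_values(rna); protein <- as_values(protein)
  genes <- intersect(rownames(rna), rownames(protein))
  samples <- intersect(colnames(rna), colnames(protein))
  if (!length(samples)) stopf("no shared samples")
  rows <- lapply(genes, function(g) {
    x <- rna[g, samples]; y <- protein[g, samples]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) return(NULL)
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(gene = g, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stopf("no gene with >= %d shared samples", min_samples)
  tab$q <- p.adjust(tab$p, method = "BH")
  list(table = tab,
       positive_significant_fraction = mean(tab$rho > 0 & tab$q < fdr))
}
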