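#' Correlation distance between samples
#'
#' Distance `1 - Pearson r` over the features observed in both samples of a
#' pair, the metric used for sample clustering throughout the proteome
#' analysis.
#'
#' @param m Feature x sample numeric matrix (or [intensity_matrix()]).
#' @return Symmetric sample x sample distance matrix with zero diagonal,
#'   entries in `[0, 2]`.
#' @export
correlation_distance <- function(m) {
  v <- as_values(m)
  sds <- apply(v, 2, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    stopf("zero-variance sample(s): %s",
          paste(colnames(v)[is.na(sds) | sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering on a precomputed distance matrix, cut into `k`
#' groups (or at height `h`).
#'
#' @param d Symmetric distance matrix or `dist` object.
#' @param k Number of clusters to cut the tree into (optional).
#' @param h Cut height, alternative to `k`.
#' @param linkage Agglomeration method, default `"complete"`.
#' @return List with the `hclust` tree and, when `k` or `h` is given, integer
#'   `labels` per sample.
#' @export
hcluster <- function(d, k = NULL, h = NULL, linkage = "complete") {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  if (!is.null(k) && (k < 1 || k > n)) stopf("k must be in [1, %d]", n)
  tree <- hclust(dd, method = linkage)
  labels <- if (!is.null(k) || !is.null(h)) cutree(tree, k = k, h = h) else NULL
  list(tree = tree, labels = labels)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of defined off-diagonal consensus values strictly inside the
#' ambiguity interval `(u1, u2)`.  A clean consensus matrix (all 0/1) scores
#' 0; a maximally ambiguous one (all 0.5) scores 1.  Lower is better; the
#' number of clusters is chosen to minimize PAC.
#'
#' @param cm Symmetric consensus matrix; `NA`/`NaN` entries (never
#'   co-sampled pairs) are excluded.
#' @param u1,u2 Ambiguity interval bounds, defaults 0.1 and 0.9.
#' @return PAC score in `[0, 1]`.
#' @export
pac_score <- function(cm, u1 = 0.1, u2 = 0.9) {
  if (u1 >= u2) stopf("u1 must be < u2")
  v <- cm[upper.tri(cm)]
  v <- v[is.finite(v)]
  if (!length(v)) stopf("no defined off-diagonal consensus entries")
  mean(v > u1 & v < u2)
}

#' Consensus clustering with PAC-based K selection
#'
#' Repeatedly subsamples the cohort, clusters each subsample by
#' complete-linkage on the `1 - Pearson` distance, and records for every
#' sample pair how often it co-clusters among the iterations in which it was
#' co-sampled.  PAC is computed per candidate K and the K with minimal PAC
#' (ties toward smaller K) is selected; final labels come from clustering
#' `1 - consensus` at the optimal K.
#'
#' @param m Feature x sample matrix (or [intensity_matrix()]).
#' @param k_range Candidate cluster numbers, default `2:6`.
#' @param n_iter Subsampling iterations, default 1000.
#' @param subsample_frac Fraction of samples drawn (without replacement) per
#'   iteration, default 0.8.
#' @param seed Optional RNG seed for reproducibility.
#' @param u1,u2 PAC ambiguity interval, passed to [pac_score()].
#' @return `consensus_result`: list with `k_range`, `consensus` (one matrix
#'   per K, `NaN` where a pair was never co-sampled), `pac`, `k_opt`,
#'   `labels` (integer, at `k_opt`).
#' @export
consensus_cluster <- function(m, k_range = 2:6, n_iter = 1000,
                              subsample_frac = 0.8, seed = NULL,
                              u1 = 0.1, u2 = 0.9) {
  v <- as_values(m)
  n <- ncol(v)
  if (n_iter < 1) stopf("n_iter must be >= 1")
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stopf("k_range must lie in [2, %d]", n - 1)
  }
  n_sub <- max(2L, floor(subsample_frac * n))
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sort(sample.int(n, n_sub))
      d <- correlation_distance(v[, idx, drop = FALSE])
      tree <- hclust(stats::as.dist(d), method = "complete")
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      for (k in k_range) {
        lab <- cutree(tree, k = k)
        same <- outer(lab, lab, "==") * 1
        kk <- as.character(k)
        co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
      }
    }
  })
  consensus <- lapply(co_clustered, function(cc) {
    cm <- cc / co_sampled           # 0/0 -> NaN marks never-co-sampled pairs
    dimnames(cm) <- list(colnames(v), colnames(v))
    diag(cm) <- 1
    cm
  })
  pac <- vapply(consensus, pac_score, numeric(1), u1 = u1, u2 = u2)
  k_opt <- k_range[which.min(pac)]   # first minimum = smallest K on ties
  dmat <- 1 - consensus[[as.character(k_opt)]]
  dmat[!is.finite(dmat)] <- 0.5
  labels <- hcluster(dmat, k = k_opt)$labels
  names(labels) <- colnames(v)
  structure(list(k_range = k_range, consensus = consensus, pac = pac,
                 k_opt = k_opt, labels = labels),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>\n  PAC:",
      paste(sprintf("K=%d %.3f", x$k_range, x$pac), collapse = ", "),
      sprintf("\n  optimal K = %d; cluster sizes: %s\n", x$k_opt,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Top PC1-loading features
#'
#' Selects the `floor(frac * n)` features with the largest absolute loading
#' on the first principal component (the component that separates the two
#' proteomic subtypes); ties are broken by feature ID order.
#'
#' @param pca A `prcomp` fit of the sample x feature matrix (features as
#'   variables, i.e. `prcomp(t(values))`).
#' @param frac Fraction of features to keep, default 0.10.
#' @return Character vector of selected feature IDs.
#' @export
pc1_top_loadings <- function(pca, frac = 0.10) {
  if (!(is.numeric(frac) && length(frac) == 1 && frac > 0 && frac <= 1)) {
    stopf("`frac` must be in (0, 1]")
  }
  loadings <- pca$rotation[, 1]
  n_keep <- floor(frac * length(loadings))
  ord <- order(-abs(loadings), names(loadings))
  names(loadings)[ord][seq_len(n_keep)]
}

#' Permutation test of cluster-phenotype association
#'
#' Statistic: among all sample pairs sharing a phenotype, the fraction that
#' are also co-clustered (phenotype-pair purity).  The null distribution is
#' obtained by permuting the phenotype labels; the reported p-value uses the
#' add-one estimator `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param clusters Cluster labels per sample.
#' @param phenotype Phenotype labels per sample (at least two classes).
#' @param n_perm Number of permutations, default 1000.
#' @param seed Optional RNG seed.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
label_association_test <- function(clusters, phenotype, n_perm = 1000,
                                   seed = NULL) {
  if (length(clusters) != length(phenotype)) stopf("length mismatch")
  if (length(unique(phenotype)) < 2) {
    stopf("phenotype must have at least two classes")
  }
  purity <- function(ph) {
    same_ph <- outer(ph, ph, "==")[upper.tri(diag(length(ph)))]
    same_cl <- outer(clusters, clusters, "==")[upper.tri(diag(length(ph)))]
    sum(same_ph & same_cl) / sum(same_ph)
  }
  obs <- purity(phenotype)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) purity(sample(phenotype)), numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
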