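#' Build a balanced GPC1-high / GPC2-high gene signature
#'
#' Selects subtype-discriminating genes by two-sample t-test between the
#' labeled groups and returns an equal number from each direction:
#' `mode = "top_n"` takes the `n` smallest p-values per side;
#' `mode = "fdr"` takes all genes at `q < fdr`, trimmed to the smaller
#' side's count so both sides stay balanced.  Optional prefilters address
#' single-cell sparsity: restriction to the most highly expressed genes of
#' the training cohort and to genes detected in at least a fraction of the
#' target cells.
#'
#' @param expr Gene x sample training matrix.
#' @param labels Two-level factor over training samples; level 1 defines
#'   the `gpc1_high` direction.
#' @param mode `"top_n"` (default) or `"fdr"`.
#' @param n Genes per side for `top_n`, default 100.
#' @param fdr FDR cut for `fdr` mode, default 0.10.
#' @param top_expressed Optional count: restrict to this many genes with the
#'   highest mean expression in `expr` before testing.
#' @param cells Optional gene x cell matrix of the data to be classified.
#' @param min_cell_frac With `cells`, keep only genes detected (> 0) in at
#'   least this fraction of cells (default 0.5 when `cells` is given).
#' @return `signature_set`: list with equal-length disjoint `gpc1_high` and
#'   `gpc2_high` gene vectors and a `meta` record of the selection.
#' @export
build_signature <- function(expr, labels, mode = c("top_n", "fdr"),
                            n = 100, fdr = 0.10,
                            top_expressed = NULL, cells = NULL,
                            min_cell_frac = if (is.null(cells)) NULL else 0.5) {
  mode <- match.arg(mode)
  v <- as_values(expr)
  if (!is.null(top_expressed)) {
    keep <- names(sort(rowMeans(v, na.rm = TRUE), decreasing = TRUE))
    v <- v[keep[seq_len(min(top_expressed, nrow(v)))], , drop = FALSE]
  }
  if (!is.null(cells) && !is.null(min_cell_frac)) {
    shared <- intersect(rownames(v), rownames(cells))
    frac <- rowMeans(cells[shared, , drop = FALSE] > 0, na.rm = TRUE)
    v <- v[shared[frac >= min_cell_frac], , drop = FALSE]
  }
  tab <- dep_test(v, labels)
  up <- tab[!is.na(tab$p) & tab$direction > 0, ]
  dn <- tab[!is.na(tab$p) & tab$direction < 0, ]
  if (mode == "top_n") {
    if (nrow(up) < n || nrow(dn) < n) {
      stopf("not enough eligible genes: %d GPC1-high, %d GPC2-high (need %d per side)",
            nrow(up), nrow(dn), n)
    }
    g1 <- up$feature[order(up$p)][seq_len(n)]
    g2 <- dn$feature[order(dn$p)][seq_len(n)]
  } else {
    up <- up[up$q < fdr, ]; dn <- dn[dn$q < fdr, ]
    k <- min(nrow(up), nrow(dn))
    if (k == 0) stopf("no genes pass FDR < %g on both sides", fdr)
    g1 <- up$feature[order(up$p)][seq_len(k)]
    g2 <- dn$feature[order(dn$p)][seq_len(k)]
  }
  signature_set(g1, g2, meta = list(mode = mode, n = n, fdr = fdr,
                                    top_expressed = top_expressed,
                                    min_cell_frac = min_cell_frac))
}

#' Construct a signature set
#'
#' @param gpc1_high,gpc2_high Equal-length, disjoint, non-empty gene
#'   vectors.
#' @param meta Optional selection metadata list.
#' @return `signature_set` object.
#' @export
signature_set <- function(gpc1_high, gpc2_high, meta = list()) {
  gpc1_high <- as.character(gpc1_high); gpc2_high <- as.character(gpc2_high)
  if (!length(gpc1_high) || length(gpc1_high) != length(gpc2_high)) {
    stopf("signature sides must be non-empty and of equal size")
  }
  if (length(intersect(gpc1_high, gpc2_high))) {
    stopf("signature sides must be disjoint")
  }
  structure(list(gpc1_high = gpc1_high, gpc2_high = gpc2_high, meta = meta),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d GPC1-high / %d GPC2-high genes\n",
              length(x$gpc1_high), length(x$gpc2_high)))
  invisible(x)
}

#' Signature delta-Z score of one sample or cell
#'
#' `mean(z[GPC1-high]) - mean(z[GPC2-high])`: positive values indicate a
#' GPC1-like profile, negative values GPC2-like.  Adding a constant to every
#' gene leaves the score unchanged; swapping the signature sides negates it.
#'
#' @param z Named numeric vector of per-gene z-scores covering all signature
#'   genes.
#' @param sig A [signature_set()].
#' @return The delta-Z score.
#' @export
delta_z <- function(z, sig) {
  genes <- c(sig$gpc1_high, sig$gpc2_high)
  missing <- setdiff(genes, names(z))
  if (length(missing)) {
    stopf("signature gene(s) missing from z: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  mean(z[sig$gpc1_high]) - mean(z[sig$gpc2_high])
}

# Permutation |delta-Z| draws for one z-vector: which genes count as
# GPC1-high is re-drawn n_perm times over the signature union.
perm_delta_z <- function(zg, n1, n_perm) {
  g <- length(zg); n2 <- g - n1
  tot <- sum(zg)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(g, n1), integer(n1))
  s1 <- colSums(matrix(zg[idx], nrow = n1))
  s1 / n1 - (tot - s1) / n2
}

#' Gene-label permutation p-value for a delta-Z score
#'
#' Permutes which signature genes belong to each side (side sizes
#' preserved) and reports the add-one two-sided estimate
#' `(1 + #{|dZ_perm| >= |dZ_obs|}) / (n_perm + 1)`, bounded below by
#' `1/(n_perm + 1)`.
#'
#' @inheritParams delta_z
#' @param n_perm Number of permutations, default 1000.
#' @param seed Optional RNG seed.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(z, sig, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  obs <- delta_z(z, sig)
  zg <- z[c(sig$gpc1_high, sig$gpc2_high)]
  perm <- with_seed(seed, perm_delta_z(zg, length(sig$gpc1_high), n_perm))
  (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
}

#' Classify cells (or samples) by signature delta-Z with permutation test
#'
#' Computes the delta-Z score and its gene-label permutation p-value for
#' every column and calls GPC1 when `delta_z > 0` and `p < alpha`, GPC2 when
#' `delta_z < 0` and `p < alpha`, otherwise `unassigned`.
#'
#' @param z Gene x cell matrix of z-scores covering all signature genes.
#' @param sig A [signature_set()].
#' @param alpha Call threshold on the permutation p-value, default 0.05.
#' @param n_perm Permutations per cell, default 1000.
#' @param seed Optional RNG seed (one stream over all cells; fixed seed
#'   reproduces the full result).
#' @return Data frame `cell`, `delta_z`, `p_perm`, `call`.
#' @export
classify_cells <- function(z, sig, alpha = 0.05, n_perm = 1000, seed = NULL) {
  v <- as_values(z)
  genes <- c(sig$gpc1_high, sig$gpc2_high)
  missing <- setdiff(genes, rownames(v))
  if (length(missing)) {
    stopf("signature gene(s) missing from matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  if (n_perm < 1) stopf("n_perm must be >= 1")
  n1 <- length(sig$gpc1_high)
  vg <- v[genes, , drop = FALSE]
  dz <- colMeans(vg[seq_len(n1), , drop = FALSE]) -
    colMeans(vg[n1 + seq_len(n1), , drop = FALSE])
  p <- with_seed(seed, {
    vapply(seq_len(ncol(vg)), function(j) {
      perm <- perm_delta_z(vg[, j], n1, n_perm)
      (1 + sum(abs(perm) >= abs(dz[j]))) / (n_perm + 1)
    }, numeric(1))
  })
  call <- ifelse(p < alpha, ifelse(dz > 0, "GPC1", "GPC2"), "unassigned")
  data.frame(cell = colnames(v) %||% as.character(seq_len(ncol(v))),
             delta_z = dz, p_perm = p, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge two expression cohorts by quantile normalization
#'
#' Restricts both cohorts to their shared genes, concatenates the samples
#' and quantile-normalizes the merged matrix so that every sample's sorted
#' value vector equals the mean-of-order-statistics reference — the standard
#' device for suppressing cohort-level batch effects before surrogate
#' classification.
#'
#' @param a,b Gene x sample matrices with overlapping rownames.
#' @return Merged, quantile-normalized gene x sample matrix.
#' @export
quantile_merge <- function(a, b) {
  a <- as_values(a); b <- as_values(b)
  genes <- intersect(rownames(a), rownames(b))
  if (!length(genes)) stopf("cohorts share no genes")
  merged <- cbind(a[genes, , drop = FALSE], b[genes, , drop = FALSE])
  if (anyDuplicated(colnames(merged))) stopf("cohorts share sample IDs")
  out <- limma::normalizeQuantiles(merged)
  dimnames(out) <- dimnames(merged)
  out
}

#' Probability-thresholded surrogate bulk classification
#'
#' Trains a random-forest classifier on the top differential genes of the
#' labeled training cohort after quantile-merging it with the test cohort;
#' the forest's parameters are selected by internal 5-fold cross-validation
#' over an `mtry` grid.  A test sample receives a subtype call only when the
#' predicted class probability reaches `prob_threshold`, otherwise it is
#' left `unassigned`.
#'
#' @param train Gene x sample training matrix.
#' @param train_labels Two-level factor over training samples.
#' @param test Gene x sample matrix to classify.
#' @param prob_threshold Minimum winning-class probability for a call,
#'   default 0.60.
#' @param top_n_genes Number of top differential genes (by t-test p-value)
#'   used as features, default 100.
#' @param n_tree Trees per forest, default 500.
#' @param seed Optional RNG seed.
#' @return Data frame `sample`, one probability column per class, `prob`
#'   (winning class), `call`.
#' @export
surrogate_bulk_classify <- function(train, train_labels, test,
                                    prob_threshold = 0.60,
                                    top_n_genes = 100, n_tree = 500,
                                    seed = NULL) {
  train <- as_values(train); test <- as_values(test)
  train_labels <- droplevels(as.factor(train_labels))
  if (nlevels(train_labels) != 2) stopf("training labels must have two classes")
  tab <- dep_test(train, train_labels)
  tab <- tab[!is.na(tab$p), ]
  sel <- tab$feature[order(tab$p)][seq_len(min(top_n_genes, nrow(tab)))]
  sel <- intersect(sel, rownames(test))
  if (length(sel) < 2) stopf("fewer than two selected genes shared with test")
  merged <- quantile_merge(train[sel, , drop = FALSE],
                           test[sel, , drop = FALSE])
  xtr <- t(merged[, colnames(train), drop = FALSE])
  xte <- t(merged[, colnames(test), drop = FALSE])
  with_seed(seed, {
    p <- ncol(xtr)
    grid <- unique(pmax(1, pmin(p, c(floor(sqrt(p) / 2), floor(sqrt(p)),
                                     2 * floor(sqrt(p))))))
    folds <- sample(rep(seq_len(5), length.out = nrow(xtr)))
    cv_acc <- vapply(grid, function(mt) {
      hits <- vapply(seq_len(5), function(f) {
        tr <- folds != f
        if (length(unique(train_labels[tr])) < 2) return(NA_real_)
        fit <- randomForest::randomForest(xtr[tr, , drop = FALSE],
                                          train_labels[tr],
                                          mtry = mt, ntree = n_tree)
        mean(predict(fit, xtr[!tr, , drop = FALSE]) == train_labels[!tr])
      }, numeric(1))
      mean(hits, na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(cv_acc)]
    fit <- randomForest::randomForest(xtr, train_labels, mtry = best,
                                      ntree = n_tree)
    prob <- predict(fit, xte, type = "prob")
    win <- apply(prob, 1, which.max)
    pw <- prob[cbind(seq_len(nrow(prob)), win)]
    out <- data.frame(sample = colnames(test), prob,
                      prob_win = pw,
                      call = ifelse(pw >= prob_threshold,
                                    colnames(prob)[win], "unassigned"),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "mtry") <- best
    out
  })
}
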