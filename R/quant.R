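#' Normalize raw TMT intensities against the global internal standard
#'
#' Each sample's reporter intensity is divided by the GIS intensity of the
#' same feature in the sample's TMT set and converted to the log2 scale.
#' Missing raw values propagate to missing ratios.
#'
#' @param x An [intensity_matrix()] in `"raw"` state.
#' @param gis Numeric matrix of GIS intensities, features x TMT sets
#'   (columns named by `tmt_set`).  Every feature quantified in a set must
#'   have a positive GIS entry there.
#' @return An [intensity_matrix()] in `"log2"` state with
#'   `out[f, s] = log2(raw[f, s] / gis[f, set(s)])`.
#' @export
gis_normalize <- function(x, gis) {
  if (!inherits(x, "intensity_matrix") || x$state != "raw") {
    stopf("`x` must be an intensity_matrix in raw state")
  }
  if (is.null(rownames(gis)) || is.null(colnames(gis))) {
    stopf("`gis` needs feature rownames and TMT-set colnames")
  }
  sets <- x$samples$tmt_set
  if (!all(unique(sets) %in% colnames(gis))) {
    stopf("GIS column missing for TMT set(s): %s",
          paste(setdiff(unique(sets), colnames(gis)), collapse = ", "))
  }
  miss <- setdiff(rownames(x$values), rownames(gis))
  if (length(miss)) stopf("no GIS entry for feature(s): %s",
                          paste(head(miss, 5), collapse = ", "))
  g <- gis[rownames(x$values), sets, drop = FALSE]
  bad <- !is.na(x$values) & (is.na(g) | g <= 0)
  if (any(bad)) {
    f <- rownames(x$values)[which(rowSums(bad) > 0)]
    stopf("non-positive or missing GIS for quantified feature(s): %s",
          paste(head(f, 5), collapse = ", "))
  }
  out <- log2(x$values / g)
  intensity_matrix(out, state = "log2", samples = x$samples)
}

#' Sample-wise then batch-restricted feature-wise median centering
#'
#' First subtracts each sample's median over all features, then, within each
#' GIS batch, subtracts each feature's median over that batch's samples.
#' After the second step every feature's within-batch median is exactly 0,
#' which removes batch-level location offsets before the two GIS batches are
#' combined.
#'
#' @param x An [intensity_matrix()] in `"log2"` state.
#' @return A centered [intensity_matrix()].
#' @export
median_center <- function(x) {
  if (!inherits(x, "intensity_matrix") || x$state != "log2") {
    stopf("`x` must be an intensity_matrix in log2 state")
  }
  if (anyNA(x$samples$gis_batch)) {
    stopf("sample(s) without GIS batch assignment: %s",
          paste(x$samples$sample[is.na(x$samples$gis_batch)], collapse = ", "))
  }
  v <- x$values
  smed <- apply(v, 2, median, na.rm = TRUE)
  v <- sweep(v, 2, smed, "-")
  for (b in unique(x$samples$gis_batch)) {
    idx <- which(x$samples$gis_batch == b)
    fmed <- apply(v[, idx, drop = FALSE], 1, median, na.rm = TRUE)
    fmed[is.na(fmed)] <- 0  # feature entirely missing in this batch
    v[, idx] <- sweep(v[, idx, drop = FALSE], 1, fmed, "-")
  }
  intensity_matrix(v, state = "log2", samples = x$samples)
}

#' Impute missing entries with the second-smallest observed value
#'
#' Missing measurements are replaced by the second order statistic of the
#' observed values, by default within each feature row (`scope = "feature"`);
#' `scope = "global"` uses the second-smallest value of the whole matrix.
#' Duplicated minima count twice, so a row `(NA, 5, 5)` imputes 5.
#'
#' @param x An [intensity_matrix()].
#' @param scope `"feature"` (default) or `"global"`.
#' @return An [intensity_matrix()] with no missing entries in rows that had
#'   at least two observations.
#' @export
impute_second_smallest <- function(x, scope = c("feature", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (!anyNA(v)) return(x)
  if (scope == "global") {
    obs <- sort(v[!is.na(v)])
    if (length(obs) < 2) stopf("fewer than two observed values in the matrix")
    v[is.na(v)] <- obs[2]
  } else {
    for (i in which(rowSums(is.na(v)) > 0)) {
      obs <- sort(v[i, !is.na(v[i, ])])
      if (length(obs) < 2) {
        stopf("feature '%s' has missing entries but fewer than two observed values",
              rownames(v)[i])
      }
      v[i, is.na(v[i, ])] <- obs[2]
    }
  }
  intensity_matrix(v, state = x$state, samples = x$samples)
}

#' Filter features by GIS coverage
#'
#' Keeps features observed (non-missing in at least one sample) in at least
#' `min_gis` GIS groups.  The global-proteome convention is coverage in all
#' groups; the sparser phosphoproteome uses `min_gis = 3` over TMT sets.
#'
#' @param x An [intensity_matrix()].
#' @param min_gis Minimum number of covered GIS groups; `0` keeps everything.
#' @param by Sample-map column defining the GIS group: `"gis_batch"`
#'   (default) or `"tmt_set"`.
#' @return The filtered [intensity_matrix()].
#' @export
filter_gis_coverage <- function(x, min_gis, by = c("gis_batch", "tmt_set")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "intensity_matrix"))
  groups <- x$samples[[by]]
  n_groups <- length(unique(groups))
  if (min_gis > n_groups) {
    stopf("min_gis (%d) exceeds the number of GIS groups (%d)", min_gis, n_groups)
  }
  if (min_gis <= 0) return(x)
  covered <- sapply(unique(groups), function(g) {
    rowSums(!is.na(x$values[, groups == g, drop = FALSE])) > 0
  })
  keep <- rowSums(covered) >= min_gis
  intensity_matrix(x$values[keep, , drop = FALSE], state = x$state,
                   samples = x$samples)
}

#' Aggregate phosphopeptides into phospho-site intensities
#'
#' Peptide intensities sharing a phospho-site are first averaged within each
#' phosphorylation class (mono-, di-, tri-or-more), then combined with the
#' self-weighted sum
#' \deqn{I_s = \sum_n I_{sn}^2 / \sum_n I_{sn}}
#' over the classes present, which up-weights the class with the higher
#' intensity.  Absent or zero classes are excluded from both sums; a
#' site/sample with no observed class stays missing.  The result is log2
#' transformed unless `log2 = FALSE`.
#'
#' @param tbl Data frame with columns `site`, `pclass` (1, 2 or 3, where 3
#'   means tri-or-more), `sample`, `intensity` (raw, non-negative).
#' @param log2 Return log2-transformed site intensities (default `TRUE`).
#' @return Numeric site x sample matrix.
#' @examples
#' tbl <- data.frame(site = "S1", pclass = c(1, 2), sample = "A",
#'                   intensity = c(3, 1))
#' aggregate_phospho_sites(tbl, log2 = FALSE)  # (9 + 1) / 4 = 2.5
#' @export
aggregate_phospho_sites <- function(tbl, log2 = TRUE) {
  need <- c("site", "pclass", "sample", "intensity")
  if (!all(need %in% names(tbl))) {
    stopf("`tbl` must have columns %s", paste(need, collapse = ", "))
  }
  if (any(tbl$intensity < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  if (!all(tbl$pclass %in% 1:3)) stopf("`pclass` must be 1, 2 or 3")
  tbl <- tbl[!is.na(tbl$intensity), , drop = FALSE]
  # class-level average per (site, class, sample)
  cls <- stats::aggregate(intensity ~ site + pclass + sample, data = tbl,
                          FUN = mean)
  sites <- sort(unique(cls$site))
  samples <- sort(unique(cls$sample))
  out <- matrix(NA_real_, length(sites), length(samples),
                dimnames = list(sites, samples))
  key <- interaction(cls$site, cls$sample, drop = TRUE)
  for (k in levels(key)) {
    rows <- cls[key == k, , drop = FALSE]
    i <- rows$intensity[rows$intensity > 0]
    if (!length(i)) next                       # all-zero classes -> missing
    out[rows$site[1], rows$sample[1]] <- sum(i^2) / sum(i)
  }
  if (log2) base::log2(out) else out
}

#' Collapse redundant protein isoform rows
#'
#' Rows whose value vectors are identical across all samples (including the
#' missingness pattern) and that share a gene symbol are merged into a
#' single row named after the symbol with member IDs recorded; rows with
#' differing quantification (true isoform signal, e.g. PKM1 vs PKM2
#' peptides) are retained separately.
#'
#' @param x An [intensity_matrix()] or plain matrix.
#' @param groups Named character vector mapping feature ID to gene symbol;
#'   features absent from the map are left untouched.
#' @return Object of the same type with merged rows; the mapping of merged
#'   IDs is in `attr(, "members")`.
#' @export
collapse_isoforms <- function(x, groups) {
  v <- as_values(x)
  sym <- groups[rownames(v)]
  keep <- rep(TRUE, nrow(v))
  members <- list()
  newname <- rownames(v)
  for (g in unique(sym[!is.na(sym)])) {
    idx <- which(!is.na(sym) & sym == g)
    if (length(idx) < 2) next
    sig <- apply(v[idx, , drop = FALSE], 1, function(r) paste(r, collapse = "\r"))
    for (s in unique(sig)) {
      grp <- idx[sig == s]
      if (length(grp) < 2) next
      lead <- grp[1]
      keep[grp[-1]] <- FALSE
      newname[lead] <- if (sum(sig == s) == length(sig)) g else rownames(v)[lead]
      members[[newname[lead]]] <- rownames(v)[grp]
    }
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- newname[keep]
  if (inherits(x, "intensity_matrix")) {
    out <- intensity_matrix(out, state = x$state, samples = x$samples)
  }
  attr(out, "members") <- members
  out
}
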