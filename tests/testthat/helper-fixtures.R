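# Shared fixtures and independent oracles, built in code at test time.

toy_intensity <- function(values, state = "log2", batch = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  smap <- data.frame(sample = colnames(values),
                     tmt_set = batch %||% rep("set1", ncol(values)),
                     gis_batch = batch %||% rep("batch1", ncol(values)))
  intensity_matrix(values, state = state, samples = smap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_signature <- function(n = 5) {
  signature_set(paste0("up", seq_len(n)), paste0("dn", seq_len(n)))
}

# Independent adjusted Rand index (contingency-table closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Brute-force agglomerative clustering oracle: repeatedly merge the two
# clusters with the smallest complete-linkage distance.
brute_agglomerate <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

# Exhaustive tryptic-digest oracle: every peptide delimited by a subset of
# cleavage boundaries, with per-side missed-cleavage and length filters.
brute_digest <- function(protein, var_start, var_end, min_len = 8,
                         max_missed = 3, n_allow = max_missed) {
  n <- nchar(protein)
  ch <- strsplit(protein, "")[[1]]
  sites <- which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
  bounds <- c(0L, sites, n)
  peps <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in (i + 1):length(bounds)) {
      s <- bounds[i] + 1L; e <- bounds[j]
      if (e - s + 1L < min_len) next
      if (e < var_start || s > var_end) next
      inner <- sites[sites > bounds[i] & sites < bounds[j]]
      if (sum(inner < var_start) > n_allow) next
      if (sum(inner >= var_end) > max_missed) next
      peps <- c(peps, substr(protein, s, e))
    }
  }
  sort(unique(peps))
}

# Brute-force Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
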