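#' Smooth a drug screen by removing abnormally high viability points
#'
#' Within each (drug, concentration) stratum across all screened cell lines,
#' a data point is removed only when BOTH conditions hold: its normalized
#' viability exceeds 1.5 AND it exceeds `Q3 + 3 * IQR` of the stratum
#' (quantiles with linear interpolation, type 7).  Strata with fewer than
#' four points cannot support the IQR rule, so their points are kept and
#' flagged.  Drug-cell pairs left with no retained point at any
#' concentration are excluded from downstream use and recorded in
#' `attr(, "dropped_pairs")`.
#'
#' @param df Long-format data frame: `drug`, `cell`, `conc_um`, `viability`.
#' @return `df` with logical columns `retained` and `small_stratum`, plus
#'   the `dropped_pairs` attribute.
#' @export
smooth_viability <- function(df) {
  need <- c("drug", "cell", "conc_um", "viability")
  if (!all(need %in% names(df))) {
    stopf("`df` must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$conc_um <= 0)) stopf("concentrations must be positive")
  df$retained <- TRUE
  df$small_stratum <- FALSE
  key <- interaction(df$drug, df$conc_um, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- df$viability[idx]
    if (length(idx) < 4) {
      df$small_stratum[idx] <- TRUE
      next
    }
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    thr <- q[2] + 3 * (q[2] - q[1])
    df$retained[idx] <- !(v > 1.5 & v > thr)
  }
  pair <- interaction(df$drug, df$cell, drop = TRUE)
  kept_any <- tapply(df$retained, pair, any)
  dropped <- names(kept_any)[!kept_any]
  df$retained[pair %in% dropped] <- FALSE
  attr(df, "dropped_pairs") <- dropped
  df
}

#' Normalized trapezoidal AUC of a viability curve
#'
#' Trapezoid rule of viability against log10 concentration, divided by the
#' log10 dose range, so a flat fully-viable curve scores 1 and a flat dead
#' curve scores 0 regardless of the dose grid.  Lower AUC means higher
#' sensitivity.
#'
#' @param conc_um Positive concentrations (any order).
#' @param viability Matching viabilities.
#' @return AUC, or `NA` (with a warning) for fewer than two points.
#' @export
auc_trapezoid <- function(conc_um, viability) {
  ok <- !is.na(conc_um) & !is.na(viability)
  conc_um <- conc_um[ok]; viability <- viability[ok]
  if (length(conc_um) < 2) {
    warning("fewer than two retained points; AUC undefined")
    return(NA_real_)
  }
  if (any(conc_um <= 0)) stopf("concentrations must be positive")
  ord <- order(conc_um)
  x <- log10(conc_um[ord]); y <- viability[ord]
  pracma::trapz(x, y) / (max(x) - min(x))
}

#' Fit a four-parameter log-logistic dose-response model
#'
#' Least-squares fit of
#' `f(x) = c + (d - c) / (1 + exp(b * (log x - log e)))`
#' (lower asymptote `c >= 0`, upper asymptote `d <= 1.5`, slope `b`,
#' inflection `e` = ED50 in uM) by Levenberg-Marquardt with multiple starts
#' of `e` at dose-grid quantiles to avoid local minima.  If the fitted ED50
#' exceeds the highest tested dose (`max_dose`, default 20 uM), `max_dose`
#' is assigned; a failed fit also assigns `max_dose` and flags the status.
#'
#' @param conc_um Positive concentrations.
#' @param viability Matching viabilities (at least four points for a fit).
#' @param max_dose Highest tested dose in uM, default 20.
#' @return `dose_response_fit`: list with `params` (b, c, d, e), `ed50_um`
#'   (the fitted inflection), `ed50_assigned`, `auc`, `status`
#'   (`"ok"`, `"capped"` or `"failed"`), `n_points`.
#' @export
fit_4pl <- function(conc_um, viability, max_dose = 20) {
  ok <- !is.na(conc_um) & !is.na(viability)
  conc_um <- conc_um[ok]; viability <- viability[ok]
  if (any(conc_um <= 0)) stopf("concentrations must be positive")
  auc <- if (length(conc_um) >= 2) {
    auc_trapezoid(conc_um, viability)
  } else NA_real_
  fail <- function(status) {
    structure(list(params = c(b = NA_real_, c = NA_real_, d = NA_real_,
                              e = NA_real_),
                   ed50_um = NA_real_, ed50_assigned = max_dose, auc = auc,
                   status = status, n_points = length(conc_um)),
              class = "dose_response_fit")
  }
  if (length(conc_um) < 4) return(fail("failed"))
  f4pl <- function(x, b, cc, d, e) cc + (d - cc) / (1 + exp(b * (log(x) - log(e))))
  e_starts <- unique(quantile(conc_um, c(0.1, 0.3, 0.5, 0.7, 0.9),
                              type = 7, names = FALSE))
  best <- NULL; best_sse <- Inf
  for (e0 in e_starts) {
    for (b0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          viability ~ f4pl(conc_um, b, cc, d, e),
          start = list(b = b0, cc = max(0, min(viability)),
                       d = min(1.5, max(viability)), e = e0),
          lower = c(b = -50, cc = 0, d = 0, e = min(conc_um) * 1e-4),
          upper = c(b = 50, cc = 1.5, d = 1.5, e = max(conc_um) * 1e4),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      sse <- sum(residuals(fit)^2)
      if (sse < best_sse) { best_sse <- sse; best <- fit }
    }
  }
  if (is.null(best)) return(fail("failed"))
  p <- coef(best)
  ed50 <- unname(p["e"])
  structure(list(params = c(b = unname(p["b"]), c = unname(p["cc"]),
                            d = unname(p["d"]), e = ed50),
                 ed50_um = ed50,
                 ed50_assigned = min(ed50, max_dose),
                 auc = auc,
                 status = if (ed50 > max_dose) "capped" else "ok",
                 n_points = length(conc_um)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> status=%s ED50=%.4g uM (assigned %.4g), AUC=%.3f, n=%d\n",
              x$status, x$ed50_um, x$ed50_assigned, x$auc, x$n_points))
  invisible(x)
}

#' Summarize a smoothed drug screen into per-pair AUC and ED50
#'
#' Applies [auc_trapezoid()] and [fit_4pl()] to the retained points of every
#' (drug, cell) pair.
#'
#' @param df Output of [smooth_viability()] (or a raw long table; points
#'   with `retained = FALSE` are excluded when the column exists).
#' @param max_dose Highest tested dose in uM for the ED50 cap, default 20.
#' @return Data frame `drug`, `cell`, `n_points`, `auc`, `ed50_um`,
#'   `ed50_assigned`, `status`.
#' @export
summarize_dose_response <- function(df, max_dose = 20) {
  if ("retained" %in% names(df)) df <- df[df$retained, , drop = FALSE]
  key <- interaction(df$drug, df$cell, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    fit <- fit_4pl(sub$conc_um, sub$viability, max_dose = max_dose)
    data.frame(drug = sub$drug[1], cell = sub$cell[1],
               n_points = nrow(sub), auc = fit$auc,
               ed50_um = fit$ed50_um, ed50_assigned = fit$ed50_assigned,
               status = fit$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subtype-selective drugs by two-sample Kolmogorov-Smirnov test
#'
#' For each drug and response metric, compares the metric's distribution
#' between the two subtype groups; the sensitive subtype is the one with
#' the lower mean response (lower AUC or ED50 = more sensitive).  Drugs with
#' fewer than `min_n` cells in either group are skipped.
#'
#' @param summaries Output of [summarize_dose_response()].
#' @param labels Named vector/factor of subtype labels per cell line.
#' @param metrics Response columns to test, default `auc` and
#'   `ed50_assigned`.
#' @param min_n Minimum group size, default 3.
#' @return Data frame `drug`, `metric`, `p`, `sensitive_subtype`.
#' @export
subtype_selectivity <- function(summaries, labels,
                                metrics = c("auc", "ed50_assigned"),
                                min_n = 3) {
  labels <- setNames(as.character(labels),
                     names(labels) %||% unique(summaries$cell))
  lev <- sort(unique(labels))
  if (length(lev) != 2) stopf("labels must have exactly two subtypes")
  rows <- list()
  for (dr in unique(summaries$drug)) {
    sub <- summaries[summaries$drug == dr, , drop = FALSE]
    grp <- labels[sub$cell]
    for (met in metrics) {
      x <- sub[[met]][grp == lev[1]]; y <- sub[[met]][grp == lev[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_n || length(y) < min_n) next
      p <- suppressWarnings(ks.test(x, y)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        drug = dr, metric = met, p = p,
        sensitive_subtype = if (mean(x) <= mean(y)) lev[1] else lev[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(drug = character(), metric = character(),
                      p = numeric(), sensitive_subtype = character()))
  }
  do.call(rbind, rows)
}

#' Spearman correlation between molecular features and drug response
#'
#' Correlates each feature's abundance with each drug's response metric
#' across the shared cell lines; BH FDR is computed per metric over all
#' tested (feature, drug) pairs.
#'
#' @param features Feature x cell matrix (protein or phosphoprotein
#'   abundance).
#' @param summaries Output of [summarize_dose_response()].
#' @param metrics Response columns, default `auc` and `ed50_assigned`.
#' @param min_shared Minimum shared non-missing cells per pair, default 5.
#' @return Data frame `feature`, `drug`, `metric`, `n`, `rho`, `p`, `q`.
#' @export
biomarker_correlation <- function(features, summaries,
                                  metrics = c("auc", "ed50_assigned"),
                                  min_shared = 5) {
  v <- as_values(features)
  rows <- list()
  for (met in metrics) {
    for (dr in unique(summaries$drug)) {
      sub <- summaries[summaries$drug == dr, , drop = FALSE]
      resp <- setNames(sub[[met]], sub$cell)
      cells <- intersect(colnames(v), names(resp)[!is.na(resp)])
      for (f in rownames(v)) {
        x <- v[f, cells]; y <- resp[cells]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < min_shared) next
        ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, drug = dr, metric = met, n = sum(ok),
          rho = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(feature = character(), drug = character(),
                      metric = character(), n = integer(), rho = numeric(),
                      p = numeric(), q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (met in metrics) {
    sel <- out$metric == met
    out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out
}
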