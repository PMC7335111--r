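#' Intensity matrix with sample annotations
#'
#' Container for a feature x sample abundance table together with its
#' quantification state and the TMT set / GIS batch assignment of every
#' sample.  `values` holds raw positive reporter intensities
#' (`state = "raw"`) or log2 GIS ratios (`state = "log2"`); missing
#' measurements are `NA` (never a sentinel number).
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param state `"raw"` for positive intensities, `"log2"` for normalized
#'   log2 ratios.
#' @param samples Data frame with columns `sample`, `tmt_set`, `gis_batch`;
#'   one row per column of `values`.  Defaults to a single set/batch.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `state` and `samples`.
#' @examples
#' m <- matrix(2^rnorm(12), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' im <- intensity_matrix(m, state = "raw")
#' @export
intensity_matrix <- function(values, state = c("log2", "raw"), samples = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate feature IDs")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample IDs")
  if (state == "raw" && any(values < 0, na.rm = TRUE)) {
    stopf("raw intensities must be non-negative where present")
  }
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(values),
                          tmt_set = "set1", gis_batch = "batch1",
                          stringsAsFactors = FALSE)
  }
  need <- c("sample", "tmt_set", "gis_batch")
  if (!all(need %in% names(samples))) {
    stopf("`samples` must have columns %s", paste(need, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) {
    stopf("every column of `values` needs a row in `samples`")
  }
  rownames(samples) <- NULL
  structure(list(values = values, state = state, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  missing: %d entries; %d TMT set(s), %d GIS batch(es)\n",
              sum(is.na(x$values)), length(unique(x$samples$tmt_set)),
              length(unique(x$samples$gis_batch))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

as_values <- function(m) {
  if (inherits(m, "intensity_matrix")) m$values else m
}
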