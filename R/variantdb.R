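#' Transcript model for variant-peptide database construction
#'
#' Holds a transcript's nucleotide sequence (coding region followed by any
#' available downstream sequence, so stop-loss read-through can be
#' translated), an expression value on the FPKM scale, and per-nucleotide
#' read depth used to bound stop-loss extension.
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence (A/C/G/T), starting at the first codon of
#'   the CDS; must contain an in-frame stop codon.
#' @param fpkm Expression value; transcripts at `fpkm <= 1` are excluded
#'   from database construction.
#' @param depth Integer read depth per nucleotide of `seq`; defaults to a
#'   uniform high depth.
#' @return `transcript_model` object.
#' @export
transcript_model <- function(id, seq, fpkm = 10, depth = NULL) {
  seq <- toupper(seq)
  if (nchar(seq) < 6 || grepl("[^ACGT]", seq)) {
    stopf("`seq` must be an A/C/G/T string of length >= 6")
  }
  if (is.null(depth)) depth <- rep(100L, nchar(seq))
  if (length(depth) != nchar(seq)) stopf("`depth` must match sequence length")
  if (any(depth < 0)) stopf("depth must be >= 0")
  obj <- structure(list(id = id, seq = seq, fpkm = fpkm,
                        depth = as.integer(depth)),
                   class = "transcript_model")
  if (is.na(translate_cds(seq)$stop_at)) {
    stopf("transcript '%s' has no in-frame stop codon", id)
  }
  obj
}

# Translate from position 1 until the first stop codon (or sequence end).
# Returns protein string and the codon index of the stop (NA when no stop
# was reached).
translate_cds <- function(seq, from_codon = 1) {
  code <- Biostrings::GENETIC_CODE
  n_codons <- nchar(seq) %/% 3
  aa <- character(0)
  stop_at <- NA_integer_
  for (i in from_codon:n_codons) {
    codon <- substr(seq, 3 * i - 2, 3 * i)
    r <- code[[codon]]
    if (r == "*") { stop_at <- i; break }
    aa <- c(aa, r)
  }
  list(protein = paste(aa, collapse = ""), stop_at = stop_at)
}

#' Apply variants to a transcript and translate
#'
#' Each variant (SNV, insertion or deletion) is applied to the nucleotide
#' sequence individually and the mutated sequence translated from the start
#' codon.  Variants that create a stop codon at the first affected position
#' (stop gain) are skipped: no sequence is emitted, because peptides ending
#' there cannot be distinguished from ordinary enzymatic termination.  When
#' a variant destroys the reference stop codon (stop loss), translation
#' continues past it for at most 20 extra residues, each requiring read
#' depth > 3 at all three of its nucleotides, and stops earlier at a new
#' stop codon.
#'
#' @param tm A [transcript_model()].
#' @param variants Data frame with columns `pos` (1-based nucleotide
#'   position in `tm$seq`), `ref`, `alt` (allele strings; lengths may
#'   differ for indels), and optionally `id`.
#' @param max_extension Stop-loss residue cap, default 20.
#' @param min_depth Depth threshold for extension (strictly greater),
#'   default 3.
#' @return List with one entry per variant: `variant` (description),
#'   `protein` (mutated sequence or `NULL` when skipped), `var_start`,
#'   `var_end` (affected protein positions), `stop_loss`, `skipped`.
#' @export
translate_with_variants <- function(tm, variants, max_extension = 20,
                                    min_depth = 3) {
  stopifnot(inherits(tm, "transcript_model"))
  ref_tr <- translate_cds(tm$seq)
  l_ref <- nchar(ref_tr$protein)           # residues before the ref stop
  if (nrow(variants) == 0) {
    return(list(list(variant = "reference", protein = ref_tr$protein,
                     var_start = NA, var_end = NA, stop_loss = FALSE,
                     skipped = FALSE)))
  }
  lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ref <- toupper(v$ref); alt <- toupper(v$alt)
    if (identical(ref, alt)) stopf("ref and alt alleles are identical")
    if (v$pos < 1 || v$pos + nchar(ref) - 1 > nchar(tm$seq)) {
      stopf("variant position %d out of range for transcript '%s'",
            v$pos, tm$id)
    }
    if (substr(tm$seq, v$pos, v$pos + nchar(ref) - 1) != ref) {
      stopf("reference allele mismatch at position %d of '%s'", v$pos, tm$id)
    }
    desc <- v$id %||% sprintf("%s:%d%s>%s", tm$id, v$pos,
                              ifelse(ref == "", "-", ref),
                              ifelse(alt == "", "-", alt))
    if (length(desc) == 0 || is.na(desc)) {
      desc <- sprintf("%s:%d%s>%s", tm$id, v$pos, ref, alt)
    }
    mut <- paste0(substr(tm$seq, 1, v$pos - 1), alt,
                  substr(tm$seq, v$pos + nchar(ref), nchar(tm$seq)))
    shift <- nchar(alt) - nchar(ref)
    first_codon <- ceiling(v$pos / 3)
    tr <- translate_cds(mut)
    # stop gain: translation terminates exactly at the first affected codon
    if (!is.na(tr$stop_at) && tr$stop_at == first_codon) {
      return(list(variant = desc, protein = NULL, var_start = NA,
                  var_end = NA, stop_loss = FALSE, skipped = TRUE))
    }
    # stop loss: the reference stop codon region is altered to a non-stop
    ref_stop_nt <- c(3 * l_ref + 1, 3 * l_ref + 3)
    overlaps_stop <- v$pos <= ref_stop_nt[2] &&
      (v$pos + max(nchar(ref), 1) - 1) >= ref_stop_nt[1]
    frame_preserving <- shift %% 3 == 0
    stop_loss <- overlaps_stop && frame_preserving &&
      (is.na(tr$stop_at) || tr$stop_at > l_ref + shift %/% 3 + 1)
    if (stop_loss) {
      prot <- substr(tr$protein, 1, l_ref)   # residues before old stop
      n_extra_avail <- nchar(tr$protein) - l_ref
      extra <- 0L
      while (extra < min(max_extension, n_extra_avail)) {
        codon_idx <- l_ref + 1L + extra      # codon in mutated coordinates
        nt_mut <- (3 * codon_idx - 2):(3 * codon_idx)
        nt_ref <- nt_mut - ifelse(nt_mut > v$pos + nchar(alt) - 1, shift, 0)
        if (any(nt_ref > length(tm$depth)) ||
            any(tm$depth[nt_ref] <= min_depth)) break
        extra <- extra + 1L
      }
      prot <- substr(tr$protein, 1, l_ref + extra)
      return(list(variant = desc, protein = prot, var_start = l_ref + 1,
                  var_end = nchar(prot), stop_loss = TRUE, skipped = FALSE))
    }
    # frame-preserving: only the codons touched by the alt allele (the
    # junction codon for a pure deletion); frameshift: downstream is all new
    var_end <- if (frame_preserving) {
      max(first_codon, ceiling((v$pos + max(nchar(alt), 1) - 1) / 3))
    } else {
      nchar(tr$protein)
    }
    list(variant = desc, protein = tr$protein,
         var_start = first_codon, var_end = min(var_end, nchar(tr$protein)),
         stop_loss = FALSE, skipped = FALSE)
  })
}

# 0-based cleavage positions after K/R not followed by P (trypsin rule);
# boundaries 0 and nchar(s) are implicit peptide ends, not counted as
# missed cleavages.
cleavage_sites <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
}

#' In-silico tryptic digestion around a variant position
#'
#' Cleaves after K/R (never before P) and emits the peptides that span the
#' variant, allowing up to `max_missed` missed cleavages on each side of the
#' variant independently (`n_term_extra_missed` on the N-terminal side for
#' stop-loss products, whose C-terminal region may be truncated by the read
#' depth rule).  Peptides shorter than `min_len` residues are discarded.
#' With `full = TRUE` the variant constraint is dropped and all peptides
#' with at most `max_missed` total missed cleavages are returned.
#'
#' @param protein Protein sequence string.
#' @param var_start,var_end Protein positions of the variant-affected
#'   region (ignored when `full = TRUE`).
#' @param min_len Minimum peptide length, default 8.
#' @param max_missed Missed cleavages allowed per side, default 3.
#' @param n_term_extra_missed N-terminal allowance for stop-loss products,
#'   default 5.
#' @param stop_loss Apply the N-terminal allowance, default `FALSE`.
#' @param full Digest the whole protein irrespective of variants, default
#'   `FALSE`.
#' @return Data frame `peptide`, `start`, `end`, `missed_n`, `missed_c`
#'   (deterministic order: by start, then end).
#' @export
digest <- function(protein, var_start = NULL, var_end = var_start,
                   min_len = 8, max_missed = 3, n_term_extra_missed = 5,
                   stop_loss = FALSE, full = FALSE) {
  if (!nchar(protein)) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_n = integer(),
                      missed_c = integer()))
  }
  n <- nchar(protein)
  bounds <- c(0L, cleavage_sites(protein), n)
  n_allow <- if (stop_loss) n_term_extra_missed else max_missed
  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in (i + 1):length(bounds)) {
      start <- bounds[i] + 1L; end <- bounds[j]
      if (end - start + 1L < min_len) next
      interior <- bounds[bounds > bounds[i] & bounds < bounds[j]]
      if (full) {
        if (length(interior) > max_missed) next
        rows[[length(rows) + 1]] <- data.frame(
          peptide = substr(protein, start, end), start = start, end = end,
          missed_n = length(interior), missed_c = length(interior))
        next
      }
      if (is.null(var_start)) stopf("var_start required unless full = TRUE")
      if (end < var_start || start > var_end) next   # must span the variant
      missed_n <- sum(interior < var_start)
      missed_c <- sum(interior >= var_end)
      if (missed_n > n_allow || missed_c > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        peptide = substr(protein, start, end), start = start, end = end,
        missed_n = missed_n, missed_c = missed_c)
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_n = integer(),
                      missed_c = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Build a sample-specific variant-peptide FASTA database
#'
#' For every expressed transcript (`fpkm > fpkm_min`), applies its variants,
#' translates (skipping stop gains, bounding stop-loss extension by read
#' depth), digests the mutated proteins around the variant positions and
#' writes the de-duplicated peptides as FASTA with provenance headers
#' `transcript|variant|start-end|mcN.M`.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param variants Data frame with columns `transcript`, `pos`, `ref`,
#'   `alt` (and optionally `id`).
#' @param out Optional FASTA output path; when `NULL` nothing is written.
#' @param fpkm_min Expression filter, default 1.
#' @param ... Passed to [digest()] (`min_len`, `max_missed`, ...).
#' @return Data frame of records: `peptide`, `header`, `transcript`,
#'   `variant`, `start`, `end`; invisibly when written to file.
#' @export
build_variant_fasta <- function(transcripts, variants, out = NULL,
                                fpkm_min = 1, ...) {
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  rows <- list()
  for (tm in transcripts) {
    if (tm$fpkm <= fpkm_min) next
    vs <- variants[variants$transcript == tm$id, , drop = FALSE]
    if (!nrow(vs)) next
    trs <- translate_with_variants(tm, vs)
    for (tr in trs) {
      if (tr$skipped || !nchar(tr$protein %||% "")) next
      peps <- digest(tr$protein, var_start = tr$var_start,
                     var_end = tr$var_end, stop_loss = tr$stop_loss, ...)
      if (!nrow(peps)) next
      peps$header <- sprintf("%s|%s|%d-%d|mc%d.%d", tm$id, tr$variant,
                             peps$start, peps$end, peps$missed_n,
                             peps$missed_c)
      peps$transcript <- tm$id
      peps$variant <- tr$variant
      rows[[length(rows) + 1]] <- peps
    }
  }
  if (!length(rows)) {
    db <- data.frame(peptide = character(), start = integer(),
                     end = integer(), missed_n = integer(),
                     missed_c = integer(), header = character(),
                     transcript = character(), variant = character())
  } else {
    db <- do.call(rbind, rows)
    db <- db[!duplicated(db$peptide), , drop = FALSE]
    rownames(db) <- NULL
  }
  if (!is.null(out)) {
    aa <- Biostrings::AAStringSet(setNames(db$peptide, db$header))
    tryCatch(Biostrings::writeXStringSet(aa, filepath = out),
             error = function(e) stopf("failed writing FASTA '%s': %s",
                                       out, conditionMessage(e)))
    return(invisible(db))
  }
  db
}

#' Jaccard coefficient and mutation-based sample distances
#'
#' `jaccard()` computes `|A ∩ B| / |A ∪ B|`; when both sets are empty the
#' coefficient is undefined and `NA` is returned.
#' `mutation_distance_matrix()` turns per-sample mutation sets into the
#' `1 - Jaccard` distance used for DNA-level sample clustering; undefined
#' pairs get distance 1 by convention (with a warning) and the diagonal is
#' 0.
#'
#' @param a,b Character vectors (e.g. mutated gene sets).
#' @return `jaccard()`: a number in `[0, 1]` or `NA`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' @rdname jaccard
#' @param sets Named list of per-sample mutation sets.
#' @return `mutation_distance_matrix()`: symmetric sample x sample distance
#'   matrix.
#' @export
mutation_distance_matrix <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  undefined <- FALSE
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        jc <- jaccard(sets[[i]], sets[[j]])
        if (is.na(jc)) { jc <- 0; undefined <- TRUE }
        d[i, j] <- d[j, i] <- 1 - jc
      }
    }
  }
  if (undefined) warning("pair(s) with two empty sets: distance 1 by convention")
  d
}
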