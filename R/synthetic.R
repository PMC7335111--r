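#' Synthetic cohort configuration
#'
#' Defaults mirror the shape of the discovery cohort: 39 tumors split
#' 26/13 between two latent proteomic subtypes, 1000 proteins measured as
#' log2 GIS ratios across two GIS batches, 20% of proteins carrying a
#' 1-log2-unit subtype shift over Gaussian noise (sd 0.5) with 5% of
#' entries missing completely at random.
#'
#' @param n_samples Total samples, default 39.
#' @param group_sizes Samples per latent subtype, default `c(26, 13)`;
#'   must sum to `n_samples`.
#' @param n_proteins Number of proteins, default 1000.
#' @param n_batches Number of GIS batches (one TMT set each), default 2.
#' @param effect_size Log2 mean shift of subtype-informative proteins,
#'   default 1.0.
#' @param frac_informative Fraction of informative proteins, default 0.2.
#' @param missing_rate Fraction of missing entries, default 0.05.
#' @param noise_sd Per-entry Gaussian sd, default 0.5.
#' @param seed RNG seed, default 1.
#' @return Validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 39, group_sizes = c(26, 13),
                          n_proteins = 1000, n_batches = 2,
                          effect_size = 1.0, frac_informative = 0.2,
                          missing_rate = 0.05, noise_sd = 0.5, seed = 1) {
  if (sum(group_sizes) != n_samples) {
    stopf("group_sizes must sum to n_samples (%d != %d)",
          sum(group_sizes), n_samples)
  }
  if (frac_informative < 0 || frac_informative > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    stopf("fractions must lie in [0, 1]")
  }
  if (n_batches < 1) stopf("n_batches must be >= 1")
  structure(list(n_samples = n_samples, group_sizes = group_sizes,
                 n_proteins = n_proteins, n_batches = n_batches,
                 effect_size = effect_size,
                 frac_informative = frac_informative,
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic TMT proteome cohort
#'
#' Produces a log2-ratio protein x sample matrix with two latent subtypes:
#' informative proteins (a `frac_informative` fraction, alternating
#' direction) differ in expectation by `effect_size` between the groups;
#' all entries carry Gaussian noise and a `missing_rate` fraction is set
#' missing at random.  Samples are assigned round-robin to GIS batches so
#' both subtypes occur in every batch.  Bit-identical for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return List: `matrix` ([intensity_matrix()], log2 state), `labels`
#'   (factor `GPC1`/`GPC2` per sample), `informative` (data frame of
#'   informative protein IDs and shift direction), `batch` (named batch
#'   vector).
#' @export
generate_proteome_bundle <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  with_seed(cf$seed, {
    n_inf <- round(cf$frac_informative * cf$n_proteins)
    proteins <- sprintf("P%04d", seq_len(cf$n_proteins))
    samples <- sprintf("S%02d", seq_len(cf$n_samples))
    labels <- factor(rep(paste0("GPC", seq_along(cf$group_sizes)),
                         cf$group_sizes))
    inf_idx <- seq_len(n_inf)
    dir <- rep_len(c(1, -1), n_inf)          # half up in each subtype
    mu <- matrix(0, cf$n_proteins, cf$n_samples)
    if (n_inf > 0 && nlevels(labels) >= 2) {
      g1 <- labels == levels(labels)[1]
      mu[inf_idx, g1] <- dir * cf$effect_size / 2
      mu[inf_idx, !g1] <- -dir * cf$effect_size / 2
    }
    v <- mu + matrix(rnorm(length(mu), sd = cf$noise_sd), nrow(mu))
    dimnames(v) <- list(proteins, samples)
    if (cf$missing_rate > 0) {
      v[runif(length(v)) < cf$missing_rate] <- NA
    }
    batch <- paste0("batch", rep_len(seq_len(cf$n_batches), cf$n_samples))
    smap <- data.frame(sample = samples,
                       tmt_set = sub("batch", "set", batch),
                       gis_batch = batch, stringsAsFactors = FALSE)
    list(matrix = intensity_matrix(v, state = "log2", samples = smap),
         labels = setNames(labels, samples),
         informative = data.frame(protein = proteins[inf_idx],
                                  direction = dir,
                                  stringsAsFactors = FALSE),
         batch = setNames(batch, samples))
  })
}

#' Generate a synthetic phosphopeptide table with known site truth
#'
#' Each site gets one to three phosphorylation classes (mono/di/tri+), each
#' with a log-normal class intensity per sample and one or two peptides
#' whose intensities average to it.  The per-class ground truth is returned
#' so aggregation can be validated.
#'
#' @param n_sites,n_samples Positive counts.
#' @param seed RNG seed, default 1.
#' @return List: `table` (long data frame `site`, `pclass`, `sample`,
#'   `intensity` at peptide level), `truth` (data frame `site`, `sample`,
#'   `i1`, `i2`, `i3` class-mean intensities, `NA` for absent classes).
#' @export
generate_phosphopeptides <- function(n_sites, n_samples, seed = 1) {
  if (n_sites < 1 || n_samples < 1) stopf("counts must be >= 1")
  with_seed(seed, {
    sites <- sprintf("site%04d", seq_len(n_sites))
    samples <- sprintf("S%02d", seq_len(n_samples))
    rows <- list(); truth <- list()
    for (s in sites) {
      n_cls <- sample(1:3, 1)
      classes <- sort(sample(1:3, n_cls))
      for (sm in samples) {
        ci <- setNames(rep(NA_real_, 3), 1:3)
        for (cl in classes) {
          val <- exp(rnorm(1, mean = log(100), sd = 0.5))
          ci[as.character(cl)] <- val
          n_pep <- sample(1:2, 1)
          # peptide intensities constructed to average exactly to `val`
          pep <- if (n_pep == 1) val else val + c(-1, 1) * val * 0.1
          rows[[length(rows) + 1]] <- data.frame(
            site = s, pclass = cl, sample = sm, intensity = pep,
            stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1]] <- data.frame(
          site = s, sample = sm, i1 = ci["1"], i2 = ci["2"], i3 = ci["3"],
          stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate synthetic single cells for surrogate subtyping
#'
#' Emits a gene x cell matrix of z-scores over the signature genes: i.i.d.
#' standard normal under the null (`signal = 0`, labels `"null"`), or with
#' `signal` added to each cell's own-side signature genes when labeled
#' GPC1/GPC2.
#'
#' @param n_cells Number of cells.
#' @param signature A [signature_set()].
#' @param signal Effect size added to own-side genes, default 0 (null).
#' @param seed RNG seed, default 1.
#' @param proportions Label proportions for `signal > 0`, default
#'   half/half.
#' @return List: `z` (gene x cell matrix), `labels` (character per cell).
#' @export
generate_single_cells <- function(n_cells, signature, signal = 0, seed = 1,
                                  proportions = c(GPC1 = 0.5, GPC2 = 0.5)) {
  stopifnot(inherits(signature, "signature_set"))
  genes <- c(signature$gpc1_high, signature$gpc2_high)
  if (anyDuplicated(genes)) stopf("signature/gene mismatch: duplicated genes")
  with_seed(seed, {
    cells <- sprintf("cell%04d", seq_len(n_cells))
    z <- matrix(rnorm(length(genes) * n_cells), length(genes), n_cells,
                dimnames = list(genes, cells))
    if (signal == 0) {
      labels <- rep("null", n_cells)
    } else {
      n1 <- round(proportions[["GPC1"]] * n_cells)
      labels <- rep(c("GPC1", "GPC2"), c(n1, n_cells - n1))
      z[signature$gpc1_high, labels == "GPC1"] <-
        z[signature$gpc1_high, labels == "GPC1"] + signal
      z[signature$gpc2_high, labels == "GPC2"] <-
        z[signature$gpc2_high, labels == "GPC2"] + signal
    }
    list(z = z, labels = setNames(labels, cells))
  })
}

#' Drug screen configuration
#'
#' @param n_drugs,n_cells Screen dimensions, defaults 5 drugs x 20 cell
#'   lines.
#' @param concentrations Ascending positive dose grid in uM; default seven
#'   log-spaced points topping at the screen's highest tested dose, 20 uM.
#' @param true_4pl Optional data frame of per-(drug, cell) truth columns
#'   `drug`, `cell`, `b`, `c`, `d`, `e`; when `NULL`, truths are drawn with
#'   `b = 1`, `c = 0`, `d = 1` and `e` log-uniform in `[0.1, 10]` uM.
#' @param outlier_rate Fraction of points replaced by high-viability
#'   artifacts, default 0.
#' @param noise_sd Viability noise sd, default 0.05.
#' @param seed RNG seed, default 1.
#' @return Validated `drug_screen_config` list.
#' @export
drug_screen_config <- function(n_drugs = 5, n_cells = 20,
                               concentrations =
                                 10^seq(log10(0.005), log10(20),
                                        length.out = 7),
                               true_4pl = NULL, outlier_rate = 0,
                               noise_sd = 0.05, seed = 1) {
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stopf("concentrations must be positive and strictly increasing")
  }
  if (!is.null(true_4pl) &&
      any(true_4pl$c > true_4pl$d | true_4pl$c < 0)) {
    stopf("true parameters must satisfy 0 <= c <= d")
  }
  structure(list(n_drugs = n_drugs, n_cells = n_cells,
                 concentrations = concentrations, true_4pl = true_4pl,
                 outlier_rate = outlier_rate, noise_sd = noise_sd,
                 seed = seed),
            class = "drug_screen_config")
}

#' Generate a synthetic dose-response screen with known truth
#'
#' Viabilities follow each pair's four-parameter log-logistic truth plus
#' Gaussian noise, clipped at 0; a fraction `outlier_rate` of points is
#' replaced by high-viability artifacts (values in 2.5-4) that satisfy the
#' smoothing-rule conditions within their stratum.
#'
#' @param config A [drug_screen_config()].
#' @return List: `data` (long data frame `drug`, `cell`, `conc_um`,
#'   `viability`, `is_outlier`), `truth` (per-pair 4PL parameters).
#' @export
generate_dose_response <- function(config) {
  stopifnot(inherits(config, "drug_screen_config"))
  cf <- config
  with_seed(cf$seed, {
    drugs <- sprintf("drug%02d", seq_len(cf$n_drugs))
    cells <- sprintf("PDC%02d", seq_len(cf$n_cells))
    truth <- cf$true_4pl %||% {
      grid <- expand.grid(drug = drugs, cell = cells,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$b <- 1; grid$c <- 0; grid$d <- 1
      grid$e <- exp(runif(nrow(grid), log(0.1), log(10)))
      grid
    }
    f4pl <- function(x, b, cc, d, e) cc + (d - cc) / (1 + exp(b * (log(x) - log(e))))
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      v <- f4pl(cf$concentrations, tr$b, tr$c, tr$d, tr$e) +
        rnorm(length(cf$concentrations), sd = cf$noise_sd)
      data.frame(drug = tr$drug, cell = tr$cell,
                 conc_um = cf$concentrations, viability = pmax(v, 0),
                 stringsAsFactors = FALSE)
    })
    dat <- do.call(rbind, rows)
    dat$is_outlier <- FALSE
    if (cf$outlier_rate > 0) {
      out <- runif(nrow(dat)) < cf$outlier_rate
      dat$viability[out] <- runif(sum(out), 2.5, 4)
      dat$is_outlier <- out
    }
    list(data = dat, truth = truth)
  })
}

#' Generate a toy variant-calling fixture
#'
#' Deterministic (seed-stamped) set of hand-shaped transcript models and
#' variant calls covering the four translation rules: a missense SNV, a
#' frame-preserving deletion, a stop-gain SNV (must yield no record) and a
#' stop-loss SNV whose downstream read-depth profile crosses the `> 3`
#' threshold after five codons.
#'
#' @param seed Seed recorded in the fixture (generation itself is
#'   deterministic), default 1.
#' @return List: `transcripts` (list of [transcript_model()]),
#'   `variants` (data frame `transcript`, `pos`, `ref`, `alt`, `class`,
#'   `id`).
#' @export
generate_variant_fixture <- function(seed = 1) {
  aa2nt <- function(aas) {
    # one fixed codon per amino acid keeps the fixture readable
    tab <- c(M = "ATG", K = "AAA", R = "CGT", P = "CCT", L = "CTT",
             A = "GCT", G = "GGT", S = "TCT", T = "ACT", V = "GTT",
             E = "GAA", D = "GAT", F = "TTT", I = "ATT", N = "AAT",
             Q = "CAA", H = "CAT", Y = "TAT", W = "TGG", C = "TGT")
    paste(tab[strsplit(aas, "")[[1]]], collapse = "")
  }
  # t1: missense SNV (L -> P in the middle of a tryptic stretch)
  seq1 <- paste0(aa2nt("MAGSLVTEKALDGSIVRAGSTLNEK"), "TAA")
  # t2: frame-preserving deletion of one codon
  seq2 <- paste0(aa2nt("MSTVAGELKDDLGSVAAARTLSGEK"), "TAA")
  # t3: stop-gain SNV: CAA (Q) -> TAA (stop)
  seq3 <- paste0(aa2nt("MAGTKLVSDQAGSLVEK"), "TAA")
  # t4: stop-loss SNV: TAA -> CAA (Q); downstream codons readable, depth
  #     > 3 for exactly five extra codons, then <= 3
  down4 <- aa2nt("AGSVLDETKW")                  # no stop in extension frame
  seq4 <- paste0(aa2nt("MKAGSTLVDEAAR"), "TAA", down4)
  cds4 <- nchar(seq4) - nchar(down4)
  depth4 <- rep(50L, nchar(seq4))
  depth4[(cds4 - 3 + 1):cds4] <- 50L            # the (mutated) stop codon = extra 1
  # extras are codons at cds positions cds4-2 .. ; extension codons start at
  # the old stop codon itself; give depth > 3 to extras 1-5, <= 3 afterwards
  ext_start_nt <- cds4 - 3 + 1
  depth4[seq(ext_start_nt, ext_start_nt + 5 * 3 - 1)] <- 20L
  depth4[seq(ext_start_nt + 5 * 3, nchar(seq4))] <- 2L
  transcripts <- list(
    transcript_model("t1", seq1, fpkm = 12),
    transcript_model("t2", seq2, fpkm = 8),
    transcript_model("t3", seq3, fpkm = 5),
    transcript_model("t4", seq4, fpkm = 30, depth = depth4),
    transcript_model("t_low", seq1, fpkm = 0.5)   # filtered by expression
  )
  variants <- data.frame(
    transcript = c("t1", "t2", "t3", "t4", "t_low"),
    pos = c(3 * 5 - 1,                      # codon 5 (L: CTT -> CCT = P)
            3 * 10 - 2,                     # delete codon 10 (D)
            3 * 10 - 2,                     # codon 10 CAA -> TAA stop gain
            3 * 13 + 1,                     # t4 stop codon TAA -> CAA
            3 * 5 - 1),
    ref = c("T", "GAT", "C", "T", "T"),
    alt = c("C", "", "T", "C", "C"),
    class = c("SNV", "deletion", "SNV", "SNV", "SNV"),
    id = c("t1_L5P", "t2_delD10", "t3_Q10X", "t4_stoploss", "tlow_snv"),
    stringsAsFactors = FALSE)
  list(transcripts = transcripts, variants = variants, seed = seed)
}
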