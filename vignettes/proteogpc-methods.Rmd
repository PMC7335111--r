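---
title: "Methods: proteomic subtyping and pharmaco-proteogenomics with proteogpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic subtyping and pharmaco-proteogenomics with proteogpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteogpc)
```

proteogpc implements the statistical core of an integrated
pharmaco-proteogenomic analysis of IDH wild-type glioblastoma (GBM): from
TMT reporter-ion intensity matrices normalized against pooled global
internal standards (GIS), through consensus discovery of two proteomic
subtypes (GPC1, Warburg-like; GPC2, OXPHOS-high), to surrogate subtyping of
RNA cohorts and single cells, drug-screen response summaries, and
variant-peptide database construction. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
experiments do and do not demonstrate.

## Quantification model

**GIS normalization.** Each TMT multiplex set carries one channel with a
pooled reference (the GIS). Protein intensities are divided by the GIS
intensity of the same feature in the same set and log2-transformed:
`out[f, s] = log2(raw[f, s] / gis[f, set(s)])`. Ratios to a common pool
make sets comparable; a non-positive GIS entry for a quantified feature is
an error (a ratio would be meaningless), and missing raw values stay
missing — the package carries missingness as `NA` throughout, never as a
sentinel value.

**Median centering** is a single sequential pass: each sample's median over
all features is subtracted first, then, within each GIS batch, each
feature's median over that batch's samples. After the pass every feature's
within-batch median is exactly zero, which is the property that lets two
GIS batches be concatenated. One caveat worth stating: sequential median
sweeps are *not* idempotent — re-running the pass changes values again,
because feature-wise centering disturbs the sample medians. The contract is
one pass; the tests assert the defining zero-median property rather than a
fixed point.

**Imputation** replaces a missing entry by the second-smallest observed
value, by default within the feature's own row. The convention avoids
negative-infinite log ratios while keeping imputed values at the low end of
the feature's observed range. The phrase "second smallest value of all
samples" is ambiguous between a per-feature and a global reading; we
implement per-feature (the only reading that yields magnitudes appropriate
to each feature) and expose `scope = "global"` for the alternative.
Duplicated minima count: the second order statistic of `(5, 5)` is 5.

**GIS-coverage filtering** keeps features observed in at least `min_gis`
GIS groups — all groups for the global proteome, three for the sparser
phosphoproteome. The grouping column is selectable (`gis_batch` by default,
`tmt_set` for per-set counting, which is what an 11-set/2-pool design
implies); the synthetic cohort assigns one set per batch so the two
coincide.

**Phospho-site aggregation.** Phosphopeptides covering one site are first
averaged within each phosphorylation class (mono-, di-, tri-or-more), at
the raw-ratio scale on which the weighting operates. The class intensities
$I_{sn}$ are then combined by the self-weighted sum

$$ I_s = \frac{\sum_n I_{sn}^2}{\sum_n I_{sn}}, $$

which up-weights the class carrying the higher intensity; $I_s$ always lies
between the smallest and largest class value and at or above their
arithmetic mean, and scales linearly with the data. Absent and zero classes
are excluded from both sums (the formula would otherwise degenerate to
0/0); a site/sample with no observed class stays missing. Sites are then
log2-transformed.

## Subtype discovery

Samples are compared by the distance `1 − Pearson r` over pairwise-complete
features and clustered by complete-linkage agglomeration. Consensus
clustering draws `n_iter = 1000` subsamples of 80% of the samples (item
resampling only — the conventional default of consensus implementations),
clusters each, and records for every sample pair the fraction of
co-sampled iterations in which it co-clustered. The *proportion of
ambiguous clustering* (PAC) is the fraction of off-diagonal consensus
values strictly inside `(0.1, 0.9)`; the number of clusters K minimizes PAC
over K = 2..6, with ties broken toward smaller K (parsimony). Pairs never
co-sampled are flagged undefined and excluded from PAC (at 1000 iterations
of 80% subsampling this is a theoretical case only). Final labels come
from complete-linkage clustering of `1 − consensus` at the optimal K; in
pipeline output the larger cluster is named GPC1, matching the 26/13 split
of the discovery cohort.

PCA (via `prcomp`) supports interpretation: the top 10% of features by
absolute PC1 loading — `floor(0.10 · n)`, ties broken by feature ID — is
the input for over-representation analysis, mirroring the 3909 → 390
selection of the original analysis. Cluster–phenotype association uses a
permutation test whose statistic is the fraction of same-phenotype sample
pairs that are co-clustered (the source analysis reports permutation
p-values without naming a statistic; pair purity is a natural choice and is
documented as ours). Because that statistic is discrete at small n, its
null p-values are super-uniform rather than exactly uniform; the tests
check validity (`P(p ≤ a) ≤ a`) rather than a continuous-uniformity fit.

## Differential expression

Two-sided unpaired Student's t-tests (pooled variance; Welch behind a
flag) compare groups per feature, preceded by an advisory Shapiro–Wilk
screen that reports, per group, the fraction of features rejecting
normality at 0.05 without gating anything. Benjamini–Hochberg FDR is used
wherever a correction is unnamed. A DEP is a feature at p < 0.05 — the
selection rule quoted for the original analysis — and the DEPP filter
removes phospho features whose parent protein is a DEP in the same
direction (sign of the mean difference), since those site-level changes
are explained by total protein abundance. Unmapped parents are kept and
flagged. RNA–protein concordance is Spearman's rho per gene over shared
samples with the significantly-positive fraction reported at FDR < 5%.

## Enrichment

Over-representation uses the upper-tail hypergeometric test against an
explicit background, after gene-set filtering (≥ 5 and ≤ 150 genes,
exact-duplicate removal) and the requirement of at least four query hits
per set; BH FDR is computed over tested sets, with 1% and 10% reporting
thresholds exposed as parameters. Enrichment-map edges connect set pairs
with overlap coefficient `|A∩B| / min(|A|,|B|)` of at least 0.5.

Single-sample GSEA walks each sample's genes in decreasing expression
order, accumulating rank-weighted in-set increments (weight
`(N − j + 1)^0.75`, the published ssGSEA default; the source cites the
method without parameters) against uniform out-of-set decrements, and
integrates the running difference. Only ranks enter, so scores are
invariant under strictly monotone transforms of a sample. Raw ES is
reported (range normalization behind a flag). One property worth knowing:
the *rank-weighted* raw ES has a strictly positive mean over random gene
sets, because expected in-set cumulative weight is concave in rank while
the out-of-set decrement is linear; only the unweighted walk (exponent 0)
is exactly centered. Comparisons should therefore be relative (as in
argmax subtype assignment — the representative RNA subtype is the
signature with the maximal ES, ties to the first of the fixed subtype
order, flagged).

## Surrogate subtyping (sGPC)

Signatures are balanced gene lists: `top_n` mode takes the n = 100
smallest-p genes per direction; `fdr` mode takes all genes at q < 0.10,
trimmed to the smaller side. For single-cell targets, candidate genes are
prefiltered to the 1000 most highly expressed in the training cohort and
to genes detected in at least 50% of cells. The per-cell score is

$$ \Delta Z = \mathrm{mean}(Z_{GPC1}) - \mathrm{mean}(Z_{GPC2}), $$

antisymmetric under swapping signature sides and invariant to adding a
constant to all genes. Its p-value comes from 1000 permutations of the
gene labels over the signature union (side sizes preserved), two-sided
with add-one smoothing: `p = (1 + #{|ΔZ*| ≥ |ΔZ|}) / (n_perm + 1)`, so
p ≥ 1/1001 and p = 0 is impossible. A cell is called GPC1 if ΔZ > 0 and
p < 0.05, GPC2 if ΔZ < 0 and p < 0.05, otherwise unassigned. Sidedness of
the call is taken from the sign of ΔZ with a two-sided p — the source
states the threshold but not the sidedness, and two-sided matches calling
either subtype. Z-scores are computed per gene across the cells or samples
under classification (the standard signature convention; per-cell scoring
is available behind a flag since the axis is not stated at the source).

Bulk cohorts without proteomes are classified by a random forest — the
model family used in the original analysis — trained on the top-100-DEG
features after the training and test cohorts are merged and
quantile-normalized (every sample's sorted vector becomes the
mean-of-order-statistics reference, via limma), with `mtry` selected by
internal 5-fold cross-validation. Calls require a winning-class
probability of at least 60%; below that a sample stays unassigned.

## Drug-screen processing

Viability smoothing removes a point only when **both** conditions hold: it
exceeds 1.5 *and* it exceeds `Q3 + 3·IQR` of its (drug, concentration)
stratum across all screened cell lines (type-7 quantiles). Strata smaller
than four points cannot support the IQR rule, so their points are kept and
flagged. A (drug, cell) pair left with no retained point at any
concentration is dropped entirely. The rationale is one-sided: targeted
agents are not expected to raise viability, so only abnormally high points
are artifacts.

AUC is the trapezoid rule of viability against log10 concentration,
normalized by the log10 dose range so a flat fully-viable curve scores 1
on any grid; lower AUC = more sensitive. ED50 comes from a four-parameter
log-logistic fit
`f(x) = c + (d − c)/(1 + exp(b (log x − log e)))`, by Levenberg–Marquardt
least squares with multiple starts of `e` at dose-grid quantiles and
bounds `0 ≤ c`, `d ≤ 1.5` (normalized-viability scale). If the fitted
inflection exceeds the highest tested dose (20 μM), 20 μM is assigned; a
failed fit is likewise assigned the top dose with a status flag, so the
assigned ED50 never exceeds the tested range. A practical identifiability
note: a 7-point grid with viability noise of sd 0.05 supports the
inflection only to roughly 10% relative error — fits initialized at the
true parameters do no better — so finer claims require denser grids or
replicate wells.

Subtype selectivity is a two-sided two-sample Kolmogorov–Smirnov test per
drug on AUC and on assigned ED50, with the sensitive subtype defined by the
lower group mean, skipping groups under three cell lines.
Drug–biomarker association is Spearman's rho between feature abundance and
response across shared cell lines (≥ 5), with BH FDR per metric.

## Variant-peptide databases

Transcripts with FPKM > 1 are mutated one variant at a time (SNV,
insertion, deletion applied at the nucleotide level) and translated with
the standard genetic code. Two special rules: a variant whose first
affected codon becomes a stop (stop gain) emits nothing, since peptides
terminating there are indistinguishable from ordinary enzymatic
termination; a variant destroying the reference stop codon (stop loss)
extends translation by at most 20 extra residues, each requiring read
depth > 3 — taken conservatively at every nucleotide of the codon, since
the source speaks of "translated positions" without fixing the unit — and
stopping earlier at any new stop codon.

Digestion is tryptic (cleave after K/R, never before P — the standard
trypsin exception, adopted where the source is silent). Only peptides
spanning the variant-affected region are emitted, with at most three
missed cleavages allowed on each side of the variant independently (the
literal "both sides" reading); stop-loss products, whose C-terminus may be
truncated by the depth rule, get up to five N-terminal missed cleavages to
avoid short products. Peptides under eight residues are discarded. Records
are de-duplicated by sequence and written as FASTA with provenance headers
(`transcript|variant|start-end|missed-cleavage counts`).

DNA-level sample similarity uses the Jaccard coefficient of mutation sets,
with `1 − J` as the clustering distance; a pair of two empty sets is
undefined and assigned distance 1 by convention, with a warning.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure each stage assumes, at
the shape of the discovery cohort:

* **Proteome cohorts** (default 1000 proteins × 39 samples, 26/13 latent
  subtypes, two GIS batches): informative proteins (20%) separate the
  groups by 1.0 log2 unit in expectation over Gaussian noise (sd 0.5),
  with 5% of entries missing completely at random. Defaults are the
  stated cohort conditions; the noise level gives per-protein effects of
  d ≈ 2, comfortably detectable at n = 26/13, so K-selection recovery
  doubles as a cohort-shaped experiment.
* **Phosphopeptide tables** with one to three classes per site, one or two
  peptides per class constructed to average exactly to the stored class
  truth, enabling aggregation recovery tests.
* **Single cells** as i.i.d. standard-normal z-scores over the signature
  genes (null), optionally with an additive own-side shift — exactly the
  null the permutation calibration requires.
* **Dose-response screens** from 4PL truths (default b = 1, c = 0, d = 1,
  inflections log-uniform in 0.1–10 μM on a 7-point grid topping at
  20 μM, noise sd 0.05), with optional high-viability artifacts drawn in
  2.5–4 so they satisfy both smoothing conditions in realistic strata.
* **Variant fixtures**: hand-shaped transcripts covering a missense SNV,
  an in-frame deletion, a stop gain, and a stop loss whose depth profile
  permits exactly five extra codons.

What passing these tests shows: the stated rules are implemented exactly,
the permutation machinery is calibrated, planted structure of the stated
magnitude is recovered, and every stage is deterministic under a fixed
seed. What it does not show: robustness to batch effects beyond location
shifts, to informative (non-random) missingness, to the heavy-tailed and
zero-inflated intensity distributions of real reporter-ion data, or to
single-cell dropout structure — real cohort properties that the simple
Gaussian/MCAR model deliberately omits.

## Numerical and design choices, collected

* Missingness is an explicit `NA` mask end to end; imputation is the only
  stage that fills it, and only on request.
* Consensus clustering: 80% item subsampling, no feature resampling,
  hierarchical/complete inner clustering on `1 − Pearson` (not k-means),
  K range 2–6, PAC interval (0.1, 0.9), PAC ties toward smaller K.
* Permutation p-values use add-one smoothing everywhere; each routine
  takes an explicit seed, restores the caller's RNG state, and the
  pipeline fans a single global seed out by fixed offsets per stage.
* 4PL fitting: 15 starts (5 inflection quantiles × 3 slopes), bounds
  `c ∈ [0, 1.5]`, `d ∈ [0, 1.5]`, `e` within four decades of the grid;
  best SSE wins; failures are flagged, never silent.
* Equal-variance t by default (the named test), Welch behind a flag; BH
  for all FDR; type-7 quantiles for all IQR computations.
* Degenerate inputs error early with the offending feature or sample
  named: zero-variance samples in correlation distance, non-positive GIS
  entries, rows with fewer than two observations at imputation, signature
  genes absent from a matrix.
* Problem sizes in the test suite (e.g. 100–1000 consensus iterations,
  200–2000 simulated cells, 100 noisy curves) are chosen so every
  statistical bound is tight at desk scale while the full suite stays
  fast.

## Known limitations

* The consensus K selection is validated on planted two-group structure;
  PAC's behavior on genuinely hierarchical or unbalanced structure is not
  exercised.
* Raw ssGSEA scores are comparable within a sample ranking, not across
  differently-sized sets (the positive shift noted above); argmax subtype
  assignment is safe, absolute ES thresholds would not be.
* ED50 precision is grid-limited (see above); assigned ED50 at the cap is
  a censoring convention, not an estimate.
* Variant translation handles one variant at a time; compound haplotypes
  and fusion junctions are out of scope, as are search-engine and PSM-FDR
  stages.
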